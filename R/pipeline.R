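# Pipeline front-end: sequences -> collapse -> translate -> align ->
# diversity -> domain conservation -> tree, with a reproducible run manifest.

#' Create a pipeline run configuration
#'
#' @param input FASTA path of kcv CDSs (in frame, incl. stop codon).
#' @param outdir Output directory (created if missing).
#' @param reference_id Reference isolate id for the difference table and
#'   domain transfer; default: representative of the largest haplotype group.
#' @param seed Integer seed, recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param max_mismatches,min_len,max_len In-silico PCR settings (used by the
#'   `pcr` subcommand).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, outdir, reference_id = NULL, seed = 1L,
                       max_mismatches = 0L, min_len = 200L, max_len = 2000L) {
  structure(list(input = input, outdir = outdir, reference_id = reference_id,
                 seed = as.integer(seed), max_mismatches = as.integer(max_mismatches),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "run_config")
}

#' Run the full diversity pipeline
#'
#' Reads the CDS FASTA, builds the [diversity_report()], aligns the unique
#' proteins, profiles per-domain conservation against the reference, computes
#' the p-distance neighbor-joining tree, and writes the bundle (diversity
#' TSV/JSON, conservation tables, domain BED, Newick tree, aligned FASTA,
#' JSON manifest) under `config$outdir`. All outputs are deterministic for a
#' fixed config, so a rerun reproduces the bundle byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory `report`, `msa`,
#'   `domain_conservation`, `tree` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input)) {
    stop("pipeline stage [input]: no such file: ", config$input, call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  cds <- stage("read", read_fasta(config$input, alphabet = "dna_iupac"))
  report <- stage("diversity", diversity_report(cds, config$reference_id))
  uprot <- lapply(report$protein_groups, `[[`, "representative")
  msa <- if (length(uprot) >= 2L) {
    stage("align", progressive_msa(uprot))
  } else NULL
  ref_id <- report$diff_table$id[match(report$reference_id, report$diff_table$id)]
  if (is.na(ref_id)) ref_id <- report$diff_table$id[1L]
  ref_prot <- uprot[[match(ref_id, vapply(uprot, `[[`, character(1), "id"))]]
  dom_cons <- if (!is.null(msa)) {
    stage("domains", per_domain_conservation(msa, ref_prot$id))
  } else NULL
  annotations <- stage("domains", {
    anns <- lapply(uprot, function(p) {
      tryCatch(annotate_domains(p, ref_prot), error = function(e) NULL)
    })
    names(anns) <- vapply(uprot, `[[`, character(1), "id")
    anns[!vapply(anns, is.null, logical(1))]
  })
  tree <- if (!is.null(msa) && length(msa$ids) >= 3L) {
    stage("tree", neighbor_joining(p_distance_matrix(msa)))
  } else NULL
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outdir, c(
    diversity_tsv = "diversity.tsv", diversity_json = "diversity.json",
    msa = "unique_proteins_aligned.fasta",
    cons = "column_conservation.tsv", dom = "domain_conservation.tsv",
    bed = "domains.bed.tsv", dist = "p_distance.tsv", tree = "tree.nwk",
    manifest = "manifest.json"))
  names(out) <- c("diversity_tsv", "diversity_json", "msa", "cons", "dom",
                  "bed", "dist", "tree", "manifest")
  write_diversity_report(report, file.path(config$outdir, "diversity"))
  if (!is.null(msa)) {
    write_msa_fasta(msa, out["msa"])
    write_conservation_tsv(column_conservation(msa), out["cons"])
    utils::write.table(
      data.frame(domain = names(dom_cons), mean_conservation = unname(dom_cons)),
      out["dom"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_domain_bed(annotations, out["bed"])
  if (!is.null(tree)) {
    write_distance_tsv(p_distance_matrix(msa), out["dist"])
    writeLines(write_newick(tree), out["tree"])
  }
  jsonlite::write_json(list(
    tool = "kcvkit", version = as.character(utils::packageVersion("kcvkit")),
    input = config$input, reference_id = ref_id, seed = config$seed,
    parameters = list(max_mismatches = config$max_mismatches,
                      min_len = config$min_len, max_len = config$max_len),
    outputs = as.list(basename(unname(out)))
  ), out["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, msa = msa, domain_conservation = dom_cons,
                 tree = tree, paths = out))
}

# ---- command-line front-end -------------------------------------------------

.cli_args <- function(argv, defaults) {
  vals <- defaults
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (!key %in% names(vals)) stop("unknown flag --", key, call. = FALSE)
    if (i == length(argv)) stop("flag --", key, " needs a value", call. = FALSE)
    vals[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  vals
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write a synthetic family), `pcr` (evaluate the primer
#' panel), `collapse`, `align`, `diversity`, `tree`, `channel-sim`,
#' `channel-analyze`, and `run` (the full pipeline). Invoke through the
#' `inst/scripts/kcvkit.R` front-end, e.g.
#' `Rscript kcvkit.R run --input family_cds.fasta --outdir out --seed 1`.
#'
#' @param argv Character vector of command-line arguments (subcommand first).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message("usage: kcvkit <synth|pcr|collapse|align|diversity|tree|",
            "channel-sim|channel-analyze|run> [--flags]")
    return(invisible(1L))
  }
  cmd <- argv[1L]
  argv <- argv[-1L]
  status <- tryCatch({
    switch(cmd,
      synth = {
        a <- .cli_args(argv, list(seed = "1", out = "family", preset = "paper-like"))
        fam <- generate_family(family_config(seed = as.integer(a$seed)))
        write_family(fam, a$out)
      },
      pcr = {
        a <- .cli_args(argv, list(input = NULL, primers = "", out = "panel.tsv",
                                  `max-mismatches` = "0", `min-len` = "200",
                                  `max-len` = "2000"))
        panel <- if (nzchar(a$primers)) read_primer_panel(a$primers) else kcv_primer_panel()
        templates <- read_fasta(a$input, "dna_iupac")
        fwd <- Filter(function(p) p$orientation == "forward", panel)
        rev <- Filter(function(p) p$orientation == "reverse", panel)
        rep <- evaluate_panel(fwd, rev, templates,
                              max_mismatches = as.integer(a$`max-mismatches`),
                              min_len = as.integer(a$`min-len`),
                              max_len = as.integer(a$`max-len`))
        write_panel_report(rep, a$out)
      },
      collapse = {
        a <- .cli_args(argv, list(input = NULL, out = "groups.tsv"))
        groups <- collapse_unique(read_fasta(a$input, "dna_iupac"))
        utils::write.table(data.frame(
          representative = vapply(groups, function(g) g$representative$id, character(1)),
          count = vapply(groups, `[[`, integer(1), "count"),
          members = vapply(groups, function(g) paste(g$member_ids, collapse = ","),
                           character(1))),
          a$out, sep = "\t", quote = FALSE, row.names = FALSE)
      },
      align = {
        a <- .cli_args(argv, list(input = NULL, alphabet = "protein",
                                  out = "aligned.fasta"))
        seqs <- read_fasta(a$input, a$alphabet)
        write_msa_fasta(progressive_msa(seqs), a$out)
      },
      diversity = {
        a <- .cli_args(argv, list(input = NULL, reference = "", out = "diversity"))
        ref <- if (nzchar(a$reference)) a$reference else NULL
        write_diversity_report(diversity_report(read_fasta(a$input, "dna_iupac"),
                                                ref), a$out)
      },
      tree = {
        a <- .cli_args(argv, list(input = NULL, alphabet = "protein",
                                  out = "tree.nwk", dist = ""))
        msa <- read_msa_fasta(a$input, a$alphabet)
        dm <- p_distance_matrix(msa)
        if (nzchar(a$dist)) write_distance_tsv(dm, a$dist)
        writeLines(write_newick(neighbor_joining(dm)), a$out)
      },
      `channel-sim` = {
        a <- .cli_args(argv, list(gamma = "87", voltage = "80", kco = "20",
                                  koc = "20", seed = "1", out = "trace.tsv"))
        model <- gating_model(k0_open = as.numeric(a$kco),
                              k0_close = as.numeric(a$koc),
                              gamma_pS = as.numeric(a$gamma))
        write_trace(simulate_trace(model, as.numeric(a$voltage),
                                   sim_config(seed = as.integer(a$seed))),
                    a$out)
      },
      `channel-analyze` = {
        a <- .cli_args(argv, list(input = NULL, out = "estimate"))
        # --input takes comma-separated trace files across voltages
        traces <- lapply(strsplit(a$input, ",")[[1L]], read_trace)
        write_channel_estimate(iv_and_conductance(traces), a$out)
      },
      run = {
        a <- .cli_args(argv, list(input = NULL, outdir = "kcvkit_run",
                                  reference = "", seed = "1"))
        ref <- if (nzchar(a$reference)) a$reference else NULL
        run_pipeline(run_config(a$input, a$outdir, reference_id = ref,
                                seed = as.integer(a$seed)))
      },
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("kcvkit ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
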