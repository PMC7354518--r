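# kcvkit

Chloroviruses — large dsDNA viruses infecting chlorella-like green algae —
carry *kcv* genes encoding miniature potassium channels (Kcv). The SAG-virus
Kcv is one of the smallest known functional K⁺ channels: an ~82-residue
subunit with two transmembrane helices (TMD1/TMD2) flanking an extracellular
turret, a pore helix, and the selectivity-filter octapeptide (TTVGYGDL and
relatives). `kcvkit` is an R toolkit for the two halves of a *kcv* diversity
study:

1. **Sequence survey** — degenerate-primer in-silico PCR with IUPAC ambiguity
   codes, unique-haplotype collapse with multiplicity accounting, translation,
   progressive multiple alignment, domain-aware conservation profiling,
   pairwise divergence vs a reference channel, and a p-distance
   neighbor-joining phylogeny with Newick output.
2. **Single-channel electrophysiology** — a two-state Markov gating simulator
   (`closed ⇌ open`, rates `k(V) = k₀·e^{sV}`), half-amplitude idealization,
   open-probability estimation (`Po = k_co/(k_co + k_oc)` at stationarity),
   and the I/V regression that yields the unitary conductance
   `γ = i(V)/(V − V_rev)` in pS — including the flicker-gating artifact, where
   open/close transitions faster than the recording bandwidth depress the
   apparent conductance of the negative branch.

A seeded synthetic-family generator (`generate_family()`) emits kcv-like gene
families with known ground truth (haplotype multiplicities, turret-insertion
and C-terminal-extension lineages, primer-compatible flanks), so the whole
pipeline is testable without any downloads.

## Worked example

```r
library(kcvkit)

fam <- generate_family(family_config(seed = 1))   # 103 synthetic isolates
rep <- diversity_report(fam$cds)
print(rep)
#> Kcv diversity report
#>   isolates:        103
#>   unique DNA:      42
#>   unique proteins: 26
#>   variable sites:  154 of 249 (modal length class)
#>   protein lengths: 82 aa x 19, 84 aa x 4, 85 aa x 2, 90 aa x 1
#>   filter motifs:   TTVGYGDL x 26
```

103 isolates collapse to 42 unique DNA haplotypes which translate to 26
unique proteins — the generator's planted ground truth (`fam$truth`), which
the report recovers exactly. Domain conservation over the aligned unique
proteins shows the canonical ranking — filter perfectly conserved,
transmembrane helices most variable:

```r
uprot <- lapply(rep$protein_groups, `[[`, "representative")
msa <- progressive_msa(uprot)
round(per_domain_conservation(msa, rep$reference_id), 3)
#> slide_helix        TMD1      turret  pore_helix      filter        TMD2      c_tail
#>          NA       0.836       0.931       0.900       1.000       0.824       0.933
```

Single-channel conductance recovery with slow (resolved) gating at ±40…±120 mV:

```r
models <- flicker_reference_models(gamma_pS = 87)
traces <- lapply(c(-120, -80, -40, 40, 80, 120), function(V)
  simulate_trace(models$slow, V, sim_config(seed = 100 + V)))
iv_and_conductance(traces)
#> <channel_estimate gamma = 86.5 +/- 0.1 pS (fit over 40, 80, 120 mV)>
#>  voltage          i      Po
#>     -120 -10.406444 0.49788
#>      -80  -6.934587 0.45494
#>      -40  -3.466235 0.47756
#>       40   3.452084 0.55468
#>       80   6.912813 0.41710
#>      120  10.390578 0.47226
```

The fitted slope over the positive branch recovers the generating 87 pS to
better than 1%; `i` is the open-channel current in pA and `Po` the fraction
of time spent open (0.5 here, since `k_co = k_oc`). Swapping in
`models$fast` and a 1 kHz filter reproduces the flicker artifact
(`flicker_artifact_check()`): the apparent negative-branch conductance drops
to roughly a third of the true γ while the positive branch is unaffected.

## Command line

```sh
Rscript inst/scripts/kcvkit.R synth --seed 1 --out family
Rscript inst/scripts/kcvkit.R run --input family_cds.fasta --outdir out --seed 1
Rscript inst/scripts/kcvkit.R pcr --input family_flanked.fasta --out panel.tsv
```

Subcommands: `synth`, `pcr`, `collapse`, `align`, `diversity`, `tree`,
`channel-sim`, `channel-analyze`, `run`.

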