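# Two-state Markov single-channel gating: simulation of current traces,
# half-amplitude idealization, open probability, I/V and unitary conductance,
# and the flicker-gating bandwidth artifact.

#' Create a two-state gating model
#'
#' Closed <-> open kinetics with voltage-dependent rates
#' `k(V) = k0 * exp(s * V)` (k0 in 1/s, s in 1/mV; s = 0 gives
#' voltage-independent gating), unitary conductance `gamma` in pS and a
#' reversal potential in mV (0 under symmetric K+ solutions). The open-state
#' current at voltage V is `gamma * (V - reversal) / 1000` pA; the closed
#' level is 0.
#'
#' @param k0_open,s_open Opening-rate parameters (closed -> open).
#' @param k0_close,s_close Closing-rate parameters (open -> closed).
#' @param gamma_pS Unitary conductance, pS (> 0).
#' @param reversal_mV Reversal potential, mV.
#' @return Object of class `gating_model`.
#' @export
gating_model <- function(k0_open, s_open = 0, k0_close, s_close = 0,
                         gamma_pS, reversal_mV = 0) {
  stopifnot(k0_open > 0, k0_close > 0, gamma_pS > 0)
  structure(list(k0_open = k0_open, s_open = s_open,
                 k0_close = k0_close, s_close = s_close,
                 gamma_pS = gamma_pS, reversal_mV = reversal_mV),
            class = "gating_model")
}

#' Gating rates of a model at a voltage
#' @param model A [gating_model()].
#' @param V Voltage, mV.
#' @return List with `k_co` (opening) and `k_oc` (closing), 1/s.
#' @export
gating_rates <- function(model, V) {
  list(k_co = model$k0_open * exp(model$s_open * V),
       k_oc = model$k0_close * exp(model$s_close * V))
}

#' Simulation configuration
#'
#' Defaults follow typical planar-bilayer acquisition: 5 kHz sampling, 10 s
#' sweeps, 1 pA RMS baseline noise and a 4-pole 1 kHz low-pass (implemented as
#' cascaded single-pole sections). Set `filter_corner = NULL` to disable
#' filtering.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Sweep duration, s (`fs * duration >= 1000` samples).
#' @param noise_sd Gaussian noise SD per sample, pA (added before filtering).
#' @param filter_corner Low-pass corner frequency, Hz, or `NULL`.
#' @param filter_poles Number of cascaded single-pole sections.
#' @param seed Integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(fs = 5000, duration = 10, noise_sd = 1,
                       filter_corner = 1000, filter_poles = 4L, seed = 1L) {
  stopifnot(fs > 0, duration > 0, round(fs * duration) >= 1000)
  if (!is.null(filter_corner) && fs <= 2 * filter_corner) {
    stop("fs must exceed twice the filter corner", call. = FALSE)
  }
  structure(list(fs = fs, duration = duration, noise_sd = noise_sd,
                 filter_corner = filter_corner, filter_poles = as.integer(filter_poles),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# cascaded single-pole low-pass sections
.lowpass <- function(x, fs, corner, poles) {
  rc <- 1 / (2 * pi * corner)
  dt <- 1 / fs
  alpha <- dt / (rc + dt)
  for (p in seq_len(poles)) {
    x <- stats::filter(alpha * x, filter = 1 - alpha, method = "recursive")
  }
  as.numeric(x)
}

#' Simulate a single-channel current trace
#'
#' A continuous-time two-state Markov chain is drawn by exponential dwell
#' times at the voltage-dependent rates (seeded; the initial state is drawn
#' from the stationary distribution), sampled at `fs`, converted to current
#' (open level `gamma * (V - reversal) / 1000` pA, closed 0), Gaussian noise
#' added per sample, and optionally low-pass filtered. The hidden per-sample
#' state sequence is retained for validation against the idealizer.
#'
#' @param model A [gating_model()].
#' @param V Holding voltage, mV.
#' @param config A [sim_config()].
#' @return Object of class `channel_trace`: list with `voltage`, `fs`,
#'   `current` (pA), `state` (0 closed / 1 open per sample), `open_level`
#'   (noise-free open current, pA), `config`.
#' @export
simulate_trace <- function(model, V, config = sim_config()) {
  stopifnot(inherits(model, "gating_model"), inherits(config, "sim_config"))
  rates <- gating_rates(model, V)
  if (!is.finite(rates$k_co) || !is.finite(rates$k_oc) ||
      rates$k_co <= 0 || rates$k_oc <= 0) {
    stop("rates must be positive and finite at V = ", V, call. = FALSE)
  }
  set.seed(config$seed)
  n <- round(config$fs * config$duration)
  p_open <- rates$k_co / (rates$k_co + rates$k_oc)
  state0 <- as.integer(stats::runif(1) < p_open)
  # draw alternating exponential dwells until the sweep is covered
  mean_rate <- 2 / (1 / rates$k_co + 1 / rates$k_oc)
  dwells <- numeric(0); states <- integer(0)
  total <- 0; cur <- state0
  while (total < config$duration) {
    chunk <- max(64L, ceiling((config$duration - total) * mean_rate * 1.5))
    # dwell in state s ends at the rate of leaving s
    add_states <- (cur + seq_len(chunk) - 1L) %% 2L
    leave <- ifelse(add_states == 1L, rates$k_oc, rates$k_co)
    add <- stats::rexp(chunk, rate = leave)
    dwells <- c(dwells, add); states <- c(states, add_states)
    total <- total + sum(add)
    cur <- 1L - add_states[chunk]
  }
  ends <- pmin(round(cumsum(dwells) * config$fs), n)
  counts <- diff(c(0L, ends))
  keep <- counts > 0L
  state <- rep(states[keep], counts[keep])
  if (length(state) < n) state <- c(state, rep(state[length(state)], n - length(state)))
  state <- state[seq_len(n)]
  open_level <- model$gamma_pS * (V - model$reversal_mV) / 1000
  current <- state * open_level + stats::rnorm(n, 0, config$noise_sd)
  if (!is.null(config$filter_corner)) {
    current <- .lowpass(current, config$fs, config$filter_corner, config$filter_poles)
  }
  structure(list(voltage = V, fs = config$fs, current = current,
                 state = state, open_level = open_level, config = config),
            class = "channel_trace")
}

# flip runs shorter than min_len into their neighbours until stable
.merge_short_events <- function(cls, min_len, max_pass = 50L) {
  for (pass in seq_len(max_pass)) {
    r <- rle(cls)
    if (length(r$lengths) <= 1L || all(r$lengths >= min_len)) break
    short <- r$lengths < min_len
    # never flip everything at once: keep the longest run fixed
    short[which.max(r$lengths)] <- FALSE
    r$values[short] <- 1L - r$values[short]
    cls <- inverse.rle(r)
    r2 <- rle(cls)  # adjacent equal runs merge implicitly on next rle
    cls <- inverse.rle(r2)
  }
  cls
}

#' Idealize a trace by half-amplitude threshold
#'
#' The two current levels are first estimated by two-class 1-D k-means on the
#' sample amplitudes (deterministic initialization at the 5th and 95th
#' percentiles); samples are classified against the midpoint threshold; events
#' shorter than `min_event_samples` are merged into their neighbours; if both
#' states survive merging, the levels are re-estimated as segment means with
#' `edge_trim` samples dropped at each dwell boundary (to avoid filter-rise
#' bias). The open level is the level of larger absolute amplitude, so the
#' convention works at both polarities.
#'
#' @param trace A `channel_trace` (or any list with `current`).
#' @param min_event_samples Shortest believable event, in samples.
#' @param edge_trim Samples ignored at each end of a dwell for level
#'   estimation.
#' @param single_level Flag stating the trace holds a single level (no
#'   gating); it is then returned as one segment, open iff its mean amplitude
#'   is distinguishable from zero.
#' @return Object of class `idealized_trace`: `segments` (data.frame `state`
#'   in {"closed","open"}, `n_samples`), `open_level`, `closed_level`,
#'   `state` (per-sample 0/1).
#' @export
idealize <- function(trace, min_event_samples = 5L, edge_trim = 2L,
                     single_level = FALSE) {
  x <- trace$current
  n <- length(x)
  if (single_level) {
    lev <- mean(x)
    is_open <- abs(lev) > 2 * stats::sd(x) || (stats::sd(x) == 0 && abs(lev) > 0)
    seg <- data.frame(state = if (is_open) "open" else "closed", n_samples = n)
    return(structure(list(segments = seg,
                          open_level = if (is_open) lev else NA_real_,
                          closed_level = if (is_open) NA_real_ else lev,
                          state = rep(as.integer(is_open), n)),
                     class = "idealized_trace"))
  }
  if (stats::sd(x) == 0) stop("degenerate all-constant trace", call. = FALSE)
  centers <- unique(stats::quantile(x, c(0.05, 0.95), names = FALSE))
  if (length(centers) < 2L) centers <- range(x)
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(sort(centers), ncol = 1)))
  lev <- sort(as.numeric(km$centers))
  thr <- mean(lev)
  cls <- as.integer(x > thr)  # 1 = upper level
  cls <- .merge_short_events(cls, min_event_samples)
  # map upper/lower to open/closed: open = larger |level|
  upper_is_open <- abs(lev[2L]) >= abs(lev[1L])
  open_cls <- if (upper_is_open) cls else 1L - cls
  r <- rle(open_cls)
  seg <- data.frame(state = ifelse(r$values == 1L, "open", "closed"),
                    n_samples = r$lengths)
  open_level <- lev[if (upper_is_open) 2L else 1L]
  closed_level <- lev[if (upper_is_open) 1L else 2L]
  if (length(unique(open_cls)) == 2L) {
    # refine levels from trimmed segments
    bounds <- cumsum(r$lengths)
    starts <- c(1L, utils::head(bounds, -1L) + 1L)
    vals <- rep(NA_real_, length(r$lengths))
    for (k in seq_along(r$lengths)) {
      s <- starts[k] + edge_trim; e <- bounds[k] - edge_trim
      if (e >= s) vals[k] <- mean(x[s:e])
    }
    ow <- r$values == 1L & !is.na(vals)
    cw <- r$values == 0L & !is.na(vals)
    if (any(ow)) open_level <- sum(vals[ow] * r$lengths[ow]) / sum(r$lengths[ow])
    if (any(cw)) closed_level <- sum(vals[cw] * r$lengths[cw]) / sum(r$lengths[cw])
  }
  structure(list(segments = seg, open_level = open_level,
                 closed_level = closed_level, state = open_cls),
            class = "idealized_trace")
}

#' Open probability of an idealized trace
#'
#' Fraction of samples assigned to the open state.
#'
#' @param ideal An `idealized_trace`.
#' @return Po in `[0, 1]`.
#' @export
open_probability <- function(ideal) {
  tot <- sum(ideal$segments$n_samples)
  sum(ideal$segments$n_samples[ideal$segments$state == "open"]) / tot
}

#' I/V relation and unitary conductance from a set of traces
#'
#' Each trace is idealized; the single-channel current at its voltage is the
#' open minus the closed level. The unitary conductance gamma is the slope
#' (in pS) of the least-squares line through the origin fitted over
#' `fit_range` (default: the positive voltages only, because unresolved
#' flicker gating makes the negative branch an apparent, biased conductance).
#'
#' @param traces List of `channel_trace` objects across voltages.
#' @param fit_range Voltages used in the conductance fit; default all positive
#'   voltages present.
#' @param ... Passed to [idealize()].
#' @return Object of class `channel_estimate`: `iv` (data.frame voltage, i
#'   (pA), Po; one row per voltage, replicates averaged), `gamma_pS`,
#'   `gamma_se`, `fit_range`.
#' @export
iv_and_conductance <- function(traces, fit_range = NULL, ...) {
  volts <- vapply(traces, `[[`, numeric(1), "voltage")
  if (is.null(fit_range)) fit_range <- sort(unique(volts[volts > 0]))
  if (length(fit_range) < 2L) {
    stop("need at least 2 distinct voltages in fit_range", call. = FALSE)
  }
  if (!all(fit_range %in% volts)) {
    stop("fit_range voltages missing from data", call. = FALSE)
  }
  per <- lapply(traces, function(tr) {
    id <- idealize(tr, ...)
    c(i = id$open_level - id$closed_level, Po = open_probability(id))
  })
  df <- data.frame(voltage = volts,
                   i = vapply(per, `[`, numeric(1), "i"),
                   Po = vapply(per, `[`, numeric(1), "Po"))
  iv <- stats::aggregate(cbind(i, Po) ~ voltage, data = df, FUN = mean)
  iv <- iv[order(iv$voltage), , drop = FALSE]
  fit <- df[df$voltage %in% fit_range, , drop = FALSE]
  # slope through the origin, pA/mV -> nS; *1000 -> pS
  slope <- sum(fit$i * fit$voltage) / sum(fit$voltage^2)
  resid <- fit$i - slope * fit$voltage
  dof <- max(nrow(fit) - 1L, 1L)
  se <- sqrt(sum(resid^2) / dof / sum(fit$voltage^2))
  structure(list(iv = iv, gamma_pS = 1000 * slope, gamma_se = 1000 * se,
                 fit_range = fit_range),
            class = "channel_estimate")
}

#' @export
print.channel_estimate <- function(x, ...) {
  cat(sprintf("<channel_estimate gamma = %.1f +/- %.1f pS (fit over %s mV)>\n",
              x$gamma_pS, x$gamma_se, paste(x$fit_range, collapse = ", ")))
  print(x$iv, row.names = FALSE)
  invisible(x)
}

#' Demonstrate the flicker-gating conductance artifact
#'
#' Simulates a fast-gating and a slow-gating model over a symmetric voltage
#' set under a recording filter and compares the apparent conductance of the
#' negative branch with the conductance fitted on the positive branch. Fast
#' open/close transitions beyond the filter bandwidth depress the apparent
#' open level, so the fast model's negative-branch conductance falls below
#' the fitted gamma while the slow model's does not.
#'
#' @param model_fast Model with unresolvably fast gating at negative voltages.
#' @param model_slow Model with resolved gating at all voltages.
#' @param config A [sim_config()] including the filter.
#' @param voltages Symmetric voltage set, mV.
#' @return List with per-model apparent `|i(V)|` tables, fitted positive-branch
#'   gammas, negative/positive apparent-conductance ratios (`ratio_fast`,
#'   `ratio_slow`), and the flags `artifact_fast` (ratio_fast well below 1)
#'   and `no_artifact_slow`.
#' @export
flicker_artifact_check <- function(model_fast, model_slow,
                                   config = sim_config(),
                                   voltages = c(-120, -80, -40, 40, 80, 120)) {
  run <- function(model) {
    traces <- lapply(seq_along(voltages), function(k) {
      cfg <- config
      cfg$seed <- config$seed + k
      simulate_trace(model, voltages[k], cfg)
    })
    est <- iv_and_conductance(traces)
    neg <- est$iv[est$iv$voltage < 0, , drop = FALSE]
    g_neg <- 1000 * sum(neg$i * neg$voltage) / sum(neg$voltage^2)
    list(iv = est$iv, gamma_pos = est$gamma_pS, gamma_neg_apparent = g_neg,
         ratio = g_neg / est$gamma_pS)
  }
  fast <- run(model_fast)
  slow <- run(model_slow)
  list(fast = fast, slow = slow,
       ratio_fast = fast$ratio, ratio_slow = slow$ratio,
       artifact_fast = fast$ratio < 0.8,
       no_artifact_slow = abs(slow$ratio - 1) < 0.15)
}

#' Reference gating models for recovery and flicker tests
#'
#' `slow` gates at a voltage-independent 20/s in both directions (dwell times
#' of 50 ms, fully resolved at a 1 kHz recording bandwidth), the regime used
#' for conductance-recovery checks. `fast` keeps the equilibrium (Po = 0.5)
#' but accelerates both rates e-fold per ~29 mV of hyperpolarization so that
#' gating is ~20/s at +80 mV but ~5000/s at -80 mV — unresolvable at 1 kHz,
#' which produces the flicker artifact: an apparent conductance drop on the
#' negative branch of the I/V relation.
#'
#' @param gamma_pS Unitary conductance of both models, pS.
#' @return List with elements `slow` and `fast` ([gating_model()]s).
#' @export
flicker_reference_models <- function(gamma_pS = 87) {
  s <- -log(250) / 160  # 20/s at +80 mV -> 5000/s at -80 mV
  k0 <- 20 / exp(s * 80)
  list(slow = gating_model(k0_open = 20, k0_close = 20, gamma_pS = gamma_pS),
       fast = gating_model(k0_open = k0, s_open = s, k0_close = k0, s_close = s,
                           gamma_pS = gamma_pS))
}

#' Write a trace as two-column delimited text
#'
#' Columns `time_s`, `current_pA`, preceded by `#` header comments carrying
#' the voltage and sampling rate.
#'
#' @param trace A `channel_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# voltage_mV=%g fs_Hz=%g", trace$voltage, trace$fs), con)
  writeLines("time_s\tcurrent_pA", con)
  t <- (seq_along(trace$current) - 1L) / trace$fs
  writeLines(sprintf("%.6f\t%.6g", t, trace$current), con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#' @param path Input path.
#' @return A `channel_trace` (without hidden state).
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  v <- as.numeric(sub(".*voltage_mV=([-0-9.eE+]+).*", "\\1", header))
  fs <- as.numeric(sub(".*fs_Hz=([-0-9.eE+]+).*", "\\1", header))
  tab <- utils::read.delim(path, comment.char = "#")
  structure(list(voltage = v, fs = fs, current = tab$current_pA,
                 state = NULL, open_level = NA_real_, config = NULL),
            class = "channel_trace")
}

#' Write a channel estimate as TSV plus JSON summary
#' @param est A `channel_estimate`.
#' @param stem Output path stem.
#' @export
write_channel_estimate <- function(est, stem) {
  utils::write.table(est$iv, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(gamma_pS = est$gamma_pS, gamma_se = est$gamma_se,
                            fit_range = est$fit_range),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
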