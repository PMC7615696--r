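# Synthetic reference hemoglobin traces with the experimentally described
# morphology, plus trace-comparison metrics. The references are SYNTHETIC
# stand-ins for unpublished mouse 2D-OIS data: they reproduce the qualitative
# shape of each condition (not measured values) and exist to exercise the
# comparison tooling and qualitative checks.

# Peak-normalized gamma kernel: 0 before `onset`, rises to 1 at
# onset + (shape-1)*scale seconds, then decays. Analytic peak normalization
# keeps the shape independent of the sampling grid.
gamma_kernel <- function(t_ms, onset_s, shape, scale_s) {
  x <- pmax(t_ms / 1000 - onset_s, 0)
  peak <- stats::dgamma((shape - 1) * scale_s, shape = shape, scale = scale_s)
  stats::dgamma(x, shape = shape, scale = scale_s) / peak
}

# Noise-free per-condition templates (fractional changes). HbT is always
# built as HbO + HbR so conservation holds by construction.
reference_template <- function(t_ms, condition, lname, t0 = 1000,
                               duration = 2000) {
  on_s <- (t0 + 300) / 1000  # 300 ms hemodynamic onset lag
  fast <- gamma_kernel(t_ms, on_s, shape = 3, scale_s = 0.35)  # peak ~0.7 s
  slow <- gamma_kernel(t_ms, on_s, shape = 3, scale_s = 1.00)  # peak ~2 s
  if (condition == "whisker") {
    hbo <- 0.060 * slow
    hbr <- -0.030 * gamma_kernel(t_ms, on_s + 0.2, shape = 3, scale_s = 1.1)
  } else if (!lname) {
    # early NPY-driven dip (HbR up, HbO down), then GABA-driven dilation
    hbo <- -0.020 * fast + 0.045 * gamma_kernel(t_ms, on_s + 0.8, 3, 1.1)
    hbr <- 0.010 * fast - 0.020 * gamma_kernel(t_ms, on_s + 0.9, 3, 1.2)
  } else {
    # constriction-dominated: NPY pathway unopposed once GABA degrades
    hbo <- -0.045 * slow
    hbr <- 0.018 * slow
  }
  list(hbo = hbo, hbr = hbr, hbt = hbo + hbr)
}

#' Generate a synthetic reference hemoglobin trace
#'
#' Deterministic condition-specific template (difference of gamma kernels)
#' plus seeded Gaussian trial noise averaged over \code{n_trials}
#' pseudo-trials, mimicking a trial-averaged mean +/- s.d. recording. HbT is
#' constructed as HbO + HbR within each pseudo-trial, so the mean trace obeys
#' hemoglobin conservation exactly.
#'
#' @param condition \code{"whisker"} or \code{"optogenetic"}.
#' @param lname logical; NOS-blockade variant of the template.
#' @param seed integer RNG seed; same seed gives an identical trace.
#' @param noise_sd per-sample trial noise s.d. (fractional-change units,
#'   >= 0).
#' @param t output time grid, ms.
#' @param t0,duration stimulus window used by the template, ms.
#' @param n_trials number of pseudo-trials averaged.
#' @return A \code{reference_trace}: data.frame with columns \code{t_ms},
#'   \code{mean_d_hbo}, \code{mean_d_hbr}, \code{mean_d_hbt}, \code{sd_d_hbo},
#'   \code{sd_d_hbr}, \code{sd_d_hbt}.
#' @export
#' @examples
#' ref <- make_reference("optogenetic", lname = FALSE, seed = 1)
#' head(ref)
make_reference <- function(condition = c("whisker", "optogenetic"),
                           lname = FALSE, seed = 1L, noise_sd = 0.005,
                           t = seq(0, 21000, by = 10),
                           t0 = 1000, duration = 2000, n_trials = 12L) {
  condition <- match.arg(condition)
  if (noise_sd < 0) stop_invalid_parameter("noise_sd must be >= 0")
  tmpl <- reference_template(t, condition, lname, t0, duration)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  n <- length(t)
  hbo_tr <- matrix(tmpl$hbo, n, n_trials) +
    matrix(stats::rnorm(n * n_trials, sd = noise_sd), n, n_trials)
  hbr_tr <- matrix(tmpl$hbr, n, n_trials) +
    matrix(stats::rnorm(n * n_trials, sd = noise_sd), n, n_trials)
  hbt_tr <- hbo_tr + hbr_tr
  sd_or_0 <- function(m) if (noise_sd == 0) numeric(n) else apply(m, 1L, stats::sd)
  ref <- data.frame(
    t_ms = t,
    mean_d_hbo = rowMeans(hbo_tr), mean_d_hbr = rowMeans(hbr_tr),
    mean_d_hbt = rowMeans(hbt_tr),
    sd_d_hbo = sd_or_0(hbo_tr), sd_d_hbr = sd_or_0(hbr_tr),
    sd_d_hbt = sd_or_0(hbt_tr))
  structure(ref, class = c("reference_trace", "data.frame"),
            condition = condition, lname = lname, seed = as.integer(seed),
            noise_sd = noise_sd, synthetic = TRUE)
}

#' Compare a simulated trace against a reference trace
#'
#' Linearly resamples the simulation onto the reference time grid (restricted
#' to the overlap) and reports, per hemoglobin channel: root-mean-square error
#' against the reference mean, peak-amplitude error (simulated peak minus
#' reference peak, peaks taken at maximal absolute excursion), peak-time error
#' (ms), and band-coverage — the fraction of samples where the simulation
#' lies within the reference mean +/- s.d. band.
#'
#' @param sim a \code{hemo_trace} (or data.frame with \code{t_ms},
#'   \code{d_hbo}, \code{d_hbr}, \code{d_hbt}).
#' @param ref a \code{reference_trace} (or data.frame with the
#'   \code{mean_*}/\code{sd_*} columns).
#' @return data.frame with one row per channel (\code{hbo}, \code{hbr},
#'   \code{hbt}) and columns \code{rmse}, \code{peak_amp_error},
#'   \code{peak_time_error}, \code{band_coverage}.
#' @export
compare_traces <- function(sim, ref) {
  need_sim <- c("t_ms", "d_hbo", "d_hbr", "d_hbt")
  need_ref <- c("t_ms", "mean_d_hbo", "mean_d_hbr", "mean_d_hbt",
                "sd_d_hbo", "sd_d_hbr", "sd_d_hbt")
  if (!all(need_sim %in% names(sim))) {
    stop_comparison_error("sim lacks hemo_trace columns")
  }
  if (!all(need_ref %in% names(ref))) {
    stop_comparison_error("ref lacks reference_trace columns")
  }
  lo <- max(min(sim$t_ms), min(ref$t_ms))
  hi <- min(max(sim$t_ms), max(ref$t_ms))
  if (lo >= hi) stop_comparison_error("sim and ref time ranges do not overlap")
  keep <- ref$t_ms >= lo & ref$t_ms <= hi
  tg <- ref$t_ms[keep]
  out <- lapply(c("hbo", "hbr", "hbt"), function(chan) {
    s <- stats::approx(sim$t_ms, sim[[paste0("d_", chan)]], xout = tg)$y
    m <- ref[[paste0("mean_d_", chan)]][keep]
    sdv <- ref[[paste0("sd_d_", chan)]][keep]
    ps <- which.max(abs(s)); pm <- which.max(abs(m))
    data.frame(channel = chan,
               rmse = sqrt(mean((s - m)^2)),
               peak_amp_error = s[ps] - m[pm],
               peak_time_error = tg[ps] - tg[pm],
               band_coverage = mean(abs(s - m) <= sdv))
  })
  do.call(rbind, out)
}
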