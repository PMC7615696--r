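# The four experimental conditions (whisker / optogenetic x no-drug / L-NAME):
# stimulus routing, baseline equilibration, and the coupled simulation that
# produces fractional hemoglobin traces.

# Order of the full state vector used by the integrator.
STATE_NAMES <- c("gaba", "npy", "glu", "no_n", "k_e", "k_p", "v_k", "v_i",
                 "ca_i", "radius", "volume", "dhb", "act")

#' Stimulation protocol
#'
#' Describes one experimental condition: whisker (somatosensory) or
#' optogenetic (nNOS-interneuron) stimulation, with or without NOS blockade
#' (L-NAME). Both experimental protocols are 2-s stimulations; the NPY input
#' pulse is half the GABA pulse width by default, which produces the early
#' constriction-dominated phase of the optogenetic response.
#'
#' @param kind \code{"whisker"} or \code{"optogenetic"}.
#' @param t0 stimulus onset, ms.
#' @param duration stimulus duration, ms (> 0).
#' @param lname logical; NOS blockade on/off.
#' @param npy_width_factor NPY pulse width as a fraction of the GABA pulse,
#'   in (0, 1].
#' @param baseline_duration maximum equilibration time, ms.
#' @return An object of class \code{stimulus_protocol}.
#' @export
#' @examples
#' stimulus_protocol("optogenetic", lname = TRUE)
stimulus_protocol <- function(kind = c("whisker", "optogenetic"),
                              t0 = 1000, duration = 2000, lname = FALSE,
                              npy_width_factor = 0.5,
                              baseline_duration = 60000) {
  if (length(kind) == 1L && !kind %in% c("whisker", "optogenetic")) {
    stop_invalid_protocol(sprintf("unknown stimulus kind '%s'", kind))
  }
  kind <- match.arg(kind)
  if (!is.numeric(duration) || duration <= 0) {
    stop_invalid_protocol("duration must be > 0")
  }
  if (npy_width_factor <= 0 || npy_width_factor > 1) {
    stop_invalid_protocol("npy_width_factor must lie in (0, 1]")
  }
  if (baseline_duration <= 0) {
    stop_invalid_protocol("baseline_duration must be > 0")
  }
  structure(list(kind = kind, t0 = t0, duration = duration,
                 lname = isTRUE(lname) || identical(lname, 1),
                 npy_width_factor = npy_width_factor,
                 baseline_duration = baseline_duration),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s%s: t0 = %g ms, duration = %g ms, NPY width x%g\n",
              x$kind, if (x$lname) " + L-NAME" else "", x$t0, x$duration,
              x$npy_width_factor))
  invisible(x)
}

#' Route a protocol to per-species input indicators
#'
#' Whisker stimulation drives extracellular K+ and neuronal NO (excitatory
#' pathway); optogenetic stimulation drives GABA, NPY and NO (nNOS-expressing
#' interneurons), with the NPY pulse truncated to
#' \code{duration * npy_width_factor}. The L-NAME switch acts downstream in
#' \code{\link{no_rhs}}, not here.
#'
#' @param proto a \code{\link{stimulus_protocol}}.
#' @param t time, ms (scalar).
#' @return named 0/1 vector \code{c(i_ke, i_gaba, i_npy, i_no)}.
#' @export
route_inputs <- function(proto, t) {
  if (!inherits(proto, "stimulus_protocol")) {
    stop_invalid_protocol("proto must be a stimulus_protocol")
  }
  h <- heaviside_input(t, proto$t0, proto$duration)
  if (proto$kind == "whisker") {
    c(i_ke = h, i_gaba = 0 * h, i_npy = 0 * h, i_no = h)
  } else {
    h_npy <- heaviside_input(t, proto$t0,
                             proto$duration * proto$npy_width_factor)
    c(i_ke = 0 * h, i_gaba = h, i_npy = h_npy, i_no = h)
  }
}

# Full coupled right-hand side for deSolve: signalling + vascular surrogate +
# balloon + activity lag. `r_eq` normalizes flow so the equilibrated baseline
# has CBF = 1; `inputs_off` freezes all stimuli (equilibration).
model_rhs <- function(t, y, parms) {
  p <- parms$p
  proto <- parms$proto
  s <- as.list(y)
  inp <- if (isTRUE(parms$inputs_off)) {
    c(i_ke = 0, i_gaba = 0, i_npy = 0, i_no = 0)
  } else {
    route_inputs(proto, t)
  }
  lname <- as.numeric(proto$lname)
  gt <- gaba_t_activity(max(s$no_n, 0), p$signalling)
  d_sig <- c(
    gaba = gaba_rhs(s, inp[["i_gaba"]], p$signalling),
    npy = npy_rhs(s, inp[["i_npy"]], p$signalling),
    glu = glu_rhs(s, s$k_e, gt, p$signalling),
    no_n = no_rhs(s, inp[["i_no"]], lname, p$signalling)
  )
  d_vas <- surrogate_rhs(s, s, inp[["i_ke"]], p)
  f_in <- cbf_from_radius(s$radius) / cbf_from_radius(parms$r_eq)
  d_bal <- balloon_rhs(s, f_in, p$balloon)
  i_stim <- if (proto$kind == "whisker") inp[["i_ke"]] else inp[["i_gaba"]]
  d_act <- p$balloon$act_rate * (i_stim - s$act)
  list(c(d_sig, d_vas, volume = d_bal[["volume"]], dhb = d_bal[["dhb"]],
         act = d_act))
}

initial_state <- function(p, proto) {
  s <- p$signalling; sp <- p$surrogate
  stats::setNames(
    c(s$gaba_base, s$npy_base, 0, s$no_rest * (1 - as.numeric(proto$lname)),
      sp$ke_base, sp$ke_base, sp$vk_rest, sp$vi_rest, 1, 1, 1, 1, 0),
    STATE_NAMES)
}

integrate_states <- function(y0, times, parms, rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::lsoda(y = y0, times = times, func = model_rhs,
                        parms = parms, rtol = rtol, atol = atol,
                        maxsteps = 1e5)
  istate <- attr(out, "istate")[1L]
  if (anyNA(out) || (!is.null(istate) && istate < 0)) {
    bad <- which(apply(out, 1L, anyNA))[1L]
    stop_integration_failure(
      sprintf("ODE integration failed (istate = %d) near t = %s ms",
              istate,
              format(if (is.na(bad)) utils::tail(times, 1) else times[bad])),
      state = if (!is.na(bad) && bad > 1) out[bad - 1L, ] else y0,
      time = times[bad])
  }
  out
}

#' Equilibrate the model to its pre-stimulus baseline
#'
#' Integrates the coupled system with all inputs off until the largest
#' absolute state derivative falls below \code{tol} (per ms) or
#' \code{baseline_duration} is reached (with a warning). The balloon
#' compartment is then pinned at its exact fixed point (volume = dhb = 1)
#' under the equilibrated radius, so a subsequent run starts from a true
#' steady state with zero fractional hemoglobin change.
#'
#' @param p an \code{nvc_params} list.
#' @param proto a \code{\link{stimulus_protocol}} (supplies the L-NAME flag
#'   and the equilibration budget).
#' @param tol derivative tolerance, per ms.
#' @return named state vector with attribute \code{r_eq}, the equilibrated
#'   radius used to normalize flow.
#' @export
equilibrate <- function(p, proto = stimulus_protocol(), tol = 1e-9) {
  parms <- list(p = p, proto = proto, inputs_off = TRUE, r_eq = 1)
  y <- initial_state(p, proto)
  chunk <- 5000
  elapsed <- 0
  repeat {
    out <- integrate_states(y, c(0, chunk), parms)
    y <- out[nrow(out), -1L]
    elapsed <- elapsed + chunk
    parms$r_eq <- y[["radius"]]
    y[c("volume", "dhb")] <- 1
    dmax <- max(abs(unlist(model_rhs(0, y, parms)[[1L]])))
    if (dmax < tol) break
    if (elapsed >= proto$baseline_duration) {
      warning(sprintf(
        "equilibration tolerance not met after %g ms (max |dy/dt| = %.3g)",
        elapsed, dmax))
      break
    }
  }
  if (!all(is.finite(y))) {
    stop_configuration_error("model diverged during baseline equilibration")
  }
  attr(y, "r_eq") <- y[["radius"]]
  y
}

#' Simulate one experimental condition
#'
#' Equilibrates to baseline, then integrates the coupled
#' signalling--vascular--balloon system over
#' \code{[0, t0 + duration + post_window]} and returns the fractional
#' hemoglobin trace. Deterministic: identical configurations give bitwise
#' identical traces.
#'
#' @param proto a \code{\link{stimulus_protocol}}.
#' @param p an \code{nvc_params} list (default \code{default_params()}).
#' @param dt_out output sampling interval, ms.
#' @param post_window post-stimulus window, ms.
#' @return A \code{hemo_trace}: data.frame with columns \code{t_ms},
#'   \code{d_hbo}, \code{d_hbr}, \code{d_hbt} (fractional changes from
#'   baseline), with the full state matrix in attribute \code{"states"} and
#'   the protocol in attribute \code{"protocol"}.
#' @export
#' @examples
#' \donttest{
#' tr <- run_condition(stimulus_protocol("whisker"))
#' max(tr$d_hbt)
#' }
run_condition <- function(proto, p = default_params(), dt_out = 10,
                          post_window = 18000) {
  if (!inherits(proto, "stimulus_protocol")) {
    stop_invalid_protocol("proto must be a stimulus_protocol")
  }
  validate_params(p)
  y0 <- equilibrate(p, proto)
  r_eq <- attr(y0, "r_eq")
  times <- seq(0, proto$t0 + proto$duration + post_window, by = dt_out)
  parms <- list(p = p, proto = proto, inputs_off = FALSE, r_eq = r_eq)
  out <- integrate_states(as.numeric(y0) |> stats::setNames(STATE_NAMES),
                          times, parms)
  states <- out[, STATE_NAMES, drop = FALSE]
  cbf <- cbf_from_radius(states[, "radius"]) / cbf_from_radius(r_eq)
  gain <- if (proto$kind == "whisker") p$balloon$cmro_gain_whisker
          else p$balloon$cmro_gain_opto
  cmro <- cmro_from_activity(states[, "act"], gain)
  hb <- hb_outputs(list(volume = states[, "volume"], dhb = states[, "dhb"]),
                   cbf, cmro, p$hbt_mode)
  n <- nrow(states)
  tr <- data.frame(t_ms = out[, "time"],
                   d_hbo = hb[seq.int(2L * n + 1L, 3L * n)],
                   d_hbr = hb[seq_len(n)],
                   d_hbt = hb[seq.int(n + 1L, 2L * n)])
  structure(tr, class = c("hemo_trace", "data.frame"),
            states = states, protocol = proto, r_eq = r_eq)
}

#' @export
print.hemo_trace <- function(x, ...) {
  proto <- attr(x, "protocol")
  cat(sprintf("<hemo_trace> %s%s, %d samples over %g s\n",
              proto$kind, if (proto$lname) " + L-NAME" else "",
              nrow(x), max(x$t_ms) / 1000))
  cat(sprintf("  peak dHbO = %+.4f, peak dHbR = %+.4f, peak dHbT = %+.4f\n",
              x$d_hbo[which.max(abs(x$d_hbo))],
              x$d_hbr[which.max(abs(x$d_hbr))],
              x$d_hbt[which.max(abs(x$d_hbt))]))
  invisible(x)
}

#' Plot a hemoglobin trace
#'
#' Base-graphics plot of the three fractional hemoglobin channels against
#' time, with the stimulus window shaded.
#'
#' @param x a \code{hemo_trace}.
#' @param ... passed to \code{matplot}.
#' @export
plot.hemo_trace <- function(x, ...) {
  proto <- attr(x, "protocol")
  graphics::matplot(x$t_ms / 1000, cbind(x$d_hbo, x$d_hbr, x$d_hbt),
                    type = "l", lty = 1, col = c("red", "blue", "darkgreen"),
                    xlab = "time (s)", ylab = "fractional change", ...)
  graphics::rect((proto$t0) / 1000, graphics::par("usr")[3],
                 (proto$t0 + proto$duration) / 1000, graphics::par("usr")[4],
                 col = grDevices::adjustcolor("grey", 0.3), border = NA)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("HbO", "HbR", "HbT"), lty = 1,
                   col = c("red", "blue", "darkgreen"), bty = "n")
  invisible(x)
}
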