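# Channel fluxes on the astrocyte and smooth muscle cell (SMC): GABA-gated
# Cl- channels and the NPY-modulated voltage-operated Ca2+ channel (VOCC),
# embedded in a reduced electro-vascular surrogate that carries signalling
# through K+ relay -> membrane potential -> SMC Ca2+ -> arteriolar radius.

#' GABA-dependent Cl- channel conductance
#'
#' \eqn{g_{GABA} = \tfrac{G_{GABA}}{2}\left(1 +
#'   \tanh\frac{GABA_N - g_{mid}}{g_{slope}}\right)}; essentially zero at
#' GABA = 0 and saturating at the maximal conductance \eqn{G_{GABA}}
#' (= 0.3 of the SMC Cl- leak conductance by default).
#'
#' @param gaba_n nondimensional GABA (vectorized, >= 0).
#' @param p channel parameter list (\code{default_params()$channels}).
#' @return conductance, uM/mV/ms.
#' @export
gaba_conductance <- function(gaba_n, p) {
  if (any(gaba_n < 0)) stop_invalid_parameter("gaba_n must be >= 0")
  (p$g_gaba_max / 2) * (1 + tanh((gaba_n - p$g_mid) / p$g_slope))
}

#' GABA-gated Cl- flux
#'
#' \eqn{J_{GABA} = g_{GABA}(GABA_N)\,(v - E_{GABA})}; identical form on the
#' astrocyte (v = v_k) and the SMC (v = v_i). Zero at the Cl- reversal
#' potential (-75 mV); for v above reversal the flux is positive and the
#' channel hyperpolarizes the cell.
#'
#' @param v membrane potential, mV.
#' @param gaba_n nondimensional GABA.
#' @param p channel parameter list.
#' @return flux, uM/ms.
#' @export
gaba_flux <- function(v, gaba_n, p) {
  gaba_conductance(gaba_n, p) * (v - p$e_gaba)
}

#' NPY-modulated VOCC conductance
#'
#' Default (\code{mode = "endpoint"}) uses the sigmoid renormalized so the two
#' printed endpoints hold exactly: \eqn{g_{VOCC}(0) = G_{Ca,i}} and
#' \eqn{g_{VOCC}(1) = (1 + N_{inc})\,G_{Ca,i}} (a 5\% increase with the
#' default \eqn{N_{inc}} = 0.05):
#' \deqn{g_{VOCC} = G_{Ca,i}\left(1 + N_{inc}\,
#'   \frac{\sigma(NPY_N) - \sigma(0)}{\sigma(1) - \sigma(0)}\right),\quad
#'   \sigma(x) = \tfrac12\left(1 + \tanh\frac{x - N_{mid}}{N_{slope}}\right)}
#' \code{mode = "literal"} keeps the unnormalized form
#' \eqn{G_{Ca,i}(1 + \tfrac{N_{inc}}{2}\tanh\frac{NPY_N - N_{mid}}{N_{slope}})},
#' whose endpoints deviate slightly from the stated values.
#'
#' @param npy_n nondimensional NPY (vectorized, >= 0).
#' @param p channel parameter list.
#' @param mode \code{"endpoint"} (default) or \code{"literal"}.
#' @return conductance, uM/mV/ms, monotone increasing in \code{npy_n}.
#' @export
#' @examples
#' p <- default_params()$channels
#' vocc_conductance(0, p) / p$g_ca_i  # 1
#' vocc_conductance(1, p) / p$g_ca_i  # 1.05
vocc_conductance <- function(npy_n, p, mode = c("endpoint", "literal")) {
  if (any(npy_n < 0)) stop_invalid_parameter("npy_n must be >= 0")
  mode <- match.arg(mode)
  sig <- function(x) 0.5 * (1 + tanh((x - p$n_mid) / p$n_slope))
  if (mode == "literal") {
    return(p$g_ca_i * (1 + (p$n_inc / 2) * tanh((npy_n - p$n_mid) / p$n_slope)))
  }
  s <- (sig(npy_n) - sig(0)) / (sig(1) - sig(0))
  p$g_ca_i * (1 + p$n_inc * s)
}

#' VOCC Ca2+ flux
#'
#' \eqn{J_{VOCC} = g_{VOCC}(NPY_N)\,
#'   \frac{v_i - v_{Ca1}}{1 + \exp(-(v_i - v_{Ca2})/R_{Ca})}}.
#' The activation factor is 1/2 at the half-point \eqn{v_{Ca2}} (-24 mV) and
#' the driving force vanishes at the reversal potential \eqn{v_{Ca1}}
#' (100 mV); below reversal the flux is negative (inward Ca2+).
#'
#' @param v_i SMC membrane potential, mV.
#' @param npy_n nondimensional NPY.
#' @param p channel parameter list.
#' @param mode VOCC sigmoid mode, passed to \code{\link{vocc_conductance}}.
#' @return Ca2+ flux, uM/ms.
#' @export
vocc_flux <- function(v_i, npy_n, p, mode = c("endpoint", "literal")) {
  g <- vocc_conductance(npy_n, p, mode)
  g * (v_i - p$v_ca1) / (1 + exp(-(v_i - p$v_ca2) / p$r_ca))
}

#' Radius set point from SMC calcium
#'
#' Monotone decreasing saturating map, fixed at 1 when Ca2+ is at its
#' baseline of 1: \eqn{r^*(Ca) = 1 + r_{amp} \tanh((1 - Ca)/ca_{scale})}.
#'
#' @param ca_i nondimensional SMC Ca2+ (baseline 1).
#' @param sp surrogate parameter list (\code{default_params()$surrogate}).
#' @return target radius ratio r/r0.
#' @export
radius_target <- function(ca_i, sp) {
  1 + sp$r_amp * tanh((1 - ca_i) / sp$ca_scale)
}

#' Reduced electro-vascular surrogate derivatives
#'
#' First-order kinetics for the six vascular states, encoding the mechanism
#' sign-chains of the full neurovascular unit:
#' \itemize{
#'   \item \code{k_e}: relaxes to baseline (3 mM) with a stimulation-gated
#'     source (\code{i_ke});
#'   \item \code{k_p}: perivascular K+ follows \code{k_e} with a first-order
#'     lag (astrocytic uptake and endfoot release);
#'   \item \code{v_k}: astrocyte potential, depolarized by K+ uptake and
#'     pulled toward the Cl- reversal by the GABA-gated flux;
#'   \item \code{v_i}: SMC potential, hyperpolarized by perivascular K+
#'     (KIR-like saturating shift) and by the GABA Cl- flux; an optional
#'     20-HETE-scaled BK-like leak (default off) is the only depolarizing
#'     modulation;
#'   \item \code{ca_i}: relaxes toward the normalized inward VOCC flux
#'     \eqn{J_{VOCC}(v_i, NPY)/J_{VOCC}(v_{i,rest}, 0)}, so baseline Ca2+ = 1;
#'   \item \code{radius}: relaxes to \code{\link{radius_target}(ca_i)}.
#' }
#'
#' @param vstate named list/vector: \code{k_e}, \code{k_p}, \code{v_k},
#'   \code{v_i}, \code{ca_i}, \code{radius}.
#' @param sstate named list/vector with at least \code{gaba} and \code{npy}.
#' @param i_ke 0/1 K+ source indicator (whisker pathway).
#' @param p full \code{nvc_params} list (uses \code{$channels},
#'   \code{$surrogate} and \code{$vocc_sigmoid}).
#' @return named numeric vector of derivatives (per ms) for the six states.
#' @export
surrogate_rhs <- function(vstate, sstate, i_ke, p) {
  sp <- p$surrogate; ch <- p$channels
  with(c(as.list(vstate), as.list(sstate)), {
    if (!is.finite(radius) || radius <= 0) {
      stop_integration_failure("non-positive or non-finite arteriolar radius",
                               state = vstate)
    }
    d_ke <- -sp$ke_rate * (k_e - sp$ke_base) + sp$ke_input * i_ke
    d_kp <- sp$kp_rate * (k_e - k_p)
    vk_tgt <- sp$vk_rest + sp$vk_k_amp * tanh((k_e - sp$ke_base) / sp$vk_k_scale)
    d_vk <- sp$vk_rate * (vk_tgt - v_k) - sp$w_cl_k * gaba_flux(v_k, gaba, ch)
    kp_exc <- pmax(k_p - sp$ke_base, 0)
    vi_tgt <- sp$vi_rest - sp$kir_amp * tanh(kp_exc / sp$kir_scale)
    d_vi <- sp$vi_rate * (vi_tgt - v_i) -
      sp$w_cl_i * gaba_flux(v_i, gaba, ch) -
      sp$hete_gain * sp$g_bk * (v_i - sp$e_bk)
    j_ref <- vocc_flux(sp$vi_rest, 0, ch, p$vocc_sigmoid)
    ca_tgt <- vocc_flux(v_i, npy, ch, p$vocc_sigmoid) / j_ref
    d_ca <- sp$ca_rate * (ca_tgt - ca_i)
    d_r <- sp$r_rate * (radius_target(ca_i, sp) - radius)
    c(k_e = d_ke, k_p = d_kp, v_k = d_vk, v_i = d_vi, ca_i = d_ca,
      radius = d_r)
  })
}
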