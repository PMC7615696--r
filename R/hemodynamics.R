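# Balloon-model hemodynamics: radius -> cerebral blood flow (CBF) -> venous
# volume/deoxyhemoglobin -> fractional HbO/HbR/HbT changes.

#' Normalized cerebral blood flow from arteriolar radius
#'
#' Poiseuille closure in baseline-normalized variables: flow scales with the
#' fourth power of the radius ratio, so \code{cbf_from_radius(1) == 1}.
#'
#' @param radius radius ratio r/r0, > 0 (vectorized).
#' @return normalized flow, unitless.
#' @export
#' @examples
#' cbf_from_radius(1.1)  # 1.4641
cbf_from_radius <- function(radius) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop_invalid_parameter("radius must be positive and finite")
  }
  radius^4
}

#' Oxygen extraction fraction as a function of flow
#'
#' Buxton's flow-diffusion form \eqn{E(f) = 1 - (1 - E_0)^{1/f}}, with
#' \eqn{E(1) = E_0}.
#'
#' @param f_in normalized inflow, > 0.
#' @param e0 baseline extraction fraction in (0, 1).
#' @return extraction fraction in (0, 1).
#' @export
extraction_fraction <- function(f_in, e0) {
  1 - (1 - e0)^(1 / f_in)
}

#' Balloon model derivatives
#'
#' Venous compartment in normalized variables (volume v, deoxyhemoglobin q,
#' baseline (1, 1)):
#' \deqn{\dot v = (f_{in} - v^{1/\alpha})/\tau}
#' \deqn{\dot q = \frac{1}{\tau}\left(f_{in}\frac{E(f_{in})}{E_0} -
#'   q\,\frac{v^{1/\alpha}}{v}\right)}
#' with outflow \eqn{f_{out} = v^{1/\alpha}} (Grubb exponent \eqn{\alpha}).
#'
#' @param b named list/vector with \code{volume} and \code{dhb}.
#' @param f_in normalized inflow, > 0.
#' @param p balloon parameter list (\code{default_params()$balloon}).
#' @return named vector \code{c(volume = dv, dhb = dq)}, per ms.
#' @export
balloon_rhs <- function(b, f_in, p) {
  v <- b$volume; q <- b$dhb
  if (!is.finite(v) || v <= 0) {
    stop_integration_failure("non-positive venous volume in balloon model",
                             state = b)
  }
  if (any(f_in <= 0)) stop_invalid_parameter("inflow must be > 0")
  f_out <- v^(1 / p$alpha_g)
  dv <- (f_in - f_out) / p$tau
  dq <- (f_in * extraction_fraction(f_in, p$e0) / p$e0 - q * f_out / v) / p$tau
  c(volume = dv, dhb = dq)
}

#' Normalized CMRO2 from smoothed neural activity
#'
#' \eqn{CMRO = 1 + gain \cdot a(t)} where \eqn{a} is the stimulus indicator
#' passed through a first-order lag. With gain 0 the metabolic coupling is
#' disabled (CMRO = 1).
#'
#' @param activity smoothed activity in [0, 1].
#' @param cmro_gain coupling gain, unitless.
#' @return normalized CMRO2.
#' @export
cmro_from_activity <- function(activity, cmro_gain) {
  if (any(activity < 0)) stop_invalid_parameter("activity must be >= 0")
  1 + cmro_gain * activity
}

#' Fractional hemoglobin changes from the balloon state
#'
#' \itemize{
#'   \item \eqn{\Delta HbR = q - 1} (deoxyhemoglobin is the balloon state);
#'   \item \eqn{\Delta HbT}: total hemoglobin from the flow closure
#'     \eqn{HbT \propto CBF \cdot HbR / CMRO} in baseline-normalized
#'     variables, i.e. \eqn{\Delta HbT = cbf \cdot q / cmro - 1}
#'     (mode \code{"flow_closure"}); mode \code{"volume"} uses the standard
#'     balloon alternative \eqn{\Delta HbT = v - 1};
#'   \item \eqn{\Delta HbO = \Delta HbT - \Delta HbR}, exact by hemoglobin
#'     conservation (HbT = HbO + HbR).
#' }
#'
#' @param b named list/vector with \code{volume} and \code{dhb}.
#' @param cbf normalized flow.
#' @param cmro normalized CMRO2, > 0.
#' @param mode \code{"flow_closure"} (default) or \code{"volume"}.
#' @return named vector \code{c(d_hbr, d_hbt, d_hbo)}.
#' @export
#' @examples
#' hb_outputs(list(volume = 1, dhb = 0.9), cbf = 1.2, cmro = 1)
hb_outputs <- function(b, cbf, cmro, mode = c("flow_closure", "volume")) {
  mode <- match.arg(mode)
  if (any(cmro <= 0)) stop_invalid_parameter("cmro must be > 0")
  d_hbr <- unname(b$dhb - 1)
  d_hbt <- unname(
    if (mode == "flow_closure") cbf * b$dhb / cmro - 1 else b$volume - 1)
  c(d_hbr = d_hbr, d_hbt = d_hbt, d_hbo = d_hbt - d_hbr)
}

#' Closed-form balloon steady state under constant inflow
#'
#' For sustained inflow F: \eqn{v_{ss} = F^{\alpha}},
#' \eqn{q_{ss} = F^{\alpha} E(F)/E_0}. Used as the analytic oracle for the
#' integrated balloon.
#'
#' @param f_in constant normalized inflow, > 0.
#' @param p balloon parameter list.
#' @return named vector \code{c(volume, dhb)}.
#' @export
balloon_steady_state <- function(f_in, p) {
  v <- f_in^p$alpha_g
  q <- v * extraction_fraction(f_in, p$e0) / p$e0
  c(volume = v, dhb = q)
}
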