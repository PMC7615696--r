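# Interneuron biochemistry: GABA, NPY, glutamate state equations, the
# NO-inhibited GABA transaminase (GABA-T) activity, and a first-order neuronal
# NO species carrying the L-NAME (NOS blockade) switch.
#
# Concentrations of GABA, NPY and glutamate are nondimensional (1 ~ the
# stimulated maximum); NO is in uM; time in ms throughout.

#' Heaviside stimulus indicator
#'
#' Rectangular stimulus window with strict boundaries: 1 for
#' \code{t0 < t < t0 + dt}, 0 otherwise (including at both endpoints).
#'
#' @param t time, ms (vectorized).
#' @param t0 stimulus onset, ms.
#' @param dt stimulus duration, ms; must be > 0.
#' @return 0/1 numeric of the same length as \code{t}.
#' @export
#' @examples
#' heaviside_input(c(999, 1500, 3001), t0 = 1000, dt = 2000)
heaviside_input <- function(t, t0, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_invalid_protocol("stimulus duration dt must be a positive number")
  }
  as.numeric(t > t0 & t < t0 + dt)
}

#' GABA transaminase activity as a function of neuronal NO
#'
#' Descending sigmoid between the activity bounds:
#' \deqn{G_{T,act}(NO) = \tfrac12\left[(G_{T,max}+G_{T,min}) -
#'   (G_{T,max}-G_{T,min})\tanh\frac{NO - GT_{mid}}{GT_{slope}}\right]}
#' NO inhibits the enzyme, so activity falls from near \eqn{G_{T,max}} at
#' NO = 0 to \eqn{G_{T,min}} at saturating NO.
#'
#' @param no_n neuronal NO concentration, uM (vectorized, >= 0).
#' @param p signalling parameter list (see \code{\link{default_params}},
#'   \code{$signalling}).
#' @return activity, unitless, strictly inside (GT_min, GT_max).
#' @export
#' @examples
#' p <- default_params()$signalling
#' gaba_t_activity(0, p)            # near GT_max = 2
#' gaba_t_activity(p$gt_midpoint, p)  # exactly (GT_max + GT_min)/2
gaba_t_activity <- function(no_n, p) {
  if (any(no_n < 0)) stop_invalid_parameter("no_n must be >= 0")
  0.5 * ((p$gt_max + p$gt_min) -
         (p$gt_max - p$gt_min) * tanh((no_n - p$gt_midpoint) / p$gt_slope))
}

#' GABA degradation rate
#'
#' \eqn{\kappa_{GABA} = \beta_{GABA} \cdot G_{T,act}}: the first-order GABA
#' degradation rate is proportional to the current GABA-T activity.
#'
#' @param gt_act GABA-T activity, unitless, > 0.
#' @param p signalling parameter list.
#' @return rate, 1/ms.
#' @export
gaba_degradation_rate <- function(gt_act, p) {
  if (any(gt_act <= 0)) stop_invalid_parameter("gt_act must be > 0")
  p$beta_gaba * gt_act
}

#' Time derivative of nondimensional GABA
#'
#' \eqn{dGABA/dt = -\kappa_{GABA}(GABA - GABA_{base}) + \alpha_{GABA} I_H(t)},
#' with \eqn{\kappa_{GABA}} evaluated from the state's NO via
#' \code{\link{gaba_t_activity}}. Fixed point at \code{gaba_base} when the
#' input is off.
#'
#' @param state named list/vector with \code{gaba} and \code{no_n}.
#' @param i_h stimulus indicator in \{0, 1\}.
#' @param p signalling parameter list.
#' @return d(GABA)/dt, 1/ms.
#' @export
gaba_rhs <- function(state, i_h, p) {
  kap <- gaba_degradation_rate(gaba_t_activity(state$no_n, p), p)
  -kap * (state$gaba - p$gaba_base) + p$alpha_gaba * i_h
}

#' Time derivative of nondimensional NPY
#'
#' \eqn{dNPY/dt = -\beta_{NPY}(NPY - NPY_{base}) + \alpha_{NPY} I_{H,NPY}(t)}.
#' The NPY input indicator uses its own pulse width (half the GABA pulse by
#' default; see \code{\link{route_inputs}}).
#'
#' @param state named list/vector with \code{npy}.
#' @param i_h_npy NPY-specific stimulus indicator in \{0, 1\}.
#' @param p signalling parameter list.
#' @return d(NPY)/dt, 1/ms.
#' @export
npy_rhs <- function(state, i_h_npy, p) {
  -p$beta_npy * (state$npy - p$npy_base) + p$alpha_npy * i_h_npy
}

#' Glutamate release from the excitatory neuron
#'
#' Released once extracellular K+ crosses a threshold:
#' \eqn{f(K_e) = \tfrac{Glu_{max}}{2}\left(1 +
#'   \tanh\frac{K_e - K_{e,switch}}{Glu_{slope}}\right)}.
#'
#' @param ke extracellular K+ concentration, mM (vectorized, >= 0).
#' @param p signalling parameter list.
#' @return nondimensional release rate, monotone increasing in \code{ke}.
#' @export
glutamate_release <- function(ke, p) {
  if (any(ke < 0)) stop_invalid_parameter("ke must be >= 0")
  (p$glu_max / 2) * (1 + tanh((ke - p$ke_switch) / p$glu_slope))
}

#' Time derivative of nondimensional glutamate
#'
#' \eqn{dGlu/dt = f(K_e) + g(GABA) - \beta_{Glu} Glu} where
#' \eqn{g(GABA) = \kappa_{GABA} GABA} is the GABA-degradation source (GABA-T
#' converts GABA to succinic semialdehyde and glutamate). At rest both sources
#' vanish and glutamate decays to zero.
#'
#' @param state named list/vector with \code{glu} and \code{gaba}.
#' @param ke extracellular K+ concentration, mM.
#' @param gt_act current GABA-T activity.
#' @param p signalling parameter list.
#' @return d(Glu)/dt, 1/ms.
#' @export
glu_rhs <- function(state, ke, gt_act, p) {
  glutamate_release(ke, p) +
    gaba_degradation_rate(gt_act, p) * state$gaba -
    p$beta_glu * state$glu
}

#' Time derivative of neuronal NO
#'
#' First-order production/decay surrogate with the NOS-blockade switch:
#' \deqn{dNO/dt = -\beta_{NO}\,(NO - NO_{rest}(1 - L)) +
#'   \alpha_{NO} I_H(t)(1 - L)}
#' With \code{lname = 0} the fixed point without stimulation is
#' \code{no_rest}; with \code{lname = 1} both the stimulated production and
#' the resting supply are zeroed (blockade modelled as complete), so NO decays
#' to zero and GABA-T disinhibits toward its maximum.
#'
#' @param state named list/vector with \code{no_n}.
#' @param i_h stimulus indicator in \{0, 1\}.
#' @param lname 0/1 NOS-blockade flag.
#' @param p signalling parameter list.
#' @return d(NO)/dt, uM/ms.
#' @export
no_rhs <- function(state, i_h, lname, p) {
  off <- 1 - as.numeric(lname)
  -p$no_beta * (state$no_n - p$no_rest * off) + p$no_alpha * i_h * off
}
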