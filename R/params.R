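#' Parameter registry with provenance
#'
#' Every model constant, keyed by its conventional symbol name, together with
#' its unit and a provenance tag: \code{"table"} (printed parameter table),
#' \code{"text"} (value stated in prose), or \code{"surrogate"} (a constant of
#' this package's reduced-order vascular / hemodynamic stages, not a published
#' kinetic parameter). Where the source prints conflicting values the table
#' value is the default and the text variant is retained here with suffix
#' \code{_text}.
#'
#' @return A data.frame with columns \code{name}, \code{value}, \code{unit},
#'   \code{provenance}, \code{description}.
#' @export
#' @examples
#' reg <- nvc_registry()
#' reg[reg$name == "G_GABA", ]
nvc_registry <- function() {
  e <- function(name, value, unit, provenance, description) {
    data.frame(name = name, value = value, unit = unit,
               provenance = provenance, description = description,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # interneuron signalling
    e("GT_min",      1,        "unitless", "table", "minimum GABA-T activity (saturating NO)"),
    e("GT_max",      2,        "unitless", "table", "maximum GABA-T activity (NO near zero)"),
    e("GT_midpoint", 0.06,     "uM",       "table", "NO at half-maximal GABA-T activity"),
    e("GT_slope",    0.02128,  "uM",       "table", "GABA-T sigmoid width"),
    e("alpha_GABA",  1.6e-3,   "1/ms",     "table", "nondimensional GABA production rate"),
    e("beta_GABA",   2.2e-3,   "1/ms",     "table", "GABA activity (degradation) rate"),
    e("alpha_NPY",   4.2e-3,   "1/ms",     "table", "nondimensional NPY production rate"),
    e("beta_NPY",    2.2e-3,   "1/ms",     "table", "NPY degradation rate"),
    e("beta_Glu",    4.2e-3,   "1/ms",     "table", "glutamate degradation rate"),
    e("GABA_base",   0,        "unitless", "surrogate", "GABA baseline (zero at rest by nondimensionalization)"),
    e("NPY_base",    0,        "unitless", "surrogate", "NPY baseline"),
    e("Glu_max",     1,        "unitless", "surrogate", "maximal glutamate release magnitude"),
    e("K_e_switch",  5,        "mM",       "text",  "extracellular K+ threshold for glutamate release"),
    e("Glu_slope",   0.1,      "mM",       "text",  "glutamate release sigmoid width"),
    e("NO_rest",     0.02047,  "uM",       "text",  "resting neuronal NO concentration"),
    e("no_alpha",    4.5034e-4,"uM/ms",    "surrogate", "NO production rate under stimulation (10x NO_rest steady elevation)"),
    e("no_beta",     2.2e-3,   "1/ms",     "surrogate", "NO first-order decay rate"),
    # membrane channels
    e("E_GABA",      -75,      "mV",       "table", "Cl- reversal potential of GABA-gated channels"),
    e("G_Cl_i",      1.34e-6,  "uM/mV/ms", "text",  "SMC Cl- leak conductance"),
    e("G_GABA",      4.02e-7,  "uM/mV/ms", "table", "maximal GABA-channel conductance (0.3 x G_Cl_i)"),
    e("G_Ca_i",      1.29e-6,  "uM/mV/ms", "text",  "base VOCC conductance"),
    e("v_Ca1",       100,      "mV",       "text",  "VOCC reversal potential"),
    e("v_Ca2",       -24,      "mV",       "text",  "VOCC half-activation potential"),
    e("R_Ca",        8.5,      "mV",       "text",  "VOCC activation sigmoid slope"),
    e("g_mid",       0.5,      "unitless", "table", "GABA-conductance sigmoid midpoint"),
    e("g_mid_text",  0.8,      "unitless", "text",  "GABA-conductance sigmoid midpoint (prose variant)"),
    e("g_slope",     0.15,     "unitless", "table", "GABA-conductance sigmoid width"),
    e("N_inc",       0.05,     "unitless", "text",  "fractional VOCC conductance increase at maximal NPY"),
    e("N_mid",       0.5,      "unitless", "table", "NPY sigmoid midpoint"),
    e("N_mid_text",  0.6,      "unitless", "text",  "NPY sigmoid midpoint (prose variant)"),
    e("N_slope",     0.15,     "unitless", "table", "NPY sigmoid width"),
    e("N_slope_text",0.1,      "unitless", "text",  "NPY sigmoid width (prose variant)"),
    # reduced electro-vascular surrogate
    e("ke_base",     3,        "mM",       "surrogate", "baseline extracellular K+"),
    e("ke_rate",     2.2e-3,   "1/ms",     "surrogate", "extracellular K+ clearance rate"),
    e("ke_input",    1.32e-2,  "mM/ms",    "surrogate", "stimulation-gated K+ source (+6 mM steady elevation)"),
    e("kp_rate",     2.0e-3,   "1/ms",     "surrogate", "astrocytic relay rate, k_p toward k_e"),
    e("vk_rest",     -80,      "mV",       "surrogate", "astrocyte resting potential"),
    e("vk_rate",     2.0e-3,   "1/ms",     "surrogate", "astrocyte membrane relaxation rate"),
    e("vk_k_amp",    10,       "mV",       "surrogate", "astrocyte depolarization amplitude by K+ uptake"),
    e("vk_k_scale",  3,        "mM",       "surrogate", "K+ scale of astrocyte depolarization"),
    e("w_cl_k",      2500,     "mV/uM",    "surrogate", "Cl- flux-to-voltage coupling, astrocyte"),
    e("vi_rest",     -45,      "mV",       "surrogate", "SMC resting potential"),
    e("vi_rate",     2.0e-3,   "1/ms",     "surrogate", "SMC membrane relaxation rate"),
    e("kir_amp",     8,        "mV",       "surrogate", "maximal KIR-like hyperpolarization by perivascular K+"),
    e("kir_scale",   3,        "mM",       "surrogate", "K+ scale of KIR-like hyperpolarization"),
    e("w_cl_i",      2500,     "mV/uM",    "surrogate", "Cl- flux-to-voltage coupling, SMC"),
    e("hete_gain",   0,        "unitless", "surrogate", "optional 20-HETE multiplier on BK-like leak (default off)"),
    e("g_bk",        1e-4,     "1/ms",     "surrogate", "BK-like leak conductance scale (only used if hete_gain > 0)"),
    e("e_bk",        -95,      "mV",       "surrogate", "BK-like leak reversal potential"),
    e("ca_rate",     2.0e-3,   "1/ms",     "surrogate", "SMC Ca2+ relaxation rate"),
    e("ca_scale",    0.5,      "unitless", "surrogate", "Ca2+ scale of the radius sigmoid"),
    e("r_rate",      4.0e-3,   "1/ms",     "surrogate", "arteriolar radius relaxation rate"),
    e("r_amp",       0.15,     "unitless", "surrogate", "maximal fractional radius excursion"),
    # balloon hemodynamics
    e("tau",         2000,     "ms",       "surrogate", "balloon mean transit time"),
    e("alpha_g",     0.38,     "unitless", "surrogate", "Grubb flow-volume exponent"),
    e("e0",          0.4,      "unitless", "surrogate", "baseline O2 extraction fraction"),
    e("cmro_gain_whisker", 0.2,"unitless", "surrogate", "CMRO2 coupling gain, whisker (excitatory) stimulation"),
    e("cmro_gain_opto",    0,  "unitless", "surrogate", "CMRO2 coupling gain, optogenetic stimulation"),
    e("act_rate",    2.0e-3,   "1/ms",     "surrogate", "first-order lag of the neural-activity indicator")
  ))
}

#' Default model parameters
#'
#' Collapses the registry (\code{\link{nvc_registry}}) into the nested list
#' the simulation functions consume: \code{signalling}, \code{channels},
#' \code{surrogate}, \code{balloon} blocks plus two switches,
#' \code{vocc_sigmoid} (\code{"endpoint"} or \code{"literal"}) and
#' \code{hbt_mode} (\code{"flow_closure"} or \code{"volume"}).
#'
#' The default VOCC sigmoid is renormalized so that its printed endpoints hold
#' exactly (conductance \eqn{G_{Ca,i}} at NPY = 0 and \eqn{1.05\,G_{Ca,i}} at
#' NPY = 1); \code{"literal"} keeps the raw tanh form for comparison.
#'
#' @param ... named overrides, e.g. \code{alpha_GABA = 2e-3} or
#'   \code{surrogate = list(kir_amp = 10)}. Scalar names may target either the
#'   flat registry name or a nested block.
#' @return An object of class \code{nvc_params}.
#' @export
#' @examples
#' p <- default_params()
#' p$channels$g_gaba_max / p$channels$g_cl_i  # 0.3
default_params <- function(...) {
  reg <- nvc_registry()
  v <- function(name) reg$value[match(name, reg$name)]
  p <- list(
    signalling = list(
      alpha_gaba = v("alpha_GABA"), beta_gaba = v("beta_GABA"),
      alpha_npy = v("alpha_NPY"), beta_npy = v("beta_NPY"),
      beta_glu = v("beta_Glu"),
      gaba_base = v("GABA_base"), npy_base = v("NPY_base"),
      gt_min = v("GT_min"), gt_max = v("GT_max"),
      gt_midpoint = v("GT_midpoint"), gt_slope = v("GT_slope"),
      glu_max = v("Glu_max"), ke_switch = v("K_e_switch"),
      glu_slope = v("Glu_slope"),
      no_rest = v("NO_rest"), no_alpha = v("no_alpha"), no_beta = v("no_beta")
    ),
    channels = list(
      g_gaba_max = v("G_GABA"), e_gaba = v("E_GABA"),
      g_cl_i = v("G_Cl_i"), g_ca_i = v("G_Ca_i"),
      v_ca1 = v("v_Ca1"), v_ca2 = v("v_Ca2"), r_ca = v("R_Ca"),
      n_inc = v("N_inc"), n_mid = v("N_mid"), n_slope = v("N_slope"),
      g_mid = v("g_mid"), g_slope = v("g_slope")
    ),
    surrogate = list(
      ke_base = v("ke_base"), ke_rate = v("ke_rate"), ke_input = v("ke_input"),
      kp_rate = v("kp_rate"),
      vk_rest = v("vk_rest"), vk_rate = v("vk_rate"),
      vk_k_amp = v("vk_k_amp"), vk_k_scale = v("vk_k_scale"),
      w_cl_k = v("w_cl_k"),
      vi_rest = v("vi_rest"), vi_rate = v("vi_rate"),
      kir_amp = v("kir_amp"), kir_scale = v("kir_scale"),
      w_cl_i = v("w_cl_i"),
      hete_gain = v("hete_gain"), g_bk = v("g_bk"), e_bk = v("e_bk"),
      ca_rate = v("ca_rate"), ca_scale = v("ca_scale"),
      r_rate = v("r_rate"), r_amp = v("r_amp")
    ),
    balloon = list(
      tau = v("tau"), alpha_g = v("alpha_g"), e0 = v("e0"),
      cmro_gain_whisker = v("cmro_gain_whisker"),
      cmro_gain_opto = v("cmro_gain_opto"),
      act_rate = v("act_rate")
    ),
    vocc_sigmoid = "endpoint",
    hbt_mode = "flow_closure"
  )
  p <- merge_params(p, list(...))
  class(p) <- "nvc_params"
  validate_params(p)
  p
}

# Recursive merge of overrides into defaults. Scalar overrides whose name is a
# registry symbol (e.g. alpha_GABA) are routed to the right nested slot.
merge_params <- function(p, over) {
  if (length(over) == 0L) return(p)
  if (is.null(names(over)) || any(names(over) == "")) {
    stop_invalid_parameter("parameter overrides must be named")
  }
  alias <- c(
    alpha_GABA = "signalling.alpha_gaba", beta_GABA = "signalling.beta_gaba",
    alpha_NPY = "signalling.alpha_npy", beta_NPY = "signalling.beta_npy",
    beta_Glu = "signalling.beta_glu", GABA_base = "signalling.gaba_base",
    NPY_base = "signalling.npy_base", GT_min = "signalling.gt_min",
    GT_max = "signalling.gt_max", GT_midpoint = "signalling.gt_midpoint",
    GT_slope = "signalling.gt_slope", Glu_max = "signalling.glu_max",
    K_e_switch = "signalling.ke_switch", Glu_slope = "signalling.glu_slope",
    NO_rest = "signalling.no_rest", no_alpha = "signalling.no_alpha",
    no_beta = "signalling.no_beta",
    G_GABA = "channels.g_gaba_max", E_GABA = "channels.e_gaba",
    G_Cl_i = "channels.g_cl_i", G_Ca_i = "channels.g_ca_i",
    v_Ca1 = "channels.v_ca1", v_Ca2 = "channels.v_ca2", R_Ca = "channels.r_ca",
    N_inc = "channels.n_inc", N_mid = "channels.n_mid",
    N_slope = "channels.n_slope", g_mid = "channels.g_mid",
    g_slope = "channels.g_slope"
  )
  for (nm in names(over)) {
    val <- over[[nm]]
    if (nm %in% names(p) && is.list(p[[nm]]) && is.list(val)) {
      bad <- setdiff(names(val), names(p[[nm]]))
      if (length(bad)) {
        stop_invalid_parameter(sprintf("unknown parameter(s) in '%s': %s",
                                       nm, paste(bad, collapse = ", ")))
      }
      p[[nm]][names(val)] <- val
    } else if (nm %in% names(p) && !is.list(p[[nm]])) {
      p[[nm]] <- val
    } else if (nm %in% names(alias)) {
      path <- strsplit(alias[[nm]], ".", fixed = TRUE)[[1L]]
      p[[path[1L]]][[path[2L]]] <- val
    } else if (nm %in% names(p$balloon)) {
      p$balloon[[nm]] <- val
    } else if (nm %in% names(p$surrogate)) {
      p$surrogate[[nm]] <- val
    } else {
      stop_invalid_parameter(sprintf("unknown parameter '%s'", nm))
    }
  }
  p
}

#' Load parameters from a YAML or JSON config file
#'
#' Keys may be registry symbol names (\code{alpha_GABA}, \code{G_Ca_i}, ...)
#' or nested blocks (\code{surrogate:}, \code{balloon:}); values override the
#' defaults of \code{\link{default_params}}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{nvc_params} object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) {
    stop_configuration_error(sprintf("config file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  over <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_configuration_error(sprintf("unsupported config format '.%s'", ext))
  )
  if (is.null(over)) over <- list()
  do.call(default_params, over)
}

#' Validate a parameter set
#'
#' Checks positivity of rates and sigmoid widths, the activity-bound ordering
#' GT_min <= GT_max, the channel orderings (v_Ca1 > v_Ca2, non-negative
#' conductances), and the balloon constraints (tau > 0, 0 < alpha_g < 1,
#' 0 < E0 < 1). Called by \code{\link{default_params}}.
#'
#' @param p an \code{nvc_params} list.
#' @return \code{p}, invisibly, if valid; otherwise an invalid-parameter error.
#' @export
validate_params <- function(p) {
  s <- p$signalling; ch <- p$channels; b <- p$balloon
  chk <- function(ok, msg) if (!isTRUE(ok)) stop_invalid_parameter(msg)
  rates <- c(s$alpha_gaba, s$beta_gaba, s$alpha_npy, s$beta_npy, s$beta_glu,
             s$no_alpha, s$no_beta)
  chk(all(is.finite(rates)) && all(rates > 0), "all kinetic rates must be > 0")
  chk(s$gt_min <= s$gt_max, "GT_min must be <= GT_max")
  chk(s$gt_slope > 0, "GT_slope must be > 0")
  chk(s$glu_slope > 0, "Glu_slope must be > 0")
  chk(s$no_rest >= 0, "NO_rest must be >= 0")
  chk(all(c(ch$g_gaba_max, ch$g_cl_i, ch$g_ca_i) >= 0),
      "conductances must be >= 0")
  chk(ch$v_ca1 > ch$v_ca2, "v_Ca1 must exceed v_Ca2")
  chk(ch$n_inc >= 0, "N_inc must be >= 0")
  chk(ch$g_slope > 0 && ch$n_slope > 0 && ch$r_ca > 0,
      "sigmoid widths must be > 0")
  chk(b$tau > 0, "balloon transit time tau must be > 0")
  chk(b$alpha_g > 0 && b$alpha_g < 1, "Grubb exponent must lie in (0, 1)")
  chk(b$e0 > 0 && b$e0 < 1, "baseline extraction fraction must lie in (0, 1)")
  chk(p$vocc_sigmoid %in% c("endpoint", "literal"),
      "vocc_sigmoid must be 'endpoint' or 'literal'")
  chk(p$hbt_mode %in% c("flow_closure", "volume"),
      "hbt_mode must be 'flow_closure' or 'volume'")
  invisible(p)
}

#' @export
print.nvc_params <- function(x, ...) {
  cat("<nvc_params>\n")
  for (blk in c("signalling", "channels", "surrogate", "balloon")) {
    vals <- unlist(x[[blk]])
    cat(sprintf("  %s: %s\n", blk,
                paste(sprintf("%s=%g", names(vals), vals), collapse = ", ")))
  }
  cat(sprintf("  vocc_sigmoid=%s, hbt_mode=%s\n", x$vocc_sigmoid, x$hbt_mode))
  invisible(x)
}
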