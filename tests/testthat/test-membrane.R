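test_that("GABA-gated Cl- conductance: midpoint, rest, maximum", {
  ch <- default_channels()
  expect_equal(gaba_conductance(ch$g_mid, ch), ch$g_gaba_max / 2)
  # frozen: (1 + tanh(-0.5/0.15))/2 at GABA = 0
  expect_equal(gaba_conductance(0, ch) / ch$g_gaba_max, 0.001271016,
               tolerance = 1e-6)
  expect_equal(gaba_conductance(10, ch), ch$g_gaba_max, tolerance = 1e-12)
  # default maximal conductance is 30% of the SMC Cl- leak conductance
  expect_equal(ch$g_gaba_max, 0.3 * ch$g_cl_i)
  expect_equal(ch$g_gaba_max, 4.02e-7)
})

test_that("Cl- flux reverses exactly at E_GABA and vanishes without GABA", {
  ch <- default_channels()
  expect_equal(gaba_flux(-75, 5, ch), 0)
  # residual flux at zero GABA is below sigmoid-saturation tolerance
  expect_lt(abs(gaba_flux(-20, 0, ch)), 1e-7)
  # saturating GABA at v = -25 mV: G_GABA * 50
  expect_equal(gaba_flux(-25, 10, ch), 4.02e-7 * 50, tolerance = 1e-10)
  # sign change across the reversal potential
  expect_lt(gaba_flux(-80, 1, ch), 0)
  expect_gt(gaba_flux(-70, 1, ch), 0)
})

test_that("VOCC conductance endpoints hold exactly in endpoint mode", {
  ch <- default_channels()
  expect_identical(vocc_conductance(0, ch), ch$g_ca_i)
  expect_equal(vocc_conductance(1, ch), 1.05 * ch$g_ca_i)
  # midpoint lies strictly between the endpoints; by the symmetry of the
  # default sigmoid about N_mid the rescaled value there is 1/2
  mid <- vocc_conductance(ch$n_mid, ch)
  expect_gt(mid, ch$g_ca_i)
  expect_lt(mid, 1.05 * ch$g_ca_i)
  expect_equal(mid, ch$g_ca_i * (1 + ch$n_inc * 0.5))
})

test_that("literal VOCC sigmoid deviates from the printed endpoints", {
  ch <- default_channels()
  lit0 <- vocc_conductance(0, ch, mode = "literal")
  expect_false(isTRUE(all.equal(lit0, ch$g_ca_i)))
  expect_equal(lit0,
               ch$g_ca_i * (1 - (ch$n_inc / 2) * tanh(ch$n_mid / ch$n_slope)))
})

test_that("channel conductances are monotone in their signalling input", {
  ch <- default_channels()
  x <- seq(0, 2, length.out = 300)
  expect_true(all(diff(gaba_conductance(x, ch)) >= 0))
  expect_true(all(diff(vocc_conductance(x, ch)) >= 0))
  expect_true(all(diff(vocc_conductance(x, ch, mode = "literal")) >= 0))
})

test_that("VOCC flux: half-activation, reversal, inward sign, frozen value", {
  ch <- default_channels()
  act <- function(v) 1 / (1 + exp(-(v - ch$v_ca2) / ch$r_ca))
  expect_equal(act(-24), 0.5)
  expect_equal(vocc_flux(100, 0.7, ch), 0)
  # inward (negative) below the reversal potential
  v <- seq(-80, 99, length.out = 100)
  expect_true(all(vocc_flux(v, 0.5, ch) <= 0))
  # frozen direct evaluation at -60 mV, NPY = 0
  expect_equal(vocc_flux(-60, 0, ch) / ch$g_ca_i, -2.28304,
               tolerance = 1e-5)
})

test_that("surrogate has a baseline fixed point (all derivatives ~0)", {
  p <- default_params()
  y0 <- equilibrate(p)
  vs <- as.list(y0[c("k_e", "k_p", "v_k", "v_i", "ca_i", "radius")])
  ss <- as.list(y0[c("gaba", "npy", "glu", "no_n")])
  d <- surrogate_rhs(vs, ss, i_ke = 0, p)
  expect_lt(max(abs(d)), 1e-9)
  expect_equal(y0[["radius"]], 1, tolerance = 1e-3)
})

test_that("baseline fixed point is recovered from perturbed initial states", {
  p <- default_params()
  y0 <- equilibrate(p)
  pert <- y0
  pert[c("k_e", "k_p")] <- pert[c("k_e", "k_p")] + 1.5
  pert[c("v_k", "v_i")] <- pert[c("v_k", "v_i")] - 5
  pert["ca_i"] <- 1.3
  pert["radius"] <- 0.9
  parms <- list(p = p, proto = stimulus_protocol(), inputs_off = TRUE,
                r_eq = attr(y0, "r_eq"))
  out <- deSolve::lsoda(as.numeric(pert) |> stats::setNames(names(y0)),
                        c(0, 10000), nvcgaba:::model_rhs, parms,
                        rtol = 1e-8, atol = 1e-10)
  final <- out[2, names(y0)]
  idx <- c("k_e", "k_p", "v_k", "v_i", "ca_i", "radius")
  expect_equal(unname(final[idx]), unname(y0[idx]), tolerance = 1e-3)
})

test_that("raising perivascular K+ drives the dilation sign-chain", {
  p <- default_params()
  y0 <- equilibrate(p)
  base <- y0[c("k_e", "k_p", "v_k", "v_i", "ca_i", "radius")]
  ss <- as.list(y0[c("gaba", "npy", "glu", "no_n")])
  # steady state of the vascular block with k_e and k_p clamped high
  clamp_run <- function(vs0, ss, hold) {
    rhs <- function(t, y, parms) {
      d <- surrogate_rhs(as.list(y), ss, i_ke = 0, p)
      d[names(hold)] <- 0
      list(d[names(y)])
    }
    out <- deSolve::lsoda(vs0, c(0, 3e4), rhs, NULL, rtol = 1e-8, atol = 1e-10)
    out[2, -1]
  }
  vhi <- base; vhi[c("k_e", "k_p")] <- vhi[c("k_e", "k_p")] + 6
  st <- clamp_run(vhi, ss, hold = c(k_e = 0, k_p = 0))
  expect_lt(st[["v_i"]], base[["v_i"]])      # hyperpolarized
  expect_lt(st[["ca_i"]], base[["ca_i"]])    # less VOCC Ca2+ entry
  expect_gt(st[["radius"]], 1)               # dilation
  # NPY alone (GABA at base) constricts
  ss_npy <- ss; ss_npy$npy <- 1.5
  st2 <- clamp_run(base, ss_npy, hold = c(k_e = 0, k_p = 0))
  expect_gt(st2[["ca_i"]], base[["ca_i"]])
  expect_lt(st2[["radius"]], 1)
  # GABA alone (NPY at base) dilates via the Cl- channel
  ss_gaba <- ss; ss_gaba$gaba <- 0.73
  st3 <- clamp_run(base, ss_gaba, hold = c(k_e = 0, k_p = 0))
  expect_lt(st3[["v_i"]], base[["v_i"]])
  expect_gt(st3[["radius"]], 1)
})

test_that("radius map is decreasing in Ca2+ and fixed at baseline", {
  sp <- default_params()$surrogate
  expect_equal(radius_target(1, sp), 1)
  ca <- seq(0, 2.5, length.out = 100)
  expect_true(all(diff(radius_target(ca, sp)) <= 0))
  expect_true(all(radius_target(ca, sp) > 0))
})
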