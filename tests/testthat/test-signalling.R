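test_that("heaviside stimulus window uses strict boundaries", {
  expect_equal(heaviside_input(1500, 1000, 2000), 1)
  expect_equal(heaviside_input(999, 1000, 2000), 0)
  expect_equal(heaviside_input(3001, 1000, 2000), 0)
  # both endpoints are outside the window
  expect_equal(heaviside_input(c(1000, 3000), 1000, 2000), c(0, 0))
  expect_error(heaviside_input(0, 0, 0), class = "nvc_invalid_protocol")
  expect_error(heaviside_input(0, 0, -5), class = "nvc_invalid_protocol")
})

test_that("GABA-T activity sigmoid hits its anchors and limits", {
  p <- default_signalling()
  expect_equal(gaba_t_activity(p$gt_midpoint, p), (p$gt_max + p$gt_min) / 2)
  expect_equal(gaba_t_activity(1e6, p), p$gt_min, tolerance = 1e-12)
  # frozen direct evaluation at zero NO with the default constants
  expect_equal(gaba_t_activity(0, p), 1.996456525, tolerance = 1e-8)
  expect_error(gaba_t_activity(-0.1, p), class = "nvc_invalid_parameter")
})

test_that("GABA-T activity is bounded and monotone non-increasing in NO", {
  p <- default_signalling()
  no_grid <- seq(0, 1, length.out = 400)
  act <- gaba_t_activity(no_grid, p)
  expect_true(all(act >= p$gt_min & act <= p$gt_max))
  expect_true(all(diff(act) <= 0))
  # strictly interior where the sigmoid has not saturated in double precision
  inner <- gaba_t_activity(seq(0, 0.15, length.out = 100), p)
  expect_true(all(inner > p$gt_min & inner < p$gt_max))
})

test_that("GABA degradation rate is proportional to GABA-T activity", {
  p <- default_signalling()
  expect_equal(gaba_degradation_rate(1, p), 2.2e-3)
  expect_equal(gaba_degradation_rate(2, p), 4.4e-3)
  p1 <- p; p1$beta_gaba <- 1
  expect_equal(gaba_degradation_rate(0.5, p1), 0.5)
  expect_error(gaba_degradation_rate(0, p), class = "nvc_invalid_parameter")
})

test_that("GABA, NPY and NO state equations rest at their baselines", {
  p <- default_signalling()
  expect_equal(gaba_rhs(list(gaba = p$gaba_base, no_n = p$no_rest), 0, p), 0)
  expect_equal(npy_rhs(list(npy = p$npy_base), 0, p), 0)
  expect_equal(no_rhs(list(no_n = p$no_rest), 0, 0, p), 0)
  # NOS blockade zeroes both sources: derivative is pure decay
  expect_equal(no_rhs(list(no_n = 0.01), 1, 1, p), -p$no_beta * 0.01)
})

test_that("integrated steady states match the alpha/beta closed forms", {
  p <- default_signalling()
  # sustained GABA input with GABA-T pinned at each bound (NO saturating vs 0)
  for (no_val in c(1e3, 0)) {
    gt <- gaba_t_activity(no_val, p)
    ss_num <- integrate_to_steady(function(g) {
      gaba_rhs(list(gaba = g, no_n = no_val), 1, p)
    })
    ss_closed <- p$gaba_base + p$alpha_gaba / (p$beta_gaba * gt)
    expect_equal(ss_num, ss_closed, tolerance = 1e-3, ignore_attr = TRUE)
  }
  # NPY: alpha/beta = 4.2/2.2
  ss_npy <- integrate_to_steady(function(y) npy_rhs(list(npy = y), 1, p))
  expect_equal(ss_npy, 4.2e-3 / 2.2e-3, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(4.2e-3 / 2.2e-3, 1.9090909, tolerance = 1e-7)
  # glutamate under a constant release source F with no GABA
  ss_glu <- integrate_to_steady(function(y) {
    glu_rhs(list(glu = y, gaba = 0), ke = 10, gt_act = 1, p)
  })
  expect_equal(ss_glu, glutamate_release(10, p) / p$beta_glu,
               tolerance = 1e-3, ignore_attr = TRUE)
  # NO under sustained stimulation without blockade
  ss_no <- integrate_to_steady(function(y) no_rhs(list(no_n = y), 1, 0, p),
                               y0 = p$no_rest)
  expect_equal(ss_no, p$no_rest + p$no_alpha / p$no_beta,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("NPY decays exponentially with time constant 1/beta_NPY", {
  p <- default_signalling()
  tau <- 1 / p$beta_npy
  expect_equal(tau, 454.5455, tolerance = 1e-6)
  out <- deSolve::lsoda(c(y = 1.5), c(0, tau),
                        function(t, y, parms) list(npy_rhs(list(npy = y), 0, p)),
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(out[2, "y"], 1.5 * exp(-1), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("stimulated GABA elevation halves between the GABA-T bounds", {
  p <- default_signalling()
  ss_min <- p$alpha_gaba / (p$beta_gaba * p$gt_min)
  ss_max <- p$alpha_gaba / (p$beta_gaba * p$gt_max)
  expect_equal(ss_min, 0.7272727, tolerance = 1e-7)
  # analytic identity: drop = 100 (1 - GT_min/GT_max)
  expect_equal(100 * (1 - ss_max / ss_min),
               100 * (1 - p$gt_min / p$gt_max))
  expect_equal(100 * (1 - ss_max / ss_min), 50)
})

test_that("glutamate release sigmoid: threshold, saturation, rest", {
  p <- default_signalling()
  expect_equal(glutamate_release(5, p), p$glu_max / 2)
  expect_equal(glutamate_release(1e4, p), p$glu_max, tolerance = 1e-12)
  expect_lt(glutamate_release(0, p), 1e-20 * p$glu_max)
  ke_grid <- seq(0, 12, length.out = 200)
  expect_true(all(diff(glutamate_release(ke_grid, p)) >= 0))
})

test_that("glutamate balance: rest decay and GABA-sourced production", {
  p <- default_signalling()
  expect_equal(glu_rhs(list(glu = 0, gaba = 0), ke = 0, gt_act = 1, p), 0,
               tolerance = 1e-21)
  # doubling GABA-T activity doubles the GABA-sourced production term
  r1 <- glu_rhs(list(glu = 0, gaba = 0.5), ke = 0, gt_act = 1, p)
  r2 <- glu_rhs(list(glu = 0, gaba = 0.5), ke = 0, gt_act = 2, p)
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
})

test_that("concentrations stay non-negative for random valid protocols", {
  set.seed(42)
  for (i in 1:3) {
    proto <- stimulus_protocol(
      kind = sample(c("whisker", "optogenetic"), 1),
      t0 = runif(1, 200, 1500),
      duration = runif(1, 500, 4000),
      lname = sample(c(TRUE, FALSE), 1))
    tr <- run_condition(proto, post_window = 6000)
    st <- attr(tr, "states")
    expect_gt(min(st[, c("gaba", "npy", "glu", "no_n")]), -1e-9)
  }
})
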