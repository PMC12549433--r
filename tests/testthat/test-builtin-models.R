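test_that("SIS factory enforces its constraints and matches its references", {
  expect_error(make_sis(2, 1.8, c(1, 2), c(1, 1), c(0.4, 0.6)), "normalised")
  expect_error(make_sis(1, 0.9, 1, 1, 1), "subcritical")
  s1 <- make_sis(1, 2, 1, 1, 1)
  expect_equal(s1$reference$E, 1, tolerance = 1e-12)        # E = beta - 1
  expect_equal(equilibrium_point(s1), 0.5, tolerance = 1e-10) # (beta-1)/beta
  s <- sis_k2()
  expect_equal(equilibrium_point(s), s$reference$ystar, tolerance = 1e-10)
  rep <- full_report(s)
  expect_true(rep$results_applicable[["result_tau_prefactor"]])
  expect_equal(tau_full(s, 40), s$reference$tau(40), tolerance = 1e-7)
})

test_that("linear-birth quadratic-death factory matches its references", {
  expect_error(make_example2(2, 0.4, 1, 1), "subcritical")
  m <- make_example2(2, 1, 0.5, 1)
  expect_equal(equilibrium_point(m), c(0.75, 0.75), tolerance = 1e-10)
  expect_gt(m$reference$omega, 0)
  expect_lt(m$reference$omega, 1)
  expect_equal(m$reference$omega, 0.5 / 2)
  rep <- full_report(m)
  expect_true(all(vapply(rep$conditions[c("bd_positive_rates", "theta_irrotational",
                                          "theta0_irrotational",
                                          "bd_constant_birth_rows")],
                         function(c) c$verdict == "PASS", logical(1))))
})

test_that("factorised BD family validates signs and reduces to special cases", {
  k <- 2
  # the linear-birth quadratic-death process in factorised form
  bc <- make_ball_clancy(
    k,
    b0 = function(u) u, d0 = function(u) 0.6 + 0.8 * u,
    bs = replicate(k, function(y) rep(1.2, length(y))),
    ds = replicate(k, function(y) y),
    derivs = list(b0 = function(u) rep(1, length(u)),
                  d0 = function(u) rep(0.8, length(u)),
                  bs = replicate(k, function(y) rep(0, length(y))),
                  ds = replicate(k, function(y) rep(1, length(y)))))
  m <- make_example2(k, 1.2, 0.6, 0.8)
  pts <- criteria_sample_points(m, 12, seed = 2)
  for (key in rownames(m$jumps)) {
    expect_equal(eval_rate(bc, key, pts), eval_rate(m, key, pts), tolerance = 1e-12)
  }
  rep <- full_report(bc)
  expect_true(rep$results_applicable[["result_tau_prefactor"]])
  # constraint violations are named
  expect_error(make_ball_clancy(
    1, b0 = function(u) u + 1, d0 = function(u) 1 + u,
    bs = list(function(y) rep(1, length(y))), ds = list(function(y) y)),
    "b0\\(0\\)")
  expect_error(make_ball_clancy(
    1, b0 = function(u) 0.1 * u, d0 = function(u) 1 + u,
    bs = list(function(y) rep(1, length(y))), ds = list(function(y) y)),
    "supercriticality")
})

test_that("competition factory matches its quadrature references", {
  f <- competition_funs()
  cm <- make_competition(c(1, 1, 1, 2, 1, 2), f)
  expect_true(cm$reference$cycle_pass)
  # generic action vs the printed five-integral decomposition
  for (y in list(c(0.1, 0.1), c(0.35, 0.4), c(0.6, 0.8))) {
    expect_equal(potential(cm, y), cm$reference$V(y), tolerance = 1e-8)
  }
  expect_equal(det(sigma_matrix(cm)), cm$reference$detSigma(), tolerance = 1e-8)
  # reversible case (no exchange jumps): prefactor matches the closed form
  cm0 <- make_competition(c(1, 1, 1, 2, 0, 0), f)
  expect_equal(nrow(cm0$jumps), 4L)
  expect_equal(tau_full(cm0, 60), cm0$reference$tau(60), tolerance = 1e-8)
  # constraint violations are named
  f_bad <- f; f_bad$d1 <- function(u) u + 0.5
  expect_error(make_competition(c(1, 1, 1, 2, 1, 2), f_bad), "d1\\(0\\)")
})

test_that("two-group factory matches printed forms and degenerates correctly", {
  tg <- two_group_ref()
  expect_equal(equilibrium_point(tg), c(1 / 3, 2 / 3), tolerance = 1e-10)
  expect_equal(tg$reference$ystar, c(1 / 3, 2 / 3), tolerance = 1e-12)
  # generic action vs the closed-form potential on an interior grid
  y1s <- seq(0.06, 0.7, length.out = 8)
  y2s <- seq(0.08, 1.3, length.out = 8)
  Vg <- potential_grid(tg, y1s, y2s)
  for (i in seq_along(y1s)) for (j in seq_along(y2s)) {
    expect_equal(Vg[i, j], tg$reference$V(c(y1s[i], y2s[j])), tolerance = 1e-8)
  }
  # nu = 0 reduces to the pure BD jump set with split birth rates
  tg0 <- two_group_nomove()
  expect_true(is_birth_death(tg0))
  y <- c(0.4, 0.8)
  expect_equal(eval_rate(tg0, "1,0", y), 1 * sum(y))
  expect_equal(eval_rate(tg0, "0,1", y), 2 * sum(y))
  expect_equal(eval_rate(tg0, "-1,0", y), y[1] * (2.9 + 0.1 * sum(y)))
  expect_error(make_two_group(3.1, 0.1, 1, 2), "subcritical")
})

test_that("reference closed forms agree with the generic machinery throughout", {
  # one consolidated consistency sweep at the reference parameter sets
  tg <- two_group_ref()
  expect_equal(log_tau_leading(tg), tg$reference$A, tolerance = 1e-7)
  expect_equal(sigma_matrix(tg), tg$reference$Sigma, tolerance = 1e-7)
  s <- sis_k2()
  expect_equal(equilibrium_point(s), s$reference$ystar, tolerance = 1e-7)
  expect_equal(log_tau_leading(s), s$reference$A, tolerance = 1e-7)
  expect_equal(tau_full(s, 60), s$reference$tau(60), tolerance = 1e-7)
  m <- make_example2(2, 1, 0.5, 1)
  expect_equal(tau_full(m, 60), m$reference$tau(60), tolerance = 1e-7)
})
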