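test_that("integer cycle basis spans the jump-set kernel", {
  # multitype BD jumps are linearly independent: empty basis, vacuous condition
  expect_equal(ncol(integer_cycle_basis(example2_k1())$basis), 0L)
  expect_equal(ncol(integer_cycle_basis(make_example2(3, 1, 0.5, 1))$basis), 0L)
  # competition jumps have the single cycle e1 - e2 - (e1 - e2) = 0
  cb <- integer_cycle_basis(two_group_ref())
  expect_equal(ncol(cb$basis), 1L)
  expect_equal(as.numeric(t(cb$jumps) %*% cb$basis), c(0, 0))
  # basis elements annihilate the jump matrix exactly for a redundant set
  J <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
             c(1L, 1L), c(-1L, -1L), c(2L, -1L), c(-2L, 1L))
  cb2 <- integer_cycle_basis(J)
  expect_equal(ncol(cb2$basis), 2L)
  expect_true(all(t(cb2$jumps) %*% cb2$basis == 0))
  expect_true(all(cb2$basis == round(cb2$basis)))
})

test_that("leading-order cycle condition discriminates movement balance", {
  # printed parameters satisfy lam1 nu1 = lam2 nu2 (1*2 = 2*1)
  expect_equal(check_cycle_condition(two_group_ref())$verdict, "PASS")
  # perturbing nu1 to 3 gives residual ln(lam2 nu2 / lam1 nu1) = ln(2/3)
  cc <- check_cycle_condition(make_two_group(2.9, 0.1, 1, 2, 3, 1))
  expect_equal(cc$verdict, "FAIL")
  expect_equal(cc$residual, abs(log(2 / 3)), tolerance = 1e-10)
  expect_false(is.null(cc$witness))
  # competition family passes iff a1 a4 a5 = a2 a3 a6
  f <- competition_funs()
  expect_equal(check_cycle_condition(
    make_competition(c(1, 1, 1, 2, 1, 2), f))$verdict, "PASS")
  expect_equal(check_cycle_condition(
    make_competition(c(1, 1, 1, 2, 1, 3), f))$verdict, "FAIL")
})

test_that("theta solves the paired-rate log-ratio system", {
  tg <- two_group_ref()
  ystar <- equilibrium_point(tg)
  s <- solve_theta(tg, ystar)
  expect_equal(s$theta, c(0, 0), tolerance = 1e-9)
  expect_lt(max(s$residual), 1e-9)
  # multitype BD: theta_i is the log death/birth ratio h_i directly
  m <- make_example2(2, 1.2, 0.6, 0.8)
  y <- c(0.5, 0.9)
  h <- vapply(1:2, function(i) {
    ei <- c(0, 0); ei[i] <- 1
    log(eval_rate(m, jump_key(-ei), y) / eval_rate(m, jump_key(ei), y))
  }, numeric(1))
  expect_equal(solve_theta(m, y)$theta, h, tolerance = 1e-12)
  # competition closed forms: theta from the factorised rates directly
  y <- c(0.4, 0.8)
  th <- solve_theta(tg, y)
  s_tot <- sum(y)
  expect_equal(th$theta[1], log(y[1] * (2.9 + 0.1 * s_tot) / (1 * s_tot)),
               tolerance = 1e-10)
  expect_equal(th$theta[2], log(y[2] * (2.9 + 0.1 * s_tot) / (2 * s_tot)),
               tolerance = 1e-10)
  expect_lt(max(th$residual), 1e-10)
  # plug-back: every individual jump equation holds when the residual is zero
  R <- qswkb:::representative_jumps(tg)
  for (i in seq_len(nrow(R))) {
    lhs <- sum(R[i, ] * th$theta)
    rhs <- log(eval_rate(tg, jump_key(-R[i, ]), y) / eval_rate(tg, jump_key(R[i, ]), y))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("theta residual vanishes exactly when the cycle condition passes", {
  pts <- criteria_sample_points(two_group_ref(), n = 16, seed = 5)
  res_pass <- max(solve_theta(two_group_ref(), pts)$residual)
  expect_lt(res_pass, 1e-10)
  bad <- make_two_group(2.9, 0.1, 1, 2, 3, 1)
  res_fail <- max(solve_theta(bad, criteria_sample_points(bad, n = 16, seed = 5))$residual)
  expect_gt(res_fail, 1e-3)
})

test_that("irrotationality holds for the reference families", {
  expect_equal(check_irrotational(two_group_ref(), "theta")$verdict, "PASS")
  expect_equal(check_irrotational(two_group_ref(), "theta0")$verdict, "PASS")
  s <- sis_k2()
  expect_equal(check_irrotational(s, "theta")$verdict, "PASS")
  expect_equal(check_irrotational(s, "theta0")$verdict, "PASS")
})

test_that("theta0 system solvability tracks the rate-product structure", {
  # BD case: theta0_i = half the log-derivative of the rate product
  m <- make_example2(2, 1.2, 0.6, 0.8)
  y <- c(0.5, 0.9)
  t0 <- solve_theta0(m, y)
  ref <- vapply(1:2, function(i) {
    ei <- c(0, 0); ei[i] <- 1
    g <- function(z) log(eval_rate(m, jump_key(ei), z) * eval_rate(m, jump_key(-ei), z))
    h <- 1e-6
    yp <- y; ym <- y; yp[i] <- yp[i] + h; ym[i] <- ym[i] - h
    0.5 * (g(yp) - g(ym)) / (2 * h)
  }, numeric(1))
  expect_equal(t0$theta0, ref, tolerance = 1e-5)
  expect_lt(max(t0$residual), 1e-10)
  # 1-d model: system square, always solvable
  expect_lt(max(solve_theta0(example2_k1(), 0.7)$residual), 1e-12)
  # competition: solvable iff b3 * d3 is constant
  f <- competition_funs()
  a <- c(1, 1, 1, 2, 1, 2)
  ok <- make_competition(a, f)
  expect_lt(max(solve_theta0(ok, criteria_sample_points(ok, 16))$residual), 1e-10)
  f2 <- f
  f2$b3 <- function(u) 1 + 0.3 * u^2
  bad <- make_competition(a, f2)
  expect_gt(max(solve_theta0(bad, criteria_sample_points(bad, 16))$residual), 1e-3)
})

test_that("full report classifies which analytic results apply", {
  rep2 <- full_report(make_example2(2, 1.2, 0.6, 0.8))
  for (nm in c("bd_positive_rates", "theta_irrotational", "theta0_irrotational",
               "bd_constant_birth_rows")) {
    expect_equal(rep2$conditions[[nm]]$verdict, "PASS")
  }
  expect_true(all(rep2$results_applicable))
  # movement model: general results apply, the BD prefactor result does not
  rtg <- full_report(two_group_ref())
  expect_false(rtg$is_birth_death)
  expect_true(rtg$results_applicable[["result_logtau_general"]])
  expect_true(rtg$results_applicable[["result_qsd_general"]])
  expect_false(rtg$results_applicable[["result_tau_prefactor"]])
  # dropping movement restores the pure BD structure and the prefactor result
  r0 <- full_report(two_group_nomove())
  expect_true(r0$is_birth_death)
  expect_true(r0$results_applicable[["result_tau_prefactor"]])
  # JSON export round-trips the verdicts
  j <- jsonlite::fromJSON(criteria_report_json(rtg))
  expect_equal(j$conditions$cycle_leading$verdict, "PASS")
})
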