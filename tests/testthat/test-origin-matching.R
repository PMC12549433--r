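test_that("origin linearisation extracts the branching-process coefficients", {
  # SIS: b_ij = beta mu_i f_i for all j, d_i = 1/alpha_i
  s <- sis_k2()
  lin <- linearise_origin(s)
  p <- s$params
  expect_equal(lin$b, matrix(p$beta * p$mu * p$f, 2, 2), tolerance = 1e-8)
  expect_equal(lin$d, 1 / p$alpha, tolerance = 1e-8)
  expect_true(lin$condition_rates)
  # linear-birth quadratic-death: b_ij = lambda, d_i = mu
  m <- make_example2(2, 1.2, 0.6, 0.8)
  lin2 <- linearise_origin(m)
  expect_equal(lin2$b, matrix(1.2, 2, 2), tolerance = 1e-8)
  expect_equal(lin2$d, c(0.6, 0.6), tolerance = 1e-8)
  # two-group without movement: constant birth rows b_i1 = b_i2 = lambda_i
  tg0 <- two_group_nomove()
  lin3 <- linearise_origin(tg0)
  expect_equal(lin3$b, rbind(c(1, 1), c(2, 2)), tolerance = 1e-8)
  expect_equal(lin3$d, c(2.9, 2.9), tolerance = 1e-8)
  # non-BD jump sets are refused
  expect_error(linearise_origin(two_group_ref()), class = "qswkb_not_birth_death")
})

test_that("the decay constant D solves its defining equation", {
  # symmetric closed form: D = k lambda - mu
  m <- make_example2(2, 1.2, 0.6, 0.8)
  lin <- linearise_origin(m)
  D <- solve_D(lin)
  expect_equal(D, 2 * 1.2 - 0.6, tolerance = 1e-12)
  expect_equal(sum(diag(lin$b) / (D + lin$d)), 1, tolerance = 1e-12)
  # k = 1: D = b - d
  lin1 <- linearise_origin(example2_k1())
  expect_equal(solve_D(lin1), 2 - 1, tolerance = 1e-12)
  # criticality boundary: no positive root
  crit <- structure(list(b = diag(c(1, 1)), d = c(2, 2)),
                    class = "origin_linearisation")
  expect_error(solve_D(crit), class = "qswkb_subcritical")
})

test_that("near-origin weights satisfy the linearised balance equation", {
  m <- make_example2(2, 1.2, 0.6, 0.8)
  lin <- linearise_origin(m)
  D <- solve_D(lin)
  # single-individual states: b_ii (1/d_i - 1/(D + d_i))
  for (i in 1:2) {
    x <- c(0, 0); x[i] <- 1
    expect_equal(u_tilde(lin, x, D = D),
                 lin$b[i, i] * (1 / lin$d[i] - 1 / (D + lin$d[i])),
                 tolerance = 1e-12)
  }
  # positivity on a block of states
  grid <- as.matrix(expand.grid(0:6, 0:6))
  grid <- grid[rowSums(grid) > 0, ]
  expect_true(all(u_tilde(lin, grid, D = D) > 0))
  # balance equation at interior states, with the convention u(0) = 0
  ut <- function(x) if (all(x >= 0) && sum(x) > 0) u_tilde(lin, x, D = D) else 0
  for (x in list(c(1, 1), c(2, 1), c(3, 2))) {
    lhs <- 0
    for (i in 1:2) {
      ei <- c(0, 0); ei[i] <- 1
      lhs <- lhs + ut(x - ei) * sum((x - ei) * lin$b[i, ]) +
        ut(x + ei) * (x[i] + 1) * lin$d[i]
    }
    out <- sum(vapply(1:2, function(i) sum(x * lin$b[i, ]) + x[i] * lin$d[i], numeric(1)))
    expect_equal(lhs, ut(x) * out, tolerance = 1e-12)
  }
  # telescoping flux identity: sum_i u(e_i) d_i = D (Lambda-free constant 1)
  flux <- sum(vapply(1:2, function(i) {
    x <- c(0, 0); x[i] <- 1
    u_tilde(lin, x, D = D) * lin$d[i]
  }, numeric(1)))
  expect_equal(flux, D, tolerance = 1e-12)
  # log-space evaluation stays finite far beyond naive overflow
  big <- c(400, 350)
  expect_true(is.finite(u_tilde(lin, big, D = D, log = TRUE)))
})

test_that("the full prefactor reproduces the printed closed forms", {
  for (m in list(example2_k1(), make_example2(2, 1, 0.5, 1),
                 make_example2(3, 0.9, 1.1, 0.4))) {
    expect_equal(tau_full(m, 50), m$reference$tau(50), tolerance = 1e-8)
  }
  tg0 <- two_group_nomove()
  expect_equal(tau_full(tg0, 60), tg0$reference$tau(60), tolerance = 1e-8)
  # symmetric two-group coincides with the one-family closed form
  e2 <- make_example2(2, 1.5, 2.9, 0.1)
  tg_eq <- make_two_group(2.9, 0.1, 1.5, 1.5, 0, 0)
  expect_equal(tau_full(tg_eq, 70), e2$reference$tau(70), tolerance = 1e-10)
  # movement model has no BD prefactor: refused
  expect_error(tau_full(two_group_ref(), 50), class = "qswkb_not_birth_death")
})

test_that("the prefactor is invariant under relabelling of coordinates", {
  f <- c(0.4, 0.6)
  mu <- c(1.3, 0.8); mu <- mu / sum(mu * f)
  s <- make_sis(2, 1.8, mu, c(1, 1.5), f)
  s_swap <- make_sis(2, 1.8, mu[2:1], c(1.5, 1), f[2:1])
  expect_equal(tau_full(s, 40), tau_full(s_swap, 40), tolerance = 1e-8)
  expect_equal(tau_full(s, 40), s$reference$tau(40), tolerance = 1e-7)
})

test_that("near-origin and WKB forms match along rays at moderate scale", {
  # log(Lambda * u_tilde) and the log WKB mass agree up to a vanishing
  # offset: the offset is independent of the ray direction and shrinks as
  # the matching region |x| ~ sqrt(N) is entered from below
  tg0 <- two_group_nomove()
  lin <- linearise_origin(tg0)
  D <- solve_D(lin)
  N <- 400
  log_lambda <- -log(D * tau_full(tg0, N))
  offs <- sapply(c(0.35, 0.6), function(xi1) {
    sapply(c(1, 2), function(scale) {
      x <- round(scale * sqrt(N) * c(xi1, 1 - xi1))
      lu <- u_tilde(lin, x, D = D, log = TRUE) + log_lambda
      lw <- log(wkb_prefactor(tg0, N)) - N * potential(tg0, x / N) -
        correction(tg0, x / N)
      lu - lw
    })
  })
  # direction-independence of the offset at each scale
  expect_lt(max(abs(offs[1, 1] - offs[1, 2])), 0.02)
  expect_lt(max(abs(offs[2, 1] - offs[2, 2])), 0.02)
  # offset decays as the scale grows
  expect_lt(abs(offs[2, 1]), abs(offs[1, 1]))
})

test_that("prefactor accuracy against the exact oracle improves with N", {
  m <- example2_study()
  errs <- vapply(c(20, 40, 60), function(N) {
    tau_ex <- exact_tau(build_truncated(m, N), m)$tau
    abs(tau_full(m, N) / tau_ex - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
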