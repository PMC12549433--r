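test_that("action potential matches closed forms and is path independent", {
  tg <- two_group_ref()
  expect_equal(potential(tg, equilibrium_point(tg)), 0, tolerance = 1e-12)
  # value at total extinction: (lam1+lam2-mu)/kappa + (mu/kappa) ln(mu/(lam1+lam2))
  A_ref <- (3 - 2.9) / 0.1 + 29 * log(2.9 / 3)
  expect_equal(potential(tg, c(0, 0)), A_ref, tolerance = 1e-9)
  expect_equal(log_tau_leading(tg), A_ref, tolerance = 1e-9)
  # two different piecewise-linear paths agree
  tgt <- c(0.22, 0.51)
  v0 <- potential(tg, tgt)
  v1 <- potential(tg, tgt, waypoints = rbind(c(0.8, 0.9), c(0.15, 1.1)))
  v2 <- potential(tg, tgt, waypoints = rbind(c(0.5, 0.2)))
  expect_lt(max(abs(c(v1, v2) - v0)), 1e-6)
  # grid fast path agrees with adaptive quadrature
  y1s <- c(0.15, 0.4); y2s <- c(0.3, 0.9)
  Vg <- potential_grid(tg, y1s, y2s)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(Vg[i, j], potential(tg, c(y1s[i], y2s[j])), tolerance = 1e-9)
  }
})

test_that("potential is positive away from the equilibrium with zero gradient there", {
  tg <- two_group_ref()
  ys <- equilibrium_point(tg)
  set.seed(11)
  for (r in 1:10) {
    y <- runif(2, 0.05, 1.6) * ys
    if (max(abs(y - ys)) < 1e-3) next
    expect_gt(potential(tg, y), 0)
  }
  h <- 1e-5
  g <- vapply(1:2, function(i) {
    e <- c(0, 0); e[i] <- h
    (potential(tg, ys + e) - potential(tg, ys - e)) / (2 * h)
  }, numeric(1))
  expect_equal(g, c(0, 0), tolerance = 1e-8)
})

test_that("paired rates balance at the equilibrium", {
  for (m in list(two_group_ref(), sis_k2(), make_example2(2, 1.2, 0.6, 0.8))) {
    ys <- equilibrium_point(m)
    for (key in rownames(m$jumps)) {
      expect_equal(eval_rate(m, key, ys),
                   eval_rate(m, jump_key(-m$jumps[key, ]), ys),
                   tolerance = 1e-9)
    }
  }
})

test_that("transport correction telescopes independently of the decomposition", {
  tg <- two_group_ref()
  ys <- equilibrium_point(tg)
  expect_equal(correction(tg, ys), 0)
  y <- c(0.21, 0.47)
  d1 <- correction(tg, y)
  d2 <- correction(tg, y, list(list(l = c(0, 1), a = y[2] - ys[2]),
                               list(l = c(1, 0), a = y[1] - ys[1])))
  d3 <- correction(tg, y, list(list(l = c(1, -1), a = y[1] - ys[1]),
                               list(l = c(0, 1), a = y[2] - ys[2] + (y[1] - ys[1]))))
  expect_lt(max(abs(c(d2, d3) - d1)), 1e-10)
  # boundary divergence
  expect_error(correction(tg, c(0, 0.5)), "diverges")
})

test_that("BD correction reproduces the nested rate-product form", {
  m <- make_example2(2, 1.2, 0.6, 0.8)
  ys <- equilibrium_point(m)
  y <- c(0.6, 1.1)
  # exp(-V0) equals the square-rooted nested product of paired rates
  prods <- 1
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- 1
    up <- ys; up[seq_len(i - 1)] <- y[seq_len(i - 1)]   # (y_1..y_{i-1}, y_i*, y_k*)
    dn <- up; dn[i] <- y[i]
    num <- eval_rate(m, jump_key(ei), up) * eval_rate(m, jump_key(-ei), up)
    den <- eval_rate(m, jump_key(ei), dn) * eval_rate(m, jump_key(-ei), dn)
    prods <- prods * num / den
  }
  expect_equal(exp(-correction(m, y)), sqrt(prods), tolerance = 1e-10)
})

test_that("Sigma is the symmetric Hessian solving the Lyapunov equation", {
  tg <- two_group_ref()
  S <- sigma_matrix(tg)
  expect_equal(S, t(S))
  expect_equal(S, tg$reference$Sigma, tolerance = 1e-8)
  expect_equal(det(S), tg$reference$detSigma, tolerance = 1e-8)
  J <- drift_jacobian(tg, equilibrium_point(tg))
  G <- diffusion_matrix(tg)
  Si <- solve(S)
  expect_lt(max(abs(J %*% Si + Si %*% t(J) + G)), 1e-8)
  # Hessian of the potential at the equilibrium equals Sigma
  ys <- equilibrium_point(tg)
  h <- 1e-4
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- c(0, 0); ei[i] <- h
    ej <- c(0, 0); ej[j] <- h
    H[i, j] <- (potential(tg, ys + ei + ej) - potential(tg, ys + ei - ej) -
                  potential(tg, ys - ei + ej) + potential(tg, ys - ei - ej)) / (4 * h^2)
  }
  expect_equal(H, S, tolerance = 1e-5)
})

test_that("WKB mass formula matches the printed closed form and normalises", {
  tg <- two_group_ref()
  N <- 99  # N y* is integer here, so the mode is an exact lattice point
  x_mode <- N * equilibrium_point(tg)
  expect_equal(wkb_qsd(tg, N, x_mode), wkb_prefactor(tg, N), tolerance = 1e-12)
  expect_equal(gaussian_qsd(tg, N, x_mode), wkb_prefactor(tg, N), tolerance = 1e-12)
  # interior grid points vs the closed-form mass
  N <- 100
  xs <- rbind(c(30, 60), c(20, 80), c(45, 70), c(12, 30), c(60, 110))
  expect_equal(wkb_qsd(tg, N, xs),
               apply(xs, 1, function(x) tg$reference$qsd(N, x)),
               tolerance = 1e-8)
  # boundary-layer states are refused
  expect_error(wkb_qsd(tg, N, c(2, 60)), "boundary")
  # total interior mass is approximately 1
  tab <- qswkb:::sim_table(tg, N)
  S <- tab$states[rowSums(tab$states) > 0, ]
  inner <- qswkb:::boundary_distance(tg, S / N) >= default_boundary_cutoff(tg, N)
  V <- qswkb:::grid_potentials(tg, S[inner, ], N)
  V0 <- vapply(which(inner), function(i) correction(tg, S[i, ] / N), numeric(1))
  mass <- sum(wkb_prefactor(tg, N) * exp(-N * V - V0))
  expect_gt(mass, 0.95)
  expect_lt(mass, 1.05)
})

test_that("Gaussian approximation agrees with WKB near the mode and not in the tail", {
  tg <- two_group_ref()
  N <- 99
  x0 <- N * equilibrium_point(tg)
  # within a sqrt(N) neighbourhood the two agree to first order
  for (r in c(4, 8)) {
    x <- x0 + c(r, -r)
    expect_equal(wkb_qsd(tg, N, x) / gaussian_qsd(tg, N, x), 1, tolerance = 0.1)
  }
  # far in the tail they diverge by orders of magnitude
  x_tail <- round(x0 * 0.35)
  ratio <- wkb_qsd(tg, N, x_tail) / gaussian_qsd(tg, N, x_tail)
  expect_gt(abs(log(ratio)), 1)
})

test_that("leading extinction exponent matches each family's closed form", {
  m <- example2_k1()
  expect_equal(log_tau_leading(m), m$reference$A, tolerance = 1e-9)
  m3 <- make_example2(3, 0.9, 1.1, 0.4)
  expect_equal(log_tau_leading(m3), m3$reference$A, tolerance = 1e-9)
  s <- sis_k2()
  expect_equal(log_tau_leading(s), s$reference$A, tolerance = 1e-9)
  s1 <- make_sis(1, 2, 1, 1, 1)
  expect_equal(log_tau_leading(s1), log(2) - 0.5, tolerance = 1e-9)  # f ln(1+E) - E/beta
})
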