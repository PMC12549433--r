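#' Built-in model families
#'
#' Factory functions for the model families analysed in the package, each
#' bundled with analytic rate gradients and, where available, closed-form
#' reference expressions (equilibrium, action, curvature, extinction time)
#' stored in the model's `reference` element.  The references are used by
#' the test-suite as independent oracles for the generic machinery.
#'
#' @name builtin_models
NULL

unit_jump_set <- function(k) {
  J <- rbind(diag(1L, k), diag(-1L, k))
  rownames(J) <- apply(J, 1L, jump_key)
  J
}

# numeric derivative of a scalar function of one variable (vectorised)
scalar_deriv <- function(fn) {
  force(fn)
  function(u) {
    h <- 1e-6 * (1 + abs(u))
    (fn(u + h) - fn(u - h)) / (2 * h)
  }
}

#' Heterogeneous-susceptibility SIS epidemic model
#'
#' Susceptible-infectious-susceptible dynamics in a population partitioned
#' into `k` groups with relative sizes `f`, susceptibilities `mu` (scaled
#' so that `sum(mu * f) = 1`) and mean infectious periods `alpha`.
#' Infection of a type-`i` susceptible occurs at rate
#' \eqn{\beta \mu_i (f_i - y_i) \sum_j y_j}; recovery at per-capita rate
#' \eqn{1/\alpha_i}.  Supercritical when
#' \eqn{\beta \sum_i \alpha_i\mu_i f_i > 1}.
#'
#' @param k number of groups.
#' @param beta overall infection rate.
#' @param mu susceptibility vector (length `k`).
#' @param alpha mean infectious period vector (length `k`).
#' @param f group fraction vector (length `k`, positive, `sum(mu*f) = 1`
#'   required).
#' @return a `population_process` (finite box state space) with a
#'   `reference` list: `E` (endemic force-of-infection root), `ystar`,
#'   `A` (leading extinction exponent) and `tau(N)`.
#' @export
make_sis <- function(k, beta, mu, alpha, f) {
  stopifnot(k >= 1, beta > 0, length(mu) == k, length(alpha) == k,
            length(f) == k, all(mu > 0), all(alpha > 0), all(f > 0))
  if (abs(sum(mu * f) - 1) > 1e-8) {
    stop("susceptibilities must be normalised: sum(mu * f) = 1")
  }
  if (beta * sum(alpha * mu * f) <= 1) {
    stop("subcritical parameters: beta * sum(alpha*mu*f) must exceed 1")
  }
  rates <- list(); grads <- list()
  for (i in seq_len(k)) {
    ei <- integer(k); ei[i] <- 1L
    local({
      i <- i
      rates[[jump_key(ei)]] <<- function(Y) {
        beta * mu[i] * pmax(f[i] - Y[, i], 0) * rowSums(Y)
      }
      rates[[jump_key(-ei)]] <<- function(Y) Y[, i] / alpha[i]
      grads[[jump_key(ei)]] <<- function(Y) {
        s <- rowSums(Y)
        G <- matrix(beta * mu[i] * (f[i] - Y[, i]), nrow(Y), k)
        G[, i] <- G[, i] - beta * mu[i] * s
        G
      }
      grads[[jump_key(-ei)]] <<- function(Y) {
        G <- matrix(0, nrow(Y), k); G[, i] <- 1 / alpha[i]; G
      }
    })
  }
  model <- population_process(k, unit_jump_set(k), rates, space = "box", f = f,
                              gradients = grads, name = "sis",
                              params = list(k = k, beta = beta, mu = mu,
                                            alpha = alpha, f = f))
  E <- stats::uniroot(function(E) beta * sum(alpha * mu * f / (alpha * mu * E + 1)) - 1,
                      c(1e-12, beta * sum(alpha * mu * f) * 10), tol = 1e-14)$root
  ystar <- alpha * mu * f * E / (1 + alpha * mu * E)
  A <- sum(f * log(1 + alpha * mu * E)) - E / beta
  D <- solve_D(structure(list(b = matrix(beta * mu * f, k, k),
                              d = 1 / alpha), class = "origin_linearisation"))
  model$reference <- list(
    E = E, ystar = ystar, A = A,
    tau = function(N) {
      (1 / (D * E)) * sqrt(2 * pi / N / sum(f * (alpha * mu / (1 + alpha * mu * E))^2)) *
        exp(N * A)
    })
  model
}

#' Linear-birth quadratic-death multitype birth-death process
#'
#' `k` interacting types on the unbounded orthant: type-`i` births at rate
#' \eqn{\lambda \sum_j y_j} and deaths at rate
#' \eqn{y_i(\mu + \kappa\sum_j y_j)}.  Supercritical when
#' \eqn{k\lambda > \mu}; the symmetric interior equilibrium has
#' \eqn{y^*_i = (k\lambda-\mu)/(k\kappa)}.
#'
#' @param k number of types.
#' @param lam per-capita birth rate \eqn{\lambda}.
#' @param mu baseline death rate \eqn{\mu}.
#' @param kappa density-dependent death coefficient \eqn{\kappa}.
#' @return a `population_process` with `reference`: `ystar`, `A`, `omega`
#'   (= \eqn{\mu/k\lambda}) and `tau(N)` (closed-form extinction time).
#' @export
make_example2 <- function(k, lam, mu, kappa) {
  stopifnot(k >= 1, lam > 0, mu > 0, kappa > 0)
  if (k * lam <= mu) stop("subcritical parameters: need k*lambda > mu")
  rates <- list(); grads <- list()
  for (i in seq_len(k)) {
    ei <- integer(k); ei[i] <- 1L
    local({
      i <- i
      rates[[jump_key(ei)]] <<- function(Y) lam * rowSums(Y)
      rates[[jump_key(-ei)]] <<- function(Y) Y[, i] * (mu + kappa * rowSums(Y))
      grads[[jump_key(ei)]] <<- function(Y) matrix(lam, nrow(Y), k)
      grads[[jump_key(-ei)]] <<- function(Y) {
        G <- matrix(kappa * Y[, i], nrow(Y), k)
        G[, i] <- G[, i] + mu + kappa * rowSums(Y)
        G
      }
    })
  }
  model <- population_process(k, unit_jump_set(k), rates, space = "unbounded",
                              gradients = grads, name = "example2",
                              params = list(k = k, lam = lam, mu = mu, kappa = kappa))
  A <- (k * lam - mu) / kappa + (mu / kappa) * log(mu / (k * lam))
  model$reference <- list(
    ystar = rep((k * lam - mu) / (k * kappa), k),
    A = A,
    omega = mu / (k * lam),
    tau = function(N) (1 / (k * lam - mu)^2) * sqrt(2 * pi * mu * kappa / N) * exp(N * A))
  model
}

#' Factorised multitype birth-death family
#'
#' Birth and death rates factorise through the total density:
#' \eqn{\beta_{e_i}(y) = b_0(\sum_j y_j)\, b_i(y_i)} and
#' \eqn{\beta_{-e_i}(y) = d_0(\sum_j y_j)\, d_i(y_i)}.  The constructor
#' enforces the sign and zero requirements of the family
#' (\eqn{b_0(0)=0}, \eqn{b_i(0)>0}, \eqn{d_i(0)=0}, positivity on the open
#' domains, and the box-endpoint conditions for finite state spaces) and
#' checks supercriticality
#' \eqn{(b_0'(0)/d_0(0)) \sum_i b_i(0)/d_i'(0) > 1}.
#'
#' @param k number of types.
#' @param b0,d0 vectorised functions of the total density `u`.
#' @param bs,ds lists of `k` vectorised functions of `y_i`.
#' @param space `"unbounded"` or `"box"`.
#' @param f box fractions (when `space = "box"`).
#' @param derivs optional list with elements `b0`, `d0`, `bs`, `ds` of
#'   derivative functions; numeric differencing is used otherwise.
#' @return a `population_process`.
#' @export
make_ball_clancy <- function(k, b0, d0, bs, ds, space = c("unbounded", "box"),
                             f = NULL, derivs = NULL) {
  space <- match.arg(space)
  stopifnot(k >= 1, length(bs) == k, length(ds) == k)
  req <- function(ok, what) if (!ok) stop("parameter constraint violated: ", what)
  req(abs(b0(0)) < 1e-12, "b0(0) = 0")
  for (i in seq_len(k)) {
    req(bs[[i]](0) > 0, paste0("b_", i, "(0) > 0"))
    req(abs(ds[[i]](0)) < 1e-12, paste0("d_", i, "(0) = 0"))
  }
  probe <- if (space == "box") {
    req(!is.null(f) && length(f) == k && all(f > 0), "box fractions f > 0")
    req(d0(1) > 0, "d0(1) > 0")
    for (i in seq_len(k)) {
      req(abs(bs[[i]](f[i])) < 1e-12, paste0("b_", i, "(f_", i, ") = 0"))
      req(ds[[i]](f[i]) > 0, paste0("d_", i, "(f_", i, ") > 0"))
    }
    lapply(seq_len(k), function(i) seq(0.05, 0.95, by = 0.15) * f[i])
  } else {
    lapply(seq_len(k), function(i) seq(0.05, 1.5, by = 0.15))
  }
  for (i in seq_len(k)) {
    req(all(bs[[i]](probe[[i]]) > 0), paste0("b_", i, " > 0 on its open domain"))
    req(all(ds[[i]](probe[[i]]) > 0), paste0("d_", i, " > 0 on its open domain"))
  }
  u_probe <- if (space == "box") seq(0.05, 0.95, by = 0.15) else seq(0.05, 1.5, by = 0.15)
  req(all(b0(u_probe) > 0), "b0 > 0 on its open domain")
  req(all(d0(u_probe) > 0), "d0 > 0 on its open domain")
  db0 <- if (!is.null(derivs$b0)) derivs$b0 else scalar_deriv(b0)
  dd0 <- if (!is.null(derivs$d0)) derivs$d0 else scalar_deriv(d0)
  dbs <- if (!is.null(derivs$bs)) derivs$bs else lapply(bs, scalar_deriv)
  dds <- if (!is.null(derivs$ds)) derivs$ds else lapply(ds, scalar_deriv)
  # supercriticality of the origin (linearised growth exceeds decay);
  # one-sided derivatives at 0 via forward differencing when not supplied
  fwd0 <- function(fn) (fn(2e-7) - fn(1e-7)) / 1e-7
  b0p0 <- if (!is.null(derivs$b0)) db0(0) else fwd0(b0)
  dsp0 <- vapply(seq_len(k), function(i)
    if (!is.null(derivs$ds)) dds[[i]](0) else fwd0(ds[[i]]), numeric(1))
  req(d0(0) > 0, "d0(0) > 0")
  req((b0p0 / d0(0)) * sum(vapply(seq_len(k), function(i) bs[[i]](0), numeric(1)) / dsp0) > 1,
      "supercriticality (b0'(0)/d0(0)) * sum b_i(0)/d_i'(0) > 1")
  rates <- list(); grads <- list()
  for (i in seq_len(k)) {
    ei <- integer(k); ei[i] <- 1L
    local({
      i <- i
      rates[[jump_key(ei)]] <<- function(Y) b0(rowSums(Y)) * bs[[i]](Y[, i])
      rates[[jump_key(-ei)]] <<- function(Y) d0(rowSums(Y)) * ds[[i]](Y[, i])
      grads[[jump_key(ei)]] <<- function(Y) {
        s <- rowSums(Y)
        G <- matrix(db0(s) * bs[[i]](Y[, i]), nrow(Y), k)
        G[, i] <- G[, i] + b0(s) * dbs[[i]](Y[, i])
        G
      }
      grads[[jump_key(-ei)]] <<- function(Y) {
        s <- rowSums(Y)
        G <- matrix(dd0(s) * ds[[i]](Y[, i]), nrow(Y), k)
        G[, i] <- G[, i] + d0(s) * dds[[i]](Y[, i])
        G
      }
    })
  }
  population_process(k, unit_jump_set(k), rates, space = space, f = f,
                     gradients = grads, name = "ball_clancy",
                     params = list(k = k))
}

competition_jump_set <- function() {
  J <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
             c(1L, -1L), c(-1L, 1L))
  rownames(J) <- apply(J, 1L, jump_key)
  J
}

#' Two-type competition process family
#'
#' Two-dimensional processes with jump set
#' \eqn{\{\pm e_1, \pm e_2, \pm(e_1 - e_2)\}} whose six rate functions
#' factorise through the coordinates, the total \eqn{y_1+y_2} and the
#' difference \eqn{y_1-y_2}:
#' \deqn{\beta_{-e_1} = a_1 d_0 d_1(y_1) c_2(y_2) d_3,\;
#'       \beta_{e_1}  = a_2 b_0 b_1(y_1) c_2(y_2) b_3,\;
#'       \beta_{-e_2} = a_3 d_0 c_1(y_1) d_2(y_2) b_3,}
#' \deqn{\beta_{e_2}  = a_4 b_0 c_1(y_1) b_2(y_2) d_3,\;
#'       \beta_{e_1-e_2} = a_5 c_0 b_1(y_1) d_2(y_2) b_3^2,\;
#'       \beta_{e_2-e_1} = a_6 c_0 d_1(y_1) b_2(y_2) d_3^2,}
#' where \eqn{b_0, c_0, d_0} take \eqn{y_1+y_2} and \eqn{b_3, d_3} take
#' \eqn{y_1-y_2}.  Setting `a[5] = a[6] = 0` drops the exchange jumps and
#' yields a reversible two-type birth-death process.
#'
#' The attached references evaluate the closed-form action
#' (five one-dimensional integrals of log rate-ratios), the closed-form
#' \eqn{\det\Sigma}, and — in the `a5 = a6 = 0` case — the closed-form
#' extinction time; they are computed from the printed factorised forms by
#' quadrature, independently of the generic path-integral machinery.
#'
#' @param a numeric vector of six nonnegative constants.
#' @param funs named list of vectorised functions `b0, b1, b2, b3, c0, c1,
#'   c2, d0, d1, d2, d3`.
#' @param space `"unbounded"` or `"box"`.
#' @param f box fractions (length 2) when `space = "box"`.
#' @param derivs optional named list of derivative functions (same names).
#' @return a `population_process` with a `reference` list (`V`,
#'   `detSigma`, and `tau(N)` when the exchange jumps are absent).
#' @export
make_competition <- function(a, funs, space = c("unbounded", "box"), f = NULL,
                             derivs = list()) {
  space <- match.arg(space)
  stopifnot(length(a) == 6, all(a >= 0))
  need <- c("b0", "b1", "b2", "b3", "c0", "c1", "c2", "d0", "d1", "d2", "d3")
  if (!all(need %in% names(funs))) {
    stop("`funs` must contain: ", paste(need, collapse = ", "))
  }
  F <- funs
  req <- function(ok, what) if (!ok) stop("parameter constraint violated: ", what)
  req(abs(F$b0(0)) < 1e-12, "b0(0) = 0")
  req(abs(F$d1(0)) < 1e-12, "d1(0) = 0")
  req(abs(F$d2(0)) < 1e-12, "d2(0) = 0")
  req(F$b1(0) > 0 && F$b2(0) > 0 && F$c1(0) > 0 && F$c2(0) > 0,
      "b1(0), b2(0), c1(0), c2(0) > 0")
  dv <- function(nm, fn) if (!is.null(derivs[[nm]])) derivs[[nm]] else scalar_deriv(fn)
  Fd <- stats::setNames(lapply(need, function(nm) dv(nm, F[[nm]])), need)
  drop_exchange <- a[5] == 0 && a[6] == 0
  J <- competition_jump_set()
  if (drop_exchange) J <- J[1:4, , drop = FALSE]
  s_ <- function(Y) Y[, 1] + Y[, 2]
  w_ <- function(Y) Y[, 1] - Y[, 2]
  rates <- list(
    "-1,0" = function(Y) a[1] * F$d0(s_(Y)) * F$d1(Y[, 1]) * F$c2(Y[, 2]) * F$d3(w_(Y)),
    "1,0"  = function(Y) a[2] * F$b0(s_(Y)) * F$b1(Y[, 1]) * F$c2(Y[, 2]) * F$b3(w_(Y)),
    "0,-1" = function(Y) a[3] * F$d0(s_(Y)) * F$c1(Y[, 1]) * F$d2(Y[, 2]) * F$b3(w_(Y)),
    "0,1"  = function(Y) a[4] * F$b0(s_(Y)) * F$c1(Y[, 1]) * F$b2(Y[, 2]) * F$d3(w_(Y)),
    "1,-1" = function(Y) a[5] * F$c0(s_(Y)) * F$b1(Y[, 1]) * F$d2(Y[, 2]) * F$b3(w_(Y))^2,
    "-1,1" = function(Y) a[6] * F$c0(s_(Y)) * F$d1(Y[, 1]) * F$b2(Y[, 2]) * F$d3(w_(Y))^2)
  # analytic gradients by the product/chain rule over the factor functions
  prod_grad <- function(const, f_s, f_1, f_2, f_w, pow_w = 1) {
    function(Y) {
      s <- s_(Y); w <- w_(Y)
      vs <- f_s$f(s); v1 <- f_1$f(Y[, 1]); v2 <- f_2$f(Y[, 2]); vw <- f_w$f(w)^pow_w
      gs <- f_s$d(s); g1 <- f_1$d(Y[, 1]); g2 <- f_2$d(Y[, 2])
      gw <- pow_w * f_w$f(w)^(pow_w - 1) * f_w$d(w)
      base <- const
      cbind(base * (gs * v1 * v2 * vw + vs * g1 * v2 * vw + vs * v1 * v2 * gw),
            base * (gs * v1 * v2 * vw + vs * v1 * g2 * vw - vs * v1 * v2 * gw))
    }
  }
  fp <- function(nm) list(f = F[[nm]], d = Fd[[nm]])
  grads <- list(
    "-1,0" = prod_grad(a[1], fp("d0"), fp("d1"), fp("c2"), fp("d3")),
    "1,0"  = prod_grad(a[2], fp("b0"), fp("b1"), fp("c2"), fp("b3")),
    "0,-1" = prod_grad(a[3], fp("d0"), fp("c1"), fp("d2"), fp("b3")),
    "0,1"  = prod_grad(a[4], fp("b0"), fp("c1"), fp("b2"), fp("d3")),
    "1,-1" = prod_grad(a[5], fp("c0"), fp("b1"), fp("d2"), fp("b3"), pow_w = 2),
    "-1,1" = prod_grad(a[6], fp("c0"), fp("d1"), fp("b2"), fp("d3"), pow_w = 2))
  keys <- rownames(J)
  model <- population_process(2L, J, rates[keys], space = space, f = f,
                              gradients = grads[keys], name = "competition",
                              params = list(a = a))
  model$reference <- competition_reference(model, a, F, Fd, drop_exchange)
  model
}

competition_reference <- function(model, a, F, Fd, drop_exchange) {
  intlog <- function(f, g, lo, hi) {
    # integral of ln(f/g) over (lo, hi), tolerant of log endpoint singularities
    if (abs(hi - lo) < 1e-15) return(0)
    stats::integrate(function(u) log(f(u) / g(u)), lo, hi,
                     rel.tol = 1e-12, abs.tol = 1e-13,
                     subdivisions = 1000L, stop.on.error = FALSE)$value
  }
  Vref <- function(y, ystar) {
    (ystar[1] - y[1]) * log(a[2] / a[1]) + (ystar[2] - y[2]) * log(a[4] / a[3]) +
      intlog(F$b0, F$d0, y[1] + y[2], ystar[1] + ystar[2]) +
      intlog(F$b1, F$d1, y[1], ystar[1]) +
      intlog(F$b2, F$d2, y[2], ystar[2]) +
      intlog(F$b3, F$d3, y[1] - y[2], ystar[1] - ystar[2])
  }
  detSigma <- function(ystar) {
    s <- ystar[1] + ystar[2]; w <- ystar[1] - ystar[2]
    r0 <- Fd$d0(s) / F$d0(s) - Fd$b0(s) / F$b0(s)
    r3 <- Fd$d3(w) / F$d3(w) - Fd$b3(w) / F$b3(w)
    r1 <- Fd$d1(ystar[1]) / F$d1(ystar[1]) - Fd$b1(ystar[1]) / F$b1(ystar[1])
    r2 <- Fd$d2(ystar[2]) / F$d2(ystar[2]) - Fd$b2(ystar[2]) / F$b2(ystar[2])
    4 * r0 * r3 + r1 * r2 + (r0 + r3) * (r1 + r2)
  }
  ref <- list(
    V = function(y) Vref(y, equilibrium_point(model)),
    detSigma = function() detSigma(equilibrium_point(model)),
    cycle_pass = a[1] * a[4] * a[5] == a[2] * a[3] * a[6])
  if (drop_exchange) {
    ref$tau <- function(N) {
      ystar <- equilibrium_point(model)
      s <- ystar[1] + ystar[2]; w <- ystar[1] - ystar[2]
      fwd0 <- function(fn) (fn(2e-7) - fn(1e-7)) / 1e-7
      b11 <- a[2] * fwd0(F$b0) * F$b1(0) * F$c2(0) * F$b3(0)
      b22 <- a[4] * fwd0(F$b0) * F$c1(0) * F$b2(0) * F$d3(0)
      d1 <- a[1] * F$d0(0) * fwd0(F$d1) * F$c2(0) * F$d3(0)
      d2 <- a[3] * F$d0(0) * F$c1(0) * fwd0(F$d2) * F$b3(0)
      D <- solve_D(structure(list(b = diag(c(b11, b22)), d = c(d1, d2)),
                             class = "origin_linearisation"))
      dS <- detSigma(ystar)
      num <- fwd0(F$b0) * F$d0(0) * F$b1(0) * fwd0(F$d1) * F$b2(0) * fwd0(F$d2) *
        F$b3(0) * F$d3(0)
      den <- F$b0(s) * F$d0(s) * F$b1(ystar[1]) * F$d1(ystar[1]) *
        F$b2(ystar[2]) * F$d2(ystar[2]) * F$b3(w) * F$d3(w)
      (1 / D) * sqrt(2 * pi / (N * dS) * num / den) * exp(N * Vref(c(0, 0), ystar))
    }
  }
  ref
}

#' Two-group birth-death process with movement between groups
#'
#' Two groups sharing a common resource: per-group deaths at rate
#' \eqn{y_i(\mu + \kappa(y_1+y_2))}, births into group `i` at rate
#' \eqn{\lambda_i (y_1+y_2)}, and movement of individuals from group `j`
#' into group `i` at rate \eqn{\nu_j y_j}.  Supercritical when
#' \eqn{\lambda_1+\lambda_2 > \mu}.  The leading-order cycle condition
#' holds precisely when \eqn{\lambda_1\nu_1 = \lambda_2\nu_2}; the
#' attached closed-form references (equilibrium, action, curvature matrix,
#' quasistationary mass, and — for \eqn{\nu_1=\nu_2=0} — the full
#' extinction time) assume it.
#'
#' @param mu baseline death rate.
#' @param kappa density-dependent death coefficient.
#' @param lam1,lam2 per-capita birth rates of the two groups.
#' @param nu1,nu2 movement rates out of groups 1 and 2 (both zero drops
#'   the movement jumps and gives a pure two-type birth-death process).
#' @return a `population_process` with `reference`: `ystar`, `V(y)`, `A`,
#'   `Sigma`, `detSigma`, `qsd(N, x)` and (for `nu1 = nu2 = 0`) `tau(N)`.
#' @export
make_two_group <- function(mu, kappa, lam1, lam2, nu1 = 0, nu2 = 0) {
  stopifnot(mu > 0, kappa > 0, lam1 > 0, lam2 > 0, nu1 >= 0, nu2 >= 0)
  if (xor(nu1 == 0, nu2 == 0)) {
    stop("movement rates nu1, nu2 must be both zero or both positive")
  }
  if (lam1 + lam2 <= mu) stop("subcritical parameters: need lambda1 + lambda2 > mu")
  no_move <- nu1 == 0 && nu2 == 0
  J <- competition_jump_set()
  if (no_move) J <- J[1:4, , drop = FALSE]
  rates <- list(
    "-1,0" = function(Y) Y[, 1] * (mu + kappa * (Y[, 1] + Y[, 2])),
    "1,0"  = function(Y) lam1 * (Y[, 1] + Y[, 2]),
    "0,-1" = function(Y) Y[, 2] * (mu + kappa * (Y[, 1] + Y[, 2])),
    "0,1"  = function(Y) lam2 * (Y[, 1] + Y[, 2]),
    "1,-1" = function(Y) nu2 * Y[, 2],
    "-1,1" = function(Y) nu1 * Y[, 1])
  grads <- list(
    "-1,0" = function(Y) cbind(mu + kappa * (Y[, 1] + Y[, 2]) + kappa * Y[, 1],
                               kappa * Y[, 1]),
    "1,0"  = function(Y) matrix(lam1, nrow(Y), 2),
    "0,-1" = function(Y) cbind(kappa * Y[, 2],
                               mu + kappa * (Y[, 1] + Y[, 2]) + kappa * Y[, 2]),
    "0,1"  = function(Y) matrix(lam2, nrow(Y), 2),
    "1,-1" = function(Y) cbind(rep(0, nrow(Y)), rep(nu2, nrow(Y))),
    "-1,1" = function(Y) cbind(rep(nu1, nrow(Y)), rep(0, nrow(Y))))
  keys <- rownames(J)
  model <- population_process(2L, J, rates[keys], space = "unbounded",
                              gradients = grads[keys], name = "two_group",
                              params = list(mu = mu, kappa = kappa, lam1 = lam1,
                                            lam2 = lam2, nu1 = nu1, nu2 = nu2))
  lam <- lam1 + lam2
  ystar <- (lam - mu) / (kappa * (lam + nu1 + nu2)) * c(lam1 + nu2, lam2 + nu1)
  A <- (lam - mu) / kappa + (mu / kappa) * log(mu / lam)
  Vref <- function(y) {
    y1 <- y[1]; y2 <- y[2]; s <- y1 + y2
    t1 <- if (y1 > 0) y1 * log(y1 / lam1) else 0
    t2 <- if (y2 > 0) y2 * log(y2 / lam2) else 0
    t3 <- if (s > 0) s * (log((mu + kappa * s) / s) - 1) else 0
    t1 + t2 + t3 + (mu / kappa) * log1p(kappa * s / mu) + A
  }
  Sigma_ref <- (kappa / (lam - mu)) *
    matrix(c(lam / lam1 - mu / lam, -mu / lam,
             -mu / lam, lam / lam2 - mu / lam), 2, 2)
  model$reference <- list(
    ystar_general = ystar,
    ystar = (lam - mu) / (kappa * lam) * c(lam1, lam2),
    A = A,
    V = Vref,
    Sigma = Sigma_ref,
    detSigma = kappa^2 * lam / (lam1 * lam2 * (lam - mu)),
    qsd = function(N, x) {
      y1 <- x[1] / N; y2 <- x[2] / N; s <- y1 + y2
      (lam - mu) / (2 * pi * N * sqrt(kappa * y1 * y2 * s * (mu + kappa * s))) *
        exp(-N * Vref(c(y1, y2)))
    })
  if (no_move) {
    model$reference$tau <- function(N) {
      (1 / (lam - mu)^2) * sqrt(2 * pi * mu * kappa / N) * exp(N * A)
    }
  }
  model
}
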