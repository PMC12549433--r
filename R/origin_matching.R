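#' Linearisation of a multitype birth-death process at the origin
#'
#' Close to the origin the process is approximated by a linear multitype
#' birth-death process in which a type-\eqn{j} individual produces type-
#' \eqn{i} births at rate \eqn{b_{ij} = \partial\beta_{e_i}/\partial y_j}
#' at \eqn{0} and type-\eqn{i} individuals die at per-capita rate
#' \eqn{d_i = \partial\beta_{-e_i}/\partial y_i} at \eqn{0}.  The cross
#' derivatives of the death rates must vanish at the origin.
#'
#' @param model a `population_process` with jump set \eqn{\{\pm e_i\}}.
#' @return An object of class `origin_linearisation` with elements `b`
#'   (`k x k` birth matrix), `d` (death-rate vector), `condition_rates`
#'   (logical: all `d > 0` and every row of `b` has a positive entry) and
#'   `supercritical` (logical: `sum(diag(b)/d) > 1`).
#' @export
linearise_origin <- function(model) {
  if (!is_birth_death(model)) {
    stop_qswkb("not_birth_death",
               "origin linearisation requires the jump set {e_i, -e_i}")
  }
  k <- model$k
  origin <- matrix(0, 1, k)
  b <- matrix(NA_real_, k, k)
  d <- numeric(k)
  for (i in seq_len(k)) {
    ei <- integer(k); ei[i] <- 1L
    b[i, ] <- eval_rate_gradient(model, jump_key(ei), origin)
    gm <- as.numeric(eval_rate_gradient(model, jump_key(-ei), origin))
    d[i] <- gm[i]
    off <- gm[-i]
    if (any(abs(off) > 1e-6 * (1 + abs(d[i])))) {
      stop_qswkb("assumption_violation",
                 "death rate for type ", i,
                 " has nonzero cross derivative at the origin")
    }
  }
  structure(list(b = b, d = d,
                 condition_rates = all(d > 0) && all(apply(b, 1L, function(r) any(r > 0))),
                 supercritical = sum(diag(b) / d) > 1),
            class = "origin_linearisation")
}

#' @export
print.origin_linearisation <- function(x, ...) {
  cat("<origin_linearisation>\n  b (births):\n")
  print(signif(x$b, 6))
  cat("  d (deaths):", paste(signif(x$d, 6), collapse = ", "), "\n")
  cat("  supercritical:", x$supercritical, "\n")
  invisible(x)
}

#' Decay-rate constant D of the linearised process
#'
#' The unique positive root of \eqn{\sum_i b_{ii}/(D + d_i) = 1}; exists
#' precisely when the linearised process is supercritical
#' (\eqn{\sum_i b_{ii}/d_i > 1}), which follows from instability of the
#' origin.  Solved by Brent bracketing on \eqn{(0, \sum_i b_{ii})} and
#' polished by Newton steps to residual below `tol`.
#'
#' @param lin an `origin_linearisation`.
#' @param tol residual tolerance on the defining equation.
#' @return positive scalar `D`.
#' @export
solve_D <- function(lin, tol = 1e-12) {
  bii <- diag(lin$b)
  d <- lin$d
  if (sum(bii / d) <= 1) {
    stop_qswkb("subcritical",
               "sum(b_ii/d_i) <= 1: linearised process is not supercritical, no positive root")
  }
  f <- function(D) sum(bii / (D + d)) - 1
  upper <- sum(bii)
  # f(0) > 0 and f(sum b_ii) < 0, so the bracket is guaranteed
  D <- stats::uniroot(f, c(.Machine$double.xmin, upper), tol = 1e-14)$root
  for (it in 1:5) {
    fd <- -sum(bii / (D + d)^2)
    step <- f(D) / fd
    D <- D - step
    if (abs(f(D)) < tol) break
  }
  if (abs(f(D)) > tol) stop("Newton polish failed to reach tolerance on D")
  D
}

#' Unnormalised near-origin quasistationary weight
#'
#' Solution of the linearised balance equations (up to the matching
#' normaliser): for a nonzero state \eqn{x},
#' \deqn{\tilde u_x = \frac{1}{\sum x_i} \frac{(\sum x_i)!}{\prod x_i!}
#'   \prod b_{ii}^{x_i} \left(\prod d_i^{-x_i} - \prod (D+d_i)^{-x_i}\right),}
#' valid when all rows of the birth matrix are constant.  Computed in
#' log space (log-gamma for the factorials; the difference of the two
#' exponential products via `log1p(-exp(.))` to avoid catastrophic
#' cancellation at large \eqn{|x|}).
#'
#' @param lin an `origin_linearisation`.
#' @param x nonzero nonnegative integer state, or a matrix of states.
#' @param D optional precomputed root from [solve_D()].
#' @param log logical: return the log weight.
#' @return numeric vector of (log) weights, strictly positive.
#' @export
u_tilde <- function(lin, x, D = NULL, log = FALSE) {
  if (is.null(D)) D <- solve_D(lin)
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  if (any(X < 0) || any(rowSums(X) == 0)) {
    stop("states must be nonzero nonnegative integer vectors")
  }
  bii <- diag(lin$b)
  d <- lin$d
  s <- rowSums(X)
  lg <- -log(s) + lgamma(s + 1) - rowSums(lgamma(X + 1)) +
    as.numeric(X %*% log(bii))
  A1 <- -as.numeric(X %*% log(d))        # log prod d^-x
  A2 <- -as.numeric(X %*% log(D + d))    # log prod (D+d)^-x, always < A1
  lg <- lg + A1 + log1p(-exp(A2 - A1))
  if (log) lg else exp(lg)
}

# partial-equilibrium point (0,...,0, ystar_i,...,ystar_k): zeros in the
# first i-1 coordinates
partial_equilibrium_point <- function(ystar, i) {
  p <- ystar
  if (i > 1) p[seq_len(i - 1L)] <- 0
  p
}

#' Extinction-time approximation with the full Eyring-Kramers prefactor
#'
#' For a multitype birth-death process satisfying the reversibility
#' criteria and with constant birth rows, matches the near-origin linear
#' solution to the WKB body of the quasistationary distribution and
#' returns \eqn{\tau^{(N)} \approx 1/(\Lambda D)}, where the matching
#' normaliser is
#' \deqn{\Lambda = \sqrt{\frac{N\det\Sigma}{2\pi}
#'   \frac{\prod_i \beta_{e_i}(P_i)\beta_{-e_i}(P_i)}
#'        {b_{kk} \prod_i \partial_i\beta_{-e_i}(Q_i)
#'         \prod_{i<k} \beta_{e_i}(Q_i)}} e^{-N V(0)}}
#' with \eqn{P_i = (0,..,0,y^*_i,..,y^*_k)} and
#' \eqn{Q_i = (0,..,0,y^*_{i+1},..,y^*_k)}.  The result is invariant under
#' relabelling of the coordinate axes.
#'
#' @param model a `population_process` with jump set \eqn{\{\pm e_i\}}.
#' @param N scale parameter (scalar or vector).
#' @param check logical: verify the structural criteria before computing.
#' @return numeric vector of \eqn{\tau^{(N)}} values, one per `N`.
#' @export
tau_full <- function(model, N, check = TRUE) {
  lin <- linearise_origin(model)
  if (check) {
    if (!lin$condition_rates) {
      stop_qswkb("criteria_violation",
                 "linearised rates violate positivity (d_i > 0, some b_ij > 0)")
    }
    bres <- max(abs(sweep(lin$b, 1L, diag(lin$b))))
    if (bres > 1e-8 * max(1, max(abs(lin$b)))) {
      stop_qswkb("criteria_violation",
                 "birth matrix rows are not constant; prefactor formula does not apply")
    }
  }
  D <- solve_D(lin)
  S <- sigma_matrix(model)
  A <- log_tau_leading(model)
  ystar <- equilibrium_point(model)
  k <- model$k
  log_num <- 0
  log_den <- log(lin$b[k, k])
  for (i in seq_len(k)) {
    ei <- integer(k); ei[i] <- 1L
    P <- partial_equilibrium_point(ystar, i)
    log_num <- log_num + log(eval_rate(model, jump_key(ei), P)) +
      log(eval_rate(model, jump_key(-ei), P))
    Q <- partial_equilibrium_point(ystar, i + 1L)
    dQ <- one_sided_partial(model, jump_key(-ei), Q, i)
    log_den <- log_den + log(dQ)
    if (i < k) log_den <- log_den + log(eval_rate(model, jump_key(ei), Q))
  }
  log_lambda_core <- 0.5 * (log(det(S)) - log(2 * pi) + log_num - log_den)
  # tau = 1/(Lambda D) with Lambda = sqrt(N det(Sigma)/(2 pi) * ...) e^{-NA}
  exp(N * A - 0.5 * log(N) - log_lambda_core - log(D))
}

# one-sided (forward) partial derivative of a rate in coordinate i at a
# boundary point; analytic gradient used when registered
one_sided_partial <- function(model, key, point, i) {
  if (!is.null(model$gradients[[key]])) {
    return(as.numeric(eval_rate_gradient(model, key, matrix(point, 1)))[i])
  }
  upper <- if (model$space == "box") model$f[i] else Inf
  h <- 1e-6 * (1 + abs(point[i]))
  h <- min(h, (upper - point[i]) / 2)
  p0 <- matrix(point, 1); p1 <- p0; p2 <- p0
  p1[, i] <- p1[, i] + h; p2[, i] <- p2[, i] + 2 * h
  (-3 * eval_rate(model, key, p0) + 4 * eval_rate(model, key, p1) -
      eval_rate(model, key, p2)) / (2 * h)
}
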