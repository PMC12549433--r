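#' Asymptotic Kolmogorov reversibility criteria
#'
#' A process whose transition rates satisfy the Kolmogorov cycle criterion
#' order-by-order in the scale parameter admits analytic solutions of its
#' Hamilton-Jacobi and transport equations.  The leading-order criterion
#' requires the log rate-ratio sums around every integer cycle of jumps to
#' vanish; the next conditions require the vector fields \eqn{\theta(y)}
#' (log ratios of paired rates) and \eqn{\theta^0(y)} (half-gradients of log
#' rate products) to be irrotational.  These functions compute an integer
#' cycle basis, evaluate the conditions on sampled interior points, and
#' solve the overdetermined linear systems defining \eqn{\theta} and
#' \eqn{\theta^0}.
#'
#' @name reversibility
NULL

# one representative per +/- jump pair: keep the lexicographically larger
representative_jumps <- function(model) {
  J <- if (inherits(model, "population_process")) model$jumps else {
    m <- as.matrix(model)
    storage.mode(m) <- "integer"
    rownames(m) <- apply(m, 1L, jump_key)
    m
  }
  keys <- rownames(J)
  keep <- logical(nrow(J))
  seen <- character(0)
  for (i in seq_len(nrow(J))) {
    neg <- jump_key(-J[i, ])
    if (!(neg %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, keys[i])
    }
  }
  J[keep, , drop = FALSE]
}

#' Integer basis of the cycle space of the jump set
#'
#' Computes an integer basis of \eqn{\{a : \sum_i a_i l_i = 0\}} over one
#' representative of each \eqn{\pm l} pair, by fraction-free Gaussian
#' elimination.  An empty basis means the leading-order cycle condition is
#' vacuous (as it is for any multitype birth-death jump set).
#'
#' @param model a `population_process` (or an integer jump matrix).
#' @return An object of class `cycle_basis`: list with `jumps` (the `m x k`
#'   representative jump matrix) and `basis` (an `m x r` integer matrix
#'   whose columns are cycles; `r = 0` when the condition is vacuous).
#' @export
integer_cycle_basis <- function(model) {
  R <- representative_jumps(model)
  B <- integer_nullspace(t(R))  # columns a with R^T a = 0, i.e. sum a_i l_i = 0
  structure(list(jumps = R, basis = B), class = "cycle_basis")
}

# integer nullspace of an integer matrix A (columns x with A x = 0),
# via fraction-free row reduction (entries stay integer throughout)
integer_nullspace <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"  # exact for the small integers involved
  n <- ncol(A)
  m <- nrow(A)
  # reduce [A; I] column-wise: column operations on A mirrored on I
  M <- rbind(A, diag(n))
  pivot_rows <- integer(0)
  col <- 1L
  for (row in seq_len(m)) {
    if (col > n) break
    # find a column with a nonzero entry in this row at or after `col`
    j <- which(abs(M[row, col:n]) > 0.5)
    if (length(j) == 0) next
    j <- j[1] + col - 1L
    if (j != col) M[, c(col, j)] <- M[, c(j, col)]
    for (j2 in seq_len(n)) {
      if (j2 == col) next
      if (abs(M[row, j2]) > 0.5) {
        p <- M[row, col]; q <- M[row, j2]
        g <- integer_gcd(abs(p), abs(q))
        M[, j2] <- (abs(p) / g) * M[, j2] - sign(p) * sign(q) * (abs(q) / g) * M[, col]
      }
    }
    col <- col + 1L
  }
  if (col > n) return(matrix(0L, n, 0))
  null_cols <- col:n
  keep <- null_cols[colSums(abs(M[seq_len(m), null_cols, drop = FALSE])) < 0.5]
  B <- M[m + seq_len(n), keep, drop = FALSE]
  # normalise: divide each column by its gcd
  if (ncol(B) > 0) {
    for (j in seq_len(ncol(B))) {
      g <- Reduce(integer_gcd, abs(B[abs(B[, j]) > 0.5, j]))
      B[, j] <- B[, j] / g
    }
  }
  storage.mode(B) <- "integer"
  B
}

integer_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

#' Low-discrepancy interior sample points for criteria checks
#'
#' Latin-hypercube points in the interior of the scaled state space, inset
#' from the boundary by a fraction of each side.  For unbounded models the
#' sampled region is the box \eqn{[0, 2 y^*]} around the stable equilibrium.
#'
#' @param model a `population_process`.
#' @param n number of points.
#' @param seed integer seed for the scrambled design.
#' @param inset fraction of each side excluded near the boundary.
#' @return an `n x k` matrix of interior points.
#' @export
criteria_sample_points <- function(model, n = 64L, seed = 1L, inset = 0.01) {
  upper <- if (model$space == "box") model$f else 2 * equilibrium_point(model)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  U <- lhs::randomLHS(n, model$k)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  lo <- inset * upper
  hi <- (1 - inset) * upper
  sweep(sweep(U, 2L, hi - lo, `*`), 2L, lo, `+`)
}

#' Leading-order cycle condition
#'
#' For each basis cycle \eqn{a} and each sample point evaluates
#' \eqn{\sum_i a_i \ln(\beta_{-l_i}(y)/\beta_{l_i}(y))}; the condition
#' passes when the largest absolute value is below tolerance, and is
#' vacuous when the cycle basis is empty.
#'
#' @param model a `population_process`.
#' @param sample_points interior points (`n x k` matrix); defaults to a
#'   seeded low-discrepancy sample.
#' @param tol pass tolerance on the absolute cycle sums.
#' @return list with `verdict` (`"PASS"`, `"FAIL"` or `"VACUOUS"`),
#'   `residual` (worst absolute cycle sum), and on failure `witness`.
#' @export
check_cycle_condition <- function(model, sample_points = NULL, tol = 1e-8) {
  cb <- integer_cycle_basis(model)
  if (ncol(cb$basis) == 0) {
    return(list(verdict = "VACUOUS", residual = 0, witness = NULL))
  }
  if (is.null(sample_points)) sample_points <- criteria_sample_points(model)
  lr <- log_rate_ratios(model, cb$jumps, sample_points)  # n x m
  vals <- lr %*% cb$basis                                # n x r cycle sums
  worst <- max(abs(vals))
  iw <- which(abs(vals) == worst, arr.ind = TRUE)[1, 1]
  list(verdict = if (worst < tol) "PASS" else "FAIL",
       residual = worst,
       witness = if (worst < tol) NULL else sample_points[iw, ])
}

# matrix of ln(beta_{-l}/beta_l) over representative jumps (columns) and
# points (rows); errors if a rate vanishes at an interior point
log_rate_ratios <- function(model, R, pts) {
  out <- matrix(NA_real_, nrow(pts), nrow(R))
  for (i in seq_len(nrow(R))) {
    num <- eval_rate(model, jump_key(-R[i, ]), pts)
    den <- eval_rate(model, jump_key(R[i, ]), pts)
    if (any(num <= 0) || any(den <= 0)) {
      stop_qswkb("evaluation", "rate for jump ", jump_key(R[i, ]),
                 " vanishes at an interior sample point")
    }
    out[, i] <- log(num) - log(den)
  }
  out
}

theta_design <- function(model) {
  R <- representative_jumps(model)
  L <- matrix(as.numeric(R), nrow(R), model$k)
  if (qr(L)$rank < model$k) {
    stop_qswkb("model", "jump set does not span R^k; theta system is rank deficient")
  }
  P <- solve(crossprod(L), t(L))  # k x m pseudo-inverse
  list(R = R, L = L, P = P)
}

#' Solve for the vector field theta(y)
#'
#' Least-squares solution of the overdetermined system
#' \eqn{l^T \theta(y) = \ln(\beta_{-l}(y)/\beta_l(y))} over one
#' representative per \eqn{\pm l} pair.  When the leading-order cycle
#' condition holds the residual vanishes and \eqn{\theta} solves every
#' equation exactly; \eqn{\theta} is the gradient of the action potential.
#'
#' @param model a `population_process`.
#' @param y interior point, or an `n x k` matrix of interior points.
#' @return list with `theta` (`n x k` matrix, or vector for a single
#'   point) and `residual` (max-norm plug-back residual per point).
#' @export
solve_theta <- function(model, y) {
  d <- theta_design(model)
  Y <- as_point_matrix(y, model$k)
  rhs <- log_rate_ratios(model, d$R, Y)        # n x m
  th <- rhs %*% t(d$P)                         # n x k
  res <- abs(th %*% t(d$L) - rhs)
  resid <- apply(res, 1L, max)
  if (nrow(Y) == 1L && !is.matrix(y)) {
    list(theta = drop(th), residual = resid)
  } else {
    list(theta = th, residual = resid)
  }
}

# n x m matrix with columns  (1/2) l^T d/dy ln(beta_{-l} beta_l)
theta0_rhs <- function(model, R, Y) {
  out <- matrix(NA_real_, nrow(Y), nrow(R))
  for (i in seq_len(nrow(R))) {
    l <- as.numeric(R[i, ])
    gp <- eval_rate_gradient(model, jump_key(l), Y)
    gm <- eval_rate_gradient(model, jump_key(-l), Y)
    bp <- eval_rate(model, jump_key(l), Y)
    bm <- eval_rate(model, jump_key(-l), Y)
    if (any(bp <= 0) || any(bm <= 0)) {
      stop_qswkb("evaluation", "rate for jump ", jump_key(l),
                 " vanishes at an interior sample point")
    }
    gl <- gp / bp + gm / bm                    # gradient of ln(beta_l beta_-l)
    out[, i] <- 0.5 * (gl %*% l)
  }
  out
}

#' Solve for the correction field theta0(y)
#'
#' Least-squares solution of
#' \eqn{l^T \theta^0(y) = (1/2) l^T \partial_y \ln(\beta_{-l}\beta_l)}.
#' A vanishing residual is equivalent to the second-order cycle condition;
#' \eqn{\theta^0} is then the gradient of the transport-equation
#' correction.
#'
#' @inheritParams solve_theta
#' @return list with `theta0` and `residual`, as for [solve_theta()].
#' @export
solve_theta0 <- function(model, y) {
  d <- theta_design(model)
  Y <- as_point_matrix(y, model$k)
  rhs <- theta0_rhs(model, d$R, Y)
  th <- rhs %*% t(d$P)
  res <- abs(th %*% t(d$L) - rhs)
  resid <- apply(res, 1L, max)
  if (nrow(Y) == 1L && !is.matrix(y)) {
    list(theta0 = drop(th), residual = resid)
  } else {
    list(theta0 = th, residual = resid)
  }
}

#' Jacobian of theta (or theta0) at a point
#'
#' When analytic rate gradients are registered the Jacobian of
#' \eqn{\theta} is assembled exactly from the gradients of the log
#' rate-ratios; otherwise (and always for \eqn{\theta^0}) central finite
#' differences of the field are used.
#'
#' @param model a `population_process`.
#' @param y interior point.
#' @param field `"theta"` or `"theta0"`.
#' @return a `k x k` matrix.
#' @export
theta_jacobian <- function(model, y, field = c("theta", "theta0")) {
  field <- match.arg(field)
  y <- as.numeric(y)
  k <- model$k
  if (field == "theta" && !is.null(model$gradients)) {
    d <- theta_design(model)
    Y <- matrix(y, 1, k)
    Dr <- matrix(NA_real_, nrow(d$R), k)   # rows: gradient of ln ratio per jump
    ok <- TRUE
    for (i in seq_len(nrow(d$R))) {
      kp <- jump_key(d$R[i, ]); km <- jump_key(-d$R[i, ])
      if (is.null(model$gradients[[kp]]) || is.null(model$gradients[[km]])) {
        ok <- FALSE; break
      }
      bp <- eval_rate(model, kp, Y); bm <- eval_rate(model, km, Y)
      Dr[i, ] <- eval_rate_gradient(model, km, Y) / bm -
                 eval_rate_gradient(model, kp, Y) / bp
    }
    if (ok) return(d$P %*% Dr)
  }
  fn <- if (field == "theta") function(z) solve_theta(model, z)$theta
        else function(z) solve_theta0(model, z)$theta0
  Jt <- matrix(NA_real_, k, k)
  upper <- if (model$space == "box") model$f else rep(Inf, k)
  for (j in seq_len(k)) {
    h <- 1e-6 * (1 + abs(y[j]))
    h <- min(h, (upper[j] - y[j]) / 2.5, y[j] / 2.5)
    yp <- y; ym <- y; yp2 <- y; ym2 <- y
    yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    yp2[j] <- yp2[j] + 2 * h; ym2[j] <- ym2[j] - 2 * h
    d1 <- (fn(yp) - fn(ym)) / (2 * h)
    d2 <- (fn(yp2) - fn(ym2)) / (4 * h)
    Jt[, j] <- (4 * d1 - d2) / 3
  }
  Jt
}

#' Irrotationality check for theta or theta0
#'
#' Verifies that the Jacobian of the field is symmetric (to tolerance) at
#' each sample point — the vector-calculus form of the second- and
#' third-order parallelogram conditions.
#'
#' @param model a `population_process`.
#' @param field `"theta"` or `"theta0"`.
#' @param sample_points interior points; defaults to a seeded
#'   low-discrepancy sample.
#' @param tol tolerance on the asymmetry, relative to the matrix scale.
#' @param boundary_cutoff points closer than this (relative to each side)
#'   to the boundary are skipped with a warning.
#' @return list with `verdict`, `residual` (worst relative asymmetry) and
#'   `n_used`.
#' @export
check_irrotational <- function(model, field = c("theta", "theta0"),
                               sample_points = NULL, tol = 1e-6,
                               boundary_cutoff = 5e-3) {
  field <- match.arg(field)
  if (is.null(sample_points)) sample_points <- criteria_sample_points(model)
  upper <- if (model$space == "box") model$f else 2 * equilibrium_point(model)
  keep <- rep(TRUE, nrow(sample_points))
  for (j in seq_len(model$k)) {
    keep <- keep & sample_points[, j] > boundary_cutoff * upper[j] &
      (model$space != "box" | sample_points[, j] < (1 - boundary_cutoff) * upper[j])
  }
  if (any(!keep)) warning(sum(!keep), " sample points too close to the boundary; skipped")
  pts <- sample_points[keep, , drop = FALSE]
  worst <- 0
  for (i in seq_len(nrow(pts))) {
    Jt <- theta_jacobian(model, pts[i, ], field)
    asym <- max(abs(Jt - t(Jt))) / max(1, max(abs(Jt)))
    worst <- max(worst, asym)
  }
  list(verdict = if (worst < tol) "PASS" else "FAIL",
       residual = worst, n_used = nrow(pts))
}

#' Full reversibility criteria report
#'
#' Evaluates all applicable asymptotic Kolmogorov criteria on a seeded
#' quasi-random interior sample: the leading-order cycle condition, the
#' irrotationality of \eqn{\theta}, solvability of the \eqn{\theta^0}
#' system, the irrotationality of \eqn{\theta^0}, and for pure birth-death
#' jump sets the specialised conditions (positive linearised rates and
#' constant birth rows).  States which analytic results apply.
#'
#' @param model a `population_process`.
#' @param n_samples number of interior sample points.
#' @param seed integer seed for the sample.
#' @param tol residual tolerance for PASS verdicts on exact conditions.
#' @return An object of class `criteria_report`.
#' @export
full_report <- function(model, n_samples = 64L, seed = 1L, tol = 1e-8) {
  pts <- criteria_sample_points(model, n = n_samples, seed = seed)
  is_bd <- is_birth_death(model)
  out <- list(model = model$name, is_birth_death = is_bd, n_samples = n_samples,
              seed = seed, conditions = list())

  cyc <- check_cycle_condition(model, pts, tol = tol)
  out$conditions$cycle_leading <- cyc

  theta_ok <- cyc$verdict != "FAIL"
  irro <- if (theta_ok) check_irrotational(model, "theta", pts)
          else list(verdict = "SKIPPED", residual = NA_real_)
  out$conditions$theta_irrotational <- irro

  t0 <- tryCatch(solve_theta0(model, pts), error = function(e) NULL)
  t0res <- if (is.null(t0)) Inf else max(t0$residual)
  out$conditions$theta0_solvable <- list(
    verdict = if (ncol(integer_cycle_basis(model)$basis) == 0) "VACUOUS"
              else if (t0res < tol) "PASS" else "FAIL",
    residual = t0res)

  irro0 <- if (t0res < 1e-4) check_irrotational(model, "theta0", pts)
           else list(verdict = "SKIPPED", residual = NA_real_)
  out$conditions$theta0_irrotational <- irro0

  if (is_bd) {
    lin <- linearise_origin(model)
    out$linearisation <- lin
    out$conditions$bd_positive_rates <- list(
      verdict = if (all(lin$d > 0) &&
                    all(apply(lin$b, 1L, function(r) any(r > 0)))) "PASS" else "FAIL",
      residual = 0)
    bres <- max(abs(sweep(lin$b, 1L, diag(lin$b))))
    out$conditions$bd_constant_birth_rows <- list(
      verdict = if (bres < 1e-8 * max(1, max(abs(lin$b)))) "PASS" else "FAIL",
      residual = bres)
  }

  v <- function(name) {
    c <- out$conditions[[name]]
    if (is.null(c)) FALSE else c$verdict %in% c("PASS", "VACUOUS")
  }
  out$results_applicable <- c(
    result_logtau_bd      = is_bd && v("bd_positive_rates") && v("theta_irrotational"),
    result_qsd_bd         = is_bd && v("theta_irrotational") && v("theta0_irrotational"),
    result_tau_prefactor  = is_bd && v("bd_positive_rates") && v("theta_irrotational") &&
                            v("theta0_irrotational") && v("bd_constant_birth_rows"),
    result_logtau_general = v("cycle_leading") && v("theta_irrotational"),
    result_qsd_general    = v("cycle_leading") && v("theta_irrotational") &&
                            v("theta0_solvable") && v("theta0_irrotational"))
  structure(out, class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat("<criteria_report> model:", x$model,
      if (x$is_birth_death) "(multitype birth-death)" else "", "\n")
  for (nm in names(x$conditions)) {
    c <- x$conditions[[nm]]
    cat(sprintf("  %-28s %-8s residual %.3g\n", nm, c$verdict,
                if (is.na(c$residual)) NA else c$residual))
  }
  cat("  applicable analytic results:\n")
  for (nm in names(x$results_applicable)) {
    cat(sprintf("    %-24s %s\n", nm, x$results_applicable[[nm]]))
  }
  invisible(x)
}

#' Criteria report as a JSON string
#'
#' @param report a `criteria_report`.
#' @return JSON character scalar.
#' @export
criteria_report_json <- function(report) {
  conds <- lapply(report$conditions, function(c)
    list(verdict = c$verdict, residual = c$residual))
  jsonlite::toJSON(list(model = report$model,
                        is_birth_death = report$is_birth_death,
                        conditions = conds,
                        results_applicable = as.list(report$results_applicable)),
                   auto_unbox = TRUE, digits = NA)
}

#' Is the jump set pure multitype birth-death?
#'
#' @param model a `population_process`.
#' @return logical: `TRUE` iff the jumps are exactly \eqn{\{\pm e_i\}}.
#' @export
is_birth_death <- function(model) {
  J <- model$jumps
  if (nrow(J) != 2L * model$k) return(FALSE)
  all(rowSums(abs(J)) == 1L)
}
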