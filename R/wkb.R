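#' WKB objects for the quasistationary distribution
#'
#' Under the asymptotic reversibility criteria the quasistationary
#' distribution has the form
#' \eqn{u_x \approx M_N \exp(-N V(y) - V_0(y))} with \eqn{y = x/N}.  The
#' action potential \eqn{V} is the line integral of \eqn{\theta} from the
#' stable equilibrium, the correction \eqn{V_0} telescopes along any jump
#' decomposition of \eqn{y - y^*}, the curvature matrix \eqn{\Sigma} is the
#' Jacobian of \eqn{\theta} at \eqn{y^*}, and
#' \eqn{M_N = \sqrt{\det\Sigma / (2\pi N)^k}}.
#'
#' @name wkb
NULL

#' Action potential V(y) as a path integral of theta
#'
#' Integrates \eqn{\theta(y')\cdot dy'} from the stable equilibrium
#' \eqn{y^*} to `y` along the straight segment (or along supplied
#' waypoints).  The integral is path independent when the reversibility
#' criteria hold; endpoints on the boundary of the state space, where
#' \eqn{\theta} has a logarithmic singularity, are handled by open adaptive
#' Gauss-Kronrod quadrature.
#'
#' @param model a `population_process`.
#' @param y target point in the scaled state space (boundary allowed).
#' @param waypoints optional matrix of intermediate points (one per row)
#'   visited between \eqn{y^*} and `y`.
#' @param rel.tol,abs.tol quadrature tolerances per segment.
#' @return scalar \eqn{V(y)} (zero at \eqn{y^*}, positive elsewhere).
#' @export
potential <- function(model, y, waypoints = NULL,
                      rel.tol = 1e-11, abs.tol = 1e-12) {
  ystar <- equilibrium_point(model)
  y <- as.numeric(y)
  if (!in_state_space(model, y)) stop("target point outside the state space")
  pts <- rbind(ystar, waypoints, matrix(y, 1))
  total <- 0
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- as.numeric(pts[s, ]); b <- as.numeric(pts[s + 1L, ])
    if (max(abs(b - a)) == 0) next
    dvec <- b - a
    f <- function(t) {
      P <- outer(t, dvec) + matrix(a, length(t), model$k, byrow = TRUE)
      th <- solve_theta(model, P)$theta
      if (is.null(dim(th))) th <- matrix(th, nrow = length(t))
      as.numeric(th %*% dvec)
    }
    q <- stats::integrate(f, 0, 1, rel.tol = rel.tol, abs.tol = abs.tol,
                          subdivisions = 1000L, stop.on.error = FALSE)
    if (!q$message %in% c("OK", "roundoff error was detected")) {
      stop_qswkb("divergent_action", "quadrature failed on path segment ", s,
                 ": ", q$message)
    }
    if (!is.finite(q$value)) {
      stop_qswkb("divergent_action", "action integral diverges towards ",
                 jump_key(round(b)))
    }
    total <- total + q$value
  }
  total
}

#' Action potential on an axis-aligned grid (fast path)
#'
#' Evaluates \eqn{V} at every node of the grid `y1s x y2s x ...` for a
#' 2-dimensional model (or at each value of `y1s` for 1-dimensional
#' models), exploiting path independence: the potential is accumulated
#' along axis-aligned paths with fixed-order Gauss-Legendre quadrature on
#' each short segment, with all \eqn{\theta} evaluations batched.
#'
#' @param model a `population_process` with `k <= 2`.
#' @param y1s,y2s increasing vectors of interior coordinates.
#' @param nodes Gauss-Legendre nodes per segment.
#' @return for `k = 2` a `length(y1s) x length(y2s)` matrix of potentials;
#'   for `k = 1` a vector.
#' @export
potential_grid <- function(model, y1s, y2s = NULL, nodes = 24L) {
  ystar <- equilibrium_point(model)
  gl <- gauss_legendre(nodes)
  seg_integral <- function(A, B) {
    # vectorised over segments: A, B are m x k matrices of endpoints
    m <- nrow(A)
    D <- B - A
    tpts <- gl$x                      # nodes in (0,1)
    P <- A[rep(seq_len(m), each = nodes), , drop = FALSE] +
      D[rep(seq_len(m), each = nodes), , drop = FALSE] * rep(tpts, m)
    th <- solve_theta(model, P)$theta
    if (is.null(dim(th))) th <- matrix(th, ncol = model$k)
    contrib <- rowSums(th * D[rep(seq_len(m), each = nodes), , drop = FALSE])
    as.numeric(tapply(contrib * rep(gl$w, m), rep(seq_len(m), each = nodes), sum))
  }
  if (model$k == 1L) {
    xs <- sort(unique(c(ystar[1], y1s)))
    A <- matrix(xs[-length(xs)], ncol = 1); B <- matrix(xs[-1], ncol = 1)
    seg <- seg_integral(A, B)
    cum <- c(0, cumsum(seg))           # potential diff from xs[1]
    Vat <- cum - cum[match(ystar[1], xs)]
    return(Vat[match(y1s, xs)])
  }
  if (model$k != 2L) stop("potential_grid supports k = 1 or 2")
  xs <- sort(unique(c(ystar[1], y1s)))
  # horizontal leg along y2 = ystar2
  A <- cbind(xs[-length(xs)], ystar[2]); B <- cbind(xs[-1], ystar[2])
  seg <- seg_integral(A, B)
  cum <- c(0, cumsum(seg))
  Vrow <- cum - cum[match(ystar[1], xs)]      # V(x, ystar2)
  Vrow <- Vrow[match(y1s, xs)]
  # vertical legs for each y1
  ys <- sort(unique(c(ystar[2], y2s)))
  n1 <- length(y1s); n2 <- length(ys)
  A <- cbind(rep(y1s, each = n2 - 1), rep(ys[-n2], n1))
  B <- cbind(rep(y1s, each = n2 - 1), rep(ys[-1], n1))
  seg <- seg_integral(A, B)
  segm <- matrix(seg, n2 - 1, n1)
  out <- matrix(NA_real_, n1, length(y2s))
  i0 <- match(ystar[2], ys)
  for (i in seq_len(n1)) {
    cum <- c(0, cumsum(segm[, i]))
    Vcol <- cum - cum[i0]
    out[i, ] <- Vrow[i] + Vcol[match(y2s, ys)]
  }
  out
}

gauss_legendre <- function(n) {
  # nodes/weights on (0,1) via the Golub-Welsch tridiagonal eigenproblem
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  E <- eigen(diag(0, n) + rbind(cbind(0, diag(b, n - 1)), 0) +
               cbind(rbind(0, diag(b, n - 1)), 0), symmetric = TRUE)
  x <- rev(E$values)
  w <- 2 * rev(E$vectors[1, ])^2
  list(x = (x + 1) / 2, w = w / 2)
}

#' Transport-equation correction V0(y)
#'
#' Telescoping form along a jump decomposition
#' \eqn{y = y^* + \sum_j a_j l_j}: each step contributes half the log
#' change of \eqn{\beta_{-l_j}\beta_{l_j}}.  The default decomposition is
#' axis-aligned in coordinate order (requires the unit jumps \eqn{\pm e_i}
#' to be in the jump set, as in all built-in families).  The value is
#' independent of the admissible decomposition chosen; it diverges on the
#' boundary of the state space.
#'
#' @param model a `population_process`.
#' @param y interior target point.
#' @param decomposition optional list of steps, each a list with elements
#'   `l` (jump vector in the jump set) and `a` (real coefficient).
#' @return scalar \eqn{V_0(y)} (zero at \eqn{y^*}).
#' @export
correction <- function(model, y, decomposition = NULL) {
  ystar <- equilibrium_point(model)
  y <- as.numeric(y)
  if (!all(in_state_space(model, y))) stop("target point outside the state space")
  if (is.null(decomposition)) {
    decomposition <- lapply(seq_len(model$k), function(i) {
      l <- integer(model$k); l[i] <- 1L
      list(l = l, a = y[i] - ystar[i])
    })
  }
  pos <- ystar
  total <- 0
  for (step in decomposition) {
    key <- jump_key(step$l)
    if (!(key %in% rownames(model$jumps))) {
      stop("decomposition uses jump ", key, " not in the jump set")
    }
    nxt <- pos + step$a * as.numeric(step$l)
    if (!in_state_space(model, nxt)) {
      stop("decomposition leaves the state space at ", jump_key(round(nxt, 6)))
    }
    prod_new <- eval_rate(model, key, nxt) * eval_rate(model, jump_key(-step$l), nxt)
    prod_old <- eval_rate(model, key, pos) * eval_rate(model, jump_key(-step$l), pos)
    if (prod_new <= 0 || prod_old <= 0) {
      stop_qswkb("divergence",
                 "transport correction diverges: rate product vanishes on the path")
    }
    total <- total + 0.5 * (log(prod_new) - log(prod_old))
    pos <- nxt
  }
  if (max(abs(pos - y)) > 1e-9 * (1 + max(abs(y)))) {
    stop("decomposition does not reach the target point")
  }
  total
}

#' Gaussian curvature matrix Sigma of the quasistationary distribution
#'
#' \eqn{\Sigma = \partial\theta/\partial y} at the stable equilibrium: the
#' Hessian of the action potential at its minimum.  Must be symmetric under
#' the reversibility criteria (asymmetry above `tol` is an error); the
#' returned matrix is symmetrised by averaging, and its inverse is checked
#' to be positive definite.
#'
#' @param model a `population_process`.
#' @param tol tolerance on the relative asymmetry.
#' @return a symmetric positive-definite `k x k` matrix.
#' @export
sigma_matrix <- function(model, tol = 1e-6) {
  cached <- model$cache$sigma
  if (!is.null(cached)) return(cached)
  ystar <- equilibrium_point(model)
  S <- theta_jacobian(model, ystar, "theta")
  asym <- max(abs(S - t(S))) / max(1, max(abs(S)))
  if (asym > tol) {
    stop_qswkb("criteria_violation",
               "theta Jacobian at y* is asymmetric (relative asymmetry ",
               signif(asym, 3), "); irrotationality fails")
  }
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop_qswkb("criteria_violation", "Sigma is not positive definite")
  }
  model$cache$sigma <- S
  S
}

#' WKB mode normalisation constant M_N
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @return scalar \eqn{\sqrt{\det\Sigma/(2\pi N)^k}}.
#' @export
wkb_prefactor <- function(model, N) {
  S <- sigma_matrix(model)
  dS <- det(S)
  stopifnot(dS > 0)
  sqrt(dS / (2 * pi * N)^model$k)
}

#' WKB approximation of the quasistationary probability mass
#'
#' \eqn{u_x \approx M_N \exp(-N V(y) - V_0(y))} at \eqn{y = x/N}.  Valid in
#' the body of the distribution; states inside the boundary layer (within
#' `boundary_cutoff` of the boundary of the scaled state space) are
#' rejected, since the correction diverges there.
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @param x integer state (vector) or matrix of states (one per row).
#' @param boundary_cutoff half-width of the excluded boundary layer, as a
#'   distance in scaled coordinates; default `min(0.1 * sides, 10/N)`.
#' @param V optional precomputed potential values (same length as states).
#' @return numeric vector of approximate probability masses.
#' @export
wkb_qsd <- function(model, N, x, boundary_cutoff = NULL, V = NULL) {
  X <- as_point_matrix(x, model$k)
  Y <- X / N
  if (is.null(boundary_cutoff)) boundary_cutoff <- default_boundary_cutoff(model, N)
  dist <- boundary_distance(model, Y)
  if (any(dist < boundary_cutoff)) {
    stop_qswkb("divergence",
               "state inside the boundary layer; the WKB correction diverges there")
  }
  M <- wkb_prefactor(model, N)
  if (is.null(V)) V <- vapply(seq_len(nrow(Y)), function(i) potential(model, Y[i, ]), numeric(1))
  V0 <- vapply(seq_len(nrow(Y)), function(i) correction(model, Y[i, ]), numeric(1))
  M * exp(-N * V - V0)
}

#' Default boundary-layer cutoff for the WKB mass formula
#'
#' The transport correction diverges on the boundary of the scaled state
#' space; states within this distance of the boundary are excluded.
#' Finite boxes use 10 percent of the shortest side (capped at `10/N`);
#' unbounded models use `10/N`.
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @return scalar cutoff distance in scaled coordinates.
#' @export
default_boundary_cutoff <- function(model, N) {
  if (model$space == "box") min(0.1 * min(model$f), 10 / N) else 10 / N
}

boundary_distance <- function(model, Y) {
  d <- apply(Y, 1L, min)
  if (model$space == "box") {
    d <- pmin(d, apply(sweep(-Y, 2L, model$f, `+`), 1L, min))
  }
  d
}

#' Gaussian (Ornstein-Uhlenbeck) approximation of the quasistationary mass
#'
#' Multivariate normal density with mean \eqn{N y^*} and variance
#' \eqn{N \Sigma^{-1}}, evaluated at the states `x`: the standard normal
#' approximation that the WKB form refines.
#'
#' @inheritParams wkb_qsd
#' @return numeric vector of approximate probability masses.
#' @export
gaussian_qsd <- function(model, N, x) {
  X <- as_point_matrix(x, model$k)
  S <- sigma_matrix(model)
  ystar <- equilibrium_point(model)
  M <- wkb_prefactor(model, N)
  Z <- sweep(X, 2L, N * ystar)
  q <- rowSums((Z %*% S) * Z) / N
  M * exp(-q / 2)
}

#' Leading-order extinction-time exponent A = V(0)
#'
#' The limit of \eqn{\ln\tau^{(N)} / N}: the action accumulated from the
#' stable equilibrium to the origin along any path, evaluated on the
#' straight ray (interior except for the endpoint).
#'
#' @param model a `population_process`.
#' @return scalar \eqn{A}.
#' @export
log_tau_leading <- function(model) {
  cached <- model$cache$leading_action
  if (!is.null(cached)) return(cached)
  A <- potential(model, rep(0, model$k))
  if (!is.finite(A)) stop_qswkb("divergent_action", "action to the origin diverges")
  model$cache$leading_action <- A
  A
}

#' Diffusion matrix G at the equilibrium
#'
#' \eqn{G = \sum_l \beta_l(y^*) l l^T}; together with the drift Jacobian it
#' determines \eqn{\Sigma^{-1}} through the Lyapunov equation
#' \eqn{J\Sigma^{-1} + \Sigma^{-1}J^T + G = 0}.
#'
#' @param model a `population_process`.
#' @return a symmetric positive-definite `k x k` matrix.
#' @export
diffusion_matrix <- function(model) {
  ystar <- equilibrium_point(model)
  G <- matrix(0, model$k, model$k)
  for (key in rownames(model$jumps)) {
    l <- as.numeric(model$jumps[key, ])
    G <- G + eval_rate(model, key, ystar) * (l %o% l)
  }
  G
}
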