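#' Density-dependent Markov population process
#'
#' Represents a sequence of Markov processes on \eqn{Z_+^k} (or a finite box)
#' indexed by a scale parameter \eqn{N}, with transition rates
#' \eqn{x \to x + l} at rate \eqn{N \beta_l(x/N)} for a finite symmetric jump
#' set.  The origin is absorbing and the remaining states form a single
#' communicating class.  The scaled process converges to the deterministic
#' flow \eqn{dy/dt = \sum_l l \beta_l(y)}, assumed to have an unstable
#' equilibrium at the origin and a unique stable interior equilibrium.
#'
#' Rate functions must be vectorised over points: they receive an
#' \eqn{n \times k} matrix of points in the scaled state space and return a
#' length-\eqn{n} nonnegative vector (set `vectorized = FALSE` to have the
#' constructor wrap plain length-`k`-vector functions).  Optional analytic
#' gradients (same call convention, returning an \eqn{n \times k} matrix)
#' make criteria checks and curvature computations exact up to rounding;
#' otherwise Richardson-extrapolated central differences are used.
#'
#' @param k positive integer, dimension of the state space.
#' @param jumps integer matrix with `k` columns, one jump vector per row.
#'   Must be symmetric (`l` present iff `-l` present) and span \eqn{R^k}.
#' @param rates named list of rate functions, one per jump; names must be
#'   `jump_key()` strings of the corresponding rows of `jumps`.
#' @param space `"unbounded"` (state space \eqn{Z_+^k}) or `"box"` (finite
#'   box with per-coordinate fractions `f`).
#' @param f positive numeric vector of length `k`: the box fractions
#'   \eqn{f_i} so that coordinate \eqn{i} lives on \eqn{[0, N f_i]}.
#'   Required when `space = "box"`.
#' @param gradients optional named list of analytic gradient functions
#'   (same names as `rates`).
#' @param name label for printing and configuration round-trips.
#' @param params named list of scalar parameters (kept for serialisation).
#' @param vectorized logical; set `FALSE` if the supplied rate/gradient
#'   functions take a single point (length-`k` vector) instead of a matrix.
#' @param validate logical; run the assumption checks (recommended).
#'
#' @return An object of class `population_process`.
#' @export
population_process <- function(k, jumps, rates, space = c("unbounded", "box"),
                               f = NULL, gradients = NULL, name = "custom",
                               params = list(), vectorized = TRUE,
                               validate = TRUE) {
  space <- match.arg(space)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  jumps <- as.matrix(jumps)
  storage.mode(jumps) <- "integer"
  if (ncol(jumps) != k) stop("`jumps` must have k = ", k, " columns")
  keys <- apply(jumps, 1L, jump_key)
  if (anyDuplicated(keys)) stop("duplicate jump vectors")
  rownames(jumps) <- keys
  if (!setequal(names(rates), keys)) {
    stop("names of `rates` must match the jump keys: ",
         paste(keys, collapse = " "))
  }
  if (space == "box") {
    if (is.null(f) || length(f) != k || any(f <= 0)) {
      stop("`space = \"box\"` requires positive fractions `f` of length k")
    }
    f <- as.numeric(f)
  } else {
    f <- NULL
  }
  if (!vectorized) {
    rates <- lapply(rates, vectorize_point_fun, value = "scalar")
    if (!is.null(gradients)) {
      gradients <- lapply(gradients, vectorize_point_fun, value = "row")
    }
  }
  if (!is.null(gradients) && !all(names(gradients) %in% keys)) {
    stop("gradient names must be a subset of the jump keys")
  }
  model <- structure(
    list(k = k, jumps = jumps, rates = rates[keys],
         gradients = gradients, space = space, f = f,
         name = name, params = params,
         cache = new.env(parent = emptyenv())),
    class = "population_process")
  if (validate) validate_process(model)
  model
}

#' @export
print.population_process <- function(x, ...) {
  cat("<population_process> ", x$name, "\n", sep = "")
  cat("  dimension k = ", x$k, ", ", nrow(x$jumps), " jumps, state space ",
      if (x$space == "box") paste0("box f = (", paste(signif(x$f, 4), collapse = ", "), ")")
      else "Z+^k (unbounded)", "\n", sep = "")
  invisible(x)
}

#' Canonical string key of an integer jump vector
#'
#' @param l integer vector.
#' @return character scalar, e.g. `"1,-1"`.
#' @export
jump_key <- function(l) paste(as.integer(l), collapse = ",")

vectorize_point_fun <- function(fn, value = c("scalar", "row")) {
  value <- match.arg(value)
  force(fn)
  if (value == "scalar") {
    function(Y) apply(Y, 1L, fn)
  } else {
    function(Y) t(apply(Y, 1L, fn))
  }
}

as_point_matrix <- function(y, k) {
  if (is.matrix(y)) {
    if (ncol(y) != k) stop("points must have ", k, " columns")
    y
  } else {
    if (length(y) != k) stop("point must have length ", k)
    matrix(as.numeric(y), nrow = 1L)
  }
}

#' Evaluate one rate function at one or many points
#'
#' @param model a `population_process`.
#' @param l integer jump vector (or its `jump_key()` string).
#' @param y point in the scaled state space, or an `n x k` matrix of points.
#' @return numeric vector of rates, one per point.
#' @export
eval_rate <- function(model, l, y) {
  key <- if (is.character(l)) l else jump_key(l)
  fn <- model$rates[[key]]
  if (is.null(fn)) stop("no rate registered for jump ", key)
  Y <- as_point_matrix(y, model$k)
  v <- as.numeric(fn(Y))
  if (length(v) != nrow(Y)) stop("rate function for ", key, " is not vectorised")
  if (any(!is.finite(v)) || any(v < -1e-12)) {
    stop("rate function for jump ", key, " returned a negative or non-finite value")
  }
  pmax(v, 0)
}

#' Gradient of one rate function (analytic if registered, else numeric)
#'
#' Central finite differences with step \eqn{h = 10^{-6}(1+|y_j|)}, one
#' Richardson extrapolation; one-sided steps are taken automatically when a
#' coordinate is within `h` of the domain boundary.
#'
#' @inheritParams eval_rate
#' @return an `n x k` matrix of partial derivatives.
#' @export
eval_rate_gradient <- function(model, l, y) {
  key <- if (is.character(l)) l else jump_key(l)
  Y <- as_point_matrix(y, model$k)
  g <- model$gradients[[key]]
  if (!is.null(g)) {
    G <- g(Y)
    if (is.null(dim(G))) G <- matrix(G, nrow = nrow(Y))
    return(G)
  }
  numeric_gradient(function(Z) eval_rate(model, key, Z), Y, model)
}

# Richardson-extrapolated central differences, switching to one-sided
# differences near the boundary of the domain (rates are only defined on S~).
numeric_gradient <- function(fn, Y, model) {
  k <- ncol(Y)
  n <- nrow(Y)
  G <- matrix(NA_real_, n, k)
  upper <- if (model$space == "box") model$f else rep(Inf, k)
  for (j in seq_len(k)) {
    h <- 1e-6 * (1 + abs(Y[, j]))
    lo_ok <- Y[, j] - 2 * h >= 0
    hi_ok <- Y[, j] + 2 * h <= upper[j]
    central <- lo_ok & hi_ok
    d <- numeric(n)
    if (any(central)) {
      Yp <- Y[central, , drop = FALSE]; Ym <- Yp
      Yp2 <- Yp; Ym2 <- Yp
      hh <- h[central]
      Yp[, j] <- Yp[, j] + hh;  Ym[, j] <- Ym[, j] - hh
      Yp2[, j] <- Yp2[, j] + 2 * hh; Ym2[, j] <- Ym2[, j] - 2 * hh
      d1 <- (fn(Yp) - fn(Ym)) / (2 * hh)
      d2 <- (fn(Yp2) - fn(Ym2)) / (4 * hh)
      d[central] <- (4 * d1 - d2) / 3
    }
    if (any(!central)) {
      idx <- which(!central)
      for (i in idx) {
        hh <- h[i]
        sgn <- if (Y[i, j] + 2 * hh <= upper[j]) 1 else -1
        y0 <- Y[i, , drop = FALSE]
        y1 <- y0; y1[, j] <- y1[, j] + sgn * hh
        y2 <- y0; y2[, j] <- y2[, j] + sgn * 2 * hh
        d[i] <- sgn * (-3 * fn(y0) + 4 * fn(y1) - fn(y2)) / (2 * hh)
      }
    }
    G[, j] <- d
  }
  G
}

in_state_space <- function(model, y, tol = 1e-12) {
  Y <- as_point_matrix(y, model$k)
  ok <- rowSums(Y < -tol) == 0
  if (model$space == "box") {
    ok <- ok & rowSums(sweep(Y, 2L, model$f) > tol) == 0
  }
  ok
}

#' Drift (deterministic limit vector field)
#'
#' Computes \eqn{\sum_l l \beta_l(y)}, the right-hand side of the fluid
#' limit ODE of the scaled process.
#'
#' @param model a `population_process`.
#' @param y point in the scaled state space, or an `n x k` matrix of points.
#' @return numeric vector of length `k` (or an `n x k` matrix).
#' @export
drift <- function(model, y) {
  Y <- as_point_matrix(y, model$k)
  if (!all(in_state_space(model, Y))) stop("point outside the state space")
  out <- matrix(0, nrow(Y), model$k)
  for (key in rownames(model$jumps)) {
    out <- out + outer(eval_rate(model, key, Y), as.numeric(model$jumps[key, ]))
  }
  if (nrow(Y) == 1L && !is.matrix(y)) drop(out) else out
}

#' Jacobian of the drift field
#'
#' \eqn{J(y) = \sum_l l (\partial \beta_l / \partial y)^T}, using analytic
#' rate gradients when registered and finite differences otherwise
#' (one-sided at the boundary).
#'
#' @inheritParams drift
#' @return a `k x k` matrix.
#' @export
drift_jacobian <- function(model, y) {
  Y <- as_point_matrix(y, model$k)
  if (nrow(Y) != 1L) stop("drift_jacobian takes a single point")
  J <- matrix(0, model$k, model$k)
  for (key in rownames(model$jumps)) {
    g <- eval_rate_gradient(model, key, Y)
    if (any(!is.finite(g))) stop("non-finite derivative of rate ", key)
    J <- J + as.numeric(model$jumps[key, ]) %o% as.numeric(g)
  }
  J
}

#' Transition rates of the N-indexed process at an integer state
#'
#' Rate of the jump `l` from state `x` is \eqn{N \beta_l(x/N)}.  Jumps that
#' would leave the state space \eqn{S^{(N)}} have rate exactly zero (this is
#' guaranteed by the boundary behaviour of valid rate functions, and is
#' additionally clamped here).
#'
#' @param model a `population_process`.
#' @param x nonnegative integer state vector.
#' @param N positive scale parameter.
#' @return named numeric vector of rates, one entry per jump.
#' @export
transition_rates <- function(model, x, N) {
  x <- as.integer(x)
  if (length(x) != model$k || any(x < 0)) stop("state must be a nonnegative integer vector of length k")
  if (model$space == "box") {
    cap <- box_caps(model, N)
    if (any(x > cap)) stop("state outside the box state space")
  }
  y <- x / N
  out <- vapply(rownames(model$jumps), function(key) {
    N * eval_rate(model, key, y)
  }, numeric(1))
  # clamp jumps that would exit S^(N)
  for (i in seq_len(nrow(model$jumps))) {
    tgt <- x + model$jumps[i, ]
    bad <- any(tgt < 0)
    if (!bad && model$space == "box") bad <- any(tgt > box_caps(model, N))
    if (bad) out[i] <- 0
  }
  out
}

# integer box bounds N*f_i, rounded to nearest integer; the model assumes N
# runs through a subsequence with N*f_i integer, so warn when rounding is material
box_caps <- function(model, N) {
  caps <- model$f * N
  r <- round(caps)
  if (any(abs(caps - r) > 1e-8)) {
    warning("N*f_i not integer valued; rounding box bounds to nearest integers")
  }
  as.integer(r)
}

#' Locate the deterministic equilibria and check stability assumptions
#'
#' Finds the interior equilibrium \eqn{y^*} of the drift field by damped
#' Newton iteration (multi-start on a coarse grid if needed), verifies that
#' all Jacobian eigenvalues at \eqn{y^*} have negative real part, and that
#' the origin is unstable.
#'
#' @param model a `population_process`.
#' @param initial_guess optional starting point; default is the box midpoint
#'   (finite state space) or the all-ones point (unbounded).
#' @param tol relative tolerance on `|drift|` for declaring an equilibrium.
#' @return An object of class `equilibrium_report` with elements `ystar`,
#'   `jacobian`, `eigenvalues`, `origin_unstable`, `origin_eigenvalues`.
#' @export
find_equilibria <- function(model, initial_guess = NULL, tol = 1e-10) {
  cached <- model$cache$equilibria
  if (!is.null(cached) && is.null(initial_guess)) return(cached)
  k <- model$k
  upper <- if (model$space == "box") model$f else rep(Inf, k)
  guess <- if (!is.null(initial_guess)) as.numeric(initial_guess)
           else if (model$space == "box") model$f / 2 else rep(1, k)
  scale_fn <- function(y) sum(vapply(rownames(model$jumps),
                                     function(key) eval_rate(model, key, y),
                                     numeric(1)))
  root <- newton_root(model, guess, upper)
  if (is.null(root)) {
    # multi-start on a coarse grid; unbounded models sweep several scales
    # since the equilibrium may sit well away from the unit point
    factors <- if (model$space == "box") c(0.25, 0.5, 0.75)
               else c(0.3, 0.75, 1.5, 3, 6)
    base <- if (model$space == "box") model$f else pmax(guess, 1)
    grid <- as.matrix(expand.grid(rep(list(factors), k)))
    for (i in seq_len(nrow(grid))) {
      root <- newton_root(model, as.numeric(grid[i, ]) * base, upper)
      if (!is.null(root)) break
    }
  }
  if (is.null(root) || any(root <= 0) ||
      (model$space == "box" && any(root >= model$f))) {
    stop_qswkb("no_equilibrium", "no interior equilibrium found for model ", model$name)
  }
  sc <- scale_fn(root)
  if (sqrt(sum(drift(model, root)^2)) > tol * max(sc, 1)) {
    stop_qswkb("no_equilibrium", "Newton iteration did not converge to an equilibrium")
  }
  J <- drift_jacobian(model, root)
  ev <- eigen(J, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    stop_qswkb("assumption_violation",
               "interior equilibrium is not locally stable; Re(eigenvalues) = ",
               paste(signif(Re(ev), 4), collapse = ", "),
               data = list(spectrum = ev, ystar = root))
  }
  J0 <- origin_jacobian(model)
  ev0 <- eigen(J0, only.values = TRUE)$values
  if (!any(Re(ev0) > 0)) {
    stop_qswkb("assumption_violation",
               "origin is not locally unstable; Re(eigenvalues) = ",
               paste(signif(Re(ev0), 4), collapse = ", "),
               data = list(spectrum = ev0))
  }
  rep <- structure(list(ystar = root, jacobian = J, eigenvalues = ev,
                        origin_unstable = TRUE, origin_eigenvalues = ev0),
                   class = "equilibrium_report")
  if (is.null(initial_guess)) model$cache$equilibria <- rep
  rep
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report>\n  y* = (", paste(signif(x$ystar, 6), collapse = ", "),
      ")\n  Re(eig J(y*)) = ", paste(signif(Re(x$eigenvalues), 4), collapse = ", "),
      "\n  origin unstable: ", x$origin_unstable, "\n", sep = "")
  invisible(x)
}

# Jacobian at the origin via one-sided derivatives of the rates.
origin_jacobian <- function(model) {
  J <- matrix(0, model$k, model$k)
  origin <- matrix(0, 1, model$k)
  for (key in rownames(model$jumps)) {
    g <- eval_rate_gradient(model, key, origin)
    J <- J + as.numeric(model$jumps[key, ]) %o% as.numeric(g)
  }
  J
}

newton_root <- function(model, y, upper, maxit = 100L) {
  y <- pmin(pmax(y, 1e-8), upper - 1e-8)
  for (it in seq_len(maxit)) {
    d <- drift(model, y)
    nd <- sqrt(sum(d^2))
    if (nd < 1e-13 * (1 + sqrt(sum(y^2)))) return(y)
    J <- tryCatch(drift_jacobian(model, y), error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, -d), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      cand <- y + lam * step
      cand <- pmin(pmax(cand, 1e-10), upper - 1e-10)
      if (sqrt(sum(drift(model, cand)^2)) < nd || lam < 1e-6) break
      lam <- lam / 2
    }
    ynew <- pmin(pmax(y + lam * step, 1e-10), upper - 1e-10)
    if (sqrt(sum((ynew - y)^2)) < 1e-14 * (1 + sqrt(sum(y^2)))) {
      y <- ynew
      d <- drift(model, y)
      if (sqrt(sum(d^2)) < 1e-11 * (1 + sqrt(sum(y^2)))) return(y) else return(NULL)
    }
    y <- ynew
  }
  if (sqrt(sum(drift(model, y)^2)) < 1e-11) y else NULL
}

#' Stable interior equilibrium of a model (cached)
#'
#' @param model a `population_process`.
#' @return numeric vector \eqn{y^*}.
#' @export
equilibrium_point <- function(model) find_equilibria(model)$ystar

# ---- validation of the standing assumptions -------------------------------

validate_process <- function(model) {
  k <- model$k
  J <- model$jumps
  # symmetric jump set spanning R^k
  for (i in seq_len(nrow(J))) {
    if (!(jump_key(-J[i, ]) %in% rownames(J))) {
      stop("jump set is not symmetric: missing -(", jump_key(J[i, ]), ")")
    }
  }
  if (qr(J)$rank < k) stop("jump set does not span R^k")
  # rates vanish at the origin
  origin <- matrix(0, 1, k)
  v0 <- vapply(rownames(J), function(key) eval_rate(model, key, origin), numeric(1))
  if (any(abs(v0) > 1e-12)) stop("rates must vanish at the origin")
  # boundary behaviour at sample points
  pts <- validation_points(model)
  for (key in rownames(J)) {
    l <- J[key, ]
    vals <- eval_rate(model, key, pts)
    blocked <- boundary_blocked(model, pts, l)
    if (any(vals[blocked] > 1e-12)) {
      stop("rate for jump ", key, " must vanish on the blocking boundary")
    }
    interior_nonzero <- !blocked & rowSums(pts) > 1e-12
    if (any(vals[interior_nonzero] <= 0)) {
      stop("rate for jump ", key, " must be positive away from its blocking boundary")
    }
  }
  # finite one-sided first derivatives at the origin
  g0 <- lapply(rownames(J), function(key) eval_rate_gradient(model, key, origin))
  if (any(!vapply(g0, function(g) all(is.finite(g)), logical(1)))) {
    stop("rates must have finite one-sided derivatives at the origin")
  }
  invisible(TRUE)
}

# sample points mixing interior points with faces of the boundary
validation_points <- function(model, n_interior = 8L) {
  k <- model$k
  upper <- if (model$space == "box") model$f else rep(1.5, k)
  set <- list()
  tics <- seq(0.2, 0.9, length.out = n_interior)
  interior <- sapply(seq_len(k), function(j) tics * upper[j] * 0.9)
  set$interior <- matrix(interior, ncol = k)
  for (j in seq_len(k)) {
    p <- set$interior
    p[, j] <- 0
    set[[paste0("lo", j)]] <- p
    if (model$space == "box") {
      q <- set$interior
      q[, j] <- model$f[j]
      set[[paste0("hi", j)]] <- q
    }
  }
  do.call(rbind, set)
}

boundary_blocked <- function(model, pts, l) {
  blocked <- rep(FALSE, nrow(pts))
  for (j in seq_len(model$k)) {
    if (l[j] < 0) blocked <- blocked | pts[, j] <= 1e-14
    if (model$space == "box" && l[j] > 0) {
      blocked <- blocked | pts[, j] >= model$f[j] - 1e-14
    }
  }
  blocked
}

# ---- error helpers --------------------------------------------------------

stop_qswkb <- function(class, ..., data = NULL) {
  cond <- structure(
    class = c(paste0("qswkb_", class), "error", "condition"),
    list(message = paste0(...), call = sys.call(-1), data = data))
  stop(cond)
}
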