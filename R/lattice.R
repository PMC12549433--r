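# Enumeration of capped integer lattices and precomputed rate tables.
# Shared by the exact truncated-chain oracle and the table-driven SSA.

#' Per-coordinate state caps for a model at scale N
#'
#' Finite-box models use their natural bounds \eqn{N f_i}; unbounded
#' models are truncated at `ceiling(c * N * ystar)` (reflecting
#' truncation: jumps beyond the cap are clipped).
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @param c truncation multiple of the equilibrium for unbounded models.
#' @param cap optional explicit integer cap vector overriding the policy.
#' @return integer vector of per-coordinate caps.
#' @export
lattice_caps <- function(model, N, c = 3, cap = NULL) {
  if (!is.null(cap)) return(as.integer(cap))
  if (model$space == "box") return(box_caps(model, N))
  as.integer(ceiling(c * N * equilibrium_point(model)))
}

enumerate_states <- function(caps) {
  k <- length(caps)
  dims <- caps + 1L
  n <- prod(dims)
  S <- matrix(0L, n, k)
  rep_each <- 1L
  for (j in seq_len(k)) {
    S[, j] <- rep(rep(0:caps[j], each = rep_each), length.out = n)
    rep_each <- rep_each * dims[j]
  }
  S
}

state_index <- function(X, caps) {
  dims <- caps + 1L
  stride <- cumprod(c(1L, dims[-length(dims)]))
  as.integer(X %*% stride) + 1L
}

# Precompute the full transition table on the capped lattice.
# Returns states (incl. origin at index 1), rates and target matrices,
# plus the count of clipped (truncated) positive-rate transitions.
rate_table <- function(model, N, caps) {
  S <- enumerate_states(caps)
  n <- nrow(S)
  Y <- S / N
  keys <- rownames(model$jumps)
  m <- length(keys)
  rates <- matrix(0, n, m)
  target <- matrix(1L, n, m)
  clipped <- 0L
  for (j in seq_len(m)) {
    l <- model$jumps[keys[j], ]
    r <- N * eval_rate(model, keys[j], Y)
    Tj <- sweep(S, 2L, l, `+`)
    ok <- rowSums(Tj < 0L) == 0L & rowSums(sweep(Tj, 2L, caps) > 0L) == 0L
    clipped <- clipped + sum(r[!ok] > 0)
    r[!ok] <- 0
    rates[, j] <- r
    target[ok, j] <- state_index(Tj[ok, , drop = FALSE], caps)
  }
  origin <- state_index(matrix(0L, 1, length(caps)), caps)
  rates[origin, ] <- 0
  list(states = S, rates = rates, target = target,
       origin = origin, caps = caps, clipped = clipped)
}
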