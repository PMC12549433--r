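# Shared fixtures: every model is built in code, no stored data.

# linear-birth quadratic-death process, unit-rate parameters used in the
# worked examples (k = 1, lambda = 2, mu = 1, kappa = 1)
example2_k1 <- function() make_example2(1, 2, 1, 1)

# parameter set used for the oracle-convergence and simulation studies:
# moderate growth-rate margin so the asymptotic regime is visible by N ~ 80
example2_study <- function() make_example2(1, 1.6, 1, 1)

# two-group movement model at the reference parameter values
two_group_ref <- function() make_two_group(2.9, 0.1, 1, 2, 2, 1)
two_group_nomove <- function() make_two_group(2.9, 0.1, 1, 2, 0, 0)

sis_k2 <- function() {
  f <- c(0.4, 0.6)
  mu <- c(1.3, 0.8)
  mu <- mu / sum(mu * f)
  make_sis(2, beta = 1.8, mu = mu, alpha = c(1, 1.5), f = f)
}

# competition-family instance built from the two-group factorisation with
# free constants a
competition_funs <- function() {
  list(b0 = function(u) u,
       b1 = function(u) rep(1, length(u)), b2 = function(u) rep(1, length(u)),
       b3 = function(u) rep(1, length(u)),
       c0 = function(u) rep(1, length(u)), c1 = function(u) rep(1, length(u)),
       c2 = function(u) rep(1, length(u)),
       d0 = function(u) 2.9 + 0.1 * u,
       d1 = function(u) u, d2 = function(u) u,
       d3 = function(u) rep(1, length(u)))
}

# one-type birth-free (pure death) process; bypasses interior-positivity
# validation since births are identically zero
pure_death_model <- function() {
  population_process(
    1L, rbind(1L, -1L),
    rates = list("1" = function(Y) rep(0, nrow(Y)),
                 "-1" = function(Y) Y[, 1]),
    space = "unbounded", name = "pure_death", validate = FALSE)
}

# two-state chain with arbitrary per-state rates, for the hand-solvable
# eigen oracle: state 1 dies at rate mu, births 1->2 at rate lam,
# state 2 falls back at rate nu
two_state_model <- function(lam, mu, nu) {
  near <- function(x, v) abs(x - v) < 1e-9
  population_process(
    1L, rbind(1L, -1L),
    rates = list(
      "1" = function(Y) ifelse(near(Y[, 1], 1), lam, 0),
      "-1" = function(Y) ifelse(near(Y[, 1], 1), mu, ifelse(near(Y[, 1], 2), nu, 0))),
    space = "unbounded", name = "two_state", validate = FALSE)
}

total_variation <- function(states_a, mass_a, states_b, mass_b) {
  key <- function(S) apply(S, 1L, paste, collapse = ",")
  all_keys <- union(key(states_a), key(states_b))
  pa <- setNames(numeric(length(all_keys)), all_keys)
  pb <- pa
  pa[key(states_a)] <- mass_a
  pb[key(states_b)] <- mass_b
  0.5 * sum(abs(pa - pb))
}

kl_divergence <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

# WKB masses over the interior states of a truncated chain (fast grid path)
wkb_mass_on_chain <- function(model, chain, N) {
  S <- chain$states
  inner <- which(qswkb:::boundary_distance(model, S / N) >=
                   default_boundary_cutoff(model, N))
  V <- qswkb:::grid_potentials(model, S[inner, , drop = FALSE], N)
  V0 <- vapply(inner, function(i) correction(model, S[i, ] / N), numeric(1))
  list(inner = inner, mass = wkb_prefactor(model, N) * exp(-N * V - V0))
}
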