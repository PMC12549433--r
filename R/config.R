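#' Configuration parsing and command dispatch
#'
#' A run configuration names a built-in parameterised model family and the
#' command parameters.  The function-valued families
#' ([make_ball_clancy()], [make_competition()]) are not expressible in a
#' plain config and must be constructed programmatically; the
#' parameterised families (`sis`, `example2`, `two_group`) round-trip
#' through YAML/JSON.
#'
#' @name cli
NULL

config_model_builders <- function() {
  list(
    sis = function(p) make_sis(p$k, p$beta, unlist(p$mu), unlist(p$alpha), unlist(p$f)),
    example2 = function(p) make_example2(p$k, p$lam, p$mu, p$kappa),
    two_group = function(p) make_two_group(p$mu, p$kappa, p$lam1, p$lam2,
                                           p$nu1 %||% 0, p$nu2 %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

required_params <- list(
  sis = c("k", "beta", "mu", "alpha", "f"),
  example2 = c("k", "lam", "mu", "kappa"),
  two_group = c("mu", "kappa", "lam1", "lam2"))

optional_params <- list(
  sis = character(0), example2 = character(0), two_group = c("nu1", "nu2"))

#' Validate a run configuration
#'
#' Parses YAML or JSON text (or accepts a list), checks it against the
#' schema (known model name, required numeric parameters, no unknown
#' keys), and instantiates the model.
#'
#' @param raw configuration text (YAML or JSON), a file path, or a list.
#' @return An object of class `run_config`: list with `model` (the
#'   instantiated `population_process`), `model_name`, `params`, `N`,
#'   `seed` and any extra command settings under `settings`.
#' @export
validate_config <- function(raw) {
  cfg <- if (is.list(raw)) {
    raw
  } else if (length(raw) == 1 && file.exists(raw)) {
    yaml::read_yaml(raw)
  } else {
    txt <- paste(raw, collapse = "\n")
    parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                       error = function(e) NULL)
    if (is.null(parsed)) parsed <- tryCatch(yaml::yaml.load(txt),
                                            error = function(e) NULL)
    if (is.null(parsed)) stop("configuration is neither valid JSON nor YAML")
    parsed
  }
  # YAML 1.1 parses a bare `N:` key as the boolean FALSE; restore it
  names(cfg)[names(cfg) %in% c("FALSE", "F")] <- "N"
  errors <- character(0)
  builders <- config_model_builders()
  top_known <- c("model", "params", "N", "seed", "settings")
  unknown <- setdiff(names(cfg), top_known)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown top-level keys: ",
                               paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$model)) {
    errors <- c(errors, "missing `model`")
  } else if (!cfg$model %in% names(builders)) {
    errors <- c(errors, paste0("unknown model `", cfg$model, "`; available: ",
                               paste(names(builders), collapse = ", ")))
  }
  if (length(errors) == 0) {
    req <- required_params[[cfg$model]]
    opt <- optional_params[[cfg$model]]
    p <- cfg$params %||% list()
    missing <- setdiff(req, names(p))
    if (length(missing)) {
      errors <- c(errors, paste0("missing params for ", cfg$model, ": ",
                                 paste(missing, collapse = ", ")))
    }
    bad <- setdiff(names(p), c(req, opt))
    if (length(bad)) {
      errors <- c(errors, paste0("unknown params: ", paste(bad, collapse = ", ")))
    }
    for (nm in intersect(names(p), c(req, opt))) {
      v <- unlist(p[[nm]])
      if (!is.numeric(v) || any(!is.finite(v))) {
        errors <- c(errors, paste0("param `", nm, "` must be finite numeric"))
      }
    }
  }
  if (length(errors)) {
    stop_qswkb("config", paste(errors, collapse = "; "),
               data = list(errors = errors))
  }
  model <- tryCatch(builders[[cfg$model]](cfg$params),
                    error = function(e) {
                      stop_qswkb("config", "model construction failed: ",
                                 conditionMessage(e))
                    })
  structure(list(model = model, model_name = cfg$model, params = cfg$params,
                 N = cfg$N %||% 100, seed = cfg$seed %||% 1L,
                 settings = cfg$settings %||% list()),
            class = "run_config")
}

#' Serialise a parameterised built-in model to a config list
#'
#' @param model a built-in `population_process` (`sis`, `example2` or
#'   `two_group`).
#' @param N,seed values to embed.
#' @return a list suitable for `yaml::as.yaml()` / `jsonlite::toJSON()`
#'   and for [validate_config()].
#' @export
model_config <- function(model, N = 100, seed = 1L) {
  if (!model$name %in% names(config_model_builders())) {
    stop("model `", model$name, "` is not expressible as a plain config")
  }
  list(model = model$name, params = model$params, N = N, seed = seed)
}

#' Run a command on a validated configuration
#'
#' Dispatches the command-line surface: `check` (criteria report), `wkb`
#' (potential/correction/mass on a state grid), `tau` (leading exponent
#' and full prefactor over the `N` values), `simulate` (protocol +
#' censored MLE), `oracle` (truncated-chain decay rate and tau), and
#' `compare` (oracle vs analytic vs simulation per `N`).  Results are
#' returned as data frames or lists; file output is handled by the
#' command-line script.
#'
#' @param config a `run_config`.
#' @param command one of `"check"`, `"wkb"`, `"tau"`, `"simulate"`,
#'   `"oracle"`, `"compare"`.
#' @param ... command settings overriding `config$settings`.
#' @return command-specific result object.
#' @export
run_command <- function(config, command = c("check", "wkb", "tau",
                                            "simulate", "oracle", "compare"),
                        ...) {
  command <- match.arg(command)
  model <- config$model
  st <- utils::modifyList(config$settings, list(...))
  N <- st$N %||% config$N
  seed <- st$seed %||% config$seed
  switch(command,
    check = full_report(model, seed = seed),
    wkb = {
      tab <- sim_table(model, N, c = st$c %||% 3)
      S <- tab$states
      keep <- rowSums(S) > 0
      S <- S[keep, , drop = FALSE]
      colnames(S) <- paste0("x", seq_len(model$k))
      Y <- S / N
      cutoff <- st$boundary_cutoff %||% default_boundary_cutoff(model, N)
      inner <- boundary_distance(model, Y) >= cutoff
      V <- grid_potentials(model, S, N)
      V0 <- rep(NA_real_, nrow(S))
      V0[inner] <- vapply(which(inner), function(i) correction(model, Y[i, ]), numeric(1))
      wmass <- rep(NA_real_, nrow(S))
      wmass[inner] <- wkb_prefactor(model, N) * exp(-N * V[inner] - V0[inner])
      data.frame(S, y = I(Y), V = V, V0 = V0, wkb_mass = wmass,
                 gaussian_mass = gaussian_qsd(model, N, S))
    },
    tau = {
      Ns <- st$N_values %||% N
      A <- log_tau_leading(model)
      tf <- tryCatch(tau_full(model, Ns), error = function(e) rep(NA_real_, length(Ns)))
      data.frame(N = Ns, logtau_leading = A, tau_full = tf)
    },
    simulate = {
      proto <- sim_protocol(n_runs = st$n_runs %||% 100L, t0 = st$t0 %||% 10,
                            t_max = st$t_max %||% 50000, seed = seed)
      samp <- sample_extinction_times(model, N, proto, c = st$c %||% 3)
      list(sample = samp, estimate = censored_exp_mle(samp, st$level %||% 0.95))
    },
    oracle = {
      chain <- build_truncated(model, N, c = st$c %||% 3)
      q <- exact_qsd(chain)
      t <- exact_tau(chain, model, q)
      list(N = N, alpha = q$alpha, tau_exact = t$tau, tau_flux = t$tau_flux,
           state_count = nrow(chain$states))
    },
    compare = {
      Ns <- st$N_values %||% N
      A <- log_tau_leading(model)
      out <- lapply(Ns, function(n) {
        chain <- build_truncated(model, n, c = st$c %||% 3)
        te <- exact_tau(chain, model)$tau
        tf <- tryCatch(tau_full(model, n), error = function(e) NA_real_)
        data.frame(N = n, tau_exact = te, tau_full = tf,
                   logtau_leading_limit = A,
                   logtau_exact_over_N = log(te) / n)
      })
      do.call(rbind, out)
    })
}

# potentials for many integer states, using the grid fast path when possible
grid_potentials <- function(model, S, N) {
  Y <- S / N
  if (model$k == 2L) {
    y1s <- sort(unique(Y[, 1])); y2s <- sort(unique(Y[, 2]))
    y1s <- pmax(y1s, 1e-12); y2s <- pmax(y2s, 1e-12)
    Vg <- potential_grid(model, y1s, y2s)
    Vg[cbind(match(pmax(Y[, 1], 1e-12), y1s), match(pmax(Y[, 2], 1e-12), y2s))]
  } else if (model$k == 1L) {
    potential_grid(model, pmax(Y[, 1], 1e-12))
  } else {
    vapply(seq_len(nrow(Y)), function(i) potential(model, Y[i, ]), numeric(1))
  }
}
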