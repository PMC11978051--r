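#' Mutation parameters
#'
#' @param mu Mutation rate per trait, in (growth cycles)^-1.
#' @param delta_m Mass mutation step.
#' @param delta_alpha Fusion-rate mutation step.
#' @param prune_threshold Minimum frequency retained; genotypes below it are
#'   removed and frequencies renormalised.
#' @param m_floor Smallest admissible mass; mass proposals below it are
#'   discarded.
#' @param seed_frequency Frequency given to a new mutant, taken from its
#'   ancestor: `min(seed_frequency, f_ancestor / 2)`.
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(mu = 0.01, delta_m = 0.02, delta_alpha = 0.02,
                            prune_threshold = 1e-6, m_floor = 1e-3,
                            seed_frequency = 1e-3) {
  if (mu <= 0) abort("`mu` must be positive.", class = "fusevol_domain_error")
  if (delta_m <= 0 || delta_alpha <= 0) {
    abort("mutation steps must be positive.", class = "fusevol_domain_error")
  }
  if (prune_threshold < 0 || prune_threshold > 1e-3) {
    abort("`prune_threshold` must lie in [0, 1e-3].",
          class = "fusevol_domain_error")
  }
  if (m_floor <= 0) abort("`m_floor` must be positive.",
                          class = "fusevol_domain_error")
  structure(list(mu = mu, delta_m = delta_m, delta_alpha = delta_alpha,
                 prune_threshold = prune_threshold, m_floor = m_floor,
                 seed_frequency = seed_frequency), class = "mutation_params")
}

## Merge genotypes whose traits coincide to tolerance 1e-12 (sums
## frequencies); keeps the genotype count bounded.
merge_genotypes <- function(traits, f, tol = 1e-12) {
  S <- nrow(traits)
  if (S < 2) return(list(traits = traits, f = f))
  key <- apply(round(traits / tol) * tol, 1, paste, collapse = "|")
  if (!anyDuplicated(key)) return(list(traits = traits, f = f))
  keep <- !duplicated(key)
  fm <- vapply(split(f, key), sum, numeric(1))
  traits <- traits[keep, , drop = FALSE]
  f <- as.numeric(fm[key[keep]])
  list(traits = traits, f = f)
}

## One mutation event on the bare trait matrix. Picks an ancestor with
## probability f, a trait uniformly among the evolvable ones, and a sign
## with probability 1/2; out-of-range proposals (alpha < 0, m < m_floor)
## consume the event without creating a genotype.
mutate_step <- function(traits, f, evolve, mutation) {
  anc <- sample.int(length(f), 1, prob = f)
  trait <- if (length(evolve) == 1) evolve else sample(evolve, 1)
  sign <- if (runif(1) < 0.5) 1 else -1
  step <- if (grepl("^m", trait)) mutation$delta_m else mutation$delta_alpha
  value <- traits[anc, trait] + sign * step
  # accumulated float error in repeated +/- steps must not strand a
  # genotype one step above a boundary: snap near-boundary proposals
  tol <- 1e-9 * step
  if (grepl("^alpha", trait)) {
    if (value < -tol) return(list(traits = traits, f = f))
    if (value < tol) value <- 0
  } else {
    if (value < mutation$m_floor - tol) return(list(traits = traits, f = f))
  }
  newrow <- traits[anc, , drop = FALSE]
  newrow[, trait] <- value
  fs <- min(mutation$seed_frequency, f[anc] / 2)
  traits <- rbind(traits, newrow)
  f <- c(f, fs)
  f[anc] <- f[anc] - fs
  merge_genotypes(traits, f)
}

#' Apply one mutation event to a population
#'
#' One stochastic mutation: an ancestor is chosen with probability equal to
#' its frequency, one evolvable trait is perturbed by plus or minus its step
#' (50% each), and the mutant is seeded with a small frequency transferred
#' from the ancestor. Proposals below the `alpha = 0` boundary or the mass
#' floor are discarded (the event is consumed). Coincident genotypes are
#' merged.
#'
#' @param pop A [population_state()].
#' @param mutation A [mutation_params()].
#' @param evolve Character vector of evolvable trait columns (e.g.
#'   `c("m", "alpha")`, or a subset to pin traits).
#' @return The updated `population_state`.
#' @export
mutate_population <- function(pop, mutation, evolve = c("m", "alpha")) {
  validate_population(pop)
  trait_cols <- setdiff(names(pop), "f")
  bad <- setdiff(evolve, trait_cols)
  if (length(bad) > 0) {
    abort(sprintf("unknown evolvable trait(s): %s", paste(bad, collapse = ", ")),
          class = "fusevol_config_error")
  }
  traits <- as.matrix(pop[, trait_cols, drop = FALSE])
  res <- mutate_step(traits, pop$f, evolve, mutation)
  out <- tibble::as_tibble(as.data.frame(res$traits))
  out$f <- res$f / sum(res$f)
  class(out) <- class(pop)
  out
}

#' Advance an environment schedule by one cycle
#'
#' Stateless helper used by the simulator: given the schedule, the upcoming
#' cycle index and the current state, returns the active environment index.
#' Fixed schedules never switch; scheduled ones toggle at the listed cycles;
#' telegraph ones switch with their per-cycle rate (residence times are
#' geometric).
#'
#' @param schedule An [env_schedule()].
#' @param cycle Growth-cycle index (1-based).
#' @param state Current environment index (1 or 2).
#' @return The environment index active during `cycle`.
#' @export
environment_step <- function(schedule, cycle, state = 1L) {
  switch(schedule$mode,
    fixed = state,
    scheduled = {
      if (cycle %in% schedule$switch_cycles) 3L - state else state
    },
    telegraph = {
      rate <- if (state == 1L) schedule$lambda_12 else schedule$lambda_21
      if (runif(1) < rate) 3L - state else state
    }
  )
}

#' Run the stochastic mutation-selection simulation
#'
#' Alternates deterministic growth-cycle updates ([cycle_update()]) with
#' stochastic mutation events arriving after geometric waiting times (a
#' single clock at rate `mu` times the number of evolvable traits, with a
#' uniform trait choice — the exact superposition of independent per-trait
#' processes) and with environment switching per the schedule. Genotypes
#' falling below the pruning threshold are removed each cycle.
#'
#' @param initial Named list or one-row data frame of initial traits, e.g.
#'   `list(m = 1.16, alpha = 0)` or the plastic
#'   `list(m1 = , alpha1 = , m2 = , alpha2 = )`.
#' @param params A [model_params()].
#' @param model A [survival_model()].
#' @param schedule An [env_schedule()] (or a single [fusion_env()], treated
#'   as a fixed schedule).
#' @param mutation A [mutation_params()].
#' @param n_cycles Number of growth cycles (`>= 1`).
#' @param seed Mandatory integer seed; identical `(configuration, seed)`
#'   pairs give identical trajectories.
#' @param evolve Evolvable trait columns; defaults to all trait columns of
#'   `initial` (pin a trait by omitting it).
#' @param record_every Record a trajectory row every this many cycles.
#' @param alpha_stop Optional early-stop threshold: the run terminates once
#'   the frequency-weighted mean fusion rate (any environment's, for plastic
#'   genotypes) exceeds it, with status `"alpha_threshold_reached"` —
#'   useful for classifying divergence towards obligate fusion.
#' @param max_genotypes Hard cap on concurrent genotypes; exceeding it is a
#'   configuration error (pruning threshold too small).
#' @return An object of class `fusion_sim`: list with `trajectory` (tibble:
#'   cycle, env, n_genotypes, trait means/variances, survival_fraction),
#'   `final` (the final [population_state()]), `status` (`"completed"`,
#'   `"extinct"` or `"alpha_threshold_reached"`), and `config`.
#' @export
run_simulation <- function(initial, params, model, schedule, mutation,
                           n_cycles, seed, evolve = NULL,
                           record_every = 1L, alpha_stop = Inf,
                           max_genotypes = 1000L) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory (reproducibility contract).",
          class = "fusevol_config_error")
  }
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.",
                          class = "fusevol_config_error")
  if (inherits(schedule, "fusion_env")) {
    schedule <- env_schedule(schedule, mode = "fixed")
  }
  init <- as.list(initial)
  plastic <- "m1" %in% names(init)
  trait_cols <- if (plastic) c("m1", "alpha1", "m2", "alpha2") else
    c("m", "alpha")
  if (!all(trait_cols %in% names(init))) {
    abort(sprintf("`initial` must provide traits: %s",
                  paste(trait_cols, collapse = ", ")),
          class = "fusevol_config_error")
  }
  if (is.null(evolve)) evolve <- trait_cols
  traits <- matrix(unlist(init[trait_cols]), nrow = 1,
                   dimnames = list(NULL, trait_cols))
  f <- 1

  set.seed(as.integer(seed))
  mu_total <- mutation$mu * length(evolve)
  next_mutation <- 1L + rgeom(1, mu_total) + 1L

  envs <- list(schedule$env1, schedule$env2)
  env_state <- 1L

  n_rec <- length(seq(1L, n_cycles, by = record_every))
  rec <- matrix(NA_real_, nrow = n_rec,
                ncol = 4L + 2L * length(trait_cols))
  rec_names <- c("cycle", "env", "n_genotypes",
                 as.vector(rbind(paste0("mean_", trait_cols),
                                 paste0("var_", trait_cols))),
                 "survival_fraction")
  colnames(rec) <- rec_names
  ri <- 0L

  status <- "completed"
  mutation_cycles <- integer()
  switch_cycles_seen <- integer()
  surv_cache_env <- 0L
  surv_fn <- NULL

  for (cycle in seq_len(n_cycles)) {
    env_prev <- env_state
    env_state <- environment_step(schedule, cycle, env_state)
    if (env_state != env_prev) {
      switch_cycles_seen <- c(switch_cycles_seen, cycle)
    }
    if (cycle >= next_mutation) {
      mutation_cycles <- c(mutation_cycles, cycle)
      res <- mutate_step(traits, f, evolve, mutation)
      traits <- res$traits
      f <- res$f / sum(res$f)
      if (nrow(traits) > max_genotypes) {
        abort(paste("genotype cap exceeded; increase `prune_threshold`",
                    "or `max_genotypes`."), class = "fusevol_config_error")
      }
      next_mutation <- cycle + rgeom(1, mu_total) + 1L
    }
    if (env_state != surv_cache_env) {
      env_now <- envs[[env_state]]
      surv_fn <- local({
        e <- env_now
        function(mass) survival_prob(model, mass, e)
      })
      surv_cache_env <- env_state
    }
    if (plastic) {
      m_act <- traits[, if (env_state == 1L) "m1" else "m2"]
      a_act <- traits[, if (env_state == 1L) "alpha1" else "alpha2"]
    } else {
      m_act <- traits[, "m"]
      a_act <- traits[, "alpha"]
    }
    step <- tryCatch(
      cycle_step(m_act, a_act, f, params$E, params$T, params$C, surv_fn),
      fusevol_extinction = function(cnd) NULL
    )
    if (is.null(step)) {
      status <- "extinct"
      ri <- ri + 1L
      rec[ri, ] <- c(cycle, env_state, nrow(traits),
                     as.vector(rbind(colSums(traits * f),
                                     rep(NA, length(trait_cols)))), 0)
      break
    }
    f <- step$f
    keep <- f >= mutation$prune_threshold
    if (!all(keep)) {
      traits <- traits[keep, , drop = FALSE]
      f <- f[keep] / sum(f[keep])
    }
    if (cycle %% record_every == 1L %% record_every) {
      ri <- ri + 1L
      means <- colSums(traits * f)
      vars <- colSums(traits^2 * f) - means^2
      rec[ri, ] <- c(cycle, env_state, nrow(traits),
                     as.vector(rbind(means, vars)), step$survival_fraction)
    }
    if (is.finite(alpha_stop)) {
      a_cols <- grep("^alpha", trait_cols)
      mean_a <- max(colSums(traits[, a_cols, drop = FALSE] * f))
      if (mean_a >= alpha_stop) {
        status <- "alpha_threshold_reached"
        break
      }
    }
  }

  trajectory <- tibble::as_tibble(as.data.frame(rec[seq_len(ri), ,
                                                    drop = FALSE]))
  trajectory$env <- envs[[1]]$label
  env_col <- rec[seq_len(ri), "env"]
  if (!is.null(envs[[2]])) {
    trajectory$env <- ifelse(env_col == 1, envs[[1]]$label, envs[[2]]$label)
  }
  final <- tibble::as_tibble(as.data.frame(traits))
  final$f <- f
  class(final) <- c("population_state", class(tibble::tibble()))
  out <- list(
    trajectory = trajectory,
    final = final,
    status = status,
    events = list(mutation_cycles = mutation_cycles,
                  switch_cycles = switch_cycles_seen),
    config = list(initial = init, params = params, model = model,
                  schedule = schedule, mutation = mutation,
                  n_cycles = n_cycles, seed = seed, evolve = evolve,
                  record_every = record_every, alpha_stop = alpha_stop)
  )
  class(out) <- "fusion_sim"
  out
}

#' @export
print.fusion_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<fusion_sim> %d recorded cycles, status: %s\n",
              nrow(tr), x$status))
  if (nrow(tr) > 0) {
    last <- tr[nrow(tr), ]
    trait_means <- last[grep("^mean_", names(last))]
    cat("  final trait means:",
        paste(sprintf("%s = %.4g", sub("mean_", "", names(trait_means)),
                      unlist(trait_means)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate the evolutionarily stable strategy from a trajectory
#'
#' Time-averages the frequency-weighted trait means over the post-burn-in
#' window, with a stationarity diagnostic (the first and second halves of
#' the window must agree within two standard deviations).
#'
#' @param sim A `fusion_sim` (or its trajectory tibble).
#' @param burn_in_fraction Fraction of the trajectory discarded as burn-in.
#' @return A tibble with one row per trait: `trait`, `mean`, `sd`,
#'   `stationary`.
#' @export
estimate_ess <- function(sim, burn_in_fraction = 0.5) {
  tr <- if (inherits(sim, "fusion_sim")) sim$trajectory else sim
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    abort("`burn_in_fraction` must lie in [0, 1).",
          class = "fusevol_domain_error")
  }
  n <- nrow(tr)
  start <- floor(n * burn_in_fraction) + 1L
  if (start >= n) {
    abort("trajectory shorter than burn-in.", class = "fusevol_domain_error")
  }
  window <- tr[start:n, ]
  mean_cols <- grep("^mean_", names(tr), value = TRUE)
  out <- purrr::map(mean_cols, function(col) {
    x <- window[[col]]
    mid <- floor(length(x) / 2)
    s <- stats::sd(x)
    # a sustained drift shifts the half-window means by more than the
    # within-window spread allows for a stationary series
    stationary <- if (s == 0) TRUE else
      abs(mean(x[seq_len(mid)]) - mean(x[(mid + 1):length(x)])) < 1.5 * s
    tibble::tibble(trait = sub("^mean_", "", col), mean = mean(x),
                   sd = s, stationary = stationary)
  })
  out <- dplyr::bind_rows(out)
  if (any(!out$stationary)) {
    warn("trajectory may not be stationary over the averaging window.",
         class = "fusevol_nonstationary")
  }
  out
}
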