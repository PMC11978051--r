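#' Model parameters for the growth cycle
#'
#' @param E Total population mass; sets the carrying capacity (a genotype at
#'   frequency `f` with daughter mass `m` enters the fusion pool with
#'   `f * E / m` cells).
#' @param T Duration of the fusion window (`>= 0`).
#' @param C Fusion cost in `[0, 1]`: the fraction of the fused-cell
#'   contribution lost (fusion failure, hindered growth and failed
#'   segregation are all equivalent multiplicatively at the frequency level).
#' @return An object of class `model_params`.
#' @export
model_params <- function(E = 100, T = 1, C = 0) {
  if (!is.numeric(E) || E <= 0) {
    abort("`E` must be positive.", class = "fusevol_domain_error")
  }
  if (!is.numeric(T) || T < 0) {
    abort("`T` must be nonnegative.", class = "fusevol_domain_error")
  }
  if (!is.numeric(C) || C < 0 || C > 1) {
    abort("`C` must lie in [0, 1].", class = "fusevol_domain_error")
  }
  structure(list(E = E, T = T, C = C), class = "model_params")
}

#' Construct a population state
#'
#' A population is a tibble with one row per genotype. Fixed-strategy
#' genotypes carry columns `m` (daughter-cell mass) and `alpha` (fusion
#' rate); plastic genotypes carry `m1`, `alpha1`, `m2`, `alpha2` (one trait
#' pair per environment). The `f` column holds genotype frequencies summing
#' to 1.
#'
#' @param ... Trait vectors (`m`, `alpha`, or `m1`/`alpha1`/`m2`/`alpha2`).
#' @param f Genotype frequencies (recycled/normalised to sum to 1).
#' @return A tibble of class `population_state`.
#' @examples
#' population_state(m = c(0.5, 1), alpha = 0, f = c(0.5, 0.5))
#' @export
population_state <- function(..., f = 1) {
  pop <- tibble::tibble(..., f = f)
  pop$f <- pop$f / sum(pop$f)
  validate_population(pop)
  class(pop) <- c("population_state", class(tibble::tibble()))
  pop
}

validate_population <- function(pop) {
  m_cols <- intersect(c("m", "m1", "m2"), names(pop))
  a_cols <- intersect(c("alpha", "alpha1", "alpha2"), names(pop))
  if (length(m_cols) == 0) {
    abort("population must have mass columns (`m` or `m1`/`m2`).",
          class = "fusevol_domain_error")
  }
  for (col in m_cols) {
    if (any(pop[[col]] <= 0)) {
      abort(sprintf("masses in `%s` must be positive.", col),
            class = "fusevol_domain_error")
    }
  }
  for (col in a_cols) {
    if (any(pop[[col]] < 0)) {
      abort(sprintf("fusion rates in `%s` must be nonnegative.", col),
            class = "fusevol_domain_error")
    }
  }
  if (any(pop$f < 0)) {
    abort("frequencies must be nonnegative.", class = "fusevol_domain_error")
  }
  if (abs(sum(pop$f) - 1) > 1e-12) {
    abort("frequencies must sum to 1 (tolerance 1e-12).",
          class = "fusevol_domain_error")
  }
  invisible(pop)
}

is_plastic <- function(pop) "m1" %in% names(pop)

active_traits <- function(pop, env_index = 1L) {
  if (is_plastic(pop)) {
    if (env_index == 1L) list(m = pop$m1, alpha = pop$alpha1)
    else list(m = pop$m2, alpha = pop$alpha2)
  } else {
    list(m = pop$m, alpha = if ("alpha" %in% names(pop)) pop$alpha else
      rep(0, nrow(pop)))
  }
}

#' Initial daughter-cell counts entering the fusion pool
#'
#' At the start of a cycle a genotype at frequency `f_i` with (environment-
#' active) daughter mass `m_i` contributes `N_i(0) = f_i * E / m_i` cells.
#'
#' @param pop A [population_state()].
#' @param params A [model_params()].
#' @param env_index Which environment's traits are active (plastic genotypes).
#' @return A tibble with the genotype traits and a column `N0`.
#' @export
initial_counts <- function(pop, params, env_index = 1L) {
  validate_population(pop)
  tr <- active_traits(pop, env_index)
  dplyr::bind_cols(pop, tibble::tibble(N0 = pop$f * params$E / tr$m))
}

## Internal fusion-window solver on bare vectors. Returns list(N, F).
## Uses the exact solution when all rates coincide (including the alpha = 0
## fast path); otherwise the adaptive Runge-Kutta kernel.
fusion_counts <- function(N0, alpha, T_window, rtol = 1e-10, atol = 1e-12) {
  S <- length(N0)
  Fm <- matrix(0, S, S)
  if (T_window == 0 || all(alpha <= 0) || sum(N0) == 0) {
    return(list(N = N0, F = Fm))
  }
  if (diff(range(alpha)) < 1e-15) {
    # equal rates: Ntot obeys dN/dt = -a Ntot^2, per-type counts decay
    # proportionally and F_ij = a N_i0 N_j0 T / (1 + a Ntot0 T) (i < j),
    # F_ii = a N_i0^2 T / (2 (1 + a Ntot0 T))
    a <- alpha[1]
    Ntot0 <- sum(N0)
    denom <- 1 + a * Ntot0 * T_window
    N <- N0 / denom
    Fm <- a * T_window / denom * outer(N0, N0)
    diag(Fm) <- diag(Fm) / 2
    return(list(N = N, F = Fm))
  }
  out <- fuse_window_cpp(N0, alpha, T_window, rtol, atol)
  list(N = out$N, F = out$F)
}

#' Integrate the fusion window
#'
#' Mass-action pairwise fusion kinetics over a window of duration `T`:
#' `dN_i/dt = -sum_j ((alpha_i + alpha_j)/2) N_i N_j`, with fused-pair counts
#' `F_ij` accumulating at the corresponding pairwise rates (same-type pairs
#' at `alpha_i N_i^2 / 2`, so that per-genotype cell number
#' `N_i(T) + 2 F_ii + sum_{j != i} F_ij = N_i(0)` is conserved).
#'
#' @param counts Initial unfused counts `N_i(0)` (nonnegative vector).
#' @param alpha Per-genotype fusion rates (nonnegative vector).
#' @param T Window duration (`>= 0`).
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `fusion_outcome`: list with unfused counts `N`
#'   and the symmetric fused-pair count matrix `F`.
#' @examples
#' fuse_window(c(200), alpha = 0.01, T = 1) # closed form: N(T) = 200/3
#' @export
fuse_window <- function(counts, alpha, T, rtol = 1e-10, atol = 1e-12) {
  if (any(counts < 0)) {
    abort("`counts` must be nonnegative.", class = "fusevol_domain_error")
  }
  if (any(alpha < 0)) {
    abort("`alpha` must be nonnegative.", class = "fusevol_domain_error")
  }
  if (T < 0) abort("`T` must be nonnegative.", class = "fusevol_domain_error")
  out <- fusion_counts(counts, rep_len(alpha, length(counts)), T, rtol, atol)
  structure(out, class = "fusion_outcome")
}

#' @export
print.fusion_outcome <- function(x, ...) {
  cat(sprintf("<fusion_outcome> %d genotype(s); unfused: %s; fused pairs: %g\n",
              length(x$N), paste(signif(x$N, 6), collapse = ", "),
              sum(x$F[upper.tri(x$F, diag = TRUE)])))
  invisible(x)
}

#' @rdname fuse_window
#' @param x A `fusion_outcome`.
#' @param ... Unused.
#' @export
tidy.fusion_outcome <- function(x, ...) {
  S <- length(x$N)
  pairs <- which(upper.tri(x$F, diag = TRUE), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(i = seq_len(S), j = NA_integer_, type = "unfused",
                   count = x$N),
    tibble::tibble(i = pairs[, 1], j = pairs[, 2], type = "fused",
                   count = x$F[pairs])
  )
}

## Internal single-cycle update on bare vectors.
## Returns list(f, survival_fraction) or signals extinction.
cycle_step <- function(m, alpha, f, E, T_window, C, surv_fn) {
  N0 <- f * E / m
  fo <- fusion_counts(N0, alpha, T_window)
  S_single <- surv_fn(m)
  if (all(alpha <= 0) || T_window == 0) {
    w <- N0 * S_single
    survivors <- sum(w)
    n_start <- sum(N0)
  } else {
    S_pair <- surv_fn(outer(m, m, "+"))
    w <- cycle_weights_cpp(fo$N, fo$F, S_single, S_pair, C)
    ut <- upper.tri(fo$F, diag = TRUE)
    survivors <- sum(fo$N * S_single) + (1 - C) * sum(fo$F[ut] * S_pair[ut])
    n_start <- sum(N0)
  }
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    abort("population extinction: no surviving cells after this cycle.",
          class = "fusevol_extinction")
  }
  list(f = w / tot, survival_fraction = survivors / n_start)
}

#' One deterministic growth cycle
#'
#' Applies fission, the fusion window, mass-dependent survival and
#' renormalisation to a multi-genotype population. The updated frequency of
#' genotype `i` is proportional to
#' `N_i(T) S(m_i) + (1 - C) [2 F_ii S(2 m_i) + sum_{j != i} F_ij S(m_i + m_j)]`
#' (same-type fused cells carry two nuclei of their genotype). With every
#' `alpha = 0` this reduces exactly to the fission-survival update
#' `f_i' \propto f_i S(m_i) / m_i`.
#'
#' @param pop A [population_state()].
#' @param params A [model_params()].
#' @param model A [survival_model()].
#' @param env A [fusion_env()].
#' @param env_index Which environment's traits are active for plastic
#'   genotypes (1 or 2).
#' @return The updated `population_state`; attribute `survival_fraction`
#'   holds the fraction of cells (unfused plus surviving fused, after cost)
#'   surviving the cycle. Signals a condition of class `fusevol_extinction`
#'   if no cells survive.
#' @export
cycle_update <- function(pop, params, model, env, env_index = 1L) {
  validate_population(pop)
  tr <- active_traits(pop, env_index)
  surv_fn <- function(mass) survival_prob(model, mass, env)
  res <- cycle_step(tr$m, tr$alpha, pop$f, params$E, params$T, params$C,
                    surv_fn)
  out <- pop
  out$f <- res$f
  attr(out, "survival_fraction") <- res$survival_fraction
  out
}

#' Finite-difference invasion-fitness gradient
#'
#' Numerical oracle for the adaptive-dynamics selection gradients: the
#' derivative, with respect to a rare mutant's trait, of the log per-cycle
#' growth ratio of the mutant relative to a monomorphic resident. Signs and
#' zero-crossings agree with the closed-form gradients
#' ([gradient_m()], [gradient_alpha()]).
#'
#' @param m,alpha Resident trait values (monomorphic resident).
#' @param trait Which trait to perturb: `"m"` or `"alpha"`.
#' @param params A [model_params()].
#' @param model A [survival_model()].
#' @param env A [fusion_env()].
#' @param h Relative finite-difference step (absolute when the trait is 0).
#' @param epsilon Mutant rarity.
#' @return Signed derivative (a bare number).
#' @export
invasion_gradient_fd <- function(m, alpha, trait = c("m", "alpha"),
                                 params, model, env,
                                 h = 1e-5, epsilon = 1e-6) {
  trait <- match.arg(trait)
  base <- if (trait == "m") m else alpha
  hh <- if (base > 0) h * base else h
  if (hh <= 0 || epsilon <= 0 || epsilon >= 0.5) {
    abort("degenerate finite-difference configuration.",
          class = "fusevol_domain_error")
  }
  surv_fn <- function(mass) survival_prob(model, mass, env)
  growth <- function(mut_m, mut_alpha) {
    res <- cycle_step(c(m, mut_m), c(alpha, mut_alpha),
                      c(1 - epsilon, epsilon),
                      params$E, params$T, params$C, surv_fn)
    log((res$f[2] / epsilon) / (res$f[1] / (1 - epsilon)))
  }
  lo_ok <- (base - hh) >= 0 || trait == "m"
  if (trait == "m" && (base - hh) <= 0) {
    abort("mass below finite-difference step.", class = "fusevol_domain_error")
  }
  if (lo_ok) {
    up <- if (trait == "m") growth(base + hh, alpha) else growth(m, base + hh)
    dn <- if (trait == "m") growth(base - hh, alpha) else growth(m, base - hh)
    (up - dn) / (2 * hh)
  } else {
    # one-sided at the alpha = 0 boundary
    up <- growth(m, base + hh)
    at <- growth(m, base)
    (up - at) / hh
  }
}
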