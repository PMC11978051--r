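#' Vance survival probability
#'
#' Mass-dependent survival of a daughter cell, `S(m; beta) = exp(-beta / m)`.
#' Survival increases with cell mass `m` and decreases with the environmental
#' harshness `beta`; the function is convex for `m < beta / 2`, implicitly
#' encoding a minimum viable cell size.
#'
#' @param m Daughter-cell mass (vectorised, `>= 0`; `m = 0` returns 0 by
#'   continuity).
#' @param beta Environmental harshness (`> 0`).
#' @return Survival probabilities in `[0, 1]`.
#' @examples
#' vance_survival(1, beta = 1) # exp(-1)
#' @export
vance_survival <- function(m, beta) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    abort("`beta` must be positive and finite.", class = "fusevol_domain_error")
  }
  if (any(m < 0, na.rm = TRUE)) {
    abort("`m` must be nonnegative.", class = "fusevol_domain_error")
  }
  out <- exp(-beta / m)
  out[m == 0] <- 0
  out
}

#' Threshold-linear survival probability
#'
#' Alternative survival family `S(m; gamma) = 1 - exp(-gamma * m)` for
#' `m >= m_min` and 0 below the minimum viable cell size `m_min`. Unlike the
#' Vance family, survival here is *increasing* in `gamma` (larger `gamma` is
#' more benign).
#'
#' @param m Daughter-cell mass (vectorised, `>= 0`).
#' @param gamma Survival rate parameter (`> 0`).
#' @param m_min Minimum viable cell mass (`>= 0`).
#' @return Survival probabilities in `[0, 1]`.
#' @export
threshold_survival <- function(m, gamma, m_min = 0) {
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    abort("`gamma` must be positive and finite.", class = "fusevol_domain_error")
  }
  if (m_min < 0) {
    abort("`m_min` must be nonnegative.", class = "fusevol_domain_error")
  }
  if (any(m < 0, na.rm = TRUE)) {
    abort("`m` must be nonnegative.", class = "fusevol_domain_error")
  }
  ifelse(m < m_min, 0, 1 - exp(-gamma * m))
}

#' Environment description
#'
#' A single environment is described by a harshness parameter and a label.
#' For the Vance family the harshness is `beta` (larger = harsher); for the
#' threshold-linear family it is `gamma` (larger = more benign).
#'
#' @param harshness Positive harshness parameter (`beta` or `gamma`).
#' @param label Short identifier, e.g. `"env1"`.
#' @return An object of class `fusion_env`.
#' @export
fusion_env <- function(harshness, label = "env1") {
  if (!is.numeric(harshness) || length(harshness) != 1 ||
      !is.finite(harshness) || harshness <= 0) {
    abort("`harshness` must be a single positive number.",
          class = "fusevol_domain_error")
  }
  structure(list(harshness = harshness, label = as.character(label)),
            class = "fusion_env")
}

#' @export
print.fusion_env <- function(x, ...) {
  cat(sprintf("<fusion_env> %s: harshness = %g\n", x$label, x$harshness))
  invisible(x)
}

#' Survival model
#'
#' Declares which mass-dependent survival family applies, together with the
#' minimum viable cell size for the threshold-linear family.
#'
#' @param family `"vance"` or `"threshold_linear"`.
#' @param m_min Minimum viable cell mass (threshold-linear family only).
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(family = c("vance", "threshold_linear"), m_min = 0) {
  family <- match.arg(family)
  if (!is.numeric(m_min) || length(m_min) != 1 || m_min < 0) {
    abort("`m_min` must be a single nonnegative number.",
          class = "fusevol_domain_error")
  }
  structure(list(family = family, m_min = m_min), class = "survival_model")
}

#' Survival probability under a model and environment
#'
#' @param model A [survival_model()].
#' @param m Daughter-cell mass (vectorised).
#' @param env A [fusion_env()] (or a bare harshness value).
#' @return Survival probabilities in `[0, 1]`.
#' @export
survival_prob <- function(model, m, env) {
  h <- if (inherits(env, "fusion_env")) env$harshness else env
  switch(model$family,
    vance = vance_survival(m, h),
    threshold_linear = threshold_survival(m, h, model$m_min)
  )
}

#' Survival probability of a fused cell
#'
#' A fused pair survives as a single cell of the combined mass `m_i + m_j`,
#' so its survival is at least that of either partner alone.
#'
#' @inheritParams survival_prob
#' @param m_i,m_j Masses of the two fusing daughter cells (`> 0`).
#' @export
fused_survival <- function(model, m_i, m_j, env) {
  if (any(m_i <= 0) || any(m_j <= 0)) {
    abort("fusing partner masses must be positive.",
          class = "fusevol_domain_error")
  }
  survival_prob(model, m_i + m_j, env)
}

#' Compare two environments' harshness
#'
#' The ordering depends on the survival family: under the Vance family larger
#' `beta` is harsher, under the threshold-linear family larger `gamma` is more
#' benign.
#'
#' @param env_a,env_b [fusion_env()] objects.
#' @param family Survival family the harshness parameters belong to.
#' @return `TRUE` if `env_a` is harsher than `env_b`.
#' @export
harsher_than <- function(env_a, env_b,
                         family = c("vance", "threshold_linear")) {
  family <- match.arg(family)
  if (family == "vance") env_a$harshness > env_b$harshness
  else env_a$harshness < env_b$harshness
}

#' Environment schedule
#'
#' Describes how the active environment changes over growth cycles: `fixed`
#' (never), `scheduled` (toggles at listed cycle indices), or `telegraph`
#' (stochastic two-state switching with geometric residence times). In
#' telegraph mode the long-run occupancy of environment 1 is
#' `P1 = tau1 / (tau1 + tau2)` with mean residences `tau_i = 1 / lambda_ij`.
#'
#' @param env1,env2 [fusion_env()] records (only `env1` is used in `fixed`
#'   mode).
#' @param mode One of `"fixed"`, `"scheduled"`, `"telegraph"`.
#' @param switch_cycles Strictly increasing growth-cycle indices at which the
#'   environment toggles (scheduled mode).
#' @param lambda_12,lambda_21 Per-cycle switching rates (telegraph mode), in
#'   (growth cycles)^-1.
#' @return An object of class `env_schedule` with derived fields `tau1`,
#'   `tau2` and `p1` in telegraph mode.
#' @export
env_schedule <- function(env1, env2 = NULL,
                         mode = c("fixed", "scheduled", "telegraph"),
                         switch_cycles = NULL,
                         lambda_12 = NULL, lambda_21 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(env1, "fusion_env"))
  if (mode != "fixed") {
    if (!inherits(env2, "fusion_env")) {
      abort("`env2` is required for scheduled and telegraph modes.",
            class = "fusevol_config_error")
    }
  }
  out <- list(mode = mode, env1 = env1, env2 = env2)
  if (mode == "scheduled") {
    if (is.null(switch_cycles) || length(switch_cycles) == 0 ||
        any(switch_cycles < 1) || is.unsorted(switch_cycles, strictly = TRUE)) {
      abort("`switch_cycles` must be strictly increasing cycle indices >= 1.",
            class = "fusevol_config_error")
    }
    out$switch_cycles <- as.integer(switch_cycles)
  }
  if (mode == "telegraph") {
    if (is.null(lambda_12) || is.null(lambda_21) ||
        lambda_12 <= 0 || lambda_21 <= 0 || lambda_12 > 1 || lambda_21 > 1) {
      abort("telegraph rates must lie in (0, 1] per growth cycle.",
            class = "fusevol_config_error")
    }
    out$lambda_12 <- lambda_12
    out$lambda_21 <- lambda_21
    out$tau1 <- 1 / lambda_12
    out$tau2 <- 1 / lambda_21
    out$p1 <- out$tau1 / (out$tau1 + out$tau2)
  }
  structure(out, class = "env_schedule")
}

#' Telegraph schedule from a target occupancy
#'
#' Convenience constructor: choose switching rates so that the long-run
#' occupancy of environment 1 equals `p1`, with a given mean residence time
#' in environment 1.
#'
#' @param env1,env2 [fusion_env()] records.
#' @param p1 Target long-run occupancy of environment 1, in (0, 1).
#' @param tau1 Mean residence (growth cycles) in environment 1.
#' @export
telegraph_schedule <- function(env1, env2, p1, tau1 = 100) {
  if (p1 <= 0 || p1 >= 1) {
    abort("`p1` must lie strictly between 0 and 1.",
          class = "fusevol_config_error")
  }
  tau2 <- tau1 * (1 - p1) / p1
  env_schedule(env1, env2, mode = "telegraph",
               lambda_12 = 1 / tau1, lambda_21 = 1 / tau2)
}
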