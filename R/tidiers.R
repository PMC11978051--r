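#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stochastic simulation
#'
#' Returns the trajectory in long format: one row per recorded cycle and
#' trait statistic.
#'
#' @param x A `fusion_sim`.
#' @param ... Unused.
#' @return A tibble `cycle`, `env`, `statistic`, `trait`, `value`.
#' @export
tidy.fusion_sim <- function(x, ...) {
  x$trajectory |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(mean|var)_"),
      names_to = c("statistic", "trait"), names_sep = "_",
      values_to = "value"
    ) |>
    dplyr::select("cycle", "env", "statistic", "trait", "value")
}

#' One-row summary of a stochastic simulation
#'
#' @param x A `fusion_sim`.
#' @param burn_in_fraction Passed to [estimate_ess()].
#' @param ... Unused.
#' @return A one-row tibble: status, cycles run, genotype count, and the
#'   post-burn-in trait means (columns `ess_<trait>`).
#' @export
glance.fusion_sim <- function(x, burn_in_fraction = 0.5, ...) {
  ess <- suppressWarnings(estimate_ess(x, burn_in_fraction))
  wide <- stats::setNames(as.list(ess$mean), paste0("ess_", ess$trait))
  tibble::tibble(
    status = x$status,
    n_cycles = max(x$trajectory$cycle),
    n_genotypes = x$trajectory$n_genotypes[nrow(x$trajectory)],
    stationary = all(ess$stationary),
    !!!wide
  )
}

#' Tidy an adaptive-dynamics flow
#'
#' @param x An `ad_flow` tibble.
#' @param ... Unused.
#' @return The trajectory with an `outcome` column attached.
#' @export
tidy.ad_flow <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$outcome <- attr(x, "outcome")
  out
}
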