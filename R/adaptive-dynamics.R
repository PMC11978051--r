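#' Adaptive-dynamics parameters
#'
#' Parameters of the (m, alpha) trait flow in a fixed environment. `E` and
#' `T` enter every closed form only through the product `ET`.
#'
#' @param beta Environmental harshness (`> 0`).
#' @param C Fusion cost in `[0, 1]`.
#' @param E,T Total mass and fusion-window duration.
#' @return An object of class `ad_params`.
#' @export
ad_params <- function(beta, C, E = 100, T = 1) {
  if (beta <= 0) abort("`beta` must be positive.", class = "fusevol_domain_error")
  if (C < 0 || C > 1) abort("`C` must lie in [0, 1].",
                            class = "fusevol_domain_error")
  if (E <= 0 || T < 0) abort("`E` > 0 and `T` >= 0 required.",
                             class = "fusevol_domain_error")
  structure(list(beta = beta, C = C, E = E, T = T, ET = E * T),
            class = "ad_params")
}

## Stable evaluation of X = (1 - C) * exp(beta / (2 m)) and A = ET * alpha * X.
## For very small m the exponential overflows; the gradients then take their
## large-A limiting forms.

#' Selection gradient on daughter-cell mass
#'
#' Closed-form selection gradient
#' `Hm = -(4 m (m - beta) + A (4 m - beta)) / (4 m^2 (m + A))` with
#' `A = E alpha T (1 - C) exp(beta / (2 m))`. At `alpha = 0` this reduces
#' exactly to `(beta - m) / m^2`; as `alpha -> Inf` it tends to
#' `-(4 m - beta) / (4 m^2)`, whose root is the `m = beta / 4` manifold.
#'
#' @param m,alpha Trait values (vectorised; `m > 0`, `alpha >= 0`).
#' @param params An [ad_params()].
#' @return Gradient values.
#' @export
gradient_m <- function(m, alpha, params) {
  beta <- params$beta
  A <- params$ET * alpha * (1 - params$C) * exp(beta / (2 * m))
  ifelse(is.finite(A) & A < 1e15,
         -(4 * m * (m - beta) + A * (4 * m - beta)) /
           (4 * m^2 * (m + A)),
         -(4 * m - beta) / (4 * m^2))
}

#' Selection gradient on the fusion rate
#'
#' Closed-form selection gradient
#' `Ha = -m (1 - X) log(1 + ET alpha / m) / (2 alpha (ET alpha X + m))` with
#' `X = (1 - C) exp(beta / (2 m))`. At the `alpha = 0` boundary the analytic
#' limit `-(1 - X) ET / (2 m)` is used; its sign flips exactly at
#' `m = -beta / (2 log(1 - C))`.
#'
#' @inheritParams gradient_m
#' @export
gradient_alpha <- function(m, alpha, params) {
  beta <- params$beta
  ET <- params$ET
  X <- (1 - params$C) * exp(beta / (2 * m))
  A <- ET * alpha * X
  boundary <- alpha == 0
  big <- !is.finite(A) | (A >= 1e15 & !boundary)
  out <- numeric(length(m + alpha + 0))
  m <- rep_len(m, length(out)); alpha <- rep_len(alpha, length(out))
  X <- rep_len(X, length(out)); A <- rep_len(A, length(out))
  boundary <- rep_len(boundary, length(out)); big <- rep_len(big, length(out))
  # generic interior form
  i <- !boundary & !big
  out[i] <- -m[i] * (1 - X[i]) * log1p(ET * alpha[i] / m[i]) /
    (2 * alpha[i] * (A[i] + m[i]))
  # X (hence A) overflow: divide numerator and denominator by X
  i <- !boundary & big
  out[i] <- m[i] * log1p(ET * alpha[i] / m[i]) / (2 * ET * alpha[i]^2)
  # alpha = 0 boundary, analytic limit
  i <- boundary & is.finite(X)
  out[i] <- -(1 - X[i]) * ET / (2 * m[i])
  i <- boundary & !is.finite(X)
  out[i] <- Inf # vanishing m: fusion always favoured at the boundary
  out
}

#' Gradient field over a trait grid
#'
#' @param params An [ad_params()].
#' @param m,alpha Grid coordinates (crossed).
#' @return A tibble with columns `m`, `alpha`, `Hm`, `Halpha`.
#' @export
gradient_field <- function(params, m, alpha) {
  grid <- tidyr::expand_grid(m = m, alpha = alpha)
  grid$Hm <- gradient_m(grid$m, grid$alpha, params)
  grid$Halpha <- gradient_alpha(grid$m, grid$alpha, params)
  grid
}

## Clamped vector field of the evolutionary flow: alpha is held at 0 when it
## sits on the boundary and selection points outward.
ad_field <- function(m, alpha, params) {
  a <- max(alpha, 0)
  Hm <- gradient_m(m, a, params)
  Ha <- gradient_alpha(m, a, params)
  if (alpha <= 0) {
    Ha0 <- gradient_alpha(m, 0, params)
    if (Ha0 < 0) Ha <- 0 else Ha <- Ha0
  }
  c(Hm, Ha)
}

## Rescale an evolutionary-time derivative to a bounded speed: the
## trajectory geometry is unchanged (tau is an abstract time), but the
## astronomically steep gradients at tiny masses no longer stall the
## integrator.
cap_speed <- function(v, cap = 1e3) {
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm)) {
    # direction dominated by the overflowing component
    v <- ifelse(is.finite(v), 0, sign(v))
    nrm <- sqrt(sum(v^2))
  }
  if (nrm > cap) v <- v * (cap / nrm)
  v
}

#' Integrate the adaptive-dynamics flow
#'
#' Integrates `dm/dtau = Hm`, `dalpha/dtau = Halpha` with the biological
#' clamp at the `alpha = 0` boundary (the rate stays 0 whenever selection
#' there points outward). Integration stops on fixed-point convergence
#' (gradient norm below `tol`), on `alpha` exceeding `alpha_max` (classified
#' as divergence to the obligate-fusion manifold `m = beta / 4`), or on
#' exhausting the `tau` budget.
#'
#' @param m0,alpha0 Admissible starting point (`m0 > 0`, `alpha0 >= 0`).
#' @param params An [ad_params()].
#' @param tau_max Evolutionary-time budget.
#' @param alpha_max Divergence threshold (default `1000 / ET`).
#' @param tol Fixed-point gradient-norm tolerance.
#' @param n_out Number of saved trajectory points.
#' @return A tibble of class `ad_flow` with columns `tau`, `m`, `alpha` and
#'   attribute `outcome` in `"fixed_point"`, `"obligate_fusion"`,
#'   `"inconclusive"`.
#' @export
ad_flow <- function(m0, alpha0, params, tau_max = 1e5,
                    alpha_max = 1000 / params$ET, tol = 1e-8,
                    n_out = 400) {
  if (m0 <= 0 || alpha0 < 0) {
    abort("start must satisfy m0 > 0, alpha0 >= 0.",
          class = "fusevol_domain_error")
  }
  # The clamped field is discontinuous across alpha = 0, so the flow is
  # integrated in alternating phases: a 2-D interior phase that stops when
  # the trajectory reaches the boundary with inward-pointing selection, and
  # a 1-D sliding phase along alpha = 0 that stops when selection for fusion
  # turns positive again (lift-off). This avoids boundary chattering.
  segs <- list()
  t_now <- 0
  m <- m0
  a <- alpha0
  outcome <- "inconclusive"
  guard <- 0L
  while (t_now < tau_max && guard < 50L) {
    guard <- guard + 1L
    on_boundary <- a <= 0 && gradient_alpha(m, 0, params) < 0
    times <- seq(t_now, tau_max, length.out = max(8L, ceiling(
      n_out * (tau_max - t_now) / tau_max)))
    if (on_boundary) {
      derivs <- function(t, y, p) list(cap_speed(gradient_m(y[1], 0, params)))
      rootfun <- function(t, y, p) {
        c(abs(gradient_m(y[1], 0, params)) - tol,
          gradient_alpha(y[1], 0, params))
      }
      sol <- deSolve::lsodar(c(m = m), times, derivs, parms = NULL,
                             rootfunc = rootfun, rtol = 1e-10, atol = 1e-12,
                             maxsteps = 1e5)
      seg <- data.frame(tau = sol[, 1], m = sol[, 2], alpha = 0)
      segs[[length(segs) + 1L]] <- seg
      t_now <- seg$tau[nrow(seg)]
      m <- seg$m[nrow(seg)]
      a <- 0
      if (abs(gradient_m(m, 0, params)) <= tol * 10) {
        outcome <- "fixed_point"
        break
      }
      if (t_now >= tau_max * (1 - 1e-12)) break
      # otherwise lift-off: selection for fusion turned nonnegative
    } else {
      derivs <- function(t, y, p) {
        aa <- max(y[2], 0)
        list(cap_speed(c(gradient_m(y[1], aa, params),
                         gradient_alpha(y[1], aa, params))))
      }
      rootfun <- function(t, y, p) {
        aa <- max(y[2], 0)
        g <- c(gradient_m(y[1], aa, params),
               gradient_alpha(y[1], aa, params))
        c(sqrt(sum(g^2)) - tol, alpha_max - y[2], y[2] + 1e-12)
      }
      sol <- deSolve::lsodar(c(m = m, alpha = a), times, derivs,
                             parms = NULL, rootfunc = rootfun,
                             rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
      seg <- data.frame(tau = sol[, 1], m = sol[, 2],
                        alpha = pmax(sol[, 3], 0))
      segs[[length(segs) + 1L]] <- seg
      t_now <- seg$tau[nrow(seg)]
      m <- seg$m[nrow(seg)]
      a <- seg$alpha[nrow(seg)]
      if (a >= alpha_max * (1 - 1e-6)) {
        outcome <- "obligate_fusion"
        break
      }
      g <- ad_field(m, a, params)
      if (sqrt(sum(g^2)) <= tol * 10) {
        outcome <- "fixed_point"
        break
      }
      if (t_now >= tau_max * (1 - 1e-12)) break
      # otherwise the trajectory touched alpha = 0 with inward selection:
      # continue in the sliding phase
      a <- 0
    }
  }
  sol <- dplyr::distinct(dplyr::bind_rows(segs), .data$tau,
                         .keep_all = TRUE)
  out <- tibble::as_tibble(sol)
  attr(out, "outcome") <- outcome
  attr(out, "params") <- params
  class(out) <- c("ad_flow", class(out))
  out
}

## Finite-difference Jacobian of the clamped flow field.
ad_jacobian <- function(m, alpha, params, h = 1e-6) {
  hh_m <- h * max(m, 1)
  hh_a <- h * max(alpha, 1)
  fm_p <- ad_field(m + hh_m, alpha, params)
  fm_m <- ad_field(m - hh_m, alpha, params)
  fa_p <- ad_field(m, alpha + hh_a, params)
  fa_m <- if (alpha - hh_a >= 0) ad_field(m, alpha - hh_a, params) else NULL
  J <- matrix(0, 2, 2)
  J[, 1] <- (fm_p - fm_m) / (2 * hh_m)
  if (is.null(fa_m)) {
    f0 <- ad_field(m, alpha, params)
    J[, 2] <- (fa_p - f0) / hh_a
  } else {
    J[, 2] <- (fa_p - fa_m) / (2 * hh_a)
  }
  J
}

classify_stability <- function(eig) {
  re <- Re(eig)
  if (all(re < 0)) "stable"
  else if (all(re > 0)) "unstable"
  else "saddle"
}

#' Fixed point on the zero-fusion boundary
#'
#' The boundary fixed point sits at `(m*, alpha*) = (beta, 0)`. It is a
#' saddle (unstable to fusion) for `C < 1 - exp(-1/2)` and stable above that
#' cost, where the interior saddle crosses into the physical quadrant.
#'
#' @param params An [ad_params()].
#' @return A one-row tibble: `m`, `alpha`, `kind`, `stability`,
#'   `eigen_1`, `eigen_2`.
#' @export
boundary_fixed_point <- function(params) {
  beta <- params$beta
  J <- ad_jacobian(beta, 0, params)
  eig <- eigen(J, only.values = TRUE)$values
  stability <- if (params$C < C_LOW) "saddle" else "stable"
  tibble::tibble(m = beta, alpha = 0, kind = "boundary",
                 stability = stability,
                 eigen_1 = Re(eig[1]), eigen_2 = Re(eig[2]))
}

#' Interior fixed point (saddle)
#'
#' The interior root of both selection gradients sits at
#' `m* = -beta / (2 log(1 - C))` (where the fused-survival advantage exactly
#' offsets the cost) with `alpha* = 4 m* (beta - m*) / (ET (4 m* - beta))`
#' obtained by solving `Hm = 0` there. `alpha*` is positive exactly on the
#' cost band `1 - exp(-1/2) < C < 1 - exp(-2)`; outside it the point is
#' flagged nonphysical. At the band edges it coincides with the boundary
#' fixed point (`alpha* = 0` at `C = 1 - exp(-1/2)`) and with the
#' obligate-fusion manifold (`m* = beta / 4` at `C = 1 - exp(-2)`).
#'
#' @param params An [ad_params()] with `0 < C < 1`.
#' @return A one-row tibble as in [boundary_fixed_point()].
#' @export
interior_fixed_point <- function(params) {
  C <- params$C
  beta <- params$beta
  if (C <= 0 || C >= 1) {
    return(tibble::tibble(m = NA_real_, alpha = NA_real_, kind = "interior",
                          stability = "nonphysical",
                          eigen_1 = NA_real_, eigen_2 = NA_real_))
  }
  L <- log(1 - C)
  m_star <- -beta / (2 * L)
  alpha_star <- 4 * m_star * (beta - m_star) / (params$ET * (4 * m_star - beta))
  if (!is.finite(alpha_star) || alpha_star < 0) {
    return(tibble::tibble(m = m_star, alpha = alpha_star, kind = "interior",
                          stability = "nonphysical",
                          eigen_1 = NA_real_, eigen_2 = NA_real_))
  }
  if (alpha_star == 0) {
    return(boundary_fixed_point(params))
  }
  J <- ad_jacobian(m_star, alpha_star, params)
  eig <- eigen(J, only.values = TRUE)$values
  tibble::tibble(m = m_star, alpha = alpha_star, kind = "interior",
                 stability = classify_stability(eig),
                 eigen_1 = Re(eig[1]), eigen_2 = Re(eig[2]))
}

#' All fixed points and asymptotic attractors
#'
#' @param params An [ad_params()].
#' @return A tibble stacking the boundary fixed point, the interior fixed
#'   point, and the obligate-fusion manifold `(beta / 4, Inf)`.
#' @export
fixed_points <- function(params) {
  manifold <- tibble::tibble(
    m = params$beta / 4, alpha = Inf, kind = "asymptotic_manifold",
    stability = if (params$C < C_HIGH) "stable" else "nonphysical",
    eigen_1 = NA_real_, eigen_2 = NA_real_
  )
  dplyr::bind_rows(boundary_fixed_point(params),
                   interior_fixed_point(params),
                   manifold)
}

#' Critical cost at which the zero-fusion basin covers the axis
#'
#' `c_base(ET)` is the fusion cost at which the separatrix of the interior
#' saddle passes through the origin, so that every zero-fusion initial
#' condition is attracted to `(beta, 0)`. It is the interior root in
#' `L = log(1 - C)` of
#' `8 (1 + 2L)^2 (5 + L (5 + 2L)) - (ET)^2 (2 + L)^4 log(6 / (2 + L) - 3) = 0`
#' on `L` in `(-2, -1/2)`. The root increases with `ET` from
#' `1 - exp(-1/2)` (sparse/short fusion windows) towards `1 - exp(-2)`
#' (dense/long windows).
#'
#' @param ET Product of total mass and fusion-window duration (`> 0`,
#'   vectorised).
#' @param tol Root-finding tolerance on `L`.
#' @return Critical cost(s) in `[1 - exp(-1/2), 1 - exp(-2))`.
#' @export
c_base <- function(ET, tol = 1e-14) {
  vapply(ET, function(et) {
    if (et <= 0) abort("`ET` must be positive.", class = "fusevol_domain_error")
    g <- function(L) {
      8 * (1 + 2 * L)^2 * (5 + L * (5 + 2 * L)) -
        et^2 * (2 + L)^4 * log(6 / (2 + L) - 3)
    }
    # L = -1/2 is an exact root of the printed equation (both factors vanish);
    # the meaningful root lies strictly inside (-2, -1/2).
    lo <- -2 + 1e-12
    hi <- -0.5 - min(1e-9, 1e-3 * et^2)
    glo <- g(lo)
    ghi <- g(hi)
    if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
      abort(sprintf(
        "no sign change bracketing C_Base: g(%.6g) = %.6g, g(%.6g) = %.6g",
        lo, glo, hi, ghi), class = "fusevol_numeric_error")
    }
    L <- uniroot(g, c(lo, hi), tol = tol)$root
    1 - exp(L)
  }, numeric(1))
}

#' Classify the evolutionary regime in a fixed environment
#'
#' Maps the fusion cost onto the qualitative outcome structure for
#' zero-fusion initial conditions: below `1 - exp(-1/2)` obligate fusion is
#' the only outcome; between that and `c_base(ET)` the outcome depends on
#' the initial mass (bistable); between `c_base(ET)` and `1 - exp(-2)` the
#' zero-fusion basin covers the whole `alpha = 0` axis (transient rises in
#' fusion possible from small masses); above `1 - exp(-2)` the zero-fusion
#' state is the only outcome.
#'
#' @param params An [ad_params()].
#' @return A one-row tibble of class `regime_classification`: `label` plus
#'   the three thresholds used.
#' @export
classify_regime <- function(params) {
  cb <- c_base(params$ET)
  C <- params$C
  label <- if (C < C_LOW) {
    "obligate_fusion_only"
  } else if (C < cb) {
    "bistable"
  } else if (C < C_HIGH) {
    "boundary_basin_covers_axis"
  } else {
    "zero_fusion_only"
  }
  out <- tibble::tibble(label = label, c_low = C_LOW, c_base = cb,
                        c_high = C_HIGH, C = C, ET = params$ET)
  class(out) <- c("regime_classification", class(out))
  out
}

#' Separatrix of the zero-fusion basin
#'
#' Computes the boundary of the basin of attraction of the stable
#' zero-fusion fixed point `(beta, 0)`.
#'
#' `method = "eigenvector"` integrates the flow backwards from the interior
#' saddle along its stable eigendirections; `method = "grid"` classifies
#' forward-flow endpoints on an `(m, alpha)` lattice and returns, per mass
#' column, the smallest fusion rate escaping to obligate fusion. The two
#' agree to lattice resolution.
#'
#' @param params An [ad_params()]; a physical interior saddle must exist
#'   (`classify_regime()` label `bistable` or `boundary_basin_covers_axis`),
#'   except that the grid method also handles the `zero_fusion_only` regime
#'   (returning an empty boundary with attribute
#'   `outcome = "entire quadrant flows to (beta, 0)"`).
#' @param method `"eigenvector"` or `"grid"`.
#' @param n_grid Lattice points per axis (grid method).
#' @param m_max,alpha_max Lattice extent (defaults `2.5 beta` and `10 / ET`).
#' @return A tibble `m`, `alpha` tracing the separatrix (eigenvector method
#'   adds `branch` and arc-length `s`); grid method attaches the full
#'   classified lattice as attribute `grid`.
#' @export
separatrix <- function(params, method = c("eigenvector", "grid"),
                       n_grid = 101, m_max = 2.5 * params$beta,
                       alpha_max = 10 / params$ET) {
  method <- match.arg(method)
  ip <- interior_fixed_point(params)
  if (method == "eigenvector") {
    if (ip$stability == "nonphysical" || is.na(ip$m)) {
      abort(paste("no physical interior saddle; use classify_regime() to",
                  "check the cost regime."),
            class = "fusevol_domain_error")
    }
    J <- ad_jacobian(ip$m, ip$alpha, params)
    eig <- eigen(J)
    stable_idx <- which(Re(eig$values) < 0)
    if (length(stable_idx) != 1) {
      abort("interior fixed point is not a saddle.",
            class = "fusevol_numeric_error")
    }
    v <- Re(eig$vectors[, stable_idx])
    v <- v / sqrt(sum(v^2))
    branches <- purrr::map(c(1, -1), function(sgn) {
      y0 <- c(ip$m, ip$alpha) + sgn * 1e-6 * max(ip$m, ip$alpha) * v
      derivs <- function(t, y, p) {
        list(cap_speed(-ad_field(y[1], max(y[2], 0), params)))
      }
      rootfun <- function(t, y, p) {
        c(y[2], y[1] - 1e-4 * params$beta, m_max * 2 - y[1],
          5 * alpha_max - y[2])
      }
      # the backward flow leaves the saddle exponentially fast; log-spaced
      # output times resolve the curve near the saddle and far from it
      times <- c(0, 10^seq(-6, 3, length.out = 600))
      sol <- try(deSolve::lsodar(y0, times, derivs, parms = NULL,
                                 rootfunc = rootfun,
                                 rtol = 1e-10, atol = 1e-12), silent = TRUE)
      if (inherits(sol, "try-error")) return(NULL)
      sol <- as.data.frame(sol)
      names(sol) <- c("s", "m", "alpha")
      sol$branch <- if (sgn > 0) "lower" else "upper"
      sol
    })
    out <- tibble::as_tibble(dplyr::bind_rows(branches))
    out <- out[, c("branch", "s", "m", "alpha")]
    attr(out, "saddle") <- c(m = ip$m, alpha = ip$alpha)
    return(out)
  }
  # grid method
  m_seq <- seq(m_max / n_grid, m_max, length.out = n_grid)
  a_seq <- seq(0, alpha_max, length.out = n_grid)
  grid <- tidyr::expand_grid(m = m_seq, alpha = a_seq)
  # Escape detection: selection on alpha is negative for every m above the
  # saddle mass, so a lattice trajectory still heading for (beta, 0) can
  # never climb; crossing twice the lattice's alpha extent identifies
  # divergence to obligate fusion.
  alpha_esc <- max(2 * alpha_max, 20 / params$ET)
  grid$endpoint <- purrr::map_chr(seq_len(nrow(grid)), function(i) {
    fl <- ad_flow(grid$m[i], grid$alpha[i], params, tau_max = 1e5,
                  alpha_max = alpha_esc, n_out = 5)
    attr(fl, "outcome")
  })
  boundary <- grid |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(alpha = {
      esc <- .data$alpha[.data$endpoint == "obligate_fusion"]
      if (length(esc) == 0) NA_real_ else min(esc)
    }, .groups = "drop") |>
    dplyr::filter(!is.na(.data$alpha))
  if (nrow(boundary) == 0) {
    attr(boundary, "outcome") <- "entire quadrant flows to (beta, 0)"
  }
  attr(boundary, "grid") <- grid
  boundary
}

#' Maximum fusion cost under threshold-linear survival
#'
#' The supremum cost `C` for which fusing can still pay, i.e. for which
#' `(1 - C) S(2m) / S(m) > 1` for some admissible mass `m >= m_min` under
#' the threshold-linear survival family. Since
#' `S(2m) / S(m) = 1 + exp(-gamma m)` is decreasing in `m`, the supremum is
#' attained at `m = m_min`, giving `1 - 1 / (1 + exp(-gamma m_min))`; with
#' no minimum cell size this equals exactly 1/2 (the fused-cell survival can
#' at most double).
#'
#' @param gamma Survival rate parameter (`> 0`).
#' @param m_min Minimum viable cell mass (`>= 0`).
#' @return The cost ceiling.
#' @export
threshold_linear_max_cost <- function(gamma, m_min = 0) {
  if (gamma <= 0) abort("`gamma` must be positive.",
                        class = "fusevol_domain_error")
  if (m_min < 0) abort("`m_min` must be nonnegative.",
                       class = "fusevol_domain_error")
  1 - 1 / (1 + exp(-gamma * m_min))
}
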