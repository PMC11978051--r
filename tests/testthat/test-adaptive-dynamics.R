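test_that("the mass gradient reduces to its boundary and large-rate limits", {
  set.seed(31)
  for (rep in 1:20) {
    p <- ad_params(runif(1, 0.2, 3), runif(1, 0.05, 0.95), 100, 1)
    m <- runif(10, 0.1, 3)
    expect_equal(gradient_m(m, 0, p), (p$beta - m) / m^2, tolerance = 1e-12)
    expect_equal(gradient_m(m, 1e6, p), -(4 * m - p$beta) / (4 * m^2),
                 tolerance = 1e-4)
  }
  expect_equal(gradient_m(1, 0, ad_params(0.5, 0.3)), -0.5, tolerance = 1e-14)
})

test_that("the fusion gradient's boundary sign flips at the saddle mass", {
  p <- ad_params(2.2, 0.6, 100, 1)
  m_thr <- -2.2 / (2 * log(0.4))
  expect_equal(m_thr, 1.2005, tolerance = 1e-4)
  expect_gt(gradient_alpha(m_thr - 1e-6, 0, p), 0)
  expect_lt(gradient_alpha(m_thr + 1e-6, 0, p), 0)
  # costless fusion is always favoured on the boundary
  p0 <- ad_params(1, 0, 100, 1)
  expect_true(all(gradient_alpha(seq(0.1, 5, by = 0.1), 0, p0) > 0))
  # full cost: fusion always disfavoured off the boundary
  p1 <- ad_params(1, 1, 100, 1)
  expect_true(all(gradient_alpha(seq(0.1, 5, by = 0.1), 0.2, p1) < 0))
})

test_that("closed-form gradients agree in sign with the invasion oracle", {
  set.seed(33)
  model <- survival_model("vance")
  n_draws <- 6
  for (draw in seq_len(n_draws)) {
    beta <- runif(1, 0.4, 2.5)
    C <- runif(1, 0.05, 0.9)
    pars <- ad_params(beta, C, 100, 1)
    mp <- model_params(100, 1, C)
    env <- fusion_env(beta)
    for (m in seq(0.3, 3, length.out = 5)) {
      for (a in c(0, 0.03, 0.3)) {
        gm <- gradient_m(m, a, pars)
        ga <- gradient_alpha(m, a, pars)
        fm <- invasion_gradient_fd(m, a, "m", mp, model, env)
        fa <- invasion_gradient_fd(m, a, "alpha", mp, model, env)
        if (abs(gm) > 1e-4) expect_equal(sign(gm), sign(fm))
        if (abs(ga) > 1e-4) expect_equal(sign(ga), sign(fa))
      }
    }
  }
})

test_that("fixed points sit where the theory puts them", {
  p <- ad_params(0.5, 0.6, 100, 1)
  bp <- boundary_fixed_point(p)
  expect_equal(bp$m, 0.5)
  expect_equal(bp$alpha, 0)
  expect_equal(bp$stability, "stable")
  # the mass-direction eigenvalue is -1/beta^2
  expect_true(any(abs(c(bp$eigen_1, bp$eigen_2) - (-1 / 0.5^2)) < 1e-4))
  # below the first bifurcation the boundary point is a saddle
  expect_equal(boundary_fixed_point(ad_params(0.5, 0.2))$stability, "saddle")

  ip <- interior_fixed_point(ad_params(2.2, 0.6, 100, 1))
  expect_equal(ip$m, -2.2 / (2 * log(0.4)), tolerance = 1e-12)
  expect_equal(ip$m, 1.2005, tolerance = 1e-4)
  expect_equal(ip$stability, "saddle")
  # both gradients vanish there
  p22 <- ad_params(2.2, 0.6, 100, 1)
  expect_lt(abs(gradient_m(ip$m, ip$alpha, p22)), 1e-10)
  expect_lt(abs(gradient_alpha(ip$m, ip$alpha, p22)), 1e-10)
})

test_that("interior fixed point crosses the bifurcations exactly", {
  beta <- 1.3
  # alpha* crosses 0 at C = 1 - exp(-1/2): root-find the crossing in C
  a_star <- function(C) interior_fixed_point(ad_params(beta, C, 100, 1))$alpha
  r <- uniroot(function(C) a_star(C), c(0.2, 0.6), tol = 1e-12)$root
  expect_equal(r, 1 - exp(-1 / 2), tolerance = 1e-10)
  # m* crosses beta/4 at C = 1 - exp(-2)
  m_star <- function(C) interior_fixed_point(ad_params(beta, C, 100, 1))$m
  r2 <- uniroot(function(C) m_star(C) - beta / 4, c(0.5, 0.95),
                tol = 1e-12)$root
  expect_equal(r2, 1 - exp(-2), tolerance = 1e-10)
  # alpha* is positive strictly inside the band, nonphysical outside
  expect_gt(a_star(0.6), 0)
  expect_equal(interior_fixed_point(ad_params(beta, 0.2))$stability,
               "nonphysical")
  expect_equal(interior_fixed_point(ad_params(beta, 0.95))$stability,
               "nonphysical")
})

test_that("at the bifurcation costs the interior point meets the boundary", {
  p <- ad_params(1, 1 - exp(-1 / 2), 100, 1)
  ip <- interior_fixed_point(p)
  expect_equal(ip$m, 1, tolerance = 1e-12)
  expect_equal(ip$alpha, 0, tolerance = 1e-12)
})

test_that("the critical basin cost respects its bounds, limits and monotonicity", {
  ets <- c(1e-2, 1, 1e2, 1e4)
  cb <- c_base(ets)
  expect_true(all(cb >= 1 - exp(-1 / 2) & cb < 1 - exp(-2)))
  expect_true(all(diff(cb) > 0))
  # limiting behaviour at extreme window sizes
  expect_equal(c_base(1e-3), 1 - exp(-1 / 2), tolerance = 1e-3)
  expect_equal(c_base(1e7), 1 - exp(-2), tolerance = 1e-3)
})

test_that("regimes are classified by the cost ordering", {
  expect_equal(classify_regime(ad_params(1, 0.2, 100, 1))$label,
               "obligate_fusion_only")
  expect_equal(classify_regime(ad_params(1, 0.5, 100, 1))$label, "bistable")
  expect_equal(classify_regime(ad_params(1, 0.84, 100, 1))$label,
               "boundary_basin_covers_axis")
  expect_equal(classify_regime(ad_params(1, 0.95, 100, 1))$label,
               "zero_fusion_only")
  # membership at C = 0.6 decided against the computed critical cost
  cr <- classify_regime(ad_params(1, 0.6, 100, 1))
  expect_equal(cr$label,
               if (0.6 < cr$c_base) "bistable" else "boundary_basin_covers_axis")
})

test_that("the flow respects the boundary clamp and reaches the attractors", {
  # costless: fusion diverges and mass approaches a quarter of the harshness
  p0 <- ad_params(1, 0, 100, 1)
  fl <- ad_flow(1.5, 0, p0)
  expect_equal(attr(fl, "outcome"), "obligate_fusion")
  expect_equal(fl$m[nrow(fl)], 0.25, tolerance = 1e-2)
  expect_true(all(fl$alpha >= 0))
  # bistable: large initial mass converges to the zero-fusion point
  p5 <- ad_params(1, 0.5, 100, 1)
  fl2 <- ad_flow(1.75, 0, p5)
  expect_equal(attr(fl2, "outcome"), "fixed_point")
  expect_equal(fl2$m[nrow(fl2)], 1, tolerance = 1e-6)
  expect_equal(fl2$alpha[nrow(fl2)], 0)
  # small initial mass escapes to obligate fusion
  expect_equal(attr(ad_flow(0.1, 0, p5), "outcome"), "obligate_fusion")
  # starting exactly at the stable boundary point is stationary
  fl3 <- ad_flow(1, 0, p5)
  expect_equal(attr(fl3, "outcome"), "fixed_point")
  expect_true(all(abs(fl3$m - 1) < 1e-8))
  # clamp correctness on random starts: alpha never goes negative
  set.seed(5)
  for (rep in 1:10) {
    p <- ad_params(runif(1, 0.5, 2), runif(1, 0.1, 0.9), 100, 1)
    fl <- ad_flow(runif(1, 0.1, 2.5), runif(1, 0, 0.05), p)
    expect_true(all(fl$alpha >= 0))
  }
})

test_that("the two separatrix methods agree to lattice resolution", {
  p <- ad_params(1, 0.5, 100, 1)
  sp_e <- separatrix(p, method = "eigenvector")
  sp_g <- separatrix(p, method = "grid", n_grid = 15)
  expect_gt(nrow(sp_g), 0)
  # the axis intercept of the eigenvector separatrix must sit between the
  # last escaping and first non-escaping lattice columns at alpha = 0
  grid <- attr(sp_g, "grid")
  axis <- grid[grid$alpha == 0, ]
  m_escape <- max(axis$m[axis$endpoint == "obligate_fusion"])
  m_stay <- min(axis$m[axis$endpoint == "fixed_point"])
  icp <- min(sp_e$m[abs(sp_e$alpha) < 1e-6])
  lattice_step <- diff(sort(unique(axis$m)))[1]
  expect_gt(icp, m_escape - lattice_step)
  expect_lt(icp, m_stay + lattice_step)
  # above the separatrix the lattice escapes: compare boundary altitude
  for (k in seq_len(nrow(sp_g))) {
    mcol <- sp_g$m[k]
    a_e <- suppressWarnings(approx(sp_e$m[sp_e$branch == "upper"],
                                   sp_e$alpha[sp_e$branch == "upper"],
                                   xout = mcol)$y)
    if (!is.na(a_e)) {
      a_step <- 0.1 / 14
      expect_lt(abs(sp_g$alpha[k] - a_e), 2.5 * a_step)
    }
  }
})

test_that("above the upper cost threshold everything flows to zero fusion", {
  p <- ad_params(1, 0.9, 100, 1)
  expect_error(separatrix(p, method = "eigenvector"),
               class = "fusevol_domain_error")
  sp <- separatrix(p, method = "grid", n_grid = 8)
  expect_equal(nrow(sp), 0)
  expect_match(attr(sp, "outcome"), "entire quadrant")
})

test_that("the critical basin cost approximates where the separatrix reaches the origin", {
  # The closed-form critical cost comes from a linearisation of the
  # separatrix; its defining property is that the zero-fusion basin's axis
  # intercept shrinks to the origin there. Check both facets: the intercept
  # decreases towards zero in C, and the exact (numerically bisected) cost
  # at which the whole axis joins the basin sits close to the closed form.
  ET <- 100
  icp <- function(C) {
    sp <- separatrix(ad_params(1, C, ET, 1), method = "eigenvector")
    low <- sp[sp$branch == "lower", ]
    min(low$m[abs(low$alpha) < 1e-8])
  }
  cb <- c_base(ET)
  icps <- vapply(c(0.78, cb, 0.837), icp, numeric(1))
  expect_true(all(diff(icps) < 0))
  expect_lt(icps[3], 0.15)
  # bisect the cost at which a near-origin axis start stops diverging
  reaches_axis_cover <- function(C) {
    attr(ad_flow(0.005, 0, ad_params(1, C, ET, 1)),
         "outcome") == "fixed_point"
  }
  lo <- 0.7
  hi <- 0.86
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (reaches_axis_cover(mid)) hi <- mid else lo <- mid
  }
  expect_lt(abs((lo + hi) / 2 - cb), 0.02)
})

test_that("threshold-linear survival caps the viable fusion cost", {
  expect_identical(threshold_linear_max_cost(1, 0), 0.5)
  expect_identical(threshold_linear_max_cost(0.3, 0), 0.5)
  expect_equal(threshold_linear_max_cost(1, log(2)), 1 / 3, tolerance = 1e-12)
  expect_lt(threshold_linear_max_cost(1, 50), 1e-10)
  # numeric supremum over a mass grid agrees with the closed form
  gamma <- 0.75
  m_min <- 0.5
  m <- seq(m_min, 20, length.out = 4000)
  ratio <- threshold_survival(2 * m, gamma, m_min) /
    threshold_survival(m, gamma, m_min)
  sup_C <- max(1 - 1 / ratio)
  expect_equal(sup_C, threshold_linear_max_cost(gamma, m_min),
               tolerance = 1e-6)
})
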