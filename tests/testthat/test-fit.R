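# The shared radial-expanding fixture is built once and reused; it is small
# (compact extent, 12 quarters) so each inner fit takes milliseconds.
re_fix <- function() memo("re_small", small_re_data(seed = 1))

test_that("adjusted AIC charges exactly 2K on top of the inner AIC", {
  obs <- re_fix()$obs
  for (lab in c("N1", "N2")) {
    f <- fit_wave_model(lab, obs)
    expect_identical(f$adjusted_aic, f$aic)
    expect_identical(f$K, 0L)
  }
  init <- wave_params("RE", gamma = re_fix()$truth[["gamma"]],
                      psi = re_fix()$truth[["psi"]], zeta = 405)
  f <- sann_optimize("RE", obs, init, iterations = 30, seed = 5)
  expect_identical(f$adjusted_aic - f$aic, 2 * 3)
  p <- wave_params("P", theta = 1, zeta = 300)
  f <- sann_optimize("P", obs, p, iterations = 30, seed = 5)
  expect_identical(f$adjusted_aic - f$aic, 2 * 2)
})

test_that("direct search is deterministic and returns empty sets for nulls", {
  obs <- re_fix()$obs
  expect_identical(direct_search_init("N1", obs)$par, numeric(0))
  expect_identical(direct_search_init("N3", obs)$par, numeric(0))
  i1 <- direct_search_init("P", obs, theta_n = 8, zeta_n = 4)
  i2 <- direct_search_init("P", obs, theta_n = 8, zeta_n = 4)
  expect_identical(i1$par, i2$par)
})

test_that("direct search returns a lattice node planted at the optimum", {
  # Noise-free single-wave data whose true epicentre and speed sit exactly
  # on nodes of the search grid: the search must return those nodes.
  # Survey locations depend only on the design seed, so a first pass
  # reveals the lattice and a second pass plants the truth on it.
  zeta_node <- sqrt(10 * 50000)           # middle of the 5-point log grid
  fix <- memo("re_clean_z",
              small_re_data(seed = 2, residual_sd = 0, zeta = zeta_node))
  obs <- fix$obs
  gx <- seq(min(obs$X) - 0.2 * diff(range(obs$X)),
            max(obs$X) + 0.2 * diff(range(obs$X)), length.out = 5)
  gy <- seq(min(obs$Y) - 0.2 * diff(range(obs$Y)),
            max(obs$Y) + 0.2 * diff(range(obs$Y)), length.out = 5)
  node <- c(gx[3], gy[3])
  planted <- small_re_data(
    seed = 2, residual_sd = 0, zeta = zeta_node,
    gamma = node[1] + attr(obs, "centre_x"),
    psi = node[2] + attr(obs, "centre_y"))
  init <- direct_search_init("RE", planted$obs, epi_n = 5, zeta_n = 5)
  expect_equal(init$par[["gamma"]], planted$truth[["gamma"]],
               tolerance = 1e-8)
  expect_equal(init$par[["psi"]], planted$truth[["psi"]], tolerance = 1e-8)
  expect_equal(init$par[["zeta"]], zeta_node, tolerance = 1e-8)
})

test_that("annealing is reproducible, monotone under nesting, and improves", {
  obs <- re_fix()$obs
  init <- wave_params("RE", gamma = re_fix()$truth[["gamma"]] + 2e4,
                      psi = re_fix()$truth[["psi"]] - 2e4, zeta = 800)
  f1 <- sann_optimize("RE", obs, init, iterations = 120, seed = 9)
  f2 <- sann_optimize("RE", obs, init, iterations = 120, seed = 9)
  expect_identical(f1$params$par, f2$params$par)
  expect_identical(f1$trace, f2$trace)
  # best-ever contract: never worse than the starting point
  init_obj <- sann_optimize("RE", obs, init, iterations = 0, seed = 9)$objective
  expect_lte(f1$objective, init_obj)
  # shared-prefix nesting: more iterations cannot worsen the best objective
  f_short <- sann_optimize("RE", obs, init, iterations = 60, seed = 9)
  expect_lte(f1$objective, f_short$objective)
  expect_identical(f_short$trace$objective, f1$trace$objective[1:60])
  # the polish stage only ever improves the objective
  f_pol <- sann_optimize("RE", obs, init, iterations = 60, seed = 9,
                         polish = TRUE)
  expect_lte(f_pol$objective, f_short$objective)
})

test_that("the model comparison table ranks by adjusted AIC with Delta = 0 at top", {
  obs <- re_fix()$obs
  cmp <- fit_catalogue(obs, labels = c("N1", "N2", "RE"), iterations = 150,
                       seed = 3)
  expect_equal(min(cmp$table$delta, na.rm = TRUE), 0)
  expect_equal(cmp$table$delta[1], 0)
  expect_identical(cmp$table$label[1], cmp$selected)
  expect_identical(cmp$selected, "RE")   # strong single-wave signal
  # rerun is bit-reproducible
  cmp2 <- fit_catalogue(obs, labels = c("N1", "N2", "RE"), iterations = 150,
                        seed = 3)
  expect_identical(cmp$table, cmp2$table)
})

test_that("per-model failures become rows with reasons, not aborts", {
  obs <- re_fix()$obs
  north_only <- obs[obs$Y >= 5068, ]
  cmp <- fit_catalogue(north_only, labels = c("N1", "RFE"), iterations = 20,
                       seed = 1)
  expect_true(is.na(cmp$table$adjusted_aic[cmp$table$label == "RFE"]))
  expect_match(cmp$table$error[cmp$table$label == "RFE"], "river")
  expect_false(is.na(cmp$table$adjusted_aic[cmp$table$label == "N1"]))
})

test_that("epicentre separation reproduces the dual-wave geometry", {
  p <- wave_params("RDE", gamma1 = -41723, psi1 = 28414, zeta1 = 405,
                   gamma2 = 23675, psi2 = -8675, zeta2 = 2287)
  expect_equal(round(epicentre_separation(p), 1), 75.2)
  p0 <- wave_params("RDC", gamma1 = 5, psi1 = 5, zeta1 = 1,
                    gamma2 = 5, psi2 = 5, zeta2 = 1)
  expect_equal(epicentre_separation(p0), 0)
  p345 <- wave_params("RDE", gamma1 = 0, psi1 = 0, zeta1 = 1,
                      gamma2 = 3000, psi2 = 4000, zeta2 = 1)
  expect_equal(epicentre_separation(p345), 5)
  expect_error(epicentre_separation(wave_params("RE", gamma = 0, psi = 0,
                                                zeta = 1)),
               "dual radial")
})

test_that("profiles follow the chi-square cutoff and quadratic limit", {
  fit <- re_clean_fit()
  est <- fit$params$par[["zeta"]]
  grid <- seq(est * 0.8, est * 1.25, length.out = 21)
  # conditional profile (no restarts) is smooth; near the optimum the
  # objective is quadratic, so the CI must match +/- 1.96 SE from its
  # curvature
  pr <- profile_ci(fit, "zeta", grid, iterations = 0)
  expect_lte(attr(pr, "lower"), est)
  expect_gte(attr(pr, "upper"), est)
  qfit <- stats::lm(objective ~ poly(grid, 2, raw = TRUE), data = pr)
  curv <- 2 * stats::coef(qfit)[[3]]
  se <- sqrt(2 / curv)
  half_quad <- 1.96 * se * sqrt(stats::qchisq(0.95, 1) / 1.96^2)
  half_obs <- (attr(pr, "upper") - attr(pr, "lower")) / 2
  expect_lt(abs(half_obs - half_quad) / half_quad, 0.05)
  # a grid that does not bracket the estimate is an error
  expect_error(profile_ci(fit, "zeta", grid + 10 * est), "does not contain")
  expect_error(profile_ci(fit, "nope", grid), "no parameter")
  # monotone profile: clamp the grid to one side rising away from the optimum
  up_grid <- seq(est, est * 1.4, length.out = 8)
  expect_warning(profile_ci(fit, "zeta", up_grid, iterations = 0),
                 "one-sided")
})
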