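test_that("an intercept-only field is constant everywhere", {
  spec <- wave_field(intercept = 0.2)
  expect_equal(evaluate_growth_field(spec, c(0, 5e4), c(0, 9e4), c(0, 500)),
               c(0.2, 0.2))
})

test_that("at the epicentre the field equals intercept plus shape(day)", {
  shape <- function(rho) 0.7 * cos(2 * pi * rho / 1095)
  spec <- wave_field(list(
    wave_component("radial-expanding", gamma = 4e4, psi = 5e4, zeta = 300,
                   shape = shape)), intercept = 0.1)
  for (d in c(0, 91, 400)) {
    expect_equal(evaluate_growth_field(spec, 4e4, 5e4, d), 0.1 + shape(d))
  }
})

test_that("an expanding radial field obeys the translation property", {
  # field(x, y, t) equals the epicentre's value at t - d/zeta
  spec <- wave_field(list(
    wave_component("radial-expanding", gamma = 6e4, psi = 9e4, zeta = 500)),
    intercept = 0.05)
  shape <- spec$waves[[1]]$shape
  set.seed(31)
  for (i in 1:25) {
    x <- stats::runif(1, 0, 2e5); y <- stats::runif(1, 0, 1.5e5)
    t <- stats::runif(1, 0, 1092)
    d <- sqrt((x - 6e4)^2 + (y - 9e4)^2)
    oracle <- 0.05 + shape(t - d / 500)
    expect_equal(evaluate_growth_field(spec, x, y, t), oracle,
                 tolerance = 1e-12)
  }
})

test_that("a near-infinite speed gives a spatially synchronous field", {
  spec <- wave_field(list(
    wave_component("radial-expanding", gamma = 6e4, psi = 9e4, zeta = 1e12)))
  set.seed(5)
  x <- stats::runif(40, 0, 2e5); y <- stats::runif(40, 0, 1.5e5)
  for (t in c(0, 250, 1000)) {
    v <- evaluate_growth_field(spec, x, y, t)
    expect_lt(diff(range(v)), 1e-6)
  }
})

test_that("a dual-wave field is the sum of its single waves plus intercept", {
  w1 <- wave_component("radial-expanding", gamma = 2e4, psi = 3e4, zeta = 405)
  w2 <- wave_component("radial-expanding", gamma = 1.5e5, psi = 1e5,
                       zeta = 2287)
  dual <- wave_field(list(w1, w2), intercept = 0.12)
  s1 <- wave_field(list(w1), intercept = 0)
  s2 <- wave_field(list(w2), intercept = 0)
  set.seed(8)
  x <- stats::runif(30, 0, 2e5); y <- stats::runif(30, 0, 1.5e5)
  t <- stats::runif(30, 0, 1092)
  expect_equal(evaluate_growth_field(dual, x, y, t),
               0.12 + evaluate_growth_field(s1, x, y, t) +
                 evaluate_growth_field(s2, x, y, t))
})

test_that("field specification rejects degenerate parameters", {
  expect_error(wave_component("radial-expanding", gamma = 0, psi = 0,
                              zeta = 0), "positive")
  expect_error(wave_component("planar", zeta = 10), "theta")
  expect_error(wave_field(period = -1), "period")
  expect_error(wave_field(amplitude = -0.1), "amplitude")
  expect_error(wave_field(extent = c(0, 0, 0, 1)), "extent")
  expect_error(evaluate_growth_field(
    wave_field(list(structure(list(form = "spiral", zeta = 1,
                                   shape = identity),
                    class = "wave_component"))), 0, 0, 0),
    "unknown wave form")
})

test_that("index series follow the exponentiated integrated growth", {
  # constant zero field: the series stays at its baseline
  flat <- wave_field(intercept = 0)
  expect_equal(simulate_index_series(flat, 0, 0, c(0, 91, 182), baseline = 7),
               c(7, 7, 7))
  # one quarter of constant growth ln(10) from baseline 0:
  # next index = 10 * (0 + 3.03) - 3.03 = 27.27
  tenfold <- wave_field(intercept = log(10))
  expect_equal(simulate_index_series(tenfold, 0, 0, c(0, 91), baseline = 0),
               c(0, 27.27), tolerance = 1e-6)
  # growth pushing the index past 100 clips with a warning
  boom <- wave_field(intercept = 5)
  expect_warning(out <- simulate_index_series(boom, 0, 0, c(0, 91),
                                              baseline = 50),
                 "clipped")
  expect_equal(out[2], 100)
  expect_error(simulate_index_series(flat, 0, 0, c(0, 0)), "increasing")
})

test_that("survey generation is reproducible and counts are exact", {
  spec <- wave_field(list(
    wave_component("radial-expanding", gamma = 3e4, psi = 3e4, zeta = 405)),
    extent = c(xmin = 0, xmax = 6e4, ymin = 0, ymax = 6e4), duration = 728)
  des <- sampling_design("uniform", n_surveys_per_quarter = 50, seed = 77)
  s1 <- generate_surveys(spec, des)
  s2 <- generate_surveys(spec, des)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50 * 8)
  # day jitter stays strictly inside each quarter
  expect_true(all(s1$day %% 91 > 0 & s1$day %% 91 < 91))
  expect_true(all(s1$index >= 0 & s1$index <= 100))
  short <- wave_field(duration = 100)
  expect_error(generate_surveys(short, des), "two quarters")
})

test_that("adaptive monitoring concentrates effort in the core area", {
  spec <- wave_field(list(
    wave_component("radial-expanding", gamma = 3e4, psi = 3e4, zeta = 405)),
    extent = c(xmin = 0, xmax = 6e4, ymin = 0, ymax = 6e4), duration = 364)
  core <- c(2e4, 4e4, 2e4, 4e4)
  inside <- outside <- 0
  for (s in 1:20) {
    des <- sampling_design("adaptive", n_surveys_per_quarter = 40,
                           core_region = core, seed = s)
    sv <- generate_surveys(spec, des)
    core_n <- sum(sv$x >= core[1] & sv$x <= core[2] &
                    sv$y >= core[3] & sv$y <= core[4])
    inside <- inside + core_n
    outside <- outside + (nrow(sv) - core_n)
  }
  area_core <- (2e4)^2
  area_out <- (6e4)^2 - area_core
  expect_gt(inside / area_core, outside / area_out)
})

test_that("survey tables round-trip through CSV with metadata", {
  spec <- wave_field(duration = 200, residual_sd = 0)
  des <- sampling_design("uniform", n_surveys_per_quarter = 5, seed = 3)
  sv <- generate_surveys(spec, des)
  path <- file.path(tempdir(), "sv.csv")
  write_surveys(sv, path, seed = 3)
  back <- read_surveys(path)
  expect_equal(back$index, sv$index, tolerance = 1e-12)
  expect_identical(back$id, sv$id)
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  expect_equal(meta$seed, 3)
  expect_error(read_surveys(file.path(tempdir(), "absent.csv")), "not found")
  file.remove(path, paste0(path, ".meta.yml"))
})
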