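surveys_at <- function(x, y, day = 10, index = 5) {
  data.frame(id = sprintf("S%03d", seq_along(x)), day = day, x = x, y = y,
             index = index, n_sections = 33L)
}

test_that("greedy centroid assignment covers with a 5 km radius", {
  # three surveys within 5 km of the first -> one centroid
  sv <- surveys_at(c(0, 3000, 4000), c(0, 0, 3000))
  expect_equal(max(assign_centroids(sv)), 1L)
  # two surveys 6 km apart -> two centroids
  sv <- surveys_at(c(0, 6000), c(0, 0))
  expect_equal(as.integer(assign_centroids(sv)), c(1L, 2L))
  # hand-traced greedy cover: 0, 4, 8 km along a line -> {0, 4} and {8}
  sv <- surveys_at(c(0, 4000, 8000), c(0, 0, 0))
  expect_equal(as.integer(assign_centroids(sv)), c(1L, 1L, 2L))
  # boundary inclusive: exactly 5 km joins
  sv <- surveys_at(c(0, 5000), c(0, 0))
  expect_equal(as.integer(assign_centroids(sv)), c(1L, 1L))
})

test_that("assignment partitions surveys and keeps references separated", {
  set.seed(42)
  sv <- surveys_at(stats::runif(300, 0, 6e4), stats::runif(300, 0, 6e4))
  a <- assign_centroids(sv, radius = 5000)
  expect_true(all(a >= 1L))
  expect_equal(sum(tabulate(a)), nrow(sv))          # partition
  refs <- attr(a, "reference")
  d <- as.matrix(stats::dist(refs[, c("x", "y")]))
  diag(d) <- Inf
  expect_true(all(d > 5000))                        # greedy cover property
  # deterministic
  expect_identical(as.integer(a), as.integer(assign_centroids(sv)))
})

test_that("aggregation takes means per centroid-quarter and mean-centres", {
  sv <- data.frame(id = c("a", "b", "c"), day = c(10, 20, 200),
                   x = c(0, 1000, 500), y = c(0, 500, 250),
                   index = c(0, 20, 7), n_sections = 33L)
  cells <- aggregate_surveys(sv, assign_centroids(sv), quarter_length = 91)
  expect_equal(nrow(cells), 2L)
  q1 <- cells[cells$quarter == 0, ]
  expect_equal(q1$N, 10)
  expect_equal(q1$T, 15)
  expect_equal(q1$n, 2L)
  expect_equal(q1$x, 500)
  # centring: mean of cell coordinates is zero afterwards
  expect_equal(mean(cells$X), 0)
  expect_equal(mean(cells$Y), 0)
  expect_equal(attr(cells, "centre_x"), mean(cells$x))
})

test_that("gaps in the quarter series produce cells but no interpolation", {
  sv <- data.frame(id = c("a", "b"), day = c(10, 200), x = 0, y = 0,
                   index = c(5, 9), n_sections = 33L)
  cells <- aggregate_surveys(sv, assign_centroids(sv))
  expect_equal(sort(cells$quarter), c(0L, 2L))
  expect_equal(nrow(compute_growth(cells)), 0L)   # quarters 0 and 2: no pair
})

test_that("growth rates and weights follow the log-difference formulas", {
  cells <- data.frame(centroid = 1L, quarter = c(0L, 1L, 2L, 3L),
                      T = c(45, 136, 227, 318), x = 0, y = 0, X = 0, Y = 0,
                      N = c(0, 0, 27.27, 27.27), n = c(10L, 10L, 2L, 2L))
  g <- compute_growth(cells, offset = 3.03)
  expect_equal(g$r[1], 0)                          # 0 -> 0
  expect_equal(g$r[2], log(30.30 / 3.03))          # = ln(10)
  expect_equal(g$r[2], log(10), tolerance = 1e-12)
  expect_equal(g$w[1], 5)                          # 10,10 -> 5
  expect_equal(g$w[3], 1)                          # 2,2 -> 1
  expect_equal(g$T, c(45, 136, 227))               # start-of-interval anchor
  g2 <- compute_growth(cells, anchor = "midpoint")
  expect_equal(g2$T, c(90.5, 181.5, 272.5))
})

test_that("site-quality scaling cancels exactly only without the offset", {
  cells <- data.frame(centroid = rep(1:2, each = 3),
                      quarter = rep(0:2, 2),
                      T = rep(c(45, 136, 227), 2), x = 0, y = 0, X = 0, Y = 0,
                      N = c(4, 9, 6, 8, 3, 5), n = 4L)
  scaled <- cells
  scaled$N[scaled$centroid == 1] <- scaled$N[scaled$centroid == 1] * 2.5
  # offset zero and positive indices: r invariant to per-site scaling
  expect_equal(compute_growth(cells, offset = 0)$r,
               compute_growth(scaled, offset = 0)$r)
  # with the offset the cancellation is broken
  expect_false(isTRUE(all.equal(compute_growth(cells, offset = 3.03)$r,
                                compute_growth(scaled, offset = 3.03)$r)))
})

test_that("noise-free pipeline recovers the field's integrated growth", {
  # one fixed transect per centroid, surveyed at the same in-quarter day,
  # so aggregation is exact and r must equal the integral of the field
  spec <- wave_field(
    list(wave_component("radial-expanding", gamma = 2e4, psi = 2e4,
                        zeta = 300)),
    amplitude = 0.3, residual_sd = 0,
    extent = c(xmin = 0, xmax = 5e4, ymin = 0, ymax = 5e4), duration = 364)
  sites <- expand.grid(x = seq(5e3, 4.5e4, by = 2e4),
                       y = seq(5e3, 4.5e4, by = 2e4))
  days <- 45 + 91 * (0:3)
  sv <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    data.frame(id = sprintf("s%d_%d", i, seq_along(days)), day = days,
               x = sites$x[i], y = sites$y[i],
               index = noise_free_index(spec, sites$x[i], sites$y[i], days,
                                        baseline = 20),
               n_sections = 33L)
  }))
  expect_true(all(sv$index > 0 & sv$index < 100))  # no clipping in play
  cells <- aggregate_surveys(sv, assign_centroids(sv))
  g <- compute_growth(cells)
  oracle <- vapply(seq_len(nrow(g)), function(i) {
    site <- cells[cells$centroid == g$centroid[i], c("x", "y")][1, ]
    stats::integrate(function(t)
      evaluate_growth_field(spec, site$x, site$y, t),
      g$T[i], g$T[i] + 91, rel.tol = 1e-12)$value / 91
  }, numeric(1))
  expect_lt(max(abs(g$r - oracle)), 1e-9)
})
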