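# Shared fixture builders. Everything is generated in code at test time;
# heavier fixtures are memoised so several test files can reuse one build.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A plain growth-observation table (no spatial structure) for smoother tests.
make_obs <- function(n = 200, seed = 1, r_fun = function(T) sin(T / 50),
                     noise = 0.01, t_range = c(0, 600)) {
  set.seed(seed)
  T <- stats::runif(n, t_range[1], t_range[2])
  data.frame(r = r_fun(T) + stats::rnorm(n, 0, noise),
             w = stats::runif(n, 0.5, 5),
             T = T,
             X = stats::rnorm(n, 0, 1000),
             Y = stats::rnorm(n, 0, 1000))
}

# A small, strong-signal radial-expanding dataset, reused across fit tests.
# Compact extent and a short span keep the inner fits fast.
small_re_data <- function(seed = 1, zeta = 405, gamma = 3e4, psi = 4.5e4,
                          n_per_quarter = 150,
                          extent = c(xmin = 0, xmax = 1e5,
                                     ymin = 0, ymax = 7.5e4),
                          duration = 1092, residual_sd = 0.3,
                          mode = "uniform") {
  spec <- wave_field(
    list(wave_component("radial-expanding", gamma = gamma, psi = psi,
                        zeta = zeta)),
    amplitude = 0.6, residual_sd = residual_sd,
    extent = extent, duration = duration)
  des <- sampling_design(mode, n_surveys_per_quarter = n_per_quarter,
                         seed = seed)
  sv <- generate_surveys(spec, des)
  a <- assign_centroids(sv)
  cells <- aggregate_surveys(sv, a)
  obs <- compute_growth(cells)
  truth <- c(gamma = gamma - attr(obs, "centre_x"),
             psi = psi - attr(obs, "centre_y"),
             zeta = zeta)
  list(spec = spec, surveys = sv, obs = obs, truth = truth)
}

# A fitted single-wave model on the clean fixture, shared by the report and
# profile tests (fitting is the expensive step, so it is memoised).
re_clean_fit <- function() {
  memo("re_clean_fit", {
    fix <- memo("re_clean_z",
                small_re_data(seed = 2, residual_sd = 0,
                              zeta = sqrt(10 * 50000)))
    fit_wave_model("RE", fix$obs, iterations = 250, seed = 4)
  })
}

# Synchrony-truth data: a spatially uniform cycle (no wave component needed;
# the intercept-plus-shape is achieved with an effectively infinite speed).
synchrony_data <- function(seed = 1, n_per_quarter = 150) {
  spec <- wave_field(
    list(wave_component("radial-expanding", gamma = 5e4, psi = 3.75e4,
                        zeta = 1e12)),
    amplitude = 0.6, residual_sd = 0.3,
    extent = c(xmin = 0, xmax = 1e5, ymin = 0, ymax = 7.5e4),
    duration = 1092)
  des <- sampling_design("uniform", n_surveys_per_quarter = n_per_quarter,
                         seed = seed)
  sv <- generate_surveys(spec, des)
  a <- assign_centroids(sv)
  obs <- compute_growth(aggregate_surveys(sv, a))
  obs
}
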