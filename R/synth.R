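#' Specify one travelling-wave component of a synthetic growth field
#'
#' @param form One of \code{"planar"}, \code{"radial-expanding"},
#'   \code{"radial-contracting"}.
#' @param theta Planar direction in radians (planar form only).
#' @param gamma,psi Epicentre easting/northing in metres (radial forms only),
#'   in the same coordinate system as the field extent.
#' @param zeta Wave speed in metres/day; must be positive.
#' @param shape Optional periodic function of space-modified time (days)
#'   returning a growth-rate contribution. Defaults to the sinusoid implied
#'   by the parent field's period and amplitude.
#' @return An object of class \code{wave_component}.
#' @export
wave_component <- function(form = c("planar", "radial-expanding",
                                    "radial-contracting"),
                           theta = NULL, gamma = NULL, psi = NULL,
                           zeta, shape = NULL) {
  form <- match.arg(form)
  if (zeta <= 0) stop("zeta must be positive")
  if (form == "planar") {
    if (is.null(theta)) stop("planar wave needs 'theta'")
  } else {
    if (is.null(gamma) || is.null(psi)) {
      stop("radial wave needs 'gamma' and 'psi'")
    }
  }
  if (!is.null(shape) && !is.function(shape)) {
    stop("'shape' must be a function of space-modified time")
  }
  structure(list(form = form, theta = theta, gamma = gamma, psi = psi,
                 zeta = zeta, shape = shape),
            class = "wave_component")
}

#' Specify a synthetic travelling-wave growth field
#'
#' Defines the noise-free quarterly population growth rate as a function of
#' space and time: an intercept plus the sum of one or more travelling-wave
#' components, each a periodic function of its own space-modified time.
#' Defaults emulate a vole-like monitoring programme: a 3-year cycle (1095
#' days), growth rates swinging roughly \eqn{\pm 1.4} per quarter,
#' survey-level residual noise with standard deviation 0.3 on the log-index
#' scale, a 200 x 150 km study region, and a 24-quarter (6-year) span like
#' the monitoring programme the package models. The default amplitude is
#' the largest for which the cumulative log-abundance swing of the cycle
#' (amplitude times period / (2 pi x 91) for the sinusoidal shape) still
#' fits the dynamic range of a 0-100 index; larger amplitudes make the
#' index saturate at its bounds for much of the cycle, which flattens the
#' growth signal there and biases wave-speed estimates low.
#'
#' @param waves List of \code{\link{wave_component}} objects (may be empty,
#'   giving a spatially uniform constant field).
#' @param intercept Baseline growth rate per quarter (the \eqn{\alpha_1} of
#'   the growth equations).
#' @param period Cycle period in days (> 0).
#' @param amplitude Half-range of the default sinusoidal shape, in
#'   growth-rate units per quarter (>= 0).
#' @param residual_sd Standard deviation of survey-level observation noise on
#'   the log-index scale (>= 0). Because transect errors are independent,
#'   centroid-mean observation variance is proportional to 1/n by
#'   construction.
#' @param extent Named numeric \code{c(xmin, xmax, ymin, ymax)} in metres.
#' @param duration Study length in days.
#' @return An object of class \code{wave_field}.
#' @examples
#' fld <- wave_field(list(
#'   wave_component("radial-expanding", gamma = 6e4, psi = 9e4, zeta = 500)))
#' evaluate_growth_field(fld, 6e4, 9e4, 0)
#' @export
wave_field <- function(waves = list(), intercept = 0, period = 1095,
                       amplitude = 0.75, residual_sd = 0.3,
                       extent = c(xmin = 0, xmax = 200000,
                                  ymin = 0, ymax = 150000),
                       duration = 2184) {
  if (period <= 0) stop("period must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (residual_sd < 0) stop("residual_sd must be non-negative")
  extent <- unname(extent)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("extent must be a non-degenerate c(xmin, xmax, ymin, ymax)")
  }
  if (duration <= 0) stop("duration must be positive")
  waves <- lapply(waves, function(w) {
    if (!inherits(w, "wave_component")) stop("waves must be wave_component objects")
    if (is.null(w$shape)) {
      w$shape <- local({
        a <- amplitude; p <- period
        function(rho) a * sin(2 * pi * rho / p)
      })
    }
    w
  })
  structure(list(waves = waves, intercept = intercept, period = period,
                 amplitude = amplitude, residual_sd = residual_sd,
                 extent = structure(extent, names = c("xmin", "xmax",
                                                      "ymin", "ymax")),
                 duration = duration),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  cat("Synthetic travelling-wave growth field\n")
  cat(sprintf("  %d wave(s); intercept %.3g; period %g d; amplitude %.3g\n",
              length(x$waves), x$intercept, x$period, x$amplitude))
  for (w in x$waves) {
    if (w$form == "planar") {
      cat(sprintf("   - planar, theta = %.3f rad, zeta = %g m/day\n",
                  w$theta, w$zeta))
    } else {
      cat(sprintf("   - %s, epicentre (%g, %g) m, zeta = %g m/day\n",
                  w$form, w$gamma, w$psi, w$zeta))
    }
  }
  cat(sprintf("  extent [%g, %g] x [%g, %g] m; duration %g d; sigma %g\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              x$duration, x$residual_sd))
  invisible(x)
}

#' Evaluate the noise-free growth field
#'
#' Returns the deterministic quarterly growth rate
#' \eqn{\alpha_1 + \sum_w s_w(\rho_w)} at the given locations and day, where
#' each wave's space-modified time is \eqn{\rho_w = t + D_w/\zeta_w} with
#' \eqn{D_w} the wave's signed distance.
#'
#' @param spec A \code{\link{wave_field}}.
#' @param x,y Coordinates in metres (vectorised).
#' @param day Day since study start (vectorised, recycled with x/y).
#' @return Growth rate(s), in units of log-index change per quarter.
#' @export
evaluate_growth_field <- function(spec, x, y, day) {
  stopifnot(inherits(spec, "wave_field"))
  r <- rep_len(spec$intercept, max(length(x), length(y), length(day)))
  for (w in spec$waves) {
    D <- switch(w$form,
      planar = planar_distance(x, y, w$theta),
      `radial-expanding` = radial_distance(x, y, w$gamma, w$psi, TRUE),
      `radial-contracting` = radial_distance(x, y, w$gamma, w$psi, FALSE),
      stop("unknown wave form: ", w$form))
    r <- r + w$shape(day + D / w$zeta)
  }
  r
}

# Cumulative log-index change from day 0 to 'day' at one location:
# integral of the growth field over time divided by the quarter length
# (growth rates are per-quarter log differences). Composite Simpson with a
# sub-day step is deterministic and accurate to ~1e-12 for the smooth,
# slowly varying shapes the generator produces.
integrated_log_growth <- function(spec, x, y, day, quarter_length = 91,
                                  step = 0.25) {
  n <- max(length(x), length(y), length(day))
  x <- rep_len(x, n); y <- rep_len(y, n); day <- rep_len(day, n)
  vapply(seq_len(n), function(i) {
    d <- day[i]
    if (d == 0) return(0)
    m <- 2L * max(2L, ceiling(abs(d) / (2 * step)))  # even interval count
    tt <- seq(0, d, length.out = m + 1L)
    ft <- evaluate_growth_field(spec, x[i], y[i], tt)
    h <- d / m
    (h / 3) * (ft[1] + ft[m + 1L] +
               4 * sum(ft[seq(2L, m, by = 2L)]) +
               2 * sum(ft[seq(3L, m - 1L, by = 2L)]))
  }, numeric(1)) / quarter_length
}

#' Noise-free abundance index implied by a growth field
#'
#' The latent log-abundance at a location follows the time-integral of the
#' growth field (scaled to the quarterly step); the observable index is the
#' back-transformed abundance clipped to the 0-100 scale of a
#' proportion-of-sections index.
#'
#' @inheritParams evaluate_growth_field
#' @param baseline Index value at day 0. The default (15) centres the default
#'   cycle within the log range of the index so its swing rarely saturates
#'   the 0-100 scale.
#' @param offset Constant added to the index before taking logs (the smallest
#'   non-zero index on a 33-section transect is 100/33 = 3.03).
#' @param quarter_length Days per quarter used to scale growth rates.
#' @return Index value(s) in [0, 100].
#' @export
noise_free_index <- function(spec, x, y, day, baseline = 15,
                             offset = 3.03, quarter_length = 91) {
  lg <- integrated_log_growth(spec, x, y, day, quarter_length)
  pmin(pmax(exp(log(baseline + offset) + lg) - offset, 0), 100)
}

#' Simulate an abundance-index series at one location
#'
#' Starting from \code{baseline} at the first day, each step multiplies the
#' offset abundance by the exponential of the field's integrated growth over
#' the interval (scaled to the quarterly step), then clips to [0, 100]. Steps
#' that hit the bounds are reported with a warning, since clipping flattens
#' the growth signal there.
#'
#' @inheritParams noise_free_index
#' @param days Strictly increasing vector of days.
#' @return Numeric vector of index values, one per day.
#' @export
simulate_index_series <- function(spec, x, y, days, baseline = 3.03,
                                  offset = 3.03, quarter_length = 91) {
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing")
  lg <- integrated_log_growth(spec, x, y, days, quarter_length)
  idx <- numeric(length(days))
  idx[1] <- baseline
  clipped <- 0L
  for (k in seq_along(days)[-1]) {
    nxt <- (idx[k - 1] + offset) * exp(lg[k] - lg[k - 1]) - offset
    if (nxt < 0 || nxt > 100) clipped <- clipped + 1L
    idx[k] <- min(max(nxt, 0), 100)
  }
  if (clipped > 0) {
    warning(sprintf("%d step(s) clipped to the [0, 100] index scale", clipped))
  }
  idx
}

#' Specify a survey sampling design
#'
#' @param mode \code{"uniform"} (locations uniform over the field extent) or
#'   \code{"adaptive"} (a core area is surveyed intensively; peripheral
#'   locations are surveyed only with low probability unless local noise-free
#'   growth exceeds a trigger, emulating outbreak-responsive monitoring).
#' @param n_surveys_per_quarter Surveys per quarter (>= 1).
#' @param core_region Rectangle \code{c(xmin, xmax, ymin, ymax)} in metres
#'   (adaptive mode). Defaults to the central third of the field extent.
#' @param core_fraction Probability that a survey is allocated to the core
#'   (adaptive mode), in [0, 1].
#' @param peripheral_trigger Growth-rate threshold above which a peripheral
#'   candidate location is always surveyed.
#' @param peripheral_prob Probability of surveying a quiet peripheral
#'   candidate anyway.
#' @param seed Integer seed making the generated table reproducible.
#' @return An object of class \code{sampling_design}.
#' @export
sampling_design <- function(mode = c("uniform", "adaptive"),
                            n_surveys_per_quarter = 400,
                            core_region = NULL, core_fraction = 0.6,
                            peripheral_trigger = 0.5,
                            peripheral_prob = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  if (n_surveys_per_quarter < 1) stop("n_surveys_per_quarter must be >= 1")
  if (core_fraction < 0 || core_fraction > 1) {
    stop("core_fraction must be in [0, 1]")
  }
  structure(list(mode = mode,
                 n_surveys_per_quarter = as.integer(n_surveys_per_quarter),
                 core_region = core_region, core_fraction = core_fraction,
                 peripheral_trigger = peripheral_trigger,
                 peripheral_prob = peripheral_prob, seed = as.integer(seed)),
            class = "sampling_design")
}

.default_core <- function(extent) {
  dx <- extent[2] - extent[1]; dy <- extent[4] - extent[3]
  c(extent[1] + dx / 3, extent[2] - dx / 3,
    extent[3] + dy / 3, extent[4] - dy / 3)
}

.in_rect <- function(x, y, r) x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]

#' Generate transect surveys over a synthetic growth field
#'
#' Simulates transect-level abundance surveys: locations per quarter follow
#' the sampling design, survey days are jittered uniformly within each
#' quarter (never on a boundary), and each survey's index is the noise-free
#' index perturbed by Normal observation error on the log-index scale with
#' standard deviation \code{spec$residual_sd}, clipped to [0, 100]. Output is
#' byte-identical under a fixed design seed.
#'
#' @param spec A \code{\link{wave_field}}.
#' @param design A \code{\link{sampling_design}}.
#' @param baseline,offset,quarter_length As in \code{\link{noise_free_index}}.
#' @return Data frame with columns \code{id}, \code{day}, \code{x}, \code{y},
#'   \code{index}, \code{n_sections}.
#' @export
generate_surveys <- function(spec, design, baseline = 15, offset = 3.03,
                             quarter_length = 91) {
  stopifnot(inherits(spec, "wave_field"), inherits(design, "sampling_design"))
  n_quarters <- floor(spec$duration / quarter_length)
  if (n_quarters < 2) {
    stop("field duration spans fewer than two quarters; ",
         "no growth rates would be computable")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)

  ext <- spec$extent
  core <- design$core_region %||% .default_core(ext)
  n_q <- design$n_surveys_per_quarter
  rows <- vector("list", n_quarters)
  for (q in seq_len(n_quarters) - 1L) {
    q_start <- q * quarter_length
    mid <- q_start + quarter_length / 2
    if (design$mode == "uniform") {
      x <- stats::runif(n_q, ext[1], ext[2])
      y <- stats::runif(n_q, ext[3], ext[4])
    } else {
      x <- numeric(n_q); y <- numeric(n_q)
      for (i in seq_len(n_q)) {
        if (stats::runif(1) < design$core_fraction) {
          x[i] <- stats::runif(1, core[1], core[2])
          y[i] <- stats::runif(1, core[3], core[4])
        } else {
          cx <- stats::runif(1, ext[1], ext[2])
          cy <- stats::runif(1, ext[3], ext[4])
          hot <- evaluate_growth_field(spec, cx, cy, mid) >
            design$peripheral_trigger
          if (.in_rect(cx, cy, core) || hot ||
              stats::runif(1) < design$peripheral_prob) {
            x[i] <- cx; y[i] <- cy
          } else {
            x[i] <- stats::runif(1, core[1], core[2])
            y[i] <- stats::runif(1, core[3], core[4])
          }
        }
      }
    }
    day <- q_start + stats::runif(n_q, 1, quarter_length - 1)
    rows[[q + 1L]] <- data.frame(day = day, x = x, y = y)
  }
  out <- do.call(rbind, rows)
  lg <- integrated_log_growth(spec, out$x, out$y, out$day, quarter_length)
  eps <- stats::rnorm(nrow(out), 0, spec$residual_sd)
  latent <- exp(log(baseline + offset) + lg + eps) - offset
  out$index <- pmin(pmax(latent, 0), 100)
  out$n_sections <- 33L
  out$id <- sprintf("S%05d", seq_len(nrow(out)))
  out[, c("id", "day", "x", "y", "index", "n_sections")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read survey tables
#'
#' Surveys are stored as plain CSV with columns \code{id}, \code{day},
#' \code{x}, \code{y}, \code{index}, \code{n_sections}; \code{write_surveys}
#' also writes a YAML metadata sidecar (\code{<path>.meta.yml}) recording the
#' generating seed when one is supplied.
#'
#' @param surveys Survey data frame.
#' @param path CSV path.
#' @param seed Optional integer recorded in the metadata sidecar.
#' @return \code{read_surveys} returns the survey data frame.
#' @export
write_surveys <- function(surveys, path, seed = NULL) {
  utils::write.csv(surveys, path, row.names = FALSE, quote = FALSE)
  meta <- list(created = "popwave", n = nrow(surveys))
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "day", "x", "y", "index", "n_sections")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survey file missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
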