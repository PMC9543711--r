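#' Predicted growth-rate field of a fitted wave model
#'
#' Evaluates the fitted growth equation
#' \eqn{\alpha_1 + \sum_k f_k(\rho_k(X, Y, t))} on a regular spatial grid at
#' one time, the quantity animated over time to visualise the cumulative
#' spatio-temporal pattern. Grid cells further than \code{margin} (as a
#' fraction of the data range) outside the observed bounding box are masked
#' (\code{NA}) with a warning rather than extrapolated.
#'
#' @param model A \code{wave_fit}.
#' @param time Day since study start at which to evaluate.
#' @param grid Optional data frame with columns \code{X}, \code{Y}
#'   (mean-centred metres); defaults to a 2 x 2 km lattice over the data
#'   bounding box.
#' @param spacing Lattice spacing in metres for the default grid.
#' @param margin Allowed extrapolation beyond the data bounding box, as a
#'   fraction of the data range per axis.
#' @return Data frame (class \code{prediction_field}) with columns \code{X},
#'   \code{Y}, \code{T}, \code{r}.
#' @export
predict_field <- function(model, time, grid = NULL, spacing = 2000,
                          margin = 0.1) {
  stopifnot(inherits(model, "wave_fit"))
  obs <- model$fit$design
  bx <- range(obs$X); by <- range(obs$Y)
  if (is.null(grid)) {
    grid <- expand.grid(X = seq(bx[1], bx[2], by = spacing),
                        Y = seq(by[1], by[2], by = spacing))
  }
  mx <- margin * diff(bx); my <- margin * diff(by)
  outside <- grid$X < bx[1] - mx | grid$X > bx[2] + mx |
    grid$Y < by[1] - my | grid$Y > by[2] + my
  nd <- data.frame(X = grid$X, Y = grid$Y, T = time,
                   r = 0, w = 1)
  design <- build_design(model$params, nd, river_y = model$fit$river_y)
  pred <- as.numeric(mgcv::predict.gam(model$fit$gam, newdata = design))
  if (any(outside)) {
    warning(sprintf("%d grid cell(s) beyond the data extent masked",
                    sum(outside)))
    pred[outside] <- NA_real_
  }
  structure(data.frame(X = grid$X, Y = grid$Y, T = time, r = pred),
            label = model$label, class = c("prediction_field", "data.frame"))
}

#' @export
plot.prediction_field <- function(x, ...) {
  xs <- sort(unique(x$X)); ys <- sort(unique(x$Y))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(x$X, xs), match(x$Y, ys))] <- x$r
  graphics::image(xs / 1000, ys / 1000, z, xlab = "X (km)", ylab = "Y (km)",
                  main = sprintf("Predicted growth rate, day %g", x$T[1]),
                  ...)
  invisible(x)
}

#' Cumulative wave-front speed from two prediction snapshots
#'
#' Applies the wave-front rule: at each of two times, find the furthest
#' south location whose predicted growth rate exceeds \code{threshold}
#' (minimum \code{Y}; ties broken by minimum \code{X}), then divide the
#' Euclidean distance between the two locations by the elapsed time.
#'
#' @param field1,field2 \code{prediction_field}s at two different times.
#' @param threshold Growth-rate threshold defining the front (default 0.5).
#' @return List with \code{km_per_day}, \code{km_per_year}, and the two
#'   front locations (\code{front1}, \code{front2}).
#' @export
front_speed <- function(field1, field2, threshold = 0.5) {
  if (field1$T[1] == field2$T[1]) stop("the two fields must differ in time")
  front <- function(f) {
    above <- !is.na(f$r) & f$r > threshold
    if (!any(above)) {
      stop(sprintf(
        "no prediction exceeds the threshold %.3g (maximum is %.3g)",
        threshold, max(f$r, na.rm = TRUE)))
    }
    g <- f[above, , drop = FALSE]
    g <- g[order(g$Y, g$X), , drop = FALSE]
    g[1, c("X", "Y")]
  }
  f1 <- front(field1); f2 <- front(field2)
  d_km <- sqrt((f1$X - f2$X)^2 + (f1$Y - f2$Y)^2) / 1000
  dt <- abs(field2$T[1] - field1$T[1])
  list(km_per_day = d_km / dt, km_per_year = d_km / dt * 365.25,
       front1 = f1, front2 = f2)
}

#' Convert a wave speed from metres/day to kilometres/year
#'
#' Uses a 365.25-day year; set \code{rounded = TRUE} for the nearest-integer
#' value conventionally reported.
#'
#' @param zeta Speed in metres per day (> 0).
#' @param rounded Round to the nearest whole km/year?
#' @return Speed in km/year.
#' @examples
#' convert_speed(405, rounded = TRUE)   # 148
#' convert_speed(2287, rounded = TRUE)  # 835
#' @export
convert_speed <- function(zeta, rounded = FALSE) {
  if (any(zeta <= 0)) stop("zeta must be positive")
  out <- zeta * 365.25 / 1000
  if (rounded) round(out) else out
}

#' Write a prediction field as CSV (columns X, Y, t, r)
#' @param field A \code{prediction_field}.
#' @param path Output CSV path.
#' @export
write_field <- function(field, path) {
  utils::write.csv(
    data.frame(X = field$X, Y = field$Y, t = field$T, r = field$r),
    path, row.names = FALSE)
  invisible(path)
}
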