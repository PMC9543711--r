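#' Distance and space-modified-time equations for travelling-wave models
#'
#' A periodic travelling wave shifts the phase of a population cycle linearly
#' with distance from a reference (a planar front direction or a radial
#' epicentre). These helpers compute the signed distance of a location from
#' that reference and the resulting space-modified time
#' \eqn{\rho = T + D/\zeta}, which aligns all locations onto a single
#' underlying cycle travelling at constant speed \eqn{\zeta}.
#'
#' @param x,y Coordinates in metres (mean-centred for fitting; any consistent
#'   projected system works).
#' @param theta Direction of a planar wave in radians, measured so that
#'   \eqn{D = \sin(\theta) x + \cos(\theta) y}.
#' @name wave-geometry
NULL

#' @describeIn wave-geometry Signed distance of a point along a planar wave
#'   direction, \eqn{D = \sin(\theta) x + \cos(\theta) y} (metres).
#' @export
planar_distance <- function(x, y, theta) {
  sin(theta) * x + cos(theta) * y
}

#' @describeIn wave-geometry Signed distance of a point from a radial wave
#'   epicentre at (\code{gamma}, \code{psi}): the negative Euclidean distance
#'   for an expanding wave (locations further out lag the epicentre), the
#'   positive distance for a contracting wave.
#' @param gamma,psi Epicentre easting and northing (metres).
#' @param expanding Logical; \code{TRUE} for an expanding wave.
#' @export
radial_distance <- function(x, y, gamma, psi, expanding = TRUE) {
  d <- sqrt((gamma - x)^2 + (psi - y)^2)
  if (expanding) -d else d
}

#' @describeIn wave-geometry Space-modified time \eqn{\rho = T + D/\zeta}
#'   (days). \code{zeta} is the constant wave speed in metres/day and must be
#'   positive.
#' @param T Time in days since the start of the study.
#' @param D Signed distance in metres.
#' @param zeta Wave speed in metres/day (> 0).
#' @export
space_modified_time <- function(T, D, zeta) {
  if (any(zeta <= 0)) stop("wave speed 'zeta' must be positive")
  T + D / zeta
}

#' Normalise an angle to [0, 2*pi)
#' @param theta Angle in radians.
#' @return Equivalent angle in [0, 2*pi).
#' @export
normalise_angle <- function(theta) {
  theta %% (2 * pi)
}

## ---------------------------------------------------------------------------
## Model catalogue
## ---------------------------------------------------------------------------

# Structure of each model label:
#   null   - no covariates (N1), time smooth (N2) or spatial tensor (N3)
#   single - one wave, one smooth of rho
#   split  - two waves separated by a river; each observation belongs to one
#   dual   - two additive overlapping waves; both smooths apply everywhere
.catalogue <- data.frame(
  label = c("N1", "N2", "N3", "P", "RE", "RC",
            "PF", "RFE", "RFC", "PD", "RDE", "RDC"),
  structure = c("null", "time", "space", "single", "single", "single",
                "split", "split", "split", "dual", "dual", "dual"),
  form = c(NA, NA, NA, "planar", "radial-expanding", "radial-contracting",
           "planar", "radial-expanding", "radial-contracting",
           "planar", "radial-expanding", "radial-contracting"),
  K = c(0L, 0L, 0L, 2L, 3L, 3L, 4L, 6L, 6L, 4L, 6L, 6L),
  hypothesis = c("null (intercept only)",
                 "phase-locked (true synchrony)",
                 "static spatial pattern",
                 "single planar wave",
                 "single expanding radial wave",
                 "single contracting radial wave",
                 "two planar waves separated by river",
                 "two expanding radial waves separated by river",
                 "two contracting radial waves separated by river",
                 "dual overlapping planar waves",
                 "dual overlapping expanding radial waves",
                 "dual overlapping contracting radial waves"),
  stringsAsFactors = FALSE
)

#' The catalogue of travelling-wave model structures
#'
#' Twelve hypotheses for the spatio-temporal pattern in population growth
#' rates: three nulls (\code{N1} intercept-only, \code{N2} a smooth of time
#' alone i.e. true synchrony, \code{N3} a static spatial smooth), three
#' single-wave models (\code{P} planar, \code{RE}/\code{RC}
#' expanding/contracting radial), three river-split models (\code{PF},
#' \code{RFE}, \code{RFC}: independent waves north and south of a river) and
#' three dual additive models (\code{PD}, \code{RDE}, \code{RDC}: two
#' overlapping waves acting everywhere). \code{K} is the number of wave
#' parameters estimated outside the inner smoother, used by the adjusted AIC.
#'
#' @return A data frame with columns \code{label}, \code{structure},
#'   \code{form}, \code{K} and \code{hypothesis}.
#' @export
wave_catalogue <- function() .catalogue

catalogue_row <- function(label) {
  i <- match(label, .catalogue$label)
  if (is.na(i)) stop("unknown model label: ", label)
  .catalogue[i, ]
}

# Names of the free wave parameters for each label, in optimizer order.
wave_par_names <- function(label) {
  row <- catalogue_row(label)
  radial <- !is.na(row$form) && grepl("radial", row$form)
  switch(row$structure,
    null = , time = , space = character(0),
    single = if (radial) c("gamma", "psi", "zeta") else c("theta", "zeta"),
    split = if (radial) {
      c("gamma_n", "psi_n", "zeta_n", "gamma_s", "psi_s", "zeta_s")
    } else c("theta_n", "zeta_n", "theta_s", "zeta_s"),
    dual = if (radial) {
      c("gamma1", "psi1", "zeta1", "gamma2", "psi2", "zeta2")
    } else c("theta1", "zeta1", "theta2", "zeta2")
  )
}

#' Construct a wave parameter set for a model label
#'
#' @param label A model label from \code{\link{wave_catalogue}}.
#' @param ... Named wave parameters. Planar waves take \code{theta} (radians)
#'   and \code{zeta} (m/day); radial waves take \code{gamma}, \code{psi}
#'   (epicentre, metres, mean-centred) and \code{zeta}. Two-wave models use
#'   suffixes \code{1}/\code{2} (dual) or \code{_n}/\code{_s} (river split).
#'   Null models take no parameters.
#' @return An object of class \code{wave_params} with elements \code{label},
#'   \code{par} (named numeric vector), and \code{K}.
#' @examples
#' wave_params("RE", gamma = -41723, psi = 28414, zeta = 405)
#' @export
wave_params <- function(label, ...) {
  row <- catalogue_row(label)
  wanted <- wave_par_names(label)
  par <- unlist(list(...))
  if (length(wanted) == 0L) {
    if (length(par)) stop("model ", label, " takes no wave parameters")
    par <- numeric(0)
  } else {
    if (!setequal(names(par), wanted)) {
      stop("model ", label, " needs parameters: ",
           paste(wanted, collapse = ", "))
    }
    par <- par[wanted]
    zs <- grepl("^zeta", names(par))
    if (any(par[zs] <= 0)) stop("wave speeds must be positive")
    th <- grepl("^theta", names(par))
    par[th] <- normalise_angle(par[th])
  }
  structure(list(label = label, par = par, K = row$K),
            class = "wave_params")
}

#' @export
print.wave_params <- function(x, ...) {
  cat("Wave parameters for model", x$label,
      sprintf("(K = %d)\n", x$K))
  if (length(x$par)) print(round(x$par, 3)) else cat("  (none)\n")
  invisible(x)
}

# Distances for one wave given its form and parameter suffix ("", "1", ...).
.wave_D <- function(form, par, suffix, X, Y) {
  p <- function(nm) unname(par[paste0(nm, suffix)])
  if (form == "planar") {
    planar_distance(X, Y, p("theta"))
  } else {
    radial_distance(X, Y, p("gamma"), p("psi"),
                    expanding = (form == "radial-expanding"))
  }
}

#' Build the smoother design for a model from growth observations
#'
#' Converts growth observations (columns \code{r}, \code{w}, \code{T},
#' \code{X}, \code{Y}) into the covariates of the model's growth equation:
#' nothing for \code{N1}, time for \code{N2}, coordinates for \code{N3}, one
#' space-modified time \code{rho} for single-wave models, \code{rho} plus a
#' north/south region factor for river-split models (each observation enters
#' exactly one regional smooth), and \code{rho1}, \code{rho2} for dual
#' models.
#'
#' @param params A \code{\link{wave_params}} object.
#' @param obs Data frame of growth observations with columns \code{r},
#'   \code{w}, \code{T}, \code{X}, \code{Y}.
#' @param river_y Northing (metres, mean-centred) of the river used by the
#'   split models; observations with \code{Y >= river_y} are "north".
#' @return \code{obs} with the model covariates appended.
#' @export
build_design <- function(params, obs, river_y = 5068) {
  if (!inherits(params, "wave_params")) stop("params must be a wave_params")
  row <- catalogue_row(params$label)
  par <- params$par
  out <- obs
  switch(row$structure,
    null = out,
    time = out,
    space = out,
    single = {
      D <- .wave_D(row$form, par, "", obs$X, obs$Y)
      out$rho <- space_modified_time(obs$T, D, par[["zeta"]])
      out
    },
    split = {
      north <- obs$Y >= river_y
      zn <- par[[grep("^zeta_n", names(par), value = TRUE)]]
      zs <- par[[grep("^zeta_s", names(par), value = TRUE)]]
      Dn <- .wave_D(row$form, par, "_n", obs$X, obs$Y)
      Ds <- .wave_D(row$form, par, "_s", obs$X, obs$Y)
      out$rho <- ifelse(north,
                        space_modified_time(obs$T, Dn, zn),
                        space_modified_time(obs$T, Ds, zs))
      out$region <- factor(ifelse(north, "north", "south"),
                           levels = c("north", "south"))
      out
    },
    dual = {
      D1 <- .wave_D(row$form, par, "1", obs$X, obs$Y)
      D2 <- .wave_D(row$form, par, "2", obs$X, obs$Y)
      out$rho1 <- space_modified_time(obs$T, D1, par[["zeta1"]])
      out$rho2 <- space_modified_time(obs$T, D2, par[["zeta2"]])
      out
    }
  )
}
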