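#' Greedy radius-based assignment of surveys to centroids
#'
#' Sequentially takes the first unassigned survey (in input order, or by an
#' optional ordering key) as the reference point of a new centroid and
#' assigns every unassigned survey within \code{radius} of it (Euclidean,
#' boundary inclusive). Repeats until all surveys are assigned, so each
#' survey belongs to exactly one centroid and any two reference points are
#' more than \code{radius} apart.
#'
#' @param surveys Survey data frame with columns \code{x}, \code{y}.
#' @param radius Assignment radius in metres (> 0).
#' @param order Processing order: \code{"input"} (default), or the name of a
#'   column of \code{surveys} to sort by (stable sort).
#' @return Integer vector of centroid ids (1-based), one per survey, with an
#'   attribute \code{"reference"}: a data frame of centroid reference points.
#' @export
assign_centroids <- function(surveys, radius = 5000, order = "input") {
  if (radius <= 0) stop("radius must be positive")
  if (nrow(surveys) == 0) stop("no surveys to assign")
  idx <- seq_len(nrow(surveys))
  if (!identical(order, "input")) {
    if (!order %in% names(surveys)) stop("no such ordering column: ", order)
    idx <- idx[order(surveys[[order]])]
  }
  x <- surveys$x; y <- surveys$y
  centroid <- integer(nrow(surveys))
  refs <- list()
  k <- 0L
  r2 <- radius^2
  for (i in idx) {
    if (centroid[i] != 0L) next
    k <- k + 1L
    free <- centroid == 0L
    near <- free & ((x - x[i])^2 + (y - y[i])^2 <= r2)
    centroid[near] <- k
    refs[[k]] <- data.frame(centroid = k, x = x[i], y = y[i])
  }
  structure(centroid, reference = do.call(rbind, refs))
}

#' Aggregate surveys into centroid-by-quarter cells
#'
#' Computes, for every (centroid, quarter) with at least one survey, the
#' arithmetic means of day, coordinates and index, plus the member count.
#' Quarters are fixed-length blocks of \code{quarter_length} days from day 0.
#' After aggregation, coordinates are mean-centred over the whole dataset;
#' the centring constants are kept as attributes \code{centre_x},
#' \code{centre_y} so estimated epicentres can be mapped back to original
#' coordinates.
#'
#' @param surveys Survey data frame (\code{day}, \code{x}, \code{y},
#'   \code{index}).
#' @param assignment Centroid ids from \code{\link{assign_centroids}}.
#' @param quarter_length Days per quarter (default 91).
#' @return Data frame with columns \code{centroid}, \code{quarter},
#'   \code{T} (mean day), \code{x}, \code{y} (raw means), \code{X}, \code{Y}
#'   (mean-centred), \code{N} (mean index), \code{n}; attributes
#'   \code{centre_x}, \code{centre_y}, \code{quarter_length}.
#' @export
aggregate_surveys <- function(surveys, assignment, quarter_length = 91) {
  if (length(assignment) != nrow(surveys)) {
    stop("assignment length does not match surveys")
  }
  quarter <- floor(surveys$day / quarter_length)
  key <- interaction(assignment, quarter, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, mean))
  cells <- data.frame(
    centroid = as.integer(tapply(assignment, key, `[`, 1L)),
    quarter = as.integer(tapply(quarter, key, `[`, 1L)),
    T = agg(surveys$day),
    x = agg(surveys$x),
    y = agg(surveys$y),
    N = agg(surveys$index),
    n = as.integer(tapply(rep(1L, nrow(surveys)), key, sum))
  )
  cells <- cells[order(cells$centroid, cells$quarter), , drop = FALSE]
  rownames(cells) <- NULL
  cx <- mean(cells$x); cy <- mean(cells$y)
  cells$X <- cells$x - cx
  cells$Y <- cells$y - cy
  structure(cells, centre_x = cx, centre_y = cy,
            quarter_length = quarter_length)
}

#' Log-difference growth rates between consecutive quarters
#'
#' For every centroid with cells in consecutive quarters \eqn{t} and
#' \eqn{t+1}, computes \eqn{r = \ln(\bar N_{t+1} + c) - \ln(\bar N_t + c)}
#' with offset \eqn{c} guarding against zero indices, and the precision
#' weight \eqn{w = n_t n_{t+1} / (n_t + n_{t+1})} reflecting observation
#' variance proportional to \eqn{1/n}. Non-consecutive quarters yield no
#' observation (no interpolation). Each observation carries the mean of the
#' two cells' coordinates and, by default, the mean day of the starting
#' quarter as its time anchor.
#'
#' @param cells Output of \code{\link{aggregate_surveys}}.
#' @param offset Constant added to the mean index before taking logs
#'   (default 3.03 = 100/33, the smallest non-zero index of a 33-section
#'   transect).
#' @param anchor \code{"start"} (mean day of quarter \eqn{t}) or
#'   \code{"midpoint"} (mean of the two quarters' mean days).
#' @return Data frame of growth observations with columns \code{centroid},
#'   \code{quarter}, \code{r}, \code{w}, \code{T}, \code{X}, \code{Y},
#'   \code{n_t}, \code{n_next}; centring attributes are carried over from
#'   \code{cells}.
#' @export
compute_growth <- function(cells, offset = 3.03,
                           anchor = c("start", "midpoint")) {
  if (offset < 0) stop("offset must be non-negative")
  anchor <- match.arg(anchor)
  cells <- cells[order(cells$centroid, cells$quarter), , drop = FALSE]
  prev <- cells[-nrow(cells), , drop = FALSE]
  nxt <- cells[-1, , drop = FALSE]
  ok <- prev$centroid == nxt$centroid & nxt$quarter == prev$quarter + 1L
  prev <- prev[ok, , drop = FALSE]
  nxt <- nxt[ok, , drop = FALSE]
  obs <- data.frame(
    centroid = prev$centroid,
    quarter = prev$quarter,
    r = log(nxt$N + offset) - log(prev$N + offset),
    w = prev$n * nxt$n / (prev$n + nxt$n),
    T = if (anchor == "start") prev$T else (prev$T + nxt$T) / 2,
    X = (prev$X + nxt$X) / 2,
    Y = (prev$Y + nxt$Y) / 2,
    n_t = prev$n,
    n_next = nxt$n
  )
  rownames(obs) <- NULL
  structure(obs,
            centre_x = attr(cells, "centre_x"),
            centre_y = attr(cells, "centre_y"),
            quarter_length = attr(cells, "quarter_length"))
}

#' Map mean-centred coordinates back to the original system
#'
#' @param X,Y Mean-centred coordinates (metres).
#' @param obs A data frame carrying \code{centre_x}/\code{centre_y}
#'   attributes (from \code{\link{aggregate_surveys}} or
#'   \code{\link{compute_growth}}).
#' @return Data frame with columns \code{x}, \code{y} in original
#'   coordinates.
#' @export
uncentre <- function(X, Y, obs) {
  cx <- attr(obs, "centre_x"); cy <- attr(obs, "centre_y")
  if (is.null(cx) || is.null(cy)) stop("no centring attributes on 'obs'")
  data.frame(x = X + cx, y = Y + cy)
}
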