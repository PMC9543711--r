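#' Fit the inner penalized-spline growth model for a wave hypothesis
#'
#' Fits the weighted Gaussian GAM of the model's growth equation to growth
#' observations, conditional on the wave parameters: an intercept-only model
#' for \code{N1}, a smooth of time for \code{N2}, a thin-plate tensor product
#' of the coordinates for \code{N3}, a thin-plate smooth of space-modified
#' time for single-wave models, per-region smooths (plus a region main
#' effect, for identifiability) for the river-split models, and two additive
#' smooths for the dual models. Univariate smooths use at most
#' \code{max_basis} (default 12) basis functions; the tensor product uses at
#' most \code{tensor_basis} (default 10) per margin. Smoothing parameters are
#' selected by GCV by default (\code{method = "GCV.Cp"}), switchable to REML.
#'
#' The AIC of the fit is the GAM-reported AIC,
#' \eqn{-2\,\ell + 2\,(\mathrm{edf} + 1)}, where \eqn{\ell} is the weighted
#' Gaussian log-likelihood at the ML variance estimate, edf the total
#' effective degrees of freedom of the linear predictor, and the +1 counts
#' the variance. This single definition is used for every model in the
#' catalogue, so only AIC differences between models are meaningful.
#'
#' @param obs Growth observations (columns \code{r}, \code{w}, \code{T},
#'   \code{X}, \code{Y}); weights must be positive and all inputs finite.
#' @param params A \code{\link{wave_params}} object naming the model.
#' @param river_y River northing for split models (metres, mean-centred).
#' @param max_basis Maximum basis size of univariate smooths.
#' @param tensor_basis Maximum basis size per tensor-product margin.
#' @param method Smoothness-selection criterion passed to \code{mgcv::gam}.
#' @param sp Optional fixed smoothing parameter(s) (bypasses selection).
#' @param max_knots Cap on the number of unique locations used to build the
#'   thin-plate eigenbasis (a cost control; the basis dimension itself is
#'   \code{max_basis}).
#' @return An object of class \code{growth_gam}: list with the fitted
#'   \code{mgcv} model (\code{$gam}), \code{$aic}, \code{$logLik},
#'   \code{$edf}, \code{$sig2}, \code{$label}, \code{$params}.
#' @export
fit_growth_gam <- function(obs, params, river_y = 5068, max_basis = 12,
                           tensor_basis = 10, method = "GCV.Cp", sp = NULL,
                           max_knots = 100) {
  if (any(!is.finite(obs$r)) || any(!is.finite(obs$w)) ||
      any(!is.finite(obs$T)) || any(!is.finite(obs$X)) ||
      any(!is.finite(obs$Y))) {
    stop("non-finite values in growth observations")
  }
  if (any(obs$w <= 0)) stop("weights must be positive")
  design <- build_design(params, obs, river_y = river_y)
  structure_ <- catalogue_row(params$label)$structure
  xt <- list(max.knots = max_knots)
  k1 <- max_basis
  fml <- switch(structure_,
    null = r ~ 1,
    time = stats::as.formula(sprintf(
      "r ~ s(T, k = %d, bs = 'tp', xt = xt)", k1)),
    space = stats::as.formula(sprintf(
      "r ~ te(X, Y, k = c(%d, %d), bs = 'tp')",
      tensor_basis, tensor_basis)),
    single = stats::as.formula(sprintf(
      "r ~ s(rho, k = %d, bs = 'tp', xt = xt)", k1)),
    split = stats::as.formula(sprintf(
      "r ~ region + s(rho, by = region, k = %d, bs = 'tp', xt = xt)", k1)),
    dual = stats::as.formula(sprintf(
      "r ~ s(rho1, k = %d, bs = 'tp', xt = xt) + s(rho2, k = %d, bs = 'tp', xt = xt)",
      k1, k1))
  )
  smooth_vars <- switch(structure_,
    null = character(0), time = "T", space = c("X", "Y"),
    single = "rho", split = "rho", dual = c("rho1", "rho2"))
  for (v in smooth_vars) {
    if (length(unique(design[[v]])) < 3) {
      stop("degenerate design: fewer than 3 unique values of ", v)
    }
  }
  env <- list2env(list(xt = xt), parent = environment())
  environment(fml) <- env
  g <- mgcv::gam(fml, data = design, weights = w, method = method, sp = sp)
  structure(list(gam = g,
                 aic = stats::AIC(g),
                 logLik = as.numeric(stats::logLik(g)),
                 edf = sum(g$edf),
                 sig2 = sum(g$prior.weights *
                              stats::residuals(g, type = "response")^2) /
                   (nrow(design) - sum(g$edf)),
                 label = params$label,
                 params = params,
                 river_y = river_y,
                 design = design),
            class = "growth_gam")
}

#' @export
print.growth_gam <- function(x, ...) {
  cat(sprintf("Inner growth GAM for model %s: n = %d, edf = %.2f, AIC = %.2f\n",
              x$label, nrow(x$design), x$edf, x$aic))
  invisible(x)
}

#' @export
fitted.growth_gam <- function(object, ...) stats::fitted(object$gam)

#' @export
residuals.growth_gam <- function(object, ...) stats::residuals(object$gam)

#' @export
AIC.growth_gam <- function(object, ..., k = 2) object$aic

# Indices of smooth terms and a small newdata template with every covariate
# held at a reference value; used by conditional_contribution.
.terms_template <- function(fit) {
  d <- fit$design
  tmpl <- lapply(d, function(col) {
    if (is.factor(col)) factor(levels(col)[1], levels = levels(col))
    else stats::median(col)
  })
  as.data.frame(tmpl)
}

#' Conditional contribution of one smooth, with pointwise intervals
#'
#' Evaluates \eqn{\alpha_1 + f_k(\rho)} over a grid for one smooth term of a
#' fitted growth GAM — the conditional prediction attributable to that wave
#' including the intercept — together with a pointwise 95\% band from the
#' smooth's standard errors. Optionally attaches partial residuals (response
#' minus all other model components) at the training covariate values.
#'
#' @param fit A \code{growth_gam}.
#' @param smooth Index of the smooth term (1-based, in formula order).
#' @param grid Covariate values at which to evaluate; defaults to 200 points
#'   spanning the training range.
#' @param level Confidence level of the pointwise band.
#' @param partial_residuals If \code{TRUE}, attach partial residuals as
#'   attribute \code{"partial"} (data frame of covariate and residual).
#' @return Data frame with columns \code{grid}, \code{estimate},
#'   \code{lower}, \code{upper}; class \code{growth_contribution}.
#' @export
conditional_contribution <- function(fit, smooth = 1, grid = NULL,
                                     level = 0.95,
                                     partial_residuals = FALSE) {
  g <- fit$gam
  smooths <- g$smooth
  if (smooth < 1 || smooth > length(smooths)) {
    stop("model has no smooth term ", smooth)
  }
  sm <- smooths[[smooth]]
  var <- sm$term[1]
  tr <- fit$design[[var]]
  if (is.null(grid)) grid <- seq(min(tr), max(tr), length.out = 200)
  nd <- .terms_template(fit)[rep(1, length(grid)), , drop = FALSE]
  nd[[var]] <- grid
  if (!is.null(sm$by) && sm$by != "NA" && is.factor(fit$design[[sm$by]])) {
    nd[[sm$by]] <- factor(sm$by.level,
                          levels = levels(fit$design[[sm$by]]))
  }
  pr <- mgcv::predict.gam(g, newdata = nd, type = "terms", se.fit = TRUE)
  lab <- sm$label
  col <- match(lab, colnames(pr$fit))
  if (is.na(col)) stop("cannot locate smooth term ", lab)
  alpha <- unname(stats::coef(g)[1])
  est <- alpha + pr$fit[, col]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(grid = grid, estimate = est,
                    lower = est - z * pr$se.fit[, col],
                    upper = est + z * pr$se.fit[, col])
  if (partial_residuals) {
    tfit <- mgcv::predict.gam(g, type = "terms")
    tcol <- match(lab, colnames(tfit))
    part <- alpha + tfit[, tcol] + stats::residuals(g, type = "response")
    attr(out, "partial") <- data.frame(covariate = tr, residual = part)
  }
  class(out) <- c("growth_contribution", "data.frame")
  out
}

#' @export
plot.growth_contribution <- function(x, xlab = "space-modified time (days)",
                                     ylab = "growth rate", ...) {
  graphics::plot(x$grid, x$estimate, type = "n",
                 ylim = range(x$lower, x$upper), xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  part <- attr(x, "partial")
  if (!is.null(part)) {
    graphics::points(part$covariate, part$residual, pch = 16,
                     col = "grey60", cex = 0.4)
  }
  graphics::lines(x$grid, x$estimate, lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
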