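#' Fit a ninhydrin standard curve
#'
#' Ordinary least-squares fit of colorimetric response (A570) against
#' glutamate mass, the calibration step of the ninhydrin assay for
#' gamma-PGA quantification after acid hydrolysis.
#'
#' @param points Data frame with columns `concentration` (ug glutamate) and
#'   `response`, or a two-column matrix.
#' @return Object of class `pga_stdcurve` with `slope`, `intercept`,
#'   `r_squared`, `n_points` and the underlying `lm` fit.
#' @examples
#' sc <- fit_standard_curve(data.frame(concentration = 0:4,
#'                                     response = 2 * (0:4) + 1))
#' glance(sc)
#' @export
fit_standard_curve <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("concentration", "response") %in% names(points))) {
    names(points)[1:2] <- c("concentration", "response")
  }
  if (nrow(points) < 2) stop("need at least 2 calibration points")
  if (length(unique(points$concentration)) < 2) {
    stop("degenerate design: all concentrations are equal")
  }
  fit <- lm(response ~ concentration, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$response - mean(points$response))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         n_points = nrow(points), model = fit),
    class = "pga_stdcurve"
  )
}

#' Construct a standard curve from published coefficients
#'
#' For back-calculation when only the regression equation (slope,
#' intercept) of a calibration is available.
#'
#' @param slope,intercept Curve coefficients (response = slope * ug +
#'   intercept).
#' @param r_squared Optional reported fit quality.
#' @return A `pga_stdcurve` without an underlying model object.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_points = NA_integer_, model = NULL),
            class = "pga_stdcurve")
}

#' @export
print.pga_stdcurve <- function(x, ...) {
  cat(sprintf("<pga_stdcurve> y = %.4gx + %.4g (R^2 = %.3f, n = %s)\n",
              x$slope, x$intercept, x$r_squared,
              ifelse(is.na(x$n_points), "?", x$n_points)))
  invisible(x)
}

#' @export
tidy.pga_stdcurve <- function(x, ...) {
  if (!is.null(x$model)) {
    s <- summary(x$model)$coefficients
    tibble(term = c("intercept", "slope"),
           estimate = unname(s[, 1]), std.error = unname(s[, 2]),
           statistic = unname(s[, 3]), p.value = unname(s[, 4]))
  } else {
    tibble(term = c("intercept", "slope"),
           estimate = c(x$intercept, x$slope),
           std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
  }
}

#' @export
glance.pga_stdcurve <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n_points = x$n_points)
}

#' @export
autoplot.pga_stdcurve <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "glutamate (ug)", y = "response (A570)") +
    ggplot2::theme_minimal()
  if (!is.null(object$model)) {
    p <- p + ggplot2::geom_point(
      data = object$model$model,
      ggplot2::aes(x = .data$concentration, y = .data$response)
    )
  }
  p
}

#' Back-calculate glutamate mass from a curve response
#'
#' Inverts the linear calibration: `x = (response - intercept) / slope`.
#' Negative results (response below the blank) are flagged with a warning.
#'
#' @param curve A `pga_stdcurve`.
#' @param response Measured response value(s).
#' @return Glutamate mass in ug.
#' @export
glutamate_from_response <- function(curve, response) {
  stopifnot(inherits(curve, "pga_stdcurve"))
  if (curve$slope == 0) stop("standard curve slope is zero")
  x <- (response - curve$intercept) / curve$slope
  if (any(x < 0)) warning("negative glutamate mass back-calculated; check blanks")
  x
}

#' Gamma-PGA content from hydrolysate glutamate
#'
#' Converts the glutamate measured in a fermentation-sample hydrolysate to
#' gamma-PGA mass using the hydrolyzed standard: G ug of glutamate are
#' recovered from W (declared unit) of standard polymer, so the default
#' `"ratio"` variant computes `content = glutamate * W / G` (dimensionally a
#' mass in W's unit, returned in grams). The `"literal"` variant keeps the
#' printed-form arithmetic `content = glutamate / ((G / W) * 100)` for
#' fidelity with assay write-ups that fold a percentage into the divisor;
#' the two differ by the factor 100. The variant used is recorded in the
#' `"provenance"` attribute.
#'
#' @param glutamate_content Glutamate in the sample hydrolysate (ug).
#' @param G Glutamate recovered from the standard hydrolysate (ug).
#' @param W Mass of standard polymer hydrolyzed, in `W_unit`.
#' @param W_unit `"g"` or `"ug"`; must be declared, never guessed.
#' @param variant `"ratio"` (default) or `"literal"`.
#' @return Gamma-PGA content in grams, with attribute `provenance`.
#' @export
pga_content <- function(glutamate_content, G, W, W_unit = c("g", "ug"),
                        variant = c("ratio", "literal")) {
  W_unit <- match.arg(W_unit)
  variant <- match.arg(variant)
  if (any(glutamate_content <= 0) || G <= 0 || W <= 0) {
    stop("glutamate_content, G and W must all be positive")
  }
  W_g <- if (W_unit == "g") W else W / 1e6
  content <- switch(variant,
    ratio = glutamate_content * W_g / G,
    literal = glutamate_content * W_g / (G * 100)
  )
  attr(content, "provenance") <- variant
  content
}

#' Volumetric gamma-PGA yield
#'
#' @param content Gamma-PGA mass in g.
#' @param volume Fermentation volume in L (> 0).
#' @return Yield in g/L.
#' @examples
#' volumetric_yield(0.4114, 0.2)  # 2.057 g/L
#' @export
volumetric_yield <- function(content, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  content / volume
}

#' Assemble an assay results table
#'
#' One row per strain, mirroring a fermentation-yield table: OD600 is
#' carried through for reporting but enters no computation.
#'
#' @param samples Data frame with columns `strain`, `od600`,
#'   `glutamate_ug` (hydrolysate glutamate of the fermentation sample).
#' @param G Standard-hydrolysate glutamate (ug).
#' @param W Standard mass, in `W_unit`.
#' @param W_unit `"g"` or `"ug"`.
#' @param volume Fermentation volume (L).
#' @param variant Content formula variant, see [pga_content()].
#' @return Tibble `strain`, `od600`, `glutamate_ug`, `content_g`,
#'   `yield_g_per_l`, `variant`.
#' @export
pga_yield_table <- function(samples, G, W, W_unit = c("g", "ug"),
                            volume = 0.2, variant = c("ratio", "literal")) {
  W_unit <- match.arg(W_unit)
  variant <- match.arg(variant)
  samples <- as_tibble(samples)
  content <- as.numeric(pga_content(samples$glutamate_ug, G, W,
                                    W_unit = W_unit, variant = variant))
  tibble(
    strain = samples$strain,
    od600 = samples$od600,
    glutamate_ug = samples$glutamate_ug,
    content_g = content,
    yield_g_per_l = volumetric_yield(content, volume),
    variant = variant
  )
}
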