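#' Bivariate ordinary least squares regression
#'
#' Fits `y ~ x` by OLS (via [stats::lm()]) and returns the quantities the
#' body-size pipeline needs: slope, intercept, sample size, r-squared and
#' residual standard deviation.
#'
#' @param x,y Numeric vectors in cm, or `x` may be a two-column data frame
#'   or matrix of (x, y) points.
#' @param xName,yName Semantic labels for reporting.
#' @return A `regressionModel` list.
#' @examples
#' fitOLS(c(0, 1, 2), c(1, 3, 5))$slope  # 2
#' @export
fitOLS <- function(x, y = NULL, xName = "x", yName = "y") {
  if (is.null(y)) {
    stopifnot(ncol(x) >= 2L)
    y <- x[[2]]; x <- x[[1]]
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points for a regression")
  if (diff(range(x)) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # exactly collinear input is legitimate here (noise-free reference tables);
  # silence lm's perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]), n = length(x),
         r2 = r2, residualSd = stats::sigma(fit),
         xName = xName, yName = yName),
    class = "regressionModel"
  )
}

#' @export
print.regressionModel <- function(x, ...) {
  cat(sprintf("%s = %.4g * %s + %.4g  (n = %d, r2 = %.3f, residual sd = %.3g)\n",
              x$yName, x$slope, x$xName, x$intercept, x$n, x$residualSd))
  invisible(x)
}

#' Antorbital notch width from a one-sided measurement
#'
#' Rostra of fossil specimens often preserve only one side at the level of
#' the antorbital notch; the half width measured from the preserved side is
#' doubled, giving a *minimum* estimate of the full antorbital notch width.
#'
#' @param halfWidth One-sided width in cm (> 0).
#' @return The doubled width (cm), with attribute `minimumEstimate = TRUE`.
#' @examples
#' deriveAON(24.7)  # 49.4
#' @export
deriveAON <- function(halfWidth) {
  if (!is.numeric(halfWidth) || length(halfWidth) != 1L || halfWidth <= 0) {
    stop("halfWidth must be a single positive number")
  }
  structure(2 * halfWidth, minimumEstimate = TRUE)
}

#' Cranial measurements of a specimen
#'
#' @param aonWidth Antorbital notch width (AON) in cm; if omitted it is
#'   derived as `2 * aonHalfWidth`.
#' @param aonHalfWidth One-sided antorbital notch measurement in cm.
#' @param rostrumLength Midline rostrum length (RL) in cm; required for the
#'   rostrum-corrected (Method 2) equations.
#' @return A `specimenMeasurements` list.
#' @export
specimenMeasurements <- function(aonWidth = NULL, aonHalfWidth = NULL,
                                 rostrumLength = NULL) {
  if (is.null(aonWidth)) {
    if (is.null(aonHalfWidth)) stop("supply aonWidth or aonHalfWidth")
    aonWidth <- deriveAON(aonHalfWidth)
  }
  if (aonWidth <= 0) stop("aonWidth must be positive")
  if (!is.null(rostrumLength) && rostrumLength <= 0) {
    stop("rostrumLength must be positive")
  }
  structure(list(aonWidth = as.numeric(aonWidth),
                 aonHalfWidth = aonHalfWidth,
                 rostrumLength = rostrumLength),
            class = "specimenMeasurements")
}

#' Regression coefficients of the two-method physeteroid size pipeline
#'
#' The published bivariate OLS equations relating condylobasal length
#' (CBL), total length (TL), rostrum length (RL) and antorbital notch width
#' (AON) in Physeteroidea, all in cm:
#' Method 1: `CBL = 2.51 * AON + 2.84` and `TL = 3.4 * CBL + 161`;
#' Method 2 (rostrum-corrected): `CBL - RL = 0.634 * AON + 31.2` and
#' `TL - CBL = 6.33 * AON + 31.2`.
#'
#' @return A named list of four `c(slope, intercept)` pairs:
#'   `cblFromAON`, `cblMinusRLFromAON`, `tlFromCBL`, `tlMinusCBLFromAON`.
#' @export
physeteroidCoefficients <- function() {
  list(cblFromAON        = c(slope = 2.51,  intercept = 2.84),
       cblMinusRLFromAON = c(slope = 0.634, intercept = 31.2),
       tlFromCBL         = c(slope = 3.4,   intercept = 161),
       tlMinusCBLFromAON = c(slope = 6.33,  intercept = 31.2))
}

#' Two-method condylobasal- and total-length estimate for a specimen
#'
#' Method 1 predicts condylobasal length directly from antorbital notch
#' width and total length from that CBL; it gives the lower bound. Method 2
#' regresses the rostrum-corrected quantities `CBL - RL` and `TL - CBL` on
#' AON and adds the preserved rostrum length back, giving the upper bound:
#' `cbl_upper = (slope * AON + intercept) + RL` and
#' `tl_upper = (slope * AON + intercept) + cbl_upper`.
#'
#' Unrounded values are carried through every composition (so the
#' total-length lower bound is computed from the unrounded CBL); rounding
#' to 0.1 cm happens only in the reported `rounded` element and in
#' printing.
#'
#' @param m A [specimenMeasurements()] object. `rostrumLength` is required
#'   for Method 2; omit it to obtain Method-1 estimates only.
#' @param coeffs Coefficient list as from [physeteroidCoefficients()]
#'   (the default) or fitted from data by [pipelineFromData()].
#' @param methods Which methods to compute (`1:2` by default; Method 2 is
#'   skipped automatically when `rostrumLength` is absent only if
#'   `methods` excludes 2, otherwise an error is raised).
#' @return A `bodySizeEstimate`: list with unrounded `cblLower`,
#'   `cblUpper`, `tlLower`, `tlUpper`, a `rounded` named vector at 0.1 cm,
#'   and `equationsUsed`.
#' @examples
#' est <- estimateBodySize(specimenMeasurements(aonWidth = 49.4,
#'                                              rostrumLength = 81.9))
#' est$rounded
#' @export
estimateBodySize <- function(m, coeffs = physeteroidCoefficients(),
                             methods = 1:2) {
  stopifnot(inherits(m, "specimenMeasurements"))
  need <- c("cblFromAON", "cblMinusRLFromAON", "tlFromCBL", "tlMinusCBLFromAON")
  miss <- setdiff(if (2 %in% methods) need else need[c(1, 3)], names(coeffs))
  if (length(miss)) stop("missing coefficient pair(s): ", paste(miss, collapse = ", "))
  aon <- m$aonWidth
  lin <- function(co, x) unname(co["slope"]) * x + unname(co["intercept"])
  out <- list(cblLower = NULL, cblUpper = NULL, tlLower = NULL, tlUpper = NULL,
              equationsUsed = coeffs[names(coeffs) %in% need],
              measurements = m)
  if (1 %in% methods) {
    out$cblLower <- lin(coeffs$cblFromAON, aon)
    out$tlLower <- lin(coeffs$tlFromCBL, out$cblLower)
  }
  if (2 %in% methods) {
    if (is.null(m$rostrumLength)) {
      stop("Method 2 requires a rostrum length measurement")
    }
    out$cblUpper <- lin(coeffs$cblMinusRLFromAON, aon) + m$rostrumLength
    out$tlUpper <- lin(coeffs$tlMinusCBLFromAON, aon) + out$cblUpper
  }
  vals <- c(cbl_lower = out$cblLower, cbl_upper = out$cblUpper,
            tl_lower = out$tlLower, tl_upper = out$tlUpper)
  if (any(vals <= 0)) stop("non-positive size estimate; check inputs")
  out$rounded <- round(vals, 1)
  class(out) <- "bodySizeEstimate"
  out
}

#' @export
print.bodySizeEstimate <- function(x, ...) {
  r <- x$rounded
  cat("Body size estimate (cm, rounded to 0.1):\n")
  if (!is.null(x$cblLower) && !is.null(x$cblUpper)) {
    cat(sprintf("  condylobasal length: %.1f - %.1f\n", r["cbl_lower"], r["cbl_upper"]))
    cat(sprintf("  total length:        %.1f - %.1f\n", r["tl_lower"], r["tl_upper"]))
  } else {
    print(r)
  }
  invisible(x)
}

#' Fit the two-method pipeline from a reference table and apply it
#'
#' Fits the four regressions from reference specimens (Method 1:
#' `CBL ~ AON` and `TL ~ CBL`; Method 2: `(CBL - RL) ~ AON` and
#' `(TL - CBL) ~ AON`), then applies [estimateBodySize()] with the fitted
#' coefficients. Rows with missing values are dropped per regression (total
#' length is typically available only for extant taxa).
#'
#' @param refTable Data frame with columns `AON`, `CBL`, `RL`, `TL`
#'   (cm; `TL` and `RL` may contain `NA`).
#' @param specimen A [specimenMeasurements()] object.
#' @param methods Which methods to fit and apply.
#' @return A `bodySizeEstimate`; the fitted `regressionModel`s are attached
#'   as the `models` element.
#' @export
pipelineFromData <- function(refTable, specimen, methods = 1:2) {
  needCols <- c("AON", "CBL", if (2 %in% methods) "RL", "TL")
  miss <- setdiff(needCols, names(refTable))
  if (length(miss)) stop("reference table lacks column(s): ", paste(miss, collapse = ", "))
  fitOne <- function(x, y, xn, yn, label) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) stop("fewer than 3 usable rows for regression ", label)
    fitOLS(x[ok], y[ok], xName = xn, yName = yn)
  }
  models <- list()
  coeffs <- list()
  if (1 %in% methods) {
    models$cblFromAON <- fitOne(refTable$AON, refTable$CBL, "AON", "CBL",
                                "CBL ~ AON (Method 1)")
    models$tlFromCBL <- fitOne(refTable$CBL, refTable$TL, "CBL", "TL",
                               "TL ~ CBL (Method 1)")
  }
  if (2 %in% methods) {
    models$cblMinusRLFromAON <- fitOne(refTable$AON, refTable$CBL - refTable$RL,
                                       "AON", "CBL-RL", "(CBL-RL) ~ AON (Method 2)")
    models$tlMinusCBLFromAON <- fitOne(refTable$AON, refTable$TL - refTable$CBL,
                                       "AON", "TL-CBL", "(TL-CBL) ~ AON (Method 2)")
  }
  coeffs <- lapply(models, function(f) c(slope = f$slope, intercept = f$intercept))
  est <- estimateBodySize(specimen, coeffs = coeffs, methods = methods)
  est$models <- models
  est
}
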