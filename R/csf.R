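#' Fit an ELISA standard curve
#'
#' Four-parameter logistic (4PL) fit of absorbance against calibrator
#' concentration by least squares,
#' `A(x) = d + (a - d) / (1 + (x / c)^b)`, with `a` the zero-concentration
#' asymptote, `d` the saturating asymptote, `c` the inflection concentration
#' and `b` the slope. Falls back to a log-log linear fit if the 4PL does not
#' converge. Fit order is invariant to calibrator ordering; monotonicity of
#' the fitted curve over the calibrated range is verified.
#'
#' @param concentration calibrator concentrations in ng/mL (>= 4 points,
#'   e.g. a serial dilution series).
#' @param absorbance mean calibrator absorbances (A450).
#' @return a `standard_curve` object with elements `type` (`"4pl"` or
#'   `"loglinear"`), `pars`, `range` (invertible absorbance range), and
#'   `residual_sd`.
#' @export
fit_standard_curve <- function(concentration, absorbance) {
  stopifnot(length(concentration) == length(absorbance),
            length(concentration) >= 4, all(concentration > 0))
  ord <- order(concentration)
  x <- concentration[ord]; y <- absorbance[ord]
  if (any(diff(y) <= 0)) {
    stop("calibrator absorbances are not monotone in concentration")
  }
  start <- list(a = min(y) * 0.9, d = max(y) * 1.1,
                c = exp(mean(log(range(x)))), b = 1.2)
  fit <- try(minpack.lm::nlsLM(
    y ~ d + (a - d) / (1 + (x / c)^b),
    start = start,
    lower = c(a = -Inf, d = min(y), c = 1e-12, b = 1e-9),
    upper = c(a = max(y), d = Inf, c = Inf, b = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    p <- as.list(coef(fit))
    pred <- p$d + (p$a - p$d) / (1 + (x / p$c)^p$b)
    if (all(diff(pred) > 0)) {
      return(structure(list(
        type = "4pl", pars = p,
        range = range(pred),
        conc_range = range(x),
        residual_sd = sd(y - pred),
        calibrators = data.frame(concentration = x, absorbance = y)
      ), class = "standard_curve"))
    }
  }
  lf <- lm(log(y) ~ log(x))
  structure(list(
    type = "loglinear", pars = as.list(coef(lf)),
    range = range(y), conc_range = range(x),
    residual_sd = sd(residuals(lf)),
    calibrators = data.frame(concentration = x, absorbance = y)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s fit over %g-%g ng/mL (residual sd %.3g)\n",
              x$type, x$conc_range[1], x$conc_range[2], x$residual_sd))
  invisible(x)
}

curve_predict <- function(curve, conc) {
  p <- curve$pars
  if (curve$type == "4pl") {
    p$d + (p$a - p$d) / (1 + (conc / p$c)^p$b)
  } else {
    exp(p[[1]] + p[[2]] * log(conc))
  }
}

curve_invert <- function(curve, absorbance) {
  p <- curve$pars
  if (curve$type == "4pl") {
    p$c * (((p$a - p$d) / (absorbance - p$d)) - 1)^(1 / p$b)
  } else {
    exp((log(absorbance) - p[[1]]) / p[[2]])
  }
}

#' Convert duplicate absorbances to a hemoglobin concentration
#'
#' Duplicates are averaged first, the mean absorbance inverted through the
#' standard curve, and the result multiplied by the dilution factor. Raw
#' estimates below the limit of detection are censored at the LOD (value =
#' LOD, `censored = TRUE`), preserving rank statistics without inventing a
#' value. Absorbances outside the curve's invertible range are flagged
#' `censored_high` (above) or censored at the LOD (below).
#'
#' @param a450 numeric vector of duplicate absorbances (usually length 2).
#' @param curve a `standard_curve`.
#' @param dilution_factor sample predilution (default 10, i.e. 1:10).
#' @param lod assay limit of detection in ng/mL (default 6.25).
#' @return list with `hb_ng_ml`, `censored`, `censored_high`.
#' @export
absorbance_to_conc <- function(a450, curve, dilution_factor = 10,
                               lod = 6.25) {
  stopifnot(length(a450) >= 1, dilution_factor > 0)
  a <- mean(a450)
  lo <- curve$range[1]; hi <- curve$range[2]
  if (a >= hi) {
    return(list(hb_ng_ml = curve_invert(curve, hi * (1 - 1e-9)) *
                  dilution_factor,
                censored = FALSE, censored_high = TRUE))
  }
  if (a <= lo) {
    return(list(hb_ng_ml = lod, censored = TRUE, censored_high = FALSE))
  }
  conc <- curve_invert(curve, a) * dilution_factor
  if (conc < lod) {
    list(hb_ng_ml = lod, censored = TRUE, censored_high = FALSE)
  } else {
    list(hb_ng_ml = conc, censored = FALSE, censored_high = FALSE)
  }
}

#' Normalize CSF hemoglobin to total protein
#'
#' Adds `hb_over_protein = hb_ng_ml / total_protein` per sample. Note that a
#' cohort's median of per-sample ratios is not the ratio of its medians;
#' normalization must happen per sample, as here, before any summary.
#'
#' @param samples data.frame with `hb_ng_ml` and `total_protein` columns.
#' @return `samples` with `hb_over_protein` added.
#' @export
normalize_to_protein <- function(samples) {
  stopifnot(all(c("hb_ng_ml", "total_protein") %in% names(samples)))
  if (any(samples$total_protein <= 0)) {
    stop("total protein must be positive for every sample")
  }
  samples$hb_over_protein <- samples$hb_ng_ml / samples$total_protein
  samples
}
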