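#' Normalise a calcium-titration fluorescence series
#'
#' Subtracts the response at maximal calcium (the lowest pCa measured) and
#' rescales so the largest-magnitude change is 100%, expressing the series
#' as per cent of maximum fluorescence change. The transform is monotone in
#' the response.
#'
#' @param series data.frame with columns `x` (pCa) and `y` (response).
#' @return the series with `y` replaced by the normalised values.
#' @export
normalize_fluorescence <- function(series) {
  stopifnot(is.data.frame(series), all(c("x", "y") %in% names(series)))
  y_ref <- series$y[which.min(series$x)]
  d <- series$y - y_ref
  scale <- d[which.max(abs(d))]
  if (abs(scale) < 1e-12)
    stop("degenerate normalization: series is constant")
  series$y <- 100 * d / scale
  series
}

# Variable-slope sigmoid in pCa:
#   y = bottom + (top - bottom) / (1 + 10^(slope * (x - pca50)))
# slope > 0 gives the descending-in-pCa (force-type) curve: maximal response
# at low pCa (high calcium).
.hill_eval <- function(x, bottom, top, pca50, slope) {
  bottom + (top - bottom) / (1 + 10^(slope * (x - pca50)))
}

#' Fit a variable-slope sigmoid (Hill) dose-response curve in pCa
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^(hill_slope * (x - pCa50)))`
#' with x in pCa units. `model = "descending"` (force-pCa, fluorescence
#' change) expects the response to fall as pCa rises (positive slope);
#' `"ascending"` the reverse. Initialisation is a deterministic multi-start:
#' five pCa50 starting values evenly spanning the observed x-range, keeping
#' the convergent fit with the lowest residual sum of squares.
#'
#' @param series data.frame with columns `x` (pCa, within [3, 10]) and `y`;
#'   an optional `replicate` column is ignored by the fit.
#' @param model `"descending"` (default) or `"ascending"`.
#' @param n_starts number of pCa50 grid starts (default 5).
#' @return object of class `hill_fit`: list with `coefficients` (named:
#'   bottom, top, pca50, hill_slope), `se` (standard errors), `rss`,
#'   `converged`, `extrapolated` (pCa50 outside observed range +/- 1),
#'   `model`, `data`, and `fit` (the underlying nls object).
#' @export
fit_hill <- function(series, model = c("descending", "ascending"),
                     n_starts = 5) {
  model <- match.arg(model)
  stopifnot(is.data.frame(series), all(c("x", "y") %in% names(series)))
  x <- series$x
  y <- series$y
  if (length(unique(x)) < 5)
    stop("need at least 5 distinct pCa values to fit a 4-parameter sigmoid")
  if (any(x < 3 | x > 10))
    stop("pCa values outside the plausible range [3, 10]")
  slope0 <- if (model == "descending") 2 else -2
  starts <- seq(min(x), max(x), length.out = n_starts)
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(slope * (x - pca50))),
        data = dat,
        start = list(bottom = min(y), top = max(y), pca50 = p0,
                     slope = slope0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
  }
  if (is.null(best))
    stop("Hill fit failed to converge from any start; ",
         "check that the data span the transition")
  f <- best$fit
  co <- stats::coef(f)
  se <- tryCatch(sqrt(diag(stats::vcov(f))), error = function(e)
    rep(NA_real_, 4))
  names(se) <- names(co)
  # canonical orientation: top > bottom (equivalent model with slope sign
  # flipped)
  if (co["top"] < co["bottom"]) {
    co[c("bottom", "top")] <- co[c("top", "bottom")]
    se[c("bottom", "top")] <- se[c("top", "bottom")]
    co["slope"] <- -co["slope"]
  }
  coefficients <- c(bottom = unname(co["bottom"]), top = unname(co["top"]),
                    pca50 = unname(co["pca50"]),
                    hill_slope = unname(co["slope"]))
  ses <- c(bottom = unname(se["bottom"]), top = unname(se["top"]),
           pca50 = unname(se["pca50"]), hill_slope = unname(se["slope"]))
  structure(list(
    coefficients = coefficients, se = ses, rss = best$rss,
    converged = TRUE,
    extrapolated = coefficients["pca50"] < min(x) - 1 ||
      coefficients["pca50"] > max(x) + 1,
    model = model, data = dat, fit = f),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  co <- x$coefficients
  se <- x$se
  cat(sprintf(
    "hill_fit (%s): pCa50 %.3f +/- %.3f, slope %.2f +/- %.2f, top %.2f, bottom %.2f (rss %.3g)%s\n",
    x$model, co["pca50"], se["pca50"], co["hill_slope"], se["hill_slope"],
    co["top"], co["bottom"], x$rss,
    if (x$extrapolated) " [pCa50 extrapolated]" else ""))
  invisible(x)
}

#' Difference in calcium sensitivity between two fits
#'
#' Reports `pCa50(B) - pCa50(A)` with its standard error propagated in
#' quadrature. Inputs may be [fit_hill()] results or plain lists/named
#' vectors carrying `pca50` and `se` (for published summary values).
#'
#' @param fit_a,fit_b [hill_fit] objects, or `list(pca50 =, se =)`.
#' @return list with `delta` and `se`.
#' @export
compare_pca50 <- function(fit_a, fit_b) {
  get <- function(f) {
    if (inherits(f, "hill_fit")) {
      if (!isTRUE(f$converged)) stop("unconverged fit passed to compare_pca50")
      c(f$coefficients["pca50"], f$se["pca50"])
    } else {
      c(f$pca50, f$se)
    }
  }
  a <- get(fit_a)
  b <- get(fit_b)
  list(delta = unname(b[1] - a[1]), se = unname(sqrt(a[2]^2 + b[2]^2)))
}
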