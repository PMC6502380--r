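#' Ordinary least-squares fit on log10-log10 axes
#'
#' The allometric workhorse: regresses log10(y) on log10(x) and reports the
#' slope, intercept, fit statistics and per-observation residuals. Pairs
#' with missing `y` are dropped pairwise by the callers before fitting.
#'
#' @param x positive predictor values (e.g. fork length, cm)
#' @param y positive response values (e.g. kype length, cm)
#' @param ids optional observation ids for error messages and residual names
#' @return object of class `loglog_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `df` (c(1, n - 2)), `p_value`, `n`,
#'   `residuals` (log10 units), `fitted` (log10 units)
#' @export
loglog_fit <- function(x, y, ids = NULL) {
  if (length(x) != length(y)) stop_ctx("loglog_fit: x and y lengths differ")
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; ids <- ids[keep]
  if (length(x) < 3L) stop_ctx("loglog_fit: need at least 3 observations")
  bad <- which(x <= 0 | y <= 0)
  if (length(bad))
    stop_ctx("loglog_fit: non-positive value for observation '%s'",
             ids[bad[1]])
  lx <- log10(x); ly <- log10(y)
  fit <- lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))   # silences the exact-fit notice
  n <- length(x)
  fstat <- unname(sm$fstatistic[1])
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 f_statistic = fstat,
                 df = c(1L, n - 2L),
                 p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
                 n = n,
                 residuals = setNames(unname(resid(fit)), ids),
                 fitted = setNames(unname(fit$fitted.values), ids),
                 slope_se = sm$coefficients[2, 2]),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("<loglog_fit> slope %.4f, intercept %.4f, R^2 = %.3f, F(1,%d) = %.1f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$df[2], x$f_statistic, x$n))
  invisible(x)
}

#' Fork-length-adjusted kype trait (AKL or AKH)
#'
#' One pooled regression (all strains and sea-winter classes together) of
#' the log10 trait on log10 fork length; the adjusted value of each fish is
#' its residual. Fish with a missing trait are excluded from the fit and
#' get `NA`. A per-group adjustment is available behind `by` but is not the
#' default.
#'
#' @param records phenotype data.frame
#' @param trait `"kype_length"` or `"kype_height"`
#' @param by optional column name to fit separate regressions per group
#' @return list with `adjusted` (named per-fish residuals, NA where the
#'   trait is missing) and `fit` (the pooled [loglog_fit], or a list of fits
#'   when `by` is given)
#' @export
size_adjust <- function(records, trait = c("kype_length", "kype_height"),
                        by = NULL) {
  trait <- match.arg(trait)
  if (all(is.na(records[[trait]])))
    stop_ctx("size_adjust: trait '%s' is entirely missing", trait)
  out <- setNames(rep(NA_real_, nrow(records)), records$fish_id)
  if (is.null(by)) {
    fit <- loglog_fit(records$fork_length, records[[trait]],
                      ids = records$fish_id)
    out[names(fit$residuals)] <- fit$residuals
    return(list(adjusted = out, fit = fit))
  }
  fits <- list()
  for (g in unique(records[[by]])) {
    sub <- records[records[[by]] == g, , drop = FALSE]
    fits[[as.character(g)]] <- loglog_fit(sub$fork_length, sub[[trait]],
                                          ids = sub$fish_id)
    out[names(fits[[as.character(g)]]$residuals)] <-
      fits[[as.character(g)]]$residuals
  }
  list(adjusted = out, fit = fits)
}

#' Gonadosomatic residuals (GSR)
#'
#' Residuals of log10 milt weight on log10 total wet weight; fish missing
#' either weight are excluded (no imputation) and get `NA`.
#'
#' @param records phenotype data.frame
#' @return list with `gsr` (named per-fish residuals) and `fit`
#' @export
gonadosomatic_residuals <- function(records) {
  fit <- loglog_fit(records$wet_weight, records$milt_weight,
                    ids = records$fish_id)
  out <- setNames(rep(NA_real_, nrow(records)), records$fish_id)
  out[names(fit$residuals)] <- fit$residuals
  list(gsr = out, fit = fit)
}

#' Per-fish adjusted-trait table (AKL, AKH, GSR)
#'
#' Convenience wrapper producing the adjusted traits the mixed models and
#' QTL scan consume.
#'
#' @param records phenotype data.frame
#' @return list with `table` (fish_id, AKL, AKH, GSR data.frame) and
#'   `fits` (the three underlying regressions)
#' @export
adjusted_traits <- function(records) {
  akl <- size_adjust(records, "kype_length")
  akh <- size_adjust(records, "kype_height")
  gsr <- gonadosomatic_residuals(records)
  list(table = data.frame(fish_id = records$fish_id,
                          AKL = unname(akl$adjusted),
                          AKH = unname(akh$adjusted),
                          GSR = unname(gsr$gsr),
                          stringsAsFactors = FALSE),
       fits = list(AKL = akl$fit, AKH = akh$fit, GSR = gsr$fit))
}
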