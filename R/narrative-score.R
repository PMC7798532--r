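#' Per-synonym per-decade sentiment means
#'
#' For every (synonym, decade) cell, the mean consensus sentiment of its
#' retained rated collocates, weighted by the windowed co-occurrence count
#' `f_joint` (frequency-faithful default; set `weight = "none"` for an
#' unweighted mean). The cell weight `w` is the synonym's occurrence count
#' `f_node` in that decade, used later by the CANS aggregation. Cells with
#' no rated collocates are omitted with a message.
#'
#' @param rated A `rated_collocates` table carrying a `sentiment` column.
#' @param weight "f_joint" (default) or "none".
#' @return A `synonym_decade_scores` data frame: `synonym`, `decade`,
#'   `mean_sentiment`, `w`, `n_collocates`.
#' @export
synonym_decade_means <- function(rated, weight = c("f_joint", "none")) {
  weight <- match.arg(weight)
  stopifnot(inherits(rated, "rated_collocates"), "sentiment" %in% names(rated))
  if (nrow(rated) == 0L) stop("no rated collocates")
  key <- paste(rated$decade, rated$synonym, sep = "\r")
  wts <- if (weight == "f_joint") rated$f_joint else rep(1, nrow(rated))
  num <- tapply(rated$sentiment * wts, key, sum)
  den <- tapply(wts, key, sum)
  nn <- tapply(rep(1L, nrow(rated)), key, sum)
  fn <- tapply(rated$f_node, key, `[`, 1L)
  parts <- strsplit(names(num), "\r", fixed = TRUE)
  out <- data.frame(
    synonym = vapply(parts, `[`, character(1), 2L),
    decade = as.integer(vapply(parts, `[`, character(1), 1L)),
    mean_sentiment = as.numeric(num / den),
    w = as.numeric(fn),
    n_collocates = as.integer(nn),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$decade, out$synonym), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("synonym_decade_scores", "data.frame"))
}

#' Cumulative Aging Narrative Score per decade
#'
#' `CANS_d = sum_s w_{s,d} * mean_{s,d} / sum_s w_{s,d}`: each synonym's
#' decade mean, weighted by how often the synonym appeared in that decade.
#' Decades with zero total weight are marked missing (`NA`).
#'
#' @param scores A `synonym_decade_scores` table.
#' @param decades Optional integer vector of decade indices the series should
#'   span (defaults to the observed range); absent decades become `NA` rows.
#' @return A `cans_series` data frame: `decade`, `cans`, `total_weight`,
#'   `n_synonyms`, with attribute `neutral` (= 3).
#' @export
compute_cans <- function(scores, decades = NULL) {
  stopifnot(inherits(scores, "synonym_decade_scores"))
  if (is.null(decades)) decades <- sort(unique(scores$decade))
  num <- tapply(scores$mean_sentiment * scores$w, scores$decade, sum)
  den <- tapply(scores$w, scores$decade, sum)
  ns <- tapply(rep(1L, nrow(scores)), scores$decade, sum)
  out <- data.frame(decade = as.integer(decades))
  idx <- match(as.character(out$decade), names(num))
  out$cans <- as.numeric(ifelse(!is.na(idx) & den[idx] > 0,
                                num[idx] / den[idx], NA_real_))
  out$total_weight <- as.numeric(ifelse(is.na(idx), 0, den[idx]))
  out$n_synonyms <- as.integer(ifelse(is.na(idx), 0L, ns[idx]))
  if (anyNA(out$cans)) {
    message(sum(is.na(out$cans)), " decade(s) with zero weight marked missing")
  }
  structure(out, class = c("cans_series", "data.frame"), neutral = 3)
}

#' Proportion of decades scoring above the neutral threshold
#'
#' Counts decades whose CANS strictly exceeds the threshold (3, the midpoint
#' of the 1-5 sentiment scale) and divides by the number of decades in the
#' requested range. Exact ties at the threshold do not count.
#'
#' @param series A `cans_series`.
#' @param decades Integer vector of decade indices to include (default: all
#'   non-missing decades in the series).
#' @param threshold Neutral cutoff (default 3).
#' @return A fraction in `[0, 1]`.
#' @export
proportion_above_neutral <- function(series, decades = NULL, threshold = 3) {
  stopifnot(inherits(series, "cans_series"))
  if (is.null(decades)) decades <- series$decade[!is.na(series$cans)]
  if (length(decades) == 0L) stop("empty decade range")
  v <- series$cans[match(decades, series$decade)]
  sum(v > threshold, na.rm = TRUE) / length(decades)
}

#' Polynomial trend fit of the CANS series
#'
#' Ordinary least squares of CANS on powers of the decade index `d` (0 at
#' the 1810s, one unit per decade) up to `degree`. Coefficients come with
#' t-distribution standard errors, two-sided p-values and 95% CIs; the
#' headline coefficient is the highest-order term. When the fit is exact
#' (zero residual variance) the coefficients are still exact but p-values
#' are flagged degenerate.
#'
#' @param series A `cans_series`.
#' @param degree Polynomial degree, 1 (linear), 2 or 3.
#' @param conf Confidence level (default 0.95).
#' @return A `trend_fit` list: `degree`, `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `p`, `ci_lo`, `ci_hi`), `headline` (the
#'   highest-order row), `r_squared`, `sigma`, `degenerate`, `n`.
#' @export
fit_trend <- function(series, degree = 1L, conf = 0.95) {
  stopifnot(inherits(series, "cans_series"), degree %in% 1:3)
  ok <- !is.na(series$cans)
  if (sum(ok) < degree + 2) stop("need at least degree + 2 non-missing decades")
  d <- series$decade[ok]
  y <- series$cans[ok]
  dat <- data.frame(y = y)
  terms <- paste0("d", seq_len(degree))
  for (p in seq_len(degree)) dat[[terms[p]]] <- d^p
  fit <- lm(reformulate(terms, "y"), data = dat)
  # degeneracy is reported via the flag below; lm's own warning is redundant
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  degenerate <- sm$sigma < 1e-8
  est <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  pval <- sm$coefficients[, "Pr(>|t|)"]
  ci <- suppressWarnings(confint(fit, level = conf))
  cf <- data.frame(
    term = c("intercept", terms), estimate = as.numeric(est),
    se = as.numeric(se), p = as.numeric(pval),
    ci_lo = ci[, 1], ci_hi = ci[, 2], stringsAsFactors = FALSE
  )
  rownames(cf) <- NULL
  structure(list(
    degree = degree, coefficients = cf, headline = cf[nrow(cf), ],
    r_squared = if (degenerate) 1 else sm$r.squared,
    sigma = sm$sigma, degenerate = degenerate, n = sum(ok)
  ), class = "trend_fit")
}

#' Linear, quadratic and cubic trend fits
#'
#' @param series A `cans_series`.
#' @param degrees Degrees to fit (default 1:3).
#' @param conf Confidence level.
#' @return Named list of `trend_fit` objects ("linear", "quadratic", "cubic").
#' @export
fit_trends <- function(series, degrees = 1:3, conf = 0.95) {
  nm <- c("linear", "quadratic", "cubic")[degrees]
  setNames(lapply(degrees, function(g) fit_trend(series, g, conf)), nm)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Polynomial trend, degree ", x$degree, " (n = ", x$n, ")\n", sep = "")
  print(x$coefficients, digits = 4)
  if (x$degenerate) cat("note: zero residual variance; p-values degenerate\n")
  invisible(x)
}

#' Plot a CANS series with its pointwise confidence band
#'
#' Dots are the per-decade CANS values; the shaded band is the linear
#' trend's pointwise confidence band; the dashed line marks the neutral
#' threshold.
#'
#' @param x A `cans_series`.
#' @param conf Band confidence level.
#' @param ... Passed to `plot()`.
#' @export
plot.cans_series <- function(x, conf = 0.95, ...) {
  ok <- !is.na(x$cans)
  d <- x$decade[ok]; y <- x$cans[ok]
  fit <- lm(y ~ d)
  pr <- stats::predict(fit, newdata = data.frame(d = d), interval = "confidence",
                       level = conf)
  plot(d, y, xlab = "decade index (0 = 1810s)", ylab = "CANS",
       ylim = range(c(y, pr, 3)), pch = 16, ...)
  graphics::polygon(c(d, rev(d)), c(pr[, "lwr"], rev(pr[, "upr"])),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::points(d, y, pch = 16)
  graphics::lines(d, pr[, "fit"], col = "steelblue")
  graphics::abline(h = attr(x, "neutral"), lty = 2, col = "grey40")
  invisible(x)
}
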