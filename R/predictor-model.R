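PREDICTOR_DIMS <- c("status", "warmth", "competence", "medicalization", "ostracism")

#' Assemble the synonym x decade predictor table
#'
#' One row per (synonym, decade): the outcome is the `f_joint`-weighted mean
#' consensus sentiment over the cell's retained rated collocates (the same
#' quantity that feeds CANS), and the predictors are the analogous weighted
#' means of status, warmth, competence, medicalization and ostracism. Rows
#' whose collocates all lack a dimension are dropped with a warning.
#'
#' @param rated A `rated_collocates` table carrying all six consensus
#'   dimensions.
#' @param weight "f_joint" (default) or "none".
#' @return A `predictor_table` data frame ordered by (decade, synonym):
#'   `synonym`, `decade`, `outcome`, the five predictors, `w`,
#'   `n_collocates`.
#' @export
build_predictor_table <- function(rated, weight = c("f_joint", "none")) {
  weight <- match.arg(weight)
  stopifnot(inherits(rated, "rated_collocates"))
  need <- c("sentiment", PREDICTOR_DIMS)
  miss <- setdiff(need, names(rated))
  if (length(miss)) stop("rated collocates lack dimension(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(rated$decade, rated$synonym, sep = "\r")
  wts <- if (weight == "f_joint") rated$f_joint else rep(1, nrow(rated))
  wmean_by <- function(v) {
    ok <- !is.na(v)
    num <- tapply(ifelse(ok, v * wts, 0), key, sum)
    den <- tapply(ifelse(ok, wts, 0), key, sum)
    as.numeric(num) / ifelse(as.numeric(den) > 0, as.numeric(den), NA_real_)
  }
  cells <- names(tapply(wts, key, sum))
  parts <- strsplit(cells, "\r", fixed = TRUE)
  out <- data.frame(
    synonym = vapply(parts, `[`, character(1), 2L),
    decade = as.integer(vapply(parts, `[`, character(1), 1L)),
    outcome = wmean_by(rated$sentiment),
    stringsAsFactors = FALSE
  )
  for (dm in PREDICTOR_DIMS) out[[dm]] <- wmean_by(rated[[dm]])
  out$w <- as.numeric(tapply(rated$f_node, key, `[`, 1L))
  out$n_collocates <- as.integer(tapply(rep(1L, nrow(rated)), key, sum))
  bad <- !stats::complete.cases(out[c("outcome", PREDICTOR_DIMS)])
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped: dimension missing for all collocates")
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$decade, out$synonym), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("predictor_table", "data.frame"))
}

#' Coerce a data frame to a predictor table
#'
#' @param df Data frame with `synonym`, `decade`, `outcome` and the five
#'   predictor columns.
#' @return A `predictor_table`.
#' @export
as_predictor_table <- function(df) {
  need <- c("synonym", "decade", "outcome", PREDICTOR_DIMS)
  stopifnot(all(need %in% names(df)))
  structure(as.data.frame(df), class = c("predictor_table", "data.frame"))
}

check_collinearity <- function(table, preds) {
  const <- preds[vapply(preds, function(p) var(table[[p]]) < 1e-12, logical(1))]
  if (length(const)) {
    stop("constant predictor column(s): ", paste(const, collapse = ", "))
  }
  X <- as.matrix(cbind(1, table[preds]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("perfectly collinear predictor(s): ", paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Mixed model of narrative sentiment on sociological predictors
#'
#' Fits a linear mixed model with the synonym-decade sentiment score as the
#' outcome, a random intercept per decade, and fixed effects for loss of
#' status, warmth, competence, medicalization of aging and social ostracism
#' (plus optional extra covariates). Estimation is restricted maximum
#' likelihood via `lme4::lmer`; inference on fixed effects uses Wald normal
#' tests. When the decade variance collapses to zero the estimates coincide
#' with ordinary least squares.
#'
#' @param table A `predictor_table`.
#' @param covariates Optional extra fixed-effect column names.
#' @param weighted Weight rows by the synonym-decade frequency `w`?
#'   (default FALSE).
#' @param conf Confidence level for Wald CIs.
#' @return A `mixed_model_fit` list: `fixed` (data frame `term`, `estimate`,
#'   `se`, `p`, `ci_lo`, `ci_hi`), `var_decade`, `var_resid`, `singular`,
#'   `converged`, `method`, `n`, and the underlying `lme4` fit as `fit`.
#' @export
fit_mixed_model <- function(table, covariates = character(0),
                            weighted = FALSE, conf = 0.95) {
  stopifnot(inherits(table, "predictor_table"))
  preds <- c(PREDICTOR_DIMS, covariates)
  if (length(unique(table$decade)) < 2L) stop("need at least 2 decades")
  if (length(unique(table$synonym)) < 2L) stop("need at least 2 synonyms")
  check_collinearity(table, preds)
  dat <- as.data.frame(table)
  dat$.decade_f <- factor(dat$decade)
  fml <- stats::as.formula(paste("outcome ~", paste(preds, collapse = " + "),
                                 "+ (1 | .decade_f)"))
  fit <- if (weighted) {
    lme4::lmer(fml, data = dat, REML = TRUE, weights = dat$w)
  } else {
    lme4::lmer(fml, data = dat, REML = TRUE)
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  if (!converged) warning("mixed model did not converge: ",
                          paste(msgs, collapse = "; "))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  fixed <- data.frame(
    term = sub("^\\(Intercept\\)$", "intercept", names(est)),
    estimate = as.numeric(est), se = as.numeric(se), p = as.numeric(p),
    ci_lo = as.numeric(est - zq * se), ci_hi = as.numeric(est + zq * se),
    stringsAsFactors = FALSE
  )
  rownames(fixed) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_decade <- vc$vcov[vc$grp == ".decade_f"][1]
  var_resid <- vc$vcov[vc$grp == "Residual"][1]
  structure(list(
    fixed = fixed, var_decade = var_decade, var_resid = var_resid,
    singular = lme4::isSingular(fit), converged = converged,
    method = "REML", n = nrow(dat), fit = fit
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("Linear mixed model (REML), random intercept per decade, n =", x$n, "\n")
  print(x$fixed, digits = 4)
  cat(sprintf("decade variance %.4g | residual variance %.4g%s\n",
              x$var_decade, x$var_resid,
              if (x$singular) " | singular (decade variance ~ 0)" else ""))
  invisible(x)
}
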