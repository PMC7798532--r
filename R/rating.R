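#' Rating dimensions and their admissible ranges
#'
#' Six dimensions are scored: `sentiment` (1 = very negative to 5 = very
#' positive), `status` (1 low, 2 neutral, 3 high), `warmth` (1 very cold to
#' 5 very warm), `competence` (1 very incompetent to 5 very competent), and
#' the binary `medicalization` and `ostracism` (0 = no, 1 = yes).
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
dimension_ranges <- function() {
  list(
    sentiment = c(1, 5), status = c(1, 3), warmth = c(1, 5),
    competence = c(1, 5), medicalization = c(0, 1), ostracism = c(0, 1)
  )
}

validate_lexicon <- function(lex) {
  need <- c("word", "rater_id", "dimension", "value")
  if (!all(need %in% names(lex))) {
    stop("rating lexicon needs columns: ", paste(need, collapse = ", "))
  }
  rng <- dimension_ranges()
  bad_dim <- !lex$dimension %in% names(rng)
  if (any(bad_dim)) {
    stop("unknown dimension '", lex$dimension[bad_dim][1], "' for word '",
         lex$word[bad_dim][1], "' (rater ", lex$rater_id[bad_dim][1], ")")
  }
  lo <- vapply(rng, `[`, numeric(1), 1L)[lex$dimension]
  hi <- vapply(rng, `[`, numeric(1), 2L)[lex$dimension]
  bad <- is.na(lex$value) | lex$value < lo | lex$value > hi
  if (any(bad)) {
    i <- which(bad)[1]
    stop("rating value ", lex$value[i], " out of range for word '",
         lex$word[i], "' dimension '", lex$dimension[i], "' (rater ",
         lex$rater_id[i], ")")
  }
  invisible(lex)
}

#' Read multi-rater rating lexicons
#'
#' Each CSV has columns `word`, `rater_id`, `dimension`, `value`. Several
#' files are concatenated; every value is validated against its dimension's
#' range, and violations are reported with the word and rater.
#'
#' @param paths Character vector of CSV paths.
#' @return A long `rating_lexicon` data frame.
#' @export
read_rating_lexicons <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("rating lexicon file not found: ", missing[1])
  lex <- do.call(rbind, lapply(paths, read.csv, stringsAsFactors = FALSE))
  lex$word <- as.character(lex$word)
  lex$rater_id <- as.character(lex$rater_id)
  as_rating_lexicon(lex)
}

#' Coerce a data frame to a validated rating lexicon
#'
#' @param df Data frame with columns `word`, `rater_id`, `dimension`, `value`.
#' @return A `rating_lexicon` data frame.
#' @export
as_rating_lexicon <- function(df) {
  validate_lexicon(df)
  structure(as.data.frame(df), class = c("rating_lexicon", "data.frame"))
}

#' Score retained collocates against rating lexicons
#'
#' For each retained collocate and requested dimension, the consensus value
#' is the arithmetic mean across the raters that rated the word (missing
#' raters are simply skipped, not imputed). Words rated by no rater on a
#' requested dimension are excluded from scoring and counted; a coverage
#' ratio below 0.8 triggers a warning. This exclusion mechanizes the
#' relevance check of the inclusion criteria: only words in the curated
#' rating lexicon enter the narrative score.
#'
#' @param records A `collocate_records` table (only rows with
#'   `retained == TRUE` are scored; if no `retained` column, all rows).
#' @param lexicons A `rating_lexicon` (long form, possibly many raters).
#' @param dimensions Dimensions to score (default all six).
#' @return A `rated_collocates` data frame: the retained records plus one
#'   consensus column per dimension and `n_raters`. Attributes:
#'   `coverage` (fraction of distinct retained words that were rated) and
#'   `unrated_words`.
#' @export
apply_ratings <- function(records, lexicons,
                          dimensions = names(dimension_ranges())) {
  stopifnot(inherits(records, "collocate_records"))
  if (!inherits(lexicons, "rating_lexicon")) lexicons <- as_rating_lexicon(lexicons)
  stopifnot(all(dimensions %in% names(dimension_ranges())))
  if (length(unique(lexicons$rater_id)) < 1L) stop("need at least one rater")
  ret <- if ("retained" %in% names(records)) records[records$retained, , drop = FALSE] else records
  lex <- lexicons[lexicons$dimension %in% dimensions, , drop = FALSE]
  # consensus per word x dimension
  agg <- aggregate(value ~ word + dimension, data = lex, FUN = mean)
  words_rated <- unique(agg$word)
  covered <- ret$collocate %in% words_rated
  unrated <- sort(unique(ret$collocate[!covered]))
  coverage <- if (nrow(ret) == 0L) 1 else length(unique(ret$collocate[covered])) /
    max(1L, length(unique(ret$collocate)))
  if (length(unrated)) {
    message(length(unrated), " retained word(s) absent from all rating lexicons; excluded from scoring")
  }
  if (coverage < 0.8) {
    warning(sprintf("rating coverage %.2f below 0.8", coverage))
  }
  out <- ret[covered, , drop = FALSE]
  for (dm in dimensions) {
    a <- agg[agg$dimension == dm, , drop = FALSE]
    out[[dm]] <- a$value[match(out$collocate, a$word)]
  }
  nr_any <- aggregate(rater_id ~ word, data = lex,
                      FUN = function(x) length(unique(x)))
  out$n_raters <- nr_any$rater_id[match(out$collocate, nr_any$word)]
  rownames(out) <- NULL
  structure(out, class = c("rated_collocates", "data.frame"),
            coverage = coverage, unrated_words = unrated)
}

#' Cronbach's alpha with a Feldt confidence interval
#'
#' Inter-rater reliability across rating columns:
#' `alpha = k/(k-1) * (1 - sum of rater variances / variance of item sums)`.
#' The 95% interval uses Feldt's F-distribution form with `n-1` and
#' `(n-1)(k-1)` degrees of freedom. Items with any missing value are dropped
#' (listwise). Zero variance of the item sums leaves alpha undefined: it is
#' returned as `NA` with `degenerate = TRUE`, never silently 1.
#'
#' @param ratings Numeric matrix or data frame, items in rows, raters in
#'   columns.
#' @param conf Confidence level (default 0.95).
#' @return A `reliability_report` list: `alpha`, `ci` (length 2),
#'   `n_items`, `n_raters`, `conf`, `degenerate`.
#' @export
cronbach_alpha <- function(ratings, conf = 0.95) {
  x <- as.matrix(ratings)
  if (ncol(x) < 2L) stop("need at least 2 raters")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L) stop("need at least 3 complete items")
  vt <- var(rowSums(x))
  if (!is.finite(vt) || vt < .Machine$double.eps) {
    return(structure(list(alpha = NA_real_, ci = c(NA_real_, NA_real_),
                          n_items = n, n_raters = k, conf = conf,
                          degenerate = TRUE),
                     class = "reliability_report"))
  }
  alpha <- (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / vt)
  a2 <- (1 - conf) / 2
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ci <- c(1 - (1 - alpha) * qf(1 - a2, df1, df2),
          1 - (1 - alpha) * qf(a2, df1, df2))
  structure(list(alpha = alpha, ci = ci, n_items = n, n_raters = k,
                 conf = conf, degenerate = FALSE),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Cronbach's alpha: undefined (zero total variance), n =", x$n_items, "\n")
  } else {
    cat(sprintf("Cronbach's alpha = %.3f (%d%% CI: %.3f, %.3f), %d items x %d raters\n",
                x$alpha, round(100 * x$conf), x$ci[1], x$ci[2], x$n_items, x$n_raters))
  }
  invisible(x)
}

#' Reliability report for a rating lexicon dimension
#'
#' Pivots a long multi-rater lexicon to an items-by-raters matrix for one
#' dimension and computes Cronbach's alpha.
#'
#' @param lexicons A `rating_lexicon`.
#' @param dimension Dimension name (default "sentiment").
#' @param conf Confidence level.
#' @return A `reliability_report`.
#' @export
lexicon_reliability <- function(lexicons, dimension = "sentiment", conf = 0.95) {
  if (!inherits(lexicons, "rating_lexicon")) lexicons <- as_rating_lexicon(lexicons)
  lex <- lexicons[lexicons$dimension == dimension, , drop = FALSE]
  if (nrow(lex) == 0L) stop("no ratings for dimension '", dimension, "'")
  raters <- sort(unique(lex$rater_id))
  words <- sort(unique(lex$word))
  m <- matrix(NA_real_, length(words), length(raters),
              dimnames = list(words, raters))
  m[cbind(match(lex$word, words), match(lex$rater_id, raters))] <- lex$value
  rep <- cronbach_alpha(m, conf = conf)
  rep$dimension <- dimension
  rep
}
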