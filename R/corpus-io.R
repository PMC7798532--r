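#' @useDynLib agenarr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var qf pnorm setNames aggregate confint lm coef vcov rnorm runif rbinom reformulate
#' @importFrom utils head write.csv read.csv
NULL

CORPUS_GENRES <- c("newspaper", "magazine", "fiction", "nonfiction")
CORPUS_YEAR_MIN <- 1810L
CORPUS_YEAR_MAX <- 2019L

#' Tokenize text into lowercase word tokens
#'
#' Lowercases, then extracts Unicode-letter tokens, keeping internal hyphens
#' and apostrophes (so "military-looking" stays one token). Digits and
#' punctuation are dropped. No lemmatization is performed; all downstream
#' counting is on surface forms.
#'
#' @param text A single character string.
#' @return Character vector of tokens (empty for empty/NA input).
#' @examples
#' tokenize("Old people are wise.")
#' tokenize("military-looking")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string; got length ", length(text))
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- tolower(text)
  m <- gregexpr("\\p{L}+(?:['-]\\p{L}+)*", text, perl = TRUE)
  regmatches(text, m)[[1]]
}

#' Decade index of a year
#'
#' Years 1810-2019 are binned into 21 decades indexed 0 (1810s) through
#' 20 (2010s).
#'
#' @param year Integer vector of years.
#' @return Integer decade indices.
#' @export
decade_of <- function(year) {
  if (any(year < CORPUS_YEAR_MIN | year > CORPUS_YEAR_MAX, na.rm = TRUE)) {
    stop("year outside ", CORPUS_YEAR_MIN, "-", CORPUS_YEAR_MAX)
  }
  as.integer(floor((year - CORPUS_YEAR_MIN) / 10))
}

new_corpus <- function(df, n_skipped = 0L) {
  stopifnot(all(c("doc_id", "year", "genre", "decade", "tokens") %in% names(df)))
  df$n_tokens <- vapply(df$tokens, length, integer(1))
  structure(df, class = c("narr_corpus", "data.frame"), n_skipped = n_skipped)
}

validate_document <- function(doc_id, year, genre, where) {
  if (is.null(doc_id) || is.na(doc_id) || !nzchar(doc_id)) {
    stop("missing doc_id at ", where, call. = FALSE)
  }
  if (is.null(year) || is.na(suppressWarnings(as.numeric(year)))) {
    stop("missing or non-numeric year at ", where, call. = FALSE)
  }
  year <- as.integer(year)
  if (year < CORPUS_YEAR_MIN || year > CORPUS_YEAR_MAX) {
    stop("year ", year, " outside ", CORPUS_YEAR_MIN, "-", CORPUS_YEAR_MAX,
         " at ", where, call. = FALSE)
  }
  if (is.null(genre) || is.na(genre) || !genre %in% CORPUS_GENRES) {
    stop("genre must be one of ", paste(CORPUS_GENRES, collapse = ", "),
         " at ", where, call. = FALSE)
  }
  invisible(year)
}

#' Build a corpus from a data frame
#'
#' Accepts columns `doc_id`, `year`, `genre`, and either `text` (tokenized
#' here) or a `tokens` list-column. Documents that tokenize to nothing are
#' dropped with a warning.
#'
#' @param df A data frame of documents.
#' @return A `narr_corpus` object (a data frame with a `tokens` list-column
#'   and a derived `decade` index).
#' @export
as_corpus <- function(df) {
  stopifnot(is.data.frame(df), all(c("doc_id", "year", "genre") %in% names(df)))
  for (i in seq_len(nrow(df))) {
    validate_document(df$doc_id[i], df$year[i], df$genre[i], paste0("row ", i))
  }
  if (anyDuplicated(df$doc_id)) stop("duplicate doc_id values")
  tokens <- if ("tokens" %in% names(df)) {
    df$tokens
  } else if ("text" %in% names(df)) {
    lapply(df$text, tokenize)
  } else {
    stop("need a 'text' or 'tokens' column")
  }
  n_tok <- vapply(tokens, length, integer(1))
  empty <- n_tok == 0L
  if (any(empty)) {
    warning(sum(empty), " document(s) empty after tokenization; skipped")
  }
  out <- data.frame(
    doc_id = as.character(df$doc_id)[!empty],
    year = as.integer(df$year)[!empty],
    genre = as.character(df$genre)[!empty],
    stringsAsFactors = FALSE
  )
  out$decade <- decade_of(out$year)
  out$tokens <- tokens[!empty]
  new_corpus(out, n_skipped = sum(empty))
}

#' Read a decade-tagged corpus from JSON-Lines
#'
#' One JSON object per line with fields `doc_id`, `year` (1810-2019),
#' `genre` (newspaper/magazine/fiction/nonfiction) and `text`. In strict
#' mode any malformed record aborts the read, naming the offending line;
#' otherwise malformed records are skipped and counted (attribute
#' `n_skipped`).
#'
#' @param path Path to a JSONL file.
#' @param strict Abort on the first malformed record?
#' @return A `narr_corpus` object.
#' @export
read_corpus <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  recs <- vector("list", sum(keep))
  n_skipped <- 0L
  j <- 0L
  for (i in which(keep)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) && strict) stop("malformed JSON at line ", i)
    ok <- !is.null(rec) && tryCatch({
      validate_document(rec$doc_id, rec$year, rec$genre, paste0("line ", i))
      if (is.null(rec$text)) stop("record missing text at line ", i, call. = FALSE)
      TRUE
    }, error = function(e) if (strict) stop(e) else FALSE)
    if (!ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    j <- j + 1L
    recs[[j]] <- data.frame(
      doc_id = as.character(rec$doc_id), year = as.integer(rec$year),
      genre = as.character(rec$genre), text = as.character(rec$text),
      stringsAsFactors = FALSE
    )
  }
  if (n_skipped > 0) warning(n_skipped, " malformed record(s) skipped")
  if (j == 0L) stop("no valid records in ", path)
  df <- do.call(rbind, recs[seq_len(j)])
  cp <- as_corpus(df)
  attr(cp, "n_skipped") <- attr(cp, "n_skipped") + n_skipped
  cp
}

#' Write a corpus to JSON-Lines
#'
#' Documents are serialized with their tokens rejoined by single spaces,
#' so `read_corpus(write_corpus(x))` reproduces the token sequences exactly.
#'
#' @param corpus A `narr_corpus`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "narr_corpus"))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      doc_id = corpus$doc_id[i], year = corpus$year[i],
      genre = corpus$genre[i],
      text = paste(corpus$tokens[[i]], collapse = " ")
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Per-decade token frequency index
#'
#' Counts every token per decade (the collocate marginal `f_coll`), the
#' per-decade corpus sizes `N_d`, and per-(decade, genre) subtotals.
#'
#' @param corpus A non-empty `narr_corpus`.
#' @return A `token_index` list with elements `freq` (list of named count
#'   vectors keyed by decade), `totals` (named numeric), and `genre_totals`
#'   (data frame).
#' @export
build_frequency_index <- function(corpus) {
  stopifnot(inherits(corpus, "narr_corpus"))
  if (nrow(corpus) == 0L) stop("empty corpus")
  decades <- sort(unique(corpus$decade))
  freq <- lapply(decades, function(d) {
    tab <- table(unlist(corpus$tokens[corpus$decade == d], use.names = FALSE))
    setNames(as.integer(tab), names(tab))
  })
  names(freq) <- as.character(decades)
  totals <- vapply(freq, sum, numeric(1))
  gt <- aggregate(n_tokens ~ decade + genre, data = as.data.frame(corpus)[c("decade", "genre", "n_tokens")], FUN = sum)
  names(gt)[names(gt) == "n_tokens"] <- "total"
  structure(list(freq = freq, totals = totals, genre_totals = gt),
            class = "token_index")
}

#' @export
print.token_index <- function(x, ...) {
  cat("<token_index> ", length(x$freq), " decade(s), ",
      format(sum(x$totals), big.mark = ","), " tokens\n", sep = "")
  invisible(x)
}

#' Flatten a token index to a (decade, token, count) data frame
#'
#' @param x A `token_index`.
#' @param row.names,optional,... Unused, for method compatibility.
#' @return A data frame with columns `decade`, `token`, `count`.
#' @export
as.data.frame.token_index <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(names(x$freq), function(d) {
    data.frame(decade = as.integer(d), token = names(x$freq[[d]]),
               count = as.integer(x$freq[[d]]), stringsAsFactors = FALSE)
  }))
}

index_count <- function(index, decade, token) {
  v <- index$freq[[as.character(decade)]][token]
  ifelse(is.na(v), 0L, v)
}

#' @export
print.narr_corpus <- function(x, ...) {
  cat("<narr_corpus> ", nrow(x), " documents, ", sum(x$n_tokens), " tokens, ",
      length(unique(x$decade)), " decade(s)\n", sep = "")
  invisible(x)
}
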