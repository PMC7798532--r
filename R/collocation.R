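#' Find concordance hits for target synonyms
#'
#' Scans every document for occurrences of the target terms (multiword terms
#' allowed). Candidate matches are resolved longest-match-first, left to
#' right, non-overlapping within a document. Each hit carries up to `window`
#' tokens of left and right context, excluding the node's own tokens and
#' never crossing a document boundary.
#'
#' @param corpus A `narr_corpus`.
#' @param synonyms Character vector of target terms (e.g. "elderly",
#'   "old people").
#' @param window Context width in tokens on each side (default 4).
#' @return A `concordance_hits` data frame: `doc_id`, `decade`, `genre`,
#'   `synonym`, `start`, `end` (1-based token positions) and list-columns
#'   `left`, `right`.
#' @export
find_hits <- function(corpus, synonyms, window = 4L) {
  stopifnot(inherits(corpus, "narr_corpus"), window >= 1)
  if (length(synonyms) == 0L) stop("empty synonym lexicon")
  syn_tokens <- lapply(synonyms, tokenize)
  if (any(vapply(syn_tokens, length, integer(1)) == 0L)) {
    stop("synonym tokenizes to nothing")
  }
  ord <- order(-vapply(syn_tokens, length, integer(1)), seq_along(synonyms))
  syn_tokens <- syn_tokens[ord]
  syn_canon <- vapply(syn_tokens, paste, character(1), collapse = " ")
  firsts <- unique(vapply(syn_tokens, `[`, character(1), 1L))

  rows <- vector("list", nrow(corpus))
  for (di in seq_len(nrow(corpus))) {
    toks <- corpus$tokens[[di]]
    n <- length(toks)
    cand <- which(toks %in% firsts)
    if (length(cand) == 0L) next
    starts <- integer(0); ends <- integer(0); which_syn <- integer(0)
    last_end <- 0L
    for (i in cand) {
      if (i <= last_end) next
      for (s in seq_along(syn_tokens)) {
        L <- length(syn_tokens[[s]])
        j <- i + L - 1L
        if (j <= n && all(toks[i:j] == syn_tokens[[s]])) {
          starts <- c(starts, i); ends <- c(ends, j); which_syn <- c(which_syn, s)
          last_end <- j
          break
        }
      }
    }
    if (length(starts) == 0L) next
    left <- lapply(seq_along(starts), function(k) {
      a <- max(1L, starts[k] - window)
      if (a > starts[k] - 1L) character(0) else toks[a:(starts[k] - 1L)]
    })
    right <- lapply(seq_along(starts), function(k) {
      b <- min(n, ends[k] + window)
      if (ends[k] + 1L > b) character(0) else toks[(ends[k] + 1L):b]
    })
    df <- data.frame(
      doc_id = corpus$doc_id[di], decade = corpus$decade[di],
      genre = corpus$genre[di], synonym = syn_canon[which_syn],
      start = starts, end = ends, stringsAsFactors = FALSE
    )
    df$left <- left
    df$right <- right
    rows[[di]] <- df
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    df <- data.frame(doc_id = character(0), decade = integer(0),
                     genre = character(0), synonym = character(0),
                     start = integer(0), end = integer(0),
                     stringsAsFactors = FALSE)
    df$left <- list(); df$right <- list()
    df
  }
  structure(out, class = c("concordance_hits", "data.frame"), window = window)
}

#' Mutual Information score of a windowed collocation
#'
#' The corpus-linguistics convention of the source-corpus interface:
#' `MI = log2( (f_joint * N) / (f_node * f_coll * W) )` in bits, where
#' `W` is the window span (8 for a +/-4-token window). `f_joint = 0` yields
#' `-Inf` (such records are never retained).
#'
#' @param f_joint Windowed co-occurrence count.
#' @param f_node Node (synonym) occurrence count in the decade.
#' @param f_coll Collocate frequency in the decade.
#' @param N Decade token total.
#' @param W Window span constant (default 8).
#' @return MI in bits (vectorized).
#' @export
mi_score <- function(f_joint, f_node, f_coll, N, W = 8) {
  if (any(f_node <= 0) || any(f_coll <= 0) || any(N <= 0) || any(W <= 0)) {
    stop("f_node, f_coll, N and W must all be positive")
  }
  ifelse(f_joint == 0, -Inf, log2((f_joint * N) / (f_node * f_coll * W)))
}

#' Count windowed collocates and score them by Mutual Information
#'
#' Aggregates hits into one record per (decade, synonym, collocate).
#' Every occurrence of a collocate in every window counts (slot counting:
#' a word appearing twice inside one window contributes 2 to `f_joint`).
#' Marginals come from the frequency index built on the same corpus.
#'
#' @param hits A `concordance_hits` object.
#' @param index A `token_index` built from the same corpus.
#' @return A `collocate_records` data frame: `decade`, `synonym`,
#'   `collocate`, `f_joint`, `f_node`, `f_coll`, `N`, `W`, `mi`.
#' @export
count_collocates <- function(hits, index) {
  stopifnot(inherits(hits, "concordance_hits"), inherits(index, "token_index"))
  window <- attr(hits, "window")
  W <- 2L * window
  if (nrow(hits) == 0L) {
    return(structure(
      data.frame(decade = integer(0), synonym = character(0),
                 collocate = character(0), f_joint = integer(0),
                 f_node = integer(0), f_coll = integer(0), N = numeric(0),
                 W = integer(0), mi = numeric(0), stringsAsFactors = FALSE),
      class = c("collocate_records", "data.frame")))
  }
  nwin <- vapply(seq_len(nrow(hits)),
                 function(i) length(hits$left[[i]]) + length(hits$right[[i]]),
                 integer(1))
  long <- data.frame(
    decade = rep(hits$decade, nwin),
    synonym = rep(hits$synonym, nwin),
    collocate = unlist(Map(c, hits$left, hits$right), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  key <- paste(long$decade, long$synonym, long$collocate, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  rec <- data.frame(
    decade = as.integer(vapply(parts, `[`, character(1), 1L)),
    synonym = vapply(parts, `[`, character(1), 2L),
    collocate = vapply(parts, `[`, character(1), 3L),
    f_joint = as.integer(tab),
    stringsAsFactors = FALSE
  )
  node_tab <- table(paste(hits$decade, hits$synonym, sep = "\r"))
  rec$f_node <- as.integer(node_tab[paste(rec$decade, rec$synonym, sep = "\r")])
  rec$f_coll <- NA_integer_
  for (d in unique(rec$decade)) {
    sel <- rec$decade == d
    v <- index$freq[[as.character(d)]][rec$collocate[sel]]
    if (anyNA(v)) {
      stop("collocate(s) absent from frequency index in decade ", d,
           " (corpus/index mismatch): ",
           paste(head(rec$collocate[sel][is.na(v)], 3), collapse = ", "))
    }
    rec$f_coll[sel] <- as.integer(v)
  }
  rec$N <- as.numeric(index$totals[as.character(rec$decade)])
  rec$W <- W
  rec$mi <- mi_score(rec$f_joint, rec$f_node, rec$f_coll, rec$N, rec$W)
  rownames(rec) <- NULL
  structure(rec, class = c("collocate_records", "data.frame"))
}

#' Apply the three inclusion criteria to collocate records
#'
#' Per (decade, synonym): rank candidates by `f_joint` descending (ties by
#' MI descending, then lexicographic), truncate to the `top_k` most frequent,
#' then drop records below the MI threshold, then drop excluded words (the
#' configurable stand-in for the human relevance check). The returned table
#' carries a logical `retained` column.
#'
#' @param records A `collocate_records` data frame.
#' @param top_k Frequency-rank cutoff per (decade, synonym) (default 100).
#' @param mi_min Minimum Mutual Information in bits (default 3).
#' @param exclusions Character vector of words to drop after filtering.
#' @return The input records, re-ordered deterministically, with `retained`
#'   set.
#' @export
select_collocates <- function(records, top_k = 100L, mi_min = 3,
                              exclusions = character(0)) {
  stopifnot(inherits(records, "collocate_records"))
  if (nrow(records) == 0L) {
    records$retained <- logical(0)
    return(records)
  }
  ord <- order(records$decade, records$synonym, -records$f_joint,
               -records$mi, records$collocate)
  records <- records[ord, , drop = FALSE]
  grp <- paste(records$decade, records$synonym, sep = "\r")
  rank_in_grp <- stats::ave(seq_len(nrow(records)), grp, FUN = seq_along)
  records$retained <- rank_in_grp <= top_k &
    records$mi >= mi_min &
    !(records$collocate %in% exclusions)
  rownames(records) <- NULL
  structure(records, class = c("collocate_records", "data.frame"))
}
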