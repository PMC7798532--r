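#' Century stratum of a year
#'
#' "1800s" covers 1810-1899, "1900s" covers 1900-2009 (the same partition
#' the decade statistics use), and "2000s" covers 2010-2019.
#'
#' @param year Integer vector of years.
#' @return Character vector of century labels.
#' @export
century_of <- function(year) {
  if (any(year < CORPUS_YEAR_MIN | year > CORPUS_YEAR_MAX)) {
    stop("year outside ", CORPUS_YEAR_MIN, "-", CORPUS_YEAR_MAX)
  }
  ifelse(year <= 1899, "1800s", ifelse(year <= 2009, "1900s", "2000s"))
}

century_of_decade <- function(decade) {
  ifelse(decade <= 8, "1800s", ifelse(decade <= 19, "1900s", "2000s"))
}

#' Build per-document collocate bags for one genre x century stratum
#'
#' For each source document in the stratum, collects the window tokens of
#' its concordance hits that are retained collocates of the matching
#' (decade, synonym) group (multiset: repeated window occurrences repeat in
#' the bag). Documents with fewer than `min_tokens` retained tokens are
#' dropped and counted.
#'
#' @param hits A `concordance_hits` table.
#' @param retained A `collocate_records` or `rated_collocates` table with
#'   retained rows (rows where `retained` is TRUE are used if the column is
#'   present).
#' @param genre Genre label.
#' @param century Century label ("1800s" or "1900s").
#' @param min_tokens Minimum bag size (default 3).
#' @return A `topic_corpus` list: `stratum`, `docs` (named list of character
#'   bags), `vocab`, `n_dropped`.
#' @export
build_topic_documents <- function(hits, retained, genre, century,
                                  min_tokens = 3L) {
  stopifnot(inherits(hits, "concordance_hits"))
  if ("retained" %in% names(retained)) {
    retained <- retained[retained$retained, , drop = FALSE]
  }
  sel <- hits$genre == genre & century_of_decade(hits$decade) == century
  if (!any(sel)) stop("empty stratum: ", genre, " ", century)
  h <- hits[sel, , drop = FALSE]
  keep_key <- paste(retained$decade, retained$synonym, retained$collocate,
                    sep = "\r")
  bags <- list()
  for (i in seq_len(nrow(h))) {
    win <- c(h$left[[i]], h$right[[i]])
    if (!length(win)) next
    kk <- paste(h$decade[i], h$synonym[i], win, sep = "\r")
    win <- win[kk %in% keep_key]
    if (!length(win)) next
    id <- h$doc_id[i]
    bags[[id]] <- c(bags[[id]], win)
  }
  hit_docs <- unique(h$doc_id)
  sizes <- setNames(integer(length(hit_docs)), hit_docs)
  sizes[names(bags)] <- vapply(bags, length, integer(1))
  n_dropped <- sum(sizes < min_tokens)
  bags <- bags[vapply(bags, length, integer(1)) >= min_tokens]
  structure(list(
    stratum = c(genre = genre, century = century),
    docs = bags,
    vocab = sort(unique(unlist(bags, use.names = FALSE))),
    n_dropped = n_dropped
  ), class = "topic_corpus")
}

#' Construct a topic corpus from raw bags
#'
#' @param bags Named list of character token bags.
#' @param stratum Optional stratum label.
#' @return A `topic_corpus`.
#' @export
as_topic_corpus <- function(bags, stratum = c(genre = NA, century = NA)) {
  stopifnot(is.list(bags), length(bags) > 0)
  structure(list(stratum = stratum, docs = bags,
                 vocab = sort(unique(unlist(bags, use.names = FALSE))),
                 n_dropped = 0L),
            class = "topic_corpus")
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Latent Dirichlet Allocation with symmetric Dirichlet priors: `alpha` on
#' document-topic mixtures (default 50/K) and `eta` on topic-word
#' distributions (default 0.01), the classical collapsed-Gibbs defaults.
#' Topic-word distributions `phi` and document-topic distributions `theta`
#' are estimated from the final sweep's counts with prior smoothing. The
#' sampler runs on R's RNG, so a fixed seed gives identical assignments.
#'
#' @param tc A `topic_corpus`.
#' @param K Number of topics (at most the vocabulary size).
#' @param alpha Document-topic concentration (default 50/K).
#' @param eta Topic-word concentration (default 0.01).
#' @param iters Gibbs sweeps (default 1000).
#' @param seed RNG seed (default 1).
#' @return A `topic_model` list: `K`, `phi` (K x V), `theta` (D x K), `z`,
#'   `vocab`, `doc_ids`, `alpha`, `eta`, `iters`, `seed`, `counts`.
#' @export
fit_lda <- function(tc, K, alpha = 50 / K, eta = 0.01, iters = 1000L,
                    seed = 1L) {
  stopifnot(inherits(tc, "topic_corpus"), K >= 1, iters >= 1)
  V <- length(tc$vocab)
  if (V == 0L) stop("empty topic corpus")
  if (K > V) stop("K (", K, ") exceeds vocabulary size (", V, ")")
  ids <- lapply(tc$docs, function(b) match(b, tc$vocab) - 1L)
  res <- withr::with_seed(seed,
    lda_gibbs_cpp(ids, V, as.integer(K), alpha, eta, as.integer(iters)))
  nkw <- res$nkw
  phi <- (nkw + eta) / (res$nk + V * eta)
  dimnames(phi) <- list(paste0("topic", seq_len(K)), tc$vocab)
  nd <- vapply(tc$docs, length, integer(1))
  theta <- (res$ndk + alpha) / (nd + K * alpha)
  dimnames(theta) <- list(names(tc$docs), paste0("topic", seq_len(K)))
  structure(list(
    K = as.integer(K), phi = phi, theta = theta, z = res$z,
    vocab = tc$vocab, doc_ids = names(tc$docs), alpha = alpha, eta = eta,
    iters = as.integer(iters), seed = as.integer(seed),
    counts = list(nkw = nkw, nk = as.integer(res$nk), ndk = res$ndk)
  ), class = "topic_model")
}

#' Highest-probability words of a topic
#'
#' @param model A `topic_model`.
#' @param topic Topic index (1-based).
#' @param n Number of words; ties broken lexicographically.
#' @return Character vector of `n` words.
#' @export
top_words <- function(model, topic, n = 10L) {
  stopifnot(inherits(model, "topic_model"), topic >= 1, topic <= model$K)
  if (n > length(model$vocab)) stop("n exceeds vocabulary size")
  if (n == 0L) return(character(0))
  p <- model$phi[topic, ]
  model$vocab[order(-p, model$vocab)][seq_len(n)]
}

#' In-sample log-likelihood of a fitted topic model
#'
#' Sum over tokens of `log( sum_k theta_dk * phi_kw )`; finite for any
#' fitted model because of prior smoothing.
#'
#' @param model A `topic_model`.
#' @param tc The `topic_corpus` it was fitted to.
#' @return A finite negative number.
#' @export
lda_log_likelihood <- function(model, tc) {
  stopifnot(inherits(model, "topic_model"), inherits(tc, "topic_corpus"))
  ll <- 0
  for (d in seq_along(tc$docs)) {
    wi <- match(tc$docs[[d]], model$vocab)
    pw <- as.numeric(model$theta[d, , drop = FALSE] %*% model$phi[, wi, drop = FALSE])
    ll <- ll + sum(log(pw))
  }
  ll
}

#' Mean top-n recall of fitted topics against planted word sets
#'
#' Matches fitted topics to planted vocabularies by the assignment (over
#' permutations for small K, greedy otherwise) that maximizes total overlap
#' between each topic's top-`n` words and a planted set, then averages
#' `|top_n intersect planted| / n` across topics.
#'
#' @param model A `topic_model`.
#' @param truth_sets List of planted word sets (length `model$K` or fewer).
#' @param n Top-word depth (default 10).
#' @return Mean recall in `[0, 1]`.
#' @export
topic_recall <- function(model, truth_sets, n = 10L) {
  K <- model$K
  Kt <- length(truth_sets)
  tops <- lapply(seq_len(K), function(k) top_words(model, k, min(n, length(model$vocab))))
  ov <- matrix(0, K, Kt)
  for (k in seq_len(K)) for (t in seq_len(Kt)) {
    ov[k, t] <- length(intersect(tops[[k]], truth_sets[[t]]))
  }
  if (Kt <= 6 && K == Kt) {
    perms <- permute_all(Kt)
    best <- max(vapply(perms, function(pr) sum(ov[cbind(seq_len(K), pr)]), numeric(1)))
  } else {
    best <- 0
    avail_k <- seq_len(K); avail_t <- seq_len(Kt)
    for (step in seq_len(min(K, Kt))) {
      m <- ov[avail_k, avail_t, drop = FALSE]
      ij <- which(m == max(m), arr.ind = TRUE)[1, ]
      best <- best + m[ij[1], ij[2]]
      avail_k <- avail_k[-ij[1]]; avail_t <- avail_t[-ij[2]]
    }
  }
  best / (min(K, Kt) * n)
}

permute_all <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permute_all(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Flatten a topic model to a (topic, rank, word, probability) table
#'
#' @param model A `topic_model`.
#' @param n_words Words per topic (default 10).
#' @return A data frame ready for CSV export.
#' @export
topic_table <- function(model, n_words = 10L) {
  n_words <- min(n_words, length(model$vocab))
  do.call(rbind, lapply(seq_len(model$K), function(k) {
    ws <- top_words(model, k, n_words)
    data.frame(topic = k, rank = seq_along(ws), word = ws,
               probability = as.numeric(model$phi[k, ws]),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.topic_model <- function(x, ...) {
  cat("<topic_model> K =", x$K, "| V =", length(x$vocab),
      "| docs =", nrow(x$theta), "| iters =", x$iters, "\n")
  for (k in seq_len(x$K)) {
    cat(sprintf("  topic %d: %s\n", k,
                paste(top_words(x, k, min(8L, length(x$vocab))), collapse = ", ")))
  }
  invisible(x)
}
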