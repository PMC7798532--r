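# Independent brute-force oracles, deliberately written in a different
# style from the package internals (plain nested loops, environment-keyed
# counters), plus small fixture builders.

# O(n * W) windowed co-occurrence scan: returns joint counts, node counts
# and per-decade token frequencies, all keyed by strings.
oracle_collocates <- function(corpus, synonyms, window = 4) {
  syn_tok <- lapply(synonyms, agenarr::tokenize)
  ord <- order(-vapply(syn_tok, length, integer(1)), seq_along(syn_tok))
  syn_tok <- syn_tok[ord]
  syn_lab <- vapply(syn_tok, paste, character(1), collapse = " ")
  joint <- new.env(parent = emptyenv())
  nodes <- new.env(parent = emptyenv())
  freq <- new.env(parent = emptyenv())
  totals <- new.env(parent = emptyenv())
  bump <- function(env, key, by = 1) {
    assign(key, (if (exists(key, env)) get(key, env) else 0) + by, env)
  }
  for (i in seq_len(nrow(corpus))) {
    toks <- corpus$tokens[[i]]
    d <- as.character(corpus$decade[i])
    for (tk in toks) bump(freq, paste(d, tk))
    bump(totals, d, length(toks))
    pos <- 1L
    n <- length(toks)
    while (pos <= n) {
      hit <- 0L
      for (s in seq_along(syn_tok)) {
        L <- length(syn_tok[[s]])
        if (pos + L - 1L <= n && identical(toks[pos:(pos + L - 1L)], syn_tok[[s]])) {
          hit <- s
          break
        }
      }
      if (hit == 0L) {
        pos <- pos + 1L
        next
      }
      L <- length(syn_tok[[hit]])
      bump(nodes, paste(d, syn_lab[hit]))
      for (q in seq(max(1L, pos - window), min(n, pos + L - 1L + window))) {
        if (q >= pos && q <= pos + L - 1L) next
        bump(joint, paste(d, syn_lab[hit], toks[q]))
      }
      pos <- pos + L
    }
  }
  list(joint = joint, nodes = nodes, freq = freq, totals = totals)
}

# MI recomputed from the oracle's own counts
oracle_mi <- function(orc, decade, synonym, collocate, W = 8) {
  d <- as.character(decade)
  fj <- get(paste(d, synonym, collocate), orc$joint)
  fn <- get(paste(d, synonym), orc$nodes)
  fc <- get(paste(d, collocate), orc$freq)
  N <- get(d, orc$totals)
  log2((fj * N) / (fn * fc * W))
}

# random corpus with scattered (multiword) synonym mentions
random_corpus <- function(seed, n_docs = 8, max_len = 250,
                          synonyms = c("aged", "old people", "elderly")) {
  vocab <- c("the", "a", "man", "woman", "frail", "wise", "sat", "home",
             "care", "health", "war", "honor", "sick", "poor", "old",
             "people", "house", "town", "letter", "friend")
  withr::with_seed(seed, {
    df <- data.frame(
      doc_id = paste0("r", seed, "_", seq_len(n_docs)),
      year = sample(1810:2019, n_docs, replace = TRUE),
      genre = sample(c("newspaper", "magazine", "fiction", "nonfiction"),
                     n_docs, replace = TRUE),
      stringsAsFactors = FALSE
    )
    df$tokens <- lapply(seq_len(n_docs), function(j) {
      toks <- sample(vocab, sample(30:max_len, 1), replace = TRUE)
      for (k in seq_len(sample(1:6, 1))) {
        syn <- agenarr::tokenize(sample(synonyms, 1))
        p <- sample(seq_len(length(toks) - length(syn)), 1)
        toks <- append(toks, syn, after = p)
      }
      toks
    })
    agenarr::as_corpus(df)
  })
}

# every pipeline record must match the brute-force scan exactly, and the
# scan must contain no pair the pipeline missed
expect_matches_oracle <- function(corpus, synonyms, window = 4) {
  orc <- oracle_collocates(corpus, synonyms, window)
  idx <- agenarr::build_frequency_index(corpus)
  hits <- agenarr::find_hits(corpus, synonyms, window)
  rec <- agenarr::count_collocates(hits, idx)
  oracle_keys <- ls(orc$joint)
  rec_keys <- paste(rec$decade, rec$synonym, rec$collocate)
  expect_setequal(rec_keys, oracle_keys)
  fj_oracle <- vapply(rec_keys, function(k) get(k, orc$joint), numeric(1))
  expect_identical(as.numeric(rec$f_joint), unname(fj_oracle))
  mi_oracle <- mapply(oracle_mi, decade = rec$decade, synonym = rec$synonym,
                      collocate = rec$collocate,
                      MoreArgs = list(orc = orc, W = 2 * window))
  expect_lt(max(abs(rec$mi - mi_oracle)), 1e-9)
  invisible(rec)
}

# independent weighted-mean CANS recomputation from a scores table
oracle_cans <- function(scores) {
  out <- numeric(0)
  for (d in sort(unique(scores$decade))) {
    num <- 0
    den <- 0
    for (i in seq_len(nrow(scores))) {
      if (scores$decade[i] == d) {
        num <- num + scores$w[i] * scores$mean_sentiment[i]
        den <- den + scores$w[i]
      }
    }
    out[as.character(d)] <- num / den
  }
  out
}

# minimal constructors for hand-built fixtures
make_records <- function(df) {
  structure(df, class = c("collocate_records", "data.frame"))
}

make_rated <- function(df) {
  structure(df, class = c("rated_collocates", "data.frame"))
}

make_scores <- function(df) {
  structure(df, class = c("synonym_decade_scores", "data.frame"))
}

quiet_ratings <- function(...) {
  suppressWarnings(suppressMessages(agenarr::apply_ratings(...)))
}

# one full synthetic pipeline pass: corpus -> CANS series
run_cans_pipeline <- function(spec) {
  gen <- agenarr::generate_corpus(spec)
  idx <- agenarr::build_frequency_index(gen$corpus)
  hits <- agenarr::find_hits(gen$corpus, spec$synonyms)
  rec <- agenarr::select_collocates(agenarr::count_collocates(hits, idx))
  rated <- quiet_ratings(rec, gen$lexicons)
  list(cans = agenarr::compute_cans(agenarr::synonym_decade_means(rated)),
       gen = gen, rated = rated)
}
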