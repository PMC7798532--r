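#' Specification for the synthetic corpus generator
#'
#' Describes a decade/genre-tagged corpus with planted structure: every
#' synonym mention is flanked (within the +/-4-token window) by collocates
#' drawn from three disjoint sentiment strata (true values 1 / 3 / 5) whose
#' mixture is solved per decade so that the expected sentiment of a rated
#' flanking collocate in decade `d` is exactly `b0 + drift * d`. A share of
#' the neutral draws comes from the document's planted (genre, century)
#' topic vocabulary (topic words carry true sentiment 3, so topic planting
#' never perturbs the expected score). Background filler words surround the
#' mentions; they are deliberately absent from the rating lexicons and are
#' rejected by the MI filter in all but borderline cases.
#'
#' @param n_decades Number of decades starting at 1810 (default 21).
#' @param genres Genre labels (default the four standard genres).
#' @param docs_per_decade_genre Documents per (decade, genre) cell.
#' @param synonyms Target terms (default the six bundled terms).
#' @param mentions_per_doc Synonym mentions per document.
#' @param collocates_per_mention Planted flanking collocates per mention
#'   (even; half on each side, all inside the window).
#' @param b0 Expected collocate sentiment in the 1810s (decade 0).
#' @param drift Planted change in expected sentiment per decade.
#' @param stratum_sizes Named sizes of the negative/neutral/positive
#'   vocabularies.
#' @param p_neutral Fixed probability mass of neutral-valued draws.
#' @param topic_share Fraction of neutral draws taken from the document's
#'   planted topic vocabulary.
#' @param n_topics_per_stratum Planted topics per (genre, century).
#' @param topic_vocab_size Words per planted topic.
#' @param background_vocab_size Background filler vocabulary size.
#' @param gap_tokens Background tokens between consecutive mentions.
#' @param rater_noise_sd SD of simulated rater noise (0 = perfect raters).
#' @param n_raters Number of simulated raters (>= 2).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(n_decades = 21L,
                           genres = CORPUS_GENRES,
                           docs_per_decade_genre = 2L,
                           synonyms = default_synonyms(),
                           mentions_per_doc = 6L,
                           collocates_per_mention = 4L,
                           b0 = 3.08,
                           drift = -0.0068,
                           stratum_sizes = c(negative = 60L, neutral = 60L, positive = 60L),
                           p_neutral = 0.2,
                           topic_share = 0.5,
                           n_topics_per_stratum = 2L,
                           topic_vocab_size = 10L,
                           background_vocab_size = 100L,
                           gap_tokens = 80L,
                           rater_noise_sd = 0.24,
                           n_raters = 2L,
                           seed = 1L) {
  spec <- list(
    n_decades = as.integer(n_decades), genres = genres,
    docs_per_decade_genre = as.integer(docs_per_decade_genre),
    synonyms = synonyms, mentions_per_doc = as.integer(mentions_per_doc),
    collocates_per_mention = as.integer(collocates_per_mention),
    b0 = b0, drift = drift, stratum_sizes = stratum_sizes,
    p_neutral = p_neutral, topic_share = topic_share,
    n_topics_per_stratum = as.integer(n_topics_per_stratum),
    topic_vocab_size = as.integer(topic_vocab_size),
    background_vocab_size = as.integer(background_vocab_size),
    gap_tokens = as.integer(gap_tokens),
    rater_noise_sd = rater_noise_sd, n_raters = as.integer(n_raters),
    seed = as.integer(seed)
  )
  stopifnot(spec$n_decades >= 1, spec$n_decades <= 21,
            spec$docs_per_decade_genre >= 1, spec$mentions_per_doc >= 1,
            spec$collocates_per_mention >= 2,
            spec$collocates_per_mention %% 2 == 0,
            spec$collocates_per_mention <= 8,
            spec$p_neutral > 0, spec$p_neutral < 1,
            spec$topic_share >= 0, spec$topic_share <= 1,
            spec$rater_noise_sd >= 0, spec$n_raters >= 2,
            all(spec$stratum_sizes >= 1), length(spec$synonyms) >= 1)
  m <- expected_cans_values(spec)
  lo <- 1 + 2 * spec$p_neutral
  hi <- 5 - 2 * spec$p_neutral
  if (any(m < lo - 1e-12 | m > hi + 1e-12)) {
    stop(sprintf(
      "infeasible expected sentiment: b0 + drift*d must stay in [%.3f, %.3f] for p_neutral = %.2f",
      lo, hi, spec$p_neutral))
  }
  if (any(m < 1 | m > 5)) stop("expected sentiment leaves [1, 5]")
  structure(spec, class = "generator_spec")
}

#' The bundled target-synonym lexicon
#'
#' The six documented "older adult" terms shipped with the package; users
#' extend the list via their own lexicon file.
#'
#' @return Character vector of terms.
#' @export
default_synonyms <- function() {
  path <- system.file("extdata", "synonyms.txt", package = "agenarr")
  if (nzchar(path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    c("aged", "elderly", "old people", "senior citizen", "older adult",
      "golden ager")
  }
}

#' Analytic expected CANS of a generator spec
#'
#' The affine ground truth `b0 + drift * d` for `d = 0 .. n_decades - 1`:
#' the expected consensus sentiment of a rated flanking collocate in each
#' decade, hence the expectation of the empirical CANS.
#'
#' @param spec A `generator_spec`.
#' @return Numeric vector of length `n_decades`.
#' @export
expected_cans <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  expected_cans_values(spec)
}

expected_cans_values <- function(spec) {
  spec$b0 + spec$drift * (seq_len(spec$n_decades) - 1)
}

# deterministic pseudo-word factory: consonant-vowel syllable triples,
# sequential and therefore collision-free across slices
make_words <- function(n, offset = 0L) {
  cons <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vows, paste0))
  ns <- length(syl)
  idx <- offset + seq_len(n) - 1L
  paste0(syl[(idx %/% (ns * ns)) %% ns + 1L],
         syl[(idx %/% ns) %% ns + 1L],
         syl[idx %% ns + 1L])
}

# vocabulary layout is purely positional, hence identical for every call
# with the same spec
build_vocab <- function(spec) {
  sz <- spec$stratum_sizes
  centuries <- unique(century_of_decade(seq_len(spec$n_decades) - 1L))
  n_topic_strata <- length(spec$genres) * length(centuries)
  n_topic_words <- n_topic_strata * spec$n_topics_per_stratum * spec$topic_vocab_size
  off <- 0L
  background <- make_words(spec$background_vocab_size, off)
  off <- off + spec$background_vocab_size
  negative <- make_words(sz[["negative"]], off); off <- off + sz[["negative"]]
  neutral <- make_words(sz[["neutral"]], off); off <- off + sz[["neutral"]]
  positive <- make_words(sz[["positive"]], off); off <- off + sz[["positive"]]
  topic_words <- make_words(n_topic_words, off)
  syn_toks <- unique(unlist(lapply(spec$synonyms, tokenize)))
  if (any(syn_toks %in% c(background, negative, neutral, positive, topic_words))) {
    stop("synonym token collides with generated vocabulary")
  }
  topics <- list()
  i <- 0L
  for (g in spec$genres) for (ct in centuries) {
    key <- paste(g, ct, sep = "|")
    topics[[key]] <- lapply(seq_len(spec$n_topics_per_stratum), function(t) {
      ws <- topic_words[i + (t - 1L) * spec$topic_vocab_size +
                          seq_len(spec$topic_vocab_size)]
      ws
    })
    i <- i + spec$n_topics_per_stratum * spec$topic_vocab_size
  }
  list(background = background, negative = negative, neutral = neutral,
       positive = positive, topics = topics)
}

# per-decade stratum mixture solving E[value] = m with values (1, 3, 5)
stratum_probs <- function(m, p_neutral) {
  p5 <- (m - 1 - 2 * p_neutral) / 4
  p1 <- 1 - p_neutral - p5
  if (p5 < -1e-12 || p1 < -1e-12) stop("infeasible expected sentiment ", m)
  c(negative = max(p1, 0), neutral = p_neutral, positive = max(p5, 0))
}

#' Simulated multi-rater rating lexicons with known truth
#'
#' Every stratum word carries a true value per dimension: sentiment 1
#' (negative stratum), 3 (neutral stratum and planted topic words) or 5
#' (positive stratum); status, warmth and competence are coupled to
#' sentiment; medicalization and ostracism are per-word binaries more
#' prevalent in the negative stratum. Each simulated rater reports the true
#' value plus rounded Gaussian noise (`rater_noise_sd`), clipped to the
#' dimension's range; binary dimensions flip when the noise crosses 0.5.
#' With `rater_noise_sd = 0` all raters reproduce the truth exactly.
#'
#' @param spec A `generator_spec`.
#' @return List: `lexicons` (a long `rating_lexicon` over all raters) and
#'   `truth` (data frame of true per-word values with a `stratum` column).
#' @export
make_rating_lexicons <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  vocab <- build_vocab(spec)
  topic_words <- unique(unlist(vocab$topics, use.names = FALSE))
  words <- c(vocab$negative, vocab$neutral, vocab$positive, topic_words)
  stratum <- c(rep("negative", length(vocab$negative)),
               rep("neutral", length(vocab$neutral)),
               rep("positive", length(vocab$positive)),
               rep("topic", length(topic_words)))
  sent <- c(negative = 1, neutral = 3, positive = 5, topic = 3)[stratum]
  truth <- withr::with_seed(spec$seed + 1000L, {
    data.frame(
      word = words, stratum = stratum, sentiment = as.numeric(sent),
      status = pmin(3, pmax(1, 1 + (sent - 1) / 2)),
      warmth = as.numeric(sent),
      competence = as.numeric(sent),
      medicalization = rbinom(length(words), 1,
                              ifelse(stratum == "negative", 0.6, 0.1)),
      ostracism = rbinom(length(words), 1,
                         ifelse(stratum == "negative", 0.4, 0.1)),
      stringsAsFactors = FALSE
    )
  })
  rng <- dimension_ranges()
  dims <- names(rng)
  binary <- c("medicalization", "ostracism")
  lex <- withr::with_seed(spec$seed + 2000L, {
    rows <- lapply(seq_len(spec$n_raters), function(r) {
      do.call(rbind, lapply(dims, function(dm) {
        tv <- truth[[dm]]
        v <- if (spec$rater_noise_sd == 0) {
          tv
        } else if (dm %in% binary) {
          flip <- abs(rnorm(length(tv), 0, spec$rater_noise_sd)) > 0.5
          ifelse(flip, 1 - tv, tv)
        } else {
          pmin(rng[[dm]][2], pmax(rng[[dm]][1],
               round(tv + rnorm(length(tv), 0, spec$rater_noise_sd))))
        }
        data.frame(word = truth$word, rater_id = paste0("rater", r),
                   dimension = dm, value = as.numeric(v),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  list(lexicons = as_rating_lexicon(lex), truth = truth)
}

#' Generate a synthetic decade/genre-tagged corpus with planted drift
#'
#' Emits `n_decades x length(genres) x docs_per_decade_genre` documents.
#' Each document is a sequence of background filler blocks and synonym
#' mentions; each mention is flanked by planted collocates (half left, half
#' right, inside the +/-4 window) drawn from the decade's sentiment-stratum
#' mixture, with a share of neutral draws replaced by the document's
#' planted (genre, century) topic words. Deterministic under `spec$seed`.
#'
#' @param spec A `generator_spec`.
#' @return List: `corpus` (a `narr_corpus`), `truth` (expected CANS,
#'   planted slope, topic word sets, true ratings), `lexicons` (the
#'   simulated `rating_lexicon`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  vocab <- build_vocab(spec)
  ratings <- make_rating_lexicons(spec)
  m <- expected_cans_values(spec)
  half <- spec$collocates_per_mention %/% 2L
  strata_vocab <- list(negative = vocab$negative, neutral = vocab$neutral,
                       positive = vocab$positive)
  docs <- withr::with_seed(spec$seed, {
    out <- vector("list", spec$n_decades * length(spec$genres) *
                    spec$docs_per_decade_genre)
    di <- 0L
    for (d in seq_len(spec$n_decades) - 1L) {
      pr <- stratum_probs(m[d + 1], spec$p_neutral)
      century <- century_of_decade(d)
      for (g in spec$genres) {
        topics_gc <- vocab$topics[[paste(g, century, sep = "|")]]
        for (j in seq_len(spec$docs_per_decade_genre)) {
          di <- di + 1L
          year <- 1810L + 10L * d + sample.int(10L, 1L) - 1L
          topic_vocab <- topics_gc[[sample.int(length(topics_gc), 1L)]]
          draw_colls <- function(n) {
            u <- runif(n)
            vapply(u, function(ui) {
              if (ui < pr[["negative"]]) {
                sample(strata_vocab$negative, 1L)
              } else if (ui < pr[["negative"]] + pr[["neutral"]]) {
                if (runif(1) < spec$topic_share) {
                  sample(topic_vocab, 1L)
                } else {
                  sample(strata_vocab$neutral, 1L)
                }
              } else {
                sample(strata_vocab$positive, 1L)
              }
            }, character(1))
          }
          toks <- character(0)
          for (mn in seq_len(spec$mentions_per_doc)) {
            gap <- sample(vocab$background, spec$gap_tokens, replace = TRUE)
            syn <- spec$synonyms[[sample.int(length(spec$synonyms), 1L)]]
            toks <- c(toks, gap, draw_colls(half), tokenize(syn),
                      draw_colls(half))
          }
          toks <- c(toks, sample(vocab$background, spec$gap_tokens,
                                 replace = TRUE))
          df <- data.frame(
            doc_id = sprintf("d%02d_%s_%02d", d, g, j),
            year = year, genre = g, stringsAsFactors = FALSE
          )
          df$tokens <- list(toks)
          out[[di]] <- df
        }
      }
    }
    do.call(rbind, out)
  })
  corpus <- as_corpus(docs)
  truth <- list(
    expected_cans = m,
    true_slope = spec$drift,
    true_intercept = spec$b0,
    true_topic_sets = vocab$topics,
    true_ratings = ratings$truth
  )
  list(corpus = corpus, truth = truth, lexicons = ratings$lexicons)
}

#' Simulate document bags with planted disjoint-vocabulary topics
#'
#' Each document draws one planted topic and fills `tokens_per_doc` slots
#' from that topic's vocabulary with probability `purity`, otherwise from
#' the pooled vocabulary — a direct recovery instrument for the LDA fitter.
#'
#' @param K Number of planted topics.
#' @param n_docs Number of documents.
#' @param vocab_size Words per planted topic (disjoint across topics).
#' @param tokens_per_doc Bag size.
#' @param purity Probability a token comes from the document's own topic.
#' @param seed RNG seed.
#' @return List: `tc` (a `topic_corpus`) and `truth_sets` (the planted word
#'   sets).
#' @export
simulate_topic_corpus <- function(K = 2L, n_docs = 200L, vocab_size = 10L,
                                  tokens_per_doc = 30L, purity = 0.9,
                                  seed = 1L) {
  stopifnot(K >= 1, n_docs >= 1, purity >= 0, purity <= 1)
  sets <- lapply(seq_len(K), function(t) {
    make_words(vocab_size, offset = 100000L + (t - 1L) * vocab_size)
  })
  all_words <- unlist(sets)
  bags <- withr::with_seed(seed, {
    lapply(seq_len(n_docs), function(j) {
      t <- ((j - 1L) %% K) + 1L
      own <- runif(tokens_per_doc) < purity
      ifelse(own, sample(sets[[t]], tokens_per_doc, replace = TRUE),
             sample(all_words, tokens_per_doc, replace = TRUE))
    })
  })
  names(bags) <- sprintf("doc%04d", seq_len(n_docs))
  list(tc = as_topic_corpus(bags), truth_sets = sets)
}

#' Simulate a predictor table with planted fixed effects
#'
#' Builds an (n_synonyms x n_decades) table whose outcome follows
#' `intercept + X beta + u_decade + noise` with known coefficients for the
#' five sociological predictors, a Gaussian random intercept per decade and
#' Gaussian residuals — the recovery instrument for the mixed model.
#'
#' @param n_synonyms Number of synonyms (default 11).
#' @param n_decades Number of decades (default 21).
#' @param beta Named coefficients for status, warmth, competence,
#'   medicalization, ostracism.
#' @param intercept Fixed intercept.
#' @param sd_decade SD of the decade random intercept.
#' @param sd_resid Residual SD.
#' @param seed RNG seed.
#' @return List: `table` (a `predictor_table`) and `truth` (the planted
#'   parameters, including the realized decade effects `u`).
#' @export
simulate_predictor_table <- function(n_synonyms = 11L, n_decades = 21L,
                                     beta = c(status = 0.68, warmth = 0.37,
                                              competence = 0.44,
                                              medicalization = -1.26,
                                              ostracism = -0.79),
                                     intercept = 0, sd_decade = 0.05,
                                     sd_resid = 0.1, seed = 1L) {
  stopifnot(all(PREDICTOR_DIMS %in% names(beta)), n_synonyms >= 2,
            n_decades >= 2)
  withr::with_seed(seed, {
    n <- n_synonyms * n_decades
    tab <- data.frame(
      synonym = rep(sprintf("syn%02d", seq_len(n_synonyms)), times = n_decades),
      decade = rep(seq_len(n_decades) - 1L, each = n_synonyms),
      status = runif(n, 1, 3), warmth = runif(n, 1, 5),
      competence = runif(n, 1, 5), medicalization = runif(n, 0, 1),
      ostracism = runif(n, 0, 1), stringsAsFactors = FALSE
    )
    u <- rnorm(n_decades, 0, sd_decade)
    X <- as.matrix(tab[PREDICTOR_DIMS])
    tab$outcome <- intercept + as.numeric(X %*% beta[PREDICTOR_DIMS]) +
      u[tab$decade + 1L] + rnorm(n, 0, sd_resid)
    tab$w <- 1
    tab$n_collocates <- 1L
    list(table = as_predictor_table(tab),
         truth = list(beta = beta[PREDICTOR_DIMS], intercept = intercept,
                      sd_decade = sd_decade, sd_resid = sd_resid, u = u))
  })
}

#' Write a complete synthetic study dataset to disk
#'
#' Generates a corpus, its rating lexicon and ground truth under one seed
#' and writes `corpus.jsonl`, `rating_lexicon.csv`, `synonyms.txt` and
#' `ground_truth.json` into `out_dir` — the on-disk inputs for a full
#' pipeline run.
#'
#' @param spec A `generator_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
simulate_study_data <- function(spec, out_dir) {
  stopifnot(inherits(spec, "generator_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_corpus(spec)
  paths <- c(
    corpus = file.path(out_dir, "corpus.jsonl"),
    lexicon = file.path(out_dir, "rating_lexicon.csv"),
    synonyms = file.path(out_dir, "synonyms.txt"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_corpus(gen$corpus, paths[["corpus"]])
  write.csv(gen$lexicons, paths[["lexicon"]], row.names = FALSE)
  writeLines(spec$synonyms, paths[["synonyms"]])
  jsonlite::write_json(
    list(expected_cans = gen$truth$expected_cans,
         true_slope = gen$truth$true_slope,
         true_intercept = gen$truth$true_intercept,
         true_topic_sets = gen$truth$true_topic_sets,
         true_ratings = gen$truth$true_ratings),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
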