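small_corpus <- function(texts, years = NULL, genres = "fiction") {
  n <- length(texts)
  as_corpus(data.frame(
    doc_id = paste0("t", seq_len(n)),
    year = if (is.null(years)) rep(1900, n) else years,
    genre = rep_len(genres, n), text = texts, stringsAsFactors = FALSE
  ))
}

test_that("concordance windows truncate at document boundaries", {
  cp <- small_corpus("the frail old man sat")
  h <- find_hits(cp, "old man")
  expect_equal(nrow(h), 1)
  expect_identical(h$left[[1]], c("the", "frail"))
  expect_identical(h$right[[1]], "sat")
  expect_identical(h$synonym, "old man")

  h0 <- find_hits(cp, "the")
  expect_identical(h0$left[[1]], character(0))
  expect_identical(h0$right[[1]], c("frail", "old", "man", "sat"))
})

test_that("multiword synonyms match longest-first, left-to-right, non-overlapping", {
  cp <- small_corpus("see the old people of the town")
  h <- find_hits(cp, c("aged", "old people", "people"))
  expect_equal(nrow(h), 1)
  expect_identical(h$synonym, "old people")

  # non-overlap: the second "old" cannot start inside the first match
  cp2 <- small_corpus("old people old people stay")
  h2 <- find_hits(cp2, c("old people"))
  expect_equal(nrow(h2), 2)
  expect_identical(h2$start, c(1L, 3L))
  expect_error(find_hits(cp, character(0)), "empty synonym lexicon")
})

test_that("windowed collocate counting uses slot counting with index marginals", {
  cp <- small_corpus(c("frail aged man", "the frail aged one"))
  idx <- build_frequency_index(cp)
  h <- find_hits(cp, "aged")
  rec <- count_collocates(h, idx)
  frail <- rec[rec$collocate == "frail", ]
  expect_equal(frail$f_joint, 2L)
  expect_equal(frail$f_node, 2L)
  expect_equal(frail$f_coll, 2L)
  expect_equal(frail$N, 7)

  # a collocate occurring twice inside one window contributes twice
  cp2 <- small_corpus("frail frail aged")
  rec2 <- count_collocates(find_hits(cp2, "aged"), build_frequency_index(cp2))
  expect_equal(rec2$f_joint[rec2$collocate == "frail"], 2L)
})

test_that("MI follows the windowed pointwise formula in bits", {
  # direct evaluation: (10 * 100000) / (100 * 200 * 8) = 6.25
  expect_equal(mi_score(10, 100, 200, 1e5, 8), log2(6.25))
  expect_equal(mi_score(10, 100, 200, 1e5, 8), 2.643856, tolerance = 1e-6)
  # independence point: f_joint = f_node * f_coll * W / N
  expect_equal(mi_score(16, 10, 20, 100, 8), 0)
  # doubling the joint count adds exactly one bit
  expect_equal(mi_score(20, 100, 200, 1e5, 8) - mi_score(10, 100, 200, 1e5, 8), 1)
  # scaling N and f_coll together leaves MI unchanged
  expect_equal(mi_score(7, 13, 50, 4000, 8), mi_score(7, 13, 500, 40000, 8))
  expect_identical(mi_score(0, 10, 10, 100, 8), -Inf)
  expect_error(mi_score(1, 0, 10, 100, 8), "positive")
})

test_that("a controlled corpus reproduces the formula through the full counting path", {
  # doc1: one "aged" mention with "frail" adjacent, 102 pad tokens;
  # doc2 (same decade): three bare "frail" occurrences raising the marginal
  filler <- paste(rep("pad", 102), collapse = " ")
  cp <- small_corpus(c(paste("frail aged", filler), "frail frail frail"))
  idx <- build_frequency_index(cp)
  rec <- count_collocates(find_hits(cp, "aged"), idx)
  frail <- rec[rec$collocate == "frail", ]
  expect_equal(frail$f_joint, 1L)
  expect_equal(frail$f_node, 1L)
  expect_equal(frail$f_coll, 4L)
  expect_equal(frail$N, 107)
  expect_equal(frail$mi, log2((1 * 107) / (1 * 4 * 8)))
})

test_that("pipeline counts and MI match the brute-force scan exactly", {
  for (seed in 1:6) {
    cp <- random_corpus(seed)
    expect_matches_oracle(cp, c("aged", "old people", "elderly"))
  }
})

test_that("inclusion filtering ranks, truncates, thresholds and excludes in order", {
  # 150 candidates in one (decade, synonym) group; MI >= 3 for 40 of the
  # top-100 by construction
  n <- 150
  df <- data.frame(
    decade = 0L, synonym = "aged", collocate = sprintf("w%03d", seq_len(n)),
    f_joint = rep(c(9L, 5L, 2L), times = c(40, 60, 50)),
    f_node = 10L, f_coll = 20L, N = 2000, W = 8L,
    stringsAsFactors = FALSE
  )
  df$mi <- mi_score(df$f_joint, df$f_node, df$f_coll, df$N, df$W)
  # f_joint 9 -> MI = log2(9*2000/1600) = 3.49; 5 -> 2.64; 2 -> 1.32
  sel <- select_collocates(make_records(df), top_k = 100, mi_min = 3)
  expect_equal(sum(sel$retained), 40)
  expect_true(all(sel$mi[sel$retained] >= 3))
  # all below threshold -> nothing retained
  sel0 <- select_collocates(make_records(df), top_k = 100, mi_min = 4)
  expect_equal(sum(sel0$retained), 0)
  # exclusions remove the node-echo collocate after filtering
  df2 <- df
  df2$collocate[1] <- "old"
  sel2 <- select_collocates(make_records(df2), exclusions = "old")
  expect_false(any(sel2$collocate[sel2$retained] == "old"))
  expect_equal(sum(sel2$retained), 39)
})

test_that("filtering is deterministic, ordered, and returns a subset", {
  withr::with_seed(42, {
    df <- data.frame(
      decade = sample(0:2, 80, replace = TRUE),
      synonym = sample(c("aged", "elderly"), 80, replace = TRUE),
      collocate = sample(sprintf("c%02d", 1:30), 80, replace = TRUE),
      f_joint = sample(1:12, 80, replace = TRUE),
      f_node = 10L, f_coll = sample(5:50, 80, replace = TRUE),
      N = 5000, W = 8L, stringsAsFactors = FALSE
    )
  })
  df <- df[!duplicated(df[c("decade", "synonym", "collocate")]), ]
  df$mi <- mi_score(df$f_joint, df$f_node, df$f_coll, df$N, df$W)
  a <- select_collocates(make_records(df), top_k = 5, mi_min = 3)
  b <- select_collocates(make_records(df[sample(nrow(df)), ]), top_k = 5, mi_min = 3)
  expect_identical(a, b)
  key_in <- paste(df$decade, df$synonym, df$collocate)
  key_out <- paste(a$decade, a$synonym, a$collocate)
  expect_setequal(key_out, key_in)
  # rank within group never exceeds top_k among retained
  grp <- paste(a$decade, a$synonym)
  for (g in unique(grp)) {
    expect_lte(sum(a$retained[grp == g]), 5)
  }
})
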