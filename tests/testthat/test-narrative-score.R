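rated_fixture <- function(df) {
  base <- data.frame(
    decade = df$decade, synonym = df$synonym, collocate = df$collocate,
    f_joint = df$f_joint, f_node = df$f_node,
    f_coll = 1L, N = 1000, W = 8L, mi = 5, retained = TRUE,
    sentiment = df$sentiment, stringsAsFactors = FALSE
  )
  make_rated(base)
}

test_that("synonym-decade means weight collocates by joint frequency", {
  # equal weights over the four canonical example ratings -> mean 3
  r1 <- rated_fixture(data.frame(
    decade = 0L, synonym = "aged",
    collocate = c("frail", "abuse", "affectionate", "wise"),
    f_joint = 1L, f_node = 4L, sentiment = c(1, 1, 5, 5),
    stringsAsFactors = FALSE
  ))
  m1 <- synonym_decade_means(r1)
  expect_equal(m1$mean_sentiment, 3)
  expect_equal(m1$w, 4)
  expect_equal(m1$n_collocates, 4L)

  # single collocate: identity
  r2 <- rated_fixture(data.frame(
    decade = 2L, synonym = "elderly", collocate = "lonely",
    f_joint = 7L, f_node = 9L, sentiment = 2, stringsAsFactors = FALSE
  ))
  expect_equal(synonym_decade_means(r2)$mean_sentiment, 2)

  # weighted: (3*1 + 1*5) / 4 = 2
  r3 <- rated_fixture(data.frame(
    decade = 0L, synonym = "aged", collocate = c("abuse", "wise"),
    f_joint = c(3L, 1L), f_node = 4L, sentiment = c(1, 5),
    stringsAsFactors = FALSE
  ))
  expect_equal(synonym_decade_means(r3)$mean_sentiment, 2)
  expect_equal(synonym_decade_means(r3, weight = "none")$mean_sentiment, 3)
})

test_that("CANS is the synonym-frequency-weighted mean and respects bounds", {
  sc <- make_scores(data.frame(
    synonym = c("aged", "elderly"), decade = 0L,
    mean_sentiment = c(2, 4), w = c(30, 10), n_collocates = 5L,
    stringsAsFactors = FALSE
  ))
  cans <- compute_cans(sc)
  expect_equal(cans$cans, 2.5)
  expect_equal(cans$total_weight, 40)

  # single synonym: identity
  sc1 <- make_scores(sc[1, ])
  expect_equal(compute_cans(sc1)$cans, 2)

  # all-neutral input yields a constant series at 3
  scn <- make_scores(data.frame(
    synonym = rep(c("aged", "elderly"), 21),
    decade = rep(0:20, each = 2), mean_sentiment = 3,
    w = rep(c(10, 17), 21), n_collocates = 3L, stringsAsFactors = FALSE
  ))
  expect_equal(compute_cans(scn)$cans, rep(3, 21))
})

test_that("CANS equals a brute-force recomputation on random score tables", {
  for (seed in 1:20) {
    sc <- withr::with_seed(seed, make_scores(data.frame(
      synonym = rep(sprintf("s%d", 1:6), times = 21),
      decade = rep(0:20, each = 6),
      mean_sentiment = runif(126, 1, 5),
      w = sample(1:50, 126, replace = TRUE),
      n_collocates = 4L, stringsAsFactors = FALSE
    )))
    cans <- compute_cans(sc)
    expect_equal(cans$cans, unname(oracle_cans(sc)))
    expect_true(all(cans$cans >= 1 & cans$cans <= 5))
    # convexity: within the min/max synonym mean per decade
    for (d in 0:20) {
      ms <- sc$mean_sentiment[sc$decade == d]
      expect_gte(cans$cans[cans$decade == d], min(ms))
      expect_lte(cans$cans[cans$decade == d], max(ms))
    }
  }
})

test_that("missing decades are marked and excluded from trends", {
  sc <- make_scores(data.frame(
    synonym = "aged", decade = c(0L, 1L, 3L), mean_sentiment = c(3, 3.1, 3.3),
    w = 5, n_collocates = 2L, stringsAsFactors = FALSE
  ))
  expect_message(cans <- compute_cans(sc, decades = 0:3), "zero weight")
  expect_true(is.na(cans$cans[cans$decade == 2]))
  tf <- fit_trend(cans, 1)
  expect_equal(tf$n, 3)
})

test_that("the above-neutral proportion uses a strict threshold", {
  cans <- structure(
    data.frame(decade = 0:8, cans = c(3.2, 3.1, 3.05, 3.2, 3.4, 3.01, 3, 2.9, 2.8)),
    class = c("cans_series", "data.frame"), neutral = 3
  )
  expect_equal(proportion_above_neutral(cans, 0:8), 6 / 9)
  expect_equal(proportion_above_neutral(cans, 0:8), 0.667, tolerance = 1e-3)
  # exact ties never count
  tie <- structure(data.frame(decade = 0:2, cans = c(3, 3, 3)),
                   class = c("cans_series", "data.frame"), neutral = 3)
  expect_equal(proportion_above_neutral(tie, 0:2), 0)
  all_up <- structure(data.frame(decade = 0:2, cans = c(3.1, 4, 5)),
                      class = c("cans_series", "data.frame"), neutral = 3)
  expect_equal(proportion_above_neutral(all_up, 0:2), 1)
})

test_that("noiseless polynomial series are interpolated exactly", {
  d <- 0:20
  lin <- structure(data.frame(decade = d, cans = 3.08 - 0.0068 * d),
                   class = c("cans_series", "data.frame"), neutral = 3)
  tf <- fit_trend(lin, 1)
  expect_equal(tf$coefficients$estimate[1], 3.08, tolerance = 1e-10)
  expect_equal(tf$headline$estimate, -0.0068, tolerance = 1e-10)
  expect_true(tf$degenerate)

  quad <- structure(data.frame(decade = d, cans = 3 - 0.001 * d^2),
                    class = c("cans_series", "data.frame"), neutral = 3)
  tf2 <- fit_trend(quad, 2)
  expect_equal(tf2$headline$term, "d2")
  expect_equal(tf2$headline$estimate, -0.001, tolerance = 1e-10)

  const <- structure(data.frame(decade = d, cans = rep(2.5, 21)),
                     class = c("cans_series", "data.frame"), neutral = 3)
  tf3 <- fit_trend(const, 1)
  expect_equal(tf3$headline$estimate, 0, tolerance = 1e-12)
  expect_true(tf3$degenerate)
})

test_that("trend fits report t-based intervals containing the estimate", {
  withr::with_seed(9, {
    d <- 0:20
    y <- 3.2 - 0.01 * d + rnorm(21, 0, 0.05)
    cans <- structure(data.frame(decade = d, cans = y),
                      class = c("cans_series", "data.frame"), neutral = 3)
    fits <- fit_trends(cans)
    expect_named(fits, c("linear", "quadratic", "cubic"))
    for (f in fits) {
      expect_false(f$degenerate)
      expect_true(all(f$coefficients$ci_lo <= f$coefficients$estimate))
      expect_true(all(f$coefficients$ci_hi >= f$coefficients$estimate))
      expect_true(all(f$coefficients$p >= 0 & f$coefficients$p <= 1))
    }
    expect_error(fit_trend(cans[1:2, ], 1), "non-missing decades")
  })
})
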