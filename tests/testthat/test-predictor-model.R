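rated_full <- function(df) {
  base <- data.frame(
    decade = df$decade, synonym = df$synonym, collocate = df$collocate,
    f_joint = df$f_joint, f_node = 1L, f_coll = 1L, N = 100, W = 8L,
    mi = 5, retained = TRUE, sentiment = df$sentiment, status = df$status,
    warmth = df$warmth, competence = df$competence,
    medicalization = df$medicalization, ostracism = df$ostracism,
    stringsAsFactors = FALSE
  )
  make_rated(base)
}

test_that("predictor rows are weighted means over the cell's collocates", {
  r <- rated_full(data.frame(
    decade = 0L, synonym = "aged",
    collocate = c("a", "b", "c", "d"), f_joint = 1L,
    sentiment = 3, status = 2, warmth = 3, competence = 3,
    medicalization = c(1, 1, 0, 0), ostracism = c(1, 0, 0, 0),
    stringsAsFactors = FALSE
  ))
  tab <- build_predictor_table(r)
  expect_equal(tab$medicalization, 0.5)
  expect_equal(tab$ostracism, 0.25)

  # "lowly" status 1 and "military-looking" status 3 average to 2
  r2 <- rated_full(data.frame(
    decade = 1L, synonym = "elderly",
    collocate = c("lowly", "military-looking"), f_joint = 1L,
    sentiment = c(2, 4), status = c(1, 3), warmth = 3, competence = 3,
    medicalization = 0, ostracism = 0, stringsAsFactors = FALSE
  ))
  tab2 <- build_predictor_table(r2)
  expect_equal(tab2$status, 2)
  expect_equal(tab2$outcome, 3)

  # single collocate: the row equals that collocate's values
  r3 <- rated_full(data.frame(
    decade = 2L, synonym = "aged", collocate = "sick", f_joint = 9L,
    sentiment = 1.5, status = 1, warmth = 2, competence = 2,
    medicalization = 1, ostracism = 0, stringsAsFactors = FALSE
  ))
  tab3 <- build_predictor_table(r3)
  expect_equal(tab3$outcome, 1.5)
  expect_equal(tab3$medicalization, 1)

  # f_joint weighting
  r4 <- rated_full(data.frame(
    decade = 0L, synonym = "aged", collocate = c("x", "y"),
    f_joint = c(3L, 1L), sentiment = c(1, 5), status = c(1, 3),
    warmth = 3, competence = 3, medicalization = 0, ostracism = 0,
    stringsAsFactors = FALSE
  ))
  expect_equal(build_predictor_table(r4)$outcome, 2)
  expect_equal(build_predictor_table(r4, weight = "none")$outcome, 3)
})

test_that("zero planted decade variance reduces the mixed model to OLS", {
  # REML puts the variance at its 0 boundary in about half such datasets;
  # every boundary (singular) fit must then coincide with OLS
  n_singular <- 0
  for (seed in 14:19) {
    sim <- simulate_predictor_table(sd_decade = 0, sd_resid = 0.1, seed = seed)
    fit <- fit_mixed_model(sim$table)
    expect_lt(fit$var_decade, 0.01)
    if (fit$singular) {
      n_singular <- n_singular + 1
      ols <- lm(outcome ~ status + warmth + competence + medicalization +
                  ostracism, data = sim$table)
      expect_lt(max(abs(fit$fixed$estimate - coef(ols))), 1e-6)
    }
  }
  expect_gte(n_singular, 1)
})

test_that("planted fixed effects are recovered with correct signs", {
  sim <- simulate_predictor_table(seed = 15)
  fit <- fit_mixed_model(sim$table)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  beta <- sim$truth$beta
  for (p in names(beta)) {
    expect_equal(sign(est[[p]]), sign(beta[[p]]))
    expect_lt(abs(est[[p]] - beta[[p]]),
              2.5 * fit$fixed$se[fit$fixed$term == p] + 0.02)
  }
  expect_true(all(fit$fixed$p >= 0 & fit$fixed$p <= 1))
  expect_gte(fit$var_decade, 0)
})

test_that("estimates are invariant to row order and to decade-constant shifts", {
  sim <- simulate_predictor_table(n_synonyms = 6, n_decades = 10, seed = 16)
  tab <- sim$table
  fit1 <- fit_mixed_model(tab)
  shuf <- as_predictor_table(tab[withr::with_seed(1, sample(nrow(tab))), ])
  fit2 <- fit_mixed_model(shuf)
  expect_equal(fit1$fixed$estimate, fit2$fixed$estimate, tolerance = 1e-8)

  # a global constant shift moves only the intercept, exactly
  tab3 <- tab
  tab3$outcome <- tab3$outcome + 0.5
  fit3 <- fit_mixed_model(as_predictor_table(tab3))
  slopes1 <- fit1$fixed$estimate[fit1$fixed$term != "intercept"]
  slopes3 <- fit3$fixed$estimate[fit3$fixed$term != "intercept"]
  expect_lt(max(abs(slopes1 - slopes3)), 1e-8)
  expect_equal(fit3$fixed$estimate[fit3$fixed$term == "intercept"],
               fit1$fixed$estimate[fit1$fixed$term == "intercept"] + 0.5,
               tolerance = 1e-6)

  # decade-level shifts are absorbed by the random intercepts; the
  # sociological coefficients move only through re-estimated variance
  # weights, not materially
  tab4 <- tab
  tab4$outcome <- tab4$outcome + 0.5 * (tab4$decade %% 2)
  fit4 <- fit_mixed_model(as_predictor_table(tab4))
  slopes4 <- fit4$fixed$estimate[fit4$fixed$term != "intercept"]
  expect_lt(max(abs(slopes1 - slopes4)), 0.05)
})

test_that("degenerate designs are rejected with the offending predictor named", {
  sim <- simulate_predictor_table(n_synonyms = 4, n_decades = 6, seed = 17)
  tab <- sim$table
  tab$warmth <- 2.5
  expect_error(fit_mixed_model(as_predictor_table(tab)), "warmth")
  tab2 <- sim$table
  tab2$ostracism <- tab2$medicalization
  expect_error(fit_mixed_model(as_predictor_table(tab2)), "collinear")
  expect_error(fit_mixed_model(as_predictor_table(sim$table[1:4, ])),
               "2 decades|2 synonyms")
})

test_that("rows missing a dimension for all collocates are dropped with a warning", {
  r <- rated_full(data.frame(
    decade = c(0L, 1L), synonym = "aged", collocate = c("a", "b"),
    f_joint = 1L, sentiment = 3, status = 2, warmth = 3, competence = 3,
    medicalization = 0, ostracism = 0, stringsAsFactors = FALSE
  ))
  r$warmth[2] <- NA
  expect_warning(tab <- build_predictor_table(r), "dropped")
  expect_equal(nrow(tab), 1)
})
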