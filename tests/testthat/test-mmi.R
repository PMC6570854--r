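test_that("standardization yields zero mean, unit SD, is idempotent and guards constants", {
  set.seed(1)
  d <- tibble::tibble(a = rnorm(40, 5, 2), b = runif(40, 0, 100))
  z <- standardize_predictors(d, c("a", "b"))
  expect_lt(max(abs(colMeans(as.matrix(z)))), 1e-12)
  expect_equal(unname(apply(as.matrix(z), 2, sd)), c(1, 1), tolerance = 1e-12)
  z2 <- standardize_predictors(z, c("a", "b"))
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  d$c <- 3
  expect_error(standardize_predictors(d, c("a", "c")),
               class = "leafspectra_degenerate_error")
})

test_that("fit_subset matches the normal-equations oracle and handles edge subsets", {
  inst <- random_instance(30, 3, seed = 5, signal = c(1, -2, 0.5))
  M <- cbind(1, inst$X)
  beta_oracle <- solve(t(M) %*% M) %*% t(M) %*% inst$y
  f <- fit_subset(inst$X, inst$y, c(TRUE, TRUE, TRUE))
  expect_equal(unname(f$coefficients), as.vector(beta_oracle),
               tolerance = 1e-8)

  null <- fit_subset(inst$X, inst$y, integer(0))
  expect_equal(null$rss, sum((inst$y - mean(inst$y))^2))

  y_exact <- as.vector(inst$X %*% c(2, 1, -1)) + 3
  perfect <- fit_subset(inst$X, y_exact, 1:3)
  expect_lt(perfect$rss, 1e-18)

  Xdup <- cbind(inst$X, x4 = inst$X[, 1])
  expect_error(fit_subset(Xdup, inst$y, c(1, 4)),
               class = "leafspectra_singular_error")
})

test_that("AICc follows the least-squares closed form with its guards", {
  expect_equal(aicc(20, 3, 20), 7.5) # ln(1) = 0 + 6 + 24/16
  r <- 13.7
  expect_equal(aicc(50, 4, 2 * r) - aicc(50, 4, r), 50 * log(2))
  expect_error(aicc(5, 4, 1), class = "leafspectra_small_sample_error")
  expect_error(aicc(20, 3, 0), class = "leafspectra_degenerate_error")
})

test_that("enumeration covers every subset and reproduces the lm-refit oracle ranking", {
  inst <- random_instance(40, 2, seed = 2)
  ms <- enumerate_models(inst$X, inst$y)
  expect_equal(nrow(ms$models), 4)

  inst <- random_instance(40, 4, seed = 3, signal = c(1, 0, -0.5, 0))
  ms <- enumerate_models(inst$X, inst$y)
  expect_equal(nrow(ms$models), 16)
  or <- oracle_enumerate(inst$X, inst$y)
  expect_equal(ms$models$mask, vapply(or$rows, function(r) r$mask, 0))
  expect_equal(ms$models$aicc, or$aicc, tolerance = 1e-10)
  expect_equal(ms$models$weight, or$weight, tolerance = 1e-10)
  expect_error(enumerate_models(inst$X, rep(1, 40)),
               class = "leafspectra_degenerate_error")
})

test_that("Akaike weights follow the exp(-delta/2) closed form and normalize", {
  fake <- structure(list(models = tibble::tibble(
    mask = 0:1, terms = c("", "x1"), k = 2, rss = 1, aicc = c(3.7, 3.7)
  )), class = "model_set")
  w <- akaike_weights(fake)$models$weight
  expect_equal(w, c(0.5, 0.5))

  fake$models$aicc <- c(0, 2)
  w <- akaike_weights(fake)$models$weight
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("the confidence set is the smallest prefix crossing the level", {
  w <- c(0.6, 0.3, 0.08, 0.02)
  fake <- structure(list(
    models = tibble::tibble(mask = 0:3, terms = letters[1:4], k = 2,
                            rss = 1, aicc = -2 * log(w),
                            delta_aicc = 0, weight = w),
    coef = matrix(0, 4, 3), se = matrix(0, 4, 3), n = 50, p = 2,
    terms = c("x1", "x2")
  ), class = "model_set")
  cs <- confidence_set(fake, 0.95)
  expect_equal(nrow(cs$models), 3)
  expect_equal(attr(cs, "cumulative_weight"), 0.98)

  expect_equal(nrow(confidence_set(fake, 1.0)$models), 4)
  one <- fake
  one$models$weight <- c(1, 0, 0, 0)
  expect_equal(nrow(confidence_set(one, 0.95)$models), 1)
  expect_error(confidence_set(fake, 0), class = "leafspectra_parameter_error")
})

test_that("zero-substituted averaging matches a direct weighted-sum oracle", {
  inst <- random_instance(50, 3, seed = 8, signal = c(2, 0, 0))
  ms <- enumerate_models(inst$X, inst$y)
  cs <- confidence_set(ms, 0.95)
  avg <- average_coefficients(cs)
  or <- oracle_chain(inst$X, inst$y, 0.95)
  expect_equal(attr(avg, "confidence_set_size"), or$set_size)
  expect_equal(avg$estimate, unname(or$estimate[avg$term]), tolerance = 1e-10)
  expect_equal(avg$std_error, unname(or$se[avg$term]), tolerance = 1e-10)
})

test_that("averaging handles constant and absent predictors exactly", {
  # predictor 1 present in every model with the same coefficient and zero
  # SE; predictor 2 absent everywhere
  fake <- structure(list(
    models = tibble::tibble(mask = c(1L, 1L), terms = "x1", k = 3,
                            rss = 1, aicc = c(0, 0), delta_aicc = 0,
                            weight = c(0.5, 0.5)),
    coef = matrix(c(0, 0, 4.2, 4.2, 0, 0), 2, 3),
    se = matrix(0, 2, 3),
    n = 50, p = 2, terms = c("x1", "x2")
  ), class = "model_set")
  avg <- average_coefficients(fake)
  expect_equal(avg$estimate, c(4.2, 0))
  expect_equal(avg$sign, c("+", "0"))
})

test_that("importance is the summed weight of models containing each predictor", {
  # p = 1: two models; importance of x1 equals the 1-predictor model weight
  inst <- random_instance(30, 1, seed = 4)
  ms <- enumerate_models(inst$X, inst$y)
  imp <- variable_importance(ms)
  expect_equal(imp$importance,
               ms$models$weight[ms$models$mask == 1])

  # a strong driver dominates an independent noise column
  set.seed(9)
  x1 <- rnorm(60)
  x2 <- rnorm(60)
  y <- 5 * x1 + rnorm(60, 0, 0.1)
  ms <- enumerate_models(cbind(x1 = x1, x2 = x2), y)
  imp <- variable_importance(ms)
  expect_gt(imp$importance[imp$term == "x1"], 0.99)
  expect_gt(0.99, imp$importance[imp$term == "x2"])
})

test_that("under a null response importances are exchangeable across predictors", {
  set.seed(123)
  acc <- matrix(0, 200, 4)
  for (r in 1:200) {
    X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
    acc[r, ] <- variable_importance(enumerate_models(X, rnorm(30)))$importance
  }
  m <- colMeans(acc)
  expect_lt(max(m) - min(m), 0.08) # within Monte-Carlo error
})

test_that("adding pure-noise predictors never ranks a strong driver below a null", {
  set.seed(31)
  for (r in 1:100) {
    n <- 60
    x1 <- rnorm(n)
    y <- 5 * x1 + rnorm(n, 0, 0.5) # effect/noise ratio 10
    noise4 <- matrix(rnorm(n * 3), n, 3)
    small <- cbind(x1 = x1, noise4)
    colnames(small) <- c("x1", paste0("n", 1:3))
    big <- cbind(small, matrix(rnorm(n * 4), n, 4,
                               dimnames = list(NULL, paste0("m", 1:4))))
    for (X in list(small, big)) {
      imp <- variable_importance(enumerate_models(X, y))
      expect_equal(imp$term[which.max(imp$importance)], "x1")
    }
  }
})

test_that("contributions normalize to 100% with correct category arithmetic", {
  sch <- predictor_schema(c("a", "b", "c"),
                          category = c("c1", "c1", "c2"),
                          biotic = c(TRUE, FALSE, TRUE))
  ct <- relative_contributions(tibble::tibble(term = c("a", "b", "c"),
                                              importance = c(0.5, 0.3, 0.2)),
                               sch)
  expect_equal(ct$predictors$contribution, c(50, 30, 20))
  c1 <- ct$categories[ct$categories$category == "c1", ]
  expect_equal(c1$total, 80)
  expect_equal(c1$per_capita, 40)
  expect_equal(ct$biotic_total, 70)
  expect_equal(ct$abiotic_total, 30)

  # category with members at 8% and 6%: total 14, per-capita 7
  ct2 <- relative_contributions(
    tibble::tibble(term = c("a", "b", "c"), importance = c(0.08, 0.06, 0.86)),
    sch
  )
  c1 <- ct2$categories[ct2$categories$category == "c1", ]
  expect_equal(c1$total, 14)
  expect_equal(c1$per_capita, 7)

  # sixteen equal importances: 6.25% each, equal per-capita
  sch16 <- predictor_schema()
  ct3 <- relative_contributions(
    tibble::tibble(term = sch16$term, importance = rep(0.4, 16)), sch16
  )
  expect_equal(ct3$predictors$contribution, rep(6.25, 16))
  expect_equal(unique(ct3$categories$per_capita), 6.25)
  expect_error(
    relative_contributions(tibble::tibble(term = "a", importance = 0),
                           predictor_schema("a")),
    class = "leafspectra_degenerate_error"
  )
})

test_that("contributions are invariant under predictor relabeling/permutation", {
  inst <- random_instance(45, 4, seed = 14, signal = c(1, -0.5, 0, 0))
  sch <- predictor_schema(colnames(inst$X),
                          category = rep(c("c1", "c2"), 2),
                          biotic = rep(TRUE, 4))
  d <- tibble::as_tibble(as.data.frame(inst$X))
  d$y <- inst$y
  f1 <- mmi(d, "y", schema = sch)
  perm <- c(3, 1, 4, 2)
  sch2 <- sch[perm, ]
  f2 <- mmi(d, "y", schema = sch2)
  t1 <- f1$contributions$predictors
  t2 <- f2$contributions$predictors
  expect_equal(t2$contribution[match(t1$term, t2$term)], t1$contribution,
               tolerance = 1e-10)
})

test_that("the full averaging chain matches the brute-force oracle end to end", {
  inst <- random_instance(60, 4, seed = 20, signal = c(1.5, 0.8, 0, 0))
  d <- tibble::as_tibble(as.data.frame(inst$X))
  d$resp <- inst$y
  sch <- predictor_schema(colnames(inst$X),
                          category = rep("c", 4), biotic = rep(FALSE, 4))
  fit <- mmi(d, "resp", schema = sch)
  or <- oracle_chain(scale(as.matrix(d[1:4])), inst$y)
  expect_equal(fit$coefficients$estimate,
               unname(or$estimate[fit$coefficients$term]), tolerance = 1e-8)
  expect_equal(fit$importance$importance,
               unname(or$importance[fit$importance$term]), tolerance = 1e-8)
  expect_equal(fit$contributions$predictors$contribution,
               unname(or$contribution[fit$contributions$predictors$term]),
               tolerance = 1e-8)
})

test_that("tidy and glance summarise an mmi fit coherently", {
  inst <- random_instance(50, 3, seed = 25, signal = c(1, 0, 0))
  d <- tibble::as_tibble(as.data.frame(inst$X))
  d$y <- inst$y
  sch <- predictor_schema(colnames(inst$X), category = rep("c", 3),
                          biotic = rep(TRUE, 3))
  fit <- mmi(d, "y", schema = sch)
  td <- tidy(fit)
  expect_setequal(td$term, colnames(inst$X))
  expect_equal(sum(td$contribution), 100, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_models, 8)
  expect_gte(gl$cumulative_weight, 0.95)
})
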