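test_that("standardized pAUC hits its analytic anchor points", {
  labels <- rep(c("real", "virtual"), each = 50)
  # perfect separation
  expect_equal(pauc(c(rep(1, 50), rep(0, 50)), labels), 1)
  # indistinguishable scores sit at chance
  expect_equal(pauc(rep(0.5, 100), labels), 0.5)
  # anti-separation reaches the standardization minimum, not 0:
  # A = 0 while A_min = (1 - s0)^2 / 2, so the floor is
  # 0.5 * (1 - (1 - s0) / 2 / (1 - (1 - s0) / 2)) shifted into [0, 1]
  s0 <- 0.9
  a_min <- (1 - s0)^2 / 2
  floor_val <- 0.5 * (1 + (0 - a_min) / ((1 - s0) - a_min))
  expect_equal(pauc(c(rep(0, 50), rep(1, 50)), labels, sens_lo = s0), floor_val)
  expect_error(pauc(rnorm(5), rep("real", 5)), "both classes")
})

test_that("standardization is monotone in the raw partial area", {
  withr::with_seed(21, {
    base <- rnorm(100)
    labels <- rep(c("real", "virtual"), 50)
  })
  shift <- seq(0, 2, length.out = 5)
  vals <- vapply(shift, function(s) {
    sc <- base + ifelse(labels == "real", s, 0)
    pauc(sc, labels)
  }, 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("pAUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(22, {
    labels <- rep(c("real", "virtual"), each = 75)
    scores <- rnorm(150, mean = ifelse(labels == "real", 0.8, 0))
  })
  ours <- pauc(scores, labels, sens_lo = 0.9)
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("virtual", "real"), direction = "<",
                   quiet = TRUE)
  ref <- as.numeric(pROC::auc(roc, partial.auc = c(1, 0.9),
                              partial.auc.focus = "sensitivity",
                              partial.auc.correct = TRUE))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("cross-validated pAUC separates what is separable and only that", {
  bn <- rand_bn(list(a = character(), b = "a", c = "b"), levels = 3, seed = 30)
  real <- ancestral_sample(bn, 200, seed = 31)
  same <- ancestral_sample(bn, 200, seed = 32)
  rep_same <- pauc_cv(real, same, k = 5, repeats = 2, num_trees = 100, seed = 33)
  expect_gte(min(rep_same$scores$pauc), 0)
  expect_lte(max(rep_same$scores$pauc), 1)
  expect_gt(rep_same$summary$median, 0.35)
  expect_lt(rep_same$summary$median, 0.65)

  # grossly different distribution: nearly perfect detection
  alien <- tibble::as_tibble(lapply(real, function(x) {
    factor(rep(rev(levels(x))[1], 200), levels = levels(x))
  }))
  alien$a <- factor(rep("1", 200), levels = levels(real$a))
  rep_diff <- pauc_cv(real, alien, k = 5, repeats = 2, num_trees = 100, seed = 34)
  expect_gte(rep_diff$summary$median, 0.9)

  # reproducible under a fixed seed
  rep2 <- pauc_cv(real, same, k = 5, repeats = 2, num_trees = 100, seed = 33)
  expect_identical(rep_same$scores, rep2$scores)
  expect_error(pauc_cv(real[1:3, ], same, k = 5), "at least k rows")
})

test_that("homogeneity tests match hand-computed chi-squared values", {
  # identical samples: statistic 0, p 1
  real <- tibble::tibble(f = rep(c("a", "b"), 50))
  ht <- homogeneity_tests(real, real)
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)

  # balanced 2x2 table: statistic 0
  r2 <- tibble::tibble(f = rep(c("a", "b"), each = 50))
  v2 <- tibble::tibble(f = rep(c("a", "b"), each = 50))
  expect_equal(homogeneity_tests(r2, v2)$statistic, 0)

  # ((90,10),(10,90)): chi-squared = sum (O-E)^2/E with E = 50 -> 128
  r3 <- tibble::tibble(f = rep(c("a", "b"), c(90, 10)))
  v3 <- tibble::tibble(f = rep(c("a", "b"), c(10, 90)))
  ht3 <- homogeneity_tests(r3, v3)
  expect_equal(ht3$statistic, 128)
  expect_equal(ht3$df, 1)
  expect_lt(ht3$p_value, 1e-20)

  # single observed level is skipped and flagged; adjusted p >= raw p
  r4 <- tibble::tibble(konst = rep("k", 30), f = rep(c("a", "b"), 15))
  v4 <- tibble::tibble(konst = rep("k", 30), f = rep(c("a", "b"), c(20, 10)))
  ht4 <- homogeneity_tests(r4, v4)
  expect_true(ht4$skipped[ht4$feature == "konst"])
  ok <- !ht4$skipped
  expect_true(all(ht4$p_adjusted[ok] >= ht4$p_value[ok]))
})

test_that("tidiers and autoplot produce well-formed output", {
  bn <- rand_bn(list(a = character(), b = "a"), levels = 2, seed = 40)
  real <- ancestral_sample(bn, 60, seed = 41)
  rep_ <- pauc_cv(real[1:30, ], real[31:60, ], k = 3, repeats = 2,
                  num_trees = 50, seed = 42)
  expect_named(tidy(rep_), c("rep", "fold", "pauc"))
  expect_true(all(c("median", "iqr") %in% names(glance(rep_))))
  expect_s3_class(autoplot(rep_), "ggplot")

  vc <- conservative_filter(real[1:30, ], real[31:60, ], seed = 43)
  expect_s3_class(autoplot(vc), "ggplot")
  expect_named(glance(vc), c("n", "accepted", "mean_confidence"))
})
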