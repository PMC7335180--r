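test_that("ancestral sampling reproduces marginals and joints", {
  # single binary node: frequency within 3 binomial SDs
  b <- discrete_bn(list(x = c("0", "1")), list(),
                   list(x = array(c(0.3, 0.7), 2, dimnames = list(c("0", "1")))))
  s <- ancestral_sample(b, 10000, seed = 1)
  f1 <- mean(s$x == "1")
  expect_lt(abs(f1 - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))

  # deterministic CPTs give the unique consistent configuration
  det <- discrete_bn(
    list(a = c("0", "1"), b = c("0", "1")), list(b = "a"),
    list(a = array(c(1, 0), 2, dimnames = list(c("0", "1"))),
         b = array(c(0, 1, 1, 0), c(2, 2),
                   dimnames = list(c("0", "1"), c("0", "1"))))
  )
  sd_ <- ancestral_sample(det, 50, seed = 2)
  expect_true(all(sd_$a == "0" & sd_$b == "1"))

  # two-node chain: empirical joint passes a chi-squared GOF test at alpha 0.01
  bn <- chain3_bn()
  joint <- enum_joint(bn)
  samp <- ancestral_sample(bn, 10000, seed = 3)
  key_obs <- paste(samp$A, samp$B, samp$C)
  key_all <- paste(joint$A, joint$B, joint$C)
  counts <- vapply(key_all, function(k) sum(key_obs == k), 0)
  gof <- stats::chisq.test(counts, p = joint$prob)
  expect_gt(gof$p.value, 0.01)

  # n = 0 gives an empty, well-typed table
  empty <- ancestral_sample(bn, 0)
  expect_equal(nrow(empty), 0)
  expect_named(empty, bn$nodes)
})

test_that("the conservative filter keeps realistic and drops outlying patients", {
  bn <- rand_bn(list(a = character(), b = "a", c = "a"), levels = 3, seed = 3)
  real <- ancestral_sample(bn, 300, seed = 4)

  # indistinguishable virtual patients (copies) all pass at threshold 0.5
  vc <- conservative_filter(real, real[101:200, ], weight = 100, seed = 5)
  expect_true(all(vc$.confidence >= 0.5))
  expect_true(all(vc$.accepted))

  # a level pattern never seen in real data is rejected
  alien <- tibble::as_tibble(lapply(real[1:50, ], function(x) {
    factor(rep("9", 50), levels = c(levels(x), "9"))
  }))
  vc2 <- conservative_filter(real, alien, weight = 100, seed = 6)
  expect_true(all(!vc2$.accepted))

  # with weight 1 and perfectly separable classes nothing is accepted
  vc3 <- conservative_filter(real, alien, weight = 1, seed = 7)
  expect_true(all(vc3$.confidence < 0.5))
  expect_equal(sum(vc3$.accepted), 0)

  expect_error(conservative_filter(real, real[, 1:2]), "share columns")

  # accepted confidences stochastically dominate the unfiltered ones
  mix <- dplyr::bind_rows(real[201:260, ], alien)
  vc4 <- conservative_filter(real, mix, weight = 100, seed = 8)
  acc <- vc4$.confidence[vc4$.accepted]
  expect_gte(min(acc), max(c(-Inf, vc4$.confidence[!vc4$.accepted])))
})

test_that("generate_vc loops until the target size and is reproducible", {
  bn <- rand_bn(list(a = character(), b = "a"), levels = 2, seed = 9)
  real <- ancestral_sample(bn, 200, seed = 10)
  fit <- fit_parameters(bn_edges(bn), real)

  vc <- generate_vc(fit, real, n_target = 150, seed = 11)
  expect_equal(nrow(vc), 150)
  expect_true(all(vc$.accepted))
  expect_s3_class(attr(vc, "acceptance_log"), "tbl_df")

  vc2 <- generate_vc(fit, real, n_target = 150, seed = 11)
  expect_equal(as.data.frame(vc), as.data.frame(vc2))

  # threshold 0 accepts everything in one round
  vc0 <- generate_vc(fit, real, n_target = 80, threshold = 0, seed = 12)
  expect_equal(nrow(vc0), 80)
  expect_equal(nrow(attr(vc0, "acceptance_log")), 1)
})

test_that("mutilation removes incoming edges and fixes the target", {
  bn <- chain3_bn()
  mut <- mutilate(bn, intervention("B", level = "1"))
  expect_length(mut$parents$B, 0)
  expect_equal(as.vector(mut$cpts$B), c(0, 1))
  # downstream CPTs untouched
  expect_equal(mut$cpts$C, bn$cpts$C)
  # intervening on a root changes only its CPT
  mroot <- mutilate(bn, intervention("A", level = "0"))
  expect_equal(mroot$parents, bn$parents)
  expect_equal(as.vector(mroot$cpts$A), c(1, 0))
  expect_error(mutilate(bn, intervention("B", level = "7")), "invalid level")
})

test_that("do-interventions match exact mutilated-network inference", {
  bn <- chain3_bn()
  lev <- c("0", "1")
  sim <- simulate_intervention(bn, intervention("B", level = "1"),
                               n = 20000, seed = 13)
  # oracle: P(C | do(B=1)) = CPT row; P(A | do(B=1)) = prior marginal of A
  expect_lt(tv_dist(emp_marginal(sim$C, lev), bn$cpts$C[, "1"]), 0.02)
  expect_lt(tv_dist(emp_marginal(sim$A, lev), as.vector(bn$cpts$A)), 0.02)

  # fixing a node to a level shifts downstream marginals toward that CPT row
  sim0 <- simulate_intervention(bn, intervention("B", level = "0"),
                                n = 20000, seed = 14)
  expect_gt(mean(sim0$C == "0"), mean(sim$C == "0"))
  expect_lt(abs(mean(sim0$C == "0") - bn$cpts$C["0", "0"]), 0.02)

  # per-patient intervened values are honored row by row
  vals <- tibble::tibble(B = rep(c("0", "1"), 10))
  simv <- simulate_intervention(bn, intervention("B"), values = vals, seed = 15)
  expect_equal(as.character(simv$B), vals$B)
  expect_equal(nrow(simulate_intervention(bn, intervention("B", level = "1"),
                                          n = 0)), 0)
})

test_that("intervention differs from conditioning on a collider", {
  bn <- collider_bn()
  lev <- c("0", "1")
  joint <- enum_joint(bn)
  prior_a <- oracle_marginal(joint, "A", lev)
  cond_a <- oracle_conditional(joint, "A", lev, "C", "1")
  # the fixture must make conditioning informative
  expect_gt(tv_dist(prior_a, cond_a), 0.05)

  # do(C = 1): sampled marginal of A stays at its prior
  sim <- simulate_intervention(bn, intervention("C", level = "1"),
                               n = 20000, seed = 16)
  expect_lt(tv_dist(emp_marginal(sim$A, lev), prior_a), 0.02)

  # conditioning (rejection from observational samples) shifts A
  obs <- ancestral_sample(bn, 20000, seed = 17)
  cond_emp <- emp_marginal(obs$A[obs$C == "1"], lev)
  expect_lt(tv_dist(cond_emp, cond_a), 0.02)
  expect_gt(tv_dist(cond_emp, emp_marginal(sim$A, lev)), 0.03)
})
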