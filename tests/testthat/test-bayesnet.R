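test_that("Dirichlet-smoothed CPT estimates match the closed form", {
  # binary node, no parents, counts (2, 0), alpha = 1 -> (0.75, 0.25)
  dat <- data.frame(x = factor(c("0", "0"), levels = c("0", "1")))
  bn <- fit_parameters(tibble::tibble(from = character(), to = character()),
                       dat, alpha = 1)
  expect_equal(as.vector(bn$cpts$x), c(0.75, 0.25))

  # unseen parent configuration yields a uniform row
  dat2 <- data.frame(p = factor(c("0", "0"), levels = c("0", "1")),
                     y = factor(c("0", "1"), levels = c("0", "1")))
  bn2 <- fit_parameters(tibble::tibble(from = "p", to = "y"), dat2, alpha = 1)
  expect_equal(as.vector(bn2$cpts$y[, "1"]), c(0.5, 0.5))

  # alpha -> 0 recovers maximum-likelihood frequencies
  dat3 <- data.frame(x = factor(c("0", "0", "1"), levels = c("0", "1")))
  bn3 <- fit_parameters(tibble::tibble(from = character(), to = character()),
                        dat3, alpha = 1e-9)
  expect_equal(as.vector(bn3$cpts$x), c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_error(fit_parameters(tibble::tibble(from = character(), to = character()),
                              dat3, alpha = 0), "alpha")
})

test_that("log-likelihood factorizes and matches joint enumeration", {
  # single uniform binary node, one row
  u <- discrete_bn(list(x = c("0", "1")), list(),
                   list(x = array(c(0.5, 0.5), 2, dimnames = list(c("0", "1")))))
  expect_equal(log_likelihood(u, data.frame(x = "1"))$total, log(0.5))

  bn <- chain3_bn()
  joint <- enum_joint(bn)
  dat <- ancestral_sample(bn, 25, seed = 3)
  ll <- log_likelihood(bn, dat)
  key <- paste(joint$A, joint$B, joint$C)
  expected <- log(joint$prob[match(paste(dat$A, dat$B, dat$C), key)])
  expect_equal(ll$per_row, expected, tolerance = 1e-12)
  expect_equal(ll$total, sum(expected), tolerance = 1e-12)

  # independent nodes: total equals the sum of marginal log-likelihoods
  ind <- rand_bn(list(a = character(), b = character()), levels = 3, seed = 2)
  d2 <- ancestral_sample(ind, 30, seed = 4)
  lla <- log_likelihood(ind, d2)$total
  direct <- sum(log(as.vector(ind$cpts$a)[match(d2$a, ind$levels$a)])) +
    sum(log(as.vector(ind$cpts$b)[match(d2$b, ind$levels$b)]))
  expect_equal(lla, direct, tolerance = 1e-12)
  expect_error(log_likelihood(bn, data.frame(A = "9", B = "0", C = "0")),
               "unseen level")
})

test_that("structure search finds the exhaustive-enumeration optimum", {
  withr::with_seed(10, {
    x <- sample(c("0", "1"), 500, TRUE)
    flip <- runif(500) < 0.05
    y <- ifelse(flip, ifelse(x == "0", "1", "0"), x) # near-deterministic copy
    z <- sample(c("0", "1"), 500, TRUE)
  })
  dat <- data.frame(X = x, Y = y, Z = z)

  # independent oracle: best of all 25 DAGs over three nodes
  dags <- all_dags(c("X", "Y", "Z"))
  scores <- vapply(dags, function(p) oracle_bdeu(dat, p, iss = 1), 0)
  best <- dags[[which.max(scores)]]
  skel <- function(edges) {
    if (length(edges) == 0) return(character())
    sort(apply(edges, 1, function(r) paste(sort(r), collapse = "~")))
  }
  best_edges <- do.call(rbind, purrr::imap(best, function(p, v) {
    if (length(p)) cbind(p, v) else NULL
  }))

  for (alg in c("hc", "tabu")) {
    dag <- learn_structure(dat, algorithm = alg, restarts = 5, seed = 1)
    got <- paste(dag$edges$from, dag$edges$to)
    # skeleton contains X-Y and no edges touching Z
    expect_true(any(got %in% c("X Y", "Y X")))
    expect_false(any(grepl("Z", got)))
    # the search attains the global optimum score; the skeleton matches
    # (direction within the equivalence class is not identified)
    expect_equal(dag$score, max(scores), tolerance = 1e-9)
    expect_identical(skel(as.matrix(dag$edges[c("from", "to")])),
                     skel(best_edges))
  }
})

test_that("constraints are respected: full blacklist, forced whitelist", {
  withr::with_seed(2, dat <- data.frame(a = sample(c("0", "1"), 200, TRUE),
                                        b = sample(c("0", "1"), 200, TRUE)))
  all_pairs <- tibble::tibble(from = c("a", "b"), to = c("b", "a"))
  empty <- learn_structure(dat, list(blacklist = all_pairs,
                                     whitelist = all_pairs[0, ]),
                           restarts = 2, seed = 1)
  expect_equal(nrow(empty$edges), 0)

  forced <- learn_structure(dat, list(blacklist = all_pairs[0, ],
                                      whitelist = tibble::tibble(from = "a", to = "b")),
                            restarts = 2, seed = 1)
  expect_true(any(forced$edges$from == "a" & forced$edges$to == "b"))

  cyc <- list(blacklist = all_pairs[0, ],
              whitelist = tibble::tibble(from = c("a", "b"), to = c("b", "a")))
  expect_error(learn_structure(dat, cyc), "cycle")
})

test_that("parameters of a known network are recovered from its own samples", {
  bn <- rand_bn(list(a = character(), b = "a", c = "b"), levels = 2, seed = 8)
  dat <- ancestral_sample(bn, 2000, seed = 9)
  fit <- fit_parameters(bn_edges(bn), dat, alpha = 1)
  for (v in bn$nodes) {
    expect_lt(max(abs(fit$cpts[[v]] - bn$cpts[[v]])), 0.05)
  }
})

test_that("cross-validated selection is reproducible and beats the empty graph", {
  bn <- chain3_bn()
  dat <- ancestral_sample(bn, 1000, seed = 5)
  cv1 <- cv_select(dat, k = 5, algorithms = c("hc", "tabu"), seed = 77,
                   restarts = 2)
  cv2 <- cv_select(dat, k = 5, algorithms = c("hc", "tabu"), seed = 77,
                   restarts = 2)
  expect_identical(cv1$scores, cv2$scores)
  # identical algorithms in the list give identical fold scores
  cv3 <- cv_select(dat, k = 5, algorithms = c("hc", "hc"), seed = 77,
                   restarts = 2)
  expect_equal(cv3$scores$neg_loglik[cv3$scores$algorithm == "hc"][1:5],
               cv3$scores$neg_loglik[cv3$scores$algorithm == "hc"][6:10])

  # forcing the empty graph (full blacklist) generalizes worse
  nodes <- names(dat)
  all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  cv_empty <- cv_select(dat, constraints = list(blacklist = all_pairs,
                                                whitelist = all_pairs[0, ]),
                        k = 5, algorithms = "hc", seed = 77, restarts = 0)
  expect_lt(mean(cv1$scores$neg_loglik[cv1$scores$algorithm == "hc"]),
            mean(cv_empty$scores$neg_loglik))
  expect_error(cv_select(dat, k = 1), "k must be")
})

test_that("bootstrap edge frequencies capture strong dependencies", {
  withr::with_seed(4, {
    x <- sample(c("0", "1"), 500, TRUE)
    flip <- runif(500) < 0.05
    y <- ifelse(flip, ifelse(x == "0", "1", "0"), x)
    z <- sample(c("0", "1"), 500, TRUE)
  })
  dat <- data.frame(X = x, Y = y, Z = z)
  conf <- bootstrap_edges(dat, B = 100, algorithm = "hc", restarts = 1, seed = 6)
  skel_xy <- edge_frequency(conf, "X", "Y") + edge_frequency(conf, "Y", "X")
  expect_gte(skel_xy, 0.9)

  # a blacklisted edge never appears
  bl <- list(blacklist = tibble::tibble(from = c("X", "Y"), to = c("Y", "X")),
             whitelist = tibble::tibble(from = character(), to = character()))
  conf_bl <- bootstrap_edges(dat, constraints = bl, B = 30, algorithm = "hc",
                             restarts = 1, seed = 6)
  expect_equal(edge_frequency(conf_bl, "X", "Y"), 0)
  expect_equal(edge_frequency(conf_bl, "Y", "X"), 0)

  # resampling indices depend on the seed, not on row storage order
  perm <- withr::with_seed(1, sample(nrow(dat)))
  conf_perm <- bootstrap_edges(dat[perm, ], B = 30, algorithm = "hc",
                               restarts = 1, seed = 6)
  conf_same <- bootstrap_edges(dat, B = 30, algorithm = "hc",
                               restarts = 1, seed = 6)
  expect_identical(conf_same$B, conf_perm$B)
  expect_true(edge_frequency(conf_perm, "X", "Y") +
                edge_frequency(conf_perm, "Y", "X") >= 0.9)
})
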