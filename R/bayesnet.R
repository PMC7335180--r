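#' Discrete Bayesian network with Dirichlet-smoothed CPTs
#'
#' Constructs a discrete Bayesian network: a DAG over discrete nodes together
#' with one conditional probability table (CPT) per node. The joint
#' distribution factorizes as `prod_v p(X_v | X_pa(v))`. CPT arrays have the
#' node's own levels on the first dimension and the parents' levels (in
#' `parents[[v]]` order) on the remaining dimensions; every conditional
#' distribution must sum to 1 (tolerance 1e-9).
#'
#' @param levels named list; per node, the character vector of its levels.
#' @param parents named list; per node, character vector of parent nodes
#'   (may be omitted for root nodes).
#' @param cpts named list of arrays as described above.
#' @param alpha optional pseudo-count used when the CPTs were fitted.
#' @return A `discrete_bn` object.
#' @export
discrete_bn <- function(levels, parents = list(), cpts, alpha = NULL) {
  nodes <- names(levels)
  assert_that(!is.null(nodes) && !anyDuplicated(nodes), "levels must be a uniquely named list")
  parents <- purrr::map(setNames(nodes, nodes), ~ parents[[.x]] %||% character())
  assert_that(all(unlist(parents) %in% nodes), "parent references an unknown node")
  ord <- topo_sort(nodes, parents) # errors on cycles
  for (v in nodes) {
    cpt <- cpts[[v]]
    assert_that(!is.null(cpt), paste("missing CPT for node", v))
    want <- c(length(levels[[v]]), vapply(parents[[v]], function(p) length(levels[[p]]), 1L))
    assert_that(identical(as.integer(dim(cpt) %||% length(cpt)), as.integer(want)),
                paste("CPT dimensions wrong for node", v))
    m <- matrix(cpt, nrow = want[1])
    assert_that(all(abs(colSums(m) - 1) < 1e-9),
                paste("CPT rows of node", v, "do not sum to 1"))
    dim(cpts[[v]]) <- want
    dimnames(cpts[[v]]) <- c(list(levels[[v]]),
                             lapply(parents[[v]], function(p) levels[[p]]))
  }
  structure(list(nodes = nodes, levels = levels, parents = parents,
                 cpts = cpts, alpha = alpha, order = ord),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("<discrete_bn> ", length(x$nodes), " nodes, ",
      sum(lengths(x$parents)), " edges\n", sep = "")
  invisible(x)
}

#' Edge list of a DAG or fitted network
#'
#' @param x a `vc_dag` or `discrete_bn`.
#' @return tibble with columns `from`, `to`.
#' @export
bn_edges <- function(x) {
  if (inherits(x, "vc_dag")) return(as_tibble(x$edges))
  stopifnot(inherits(x, "discrete_bn"))
  purrr::imap_dfr(x$parents, ~ if (length(.x)) tibble(from = .x, to = .y) else NULL) |>
    arrange(.data$from, .data$to)
}

topo_sort <- function(nodes, parents) {
  indeg <- vapply(parents, length, 1L)[nodes]
  children <- purrr::map(setNames(nodes, nodes), ~ character())
  for (v in nodes) for (p in parents[[v]]) children[[p]] <- c(children[[p]], v)
  ord <- character(0)
  ready <- sort(nodes[indeg == 0L])
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  assert_that(length(ord) == length(nodes), "graph contains a cycle",
              class = "vcforge_cycle_error")
  ord
}

# ---- internal discrete-data representation -------------------------------

# Coerce a data frame of discrete columns to an integer matrix + level list.
as_discrete <- function(data, levels = NULL) {
  data <- as.data.frame(data)
  out <- matrix(0L, nrow(data), ncol(data), dimnames = list(NULL, names(data)))
  levs <- list()
  for (j in names(data)) {
    x <- data[[j]]
    if (is.numeric(x) && !all(is.na(x) | x == round(x))) {
      abort(paste("column", j, "is not discrete"), class = "vcforge_error")
    }
    f <- if (is.null(levels)) {
      if (is.factor(x)) x else factor(x) # keep declared factor levels
    } else {
      bad <- setdiff(unique(as.character(x)), levels[[j]])
      assert_that(length(bad) == 0L,
                  paste0("unseen level '", bad[1], "' in column ", j),
                  class = "vcforge_level_error")
      factor(as.character(x), levels = levels[[j]])
    }
    assert_that(!anyNA(f), paste("missing or unmapped values in column", j))
    out[, j] <- as.integer(f)
    levs[[j]] <- levels(f)
  }
  list(x = out, levels = levs)
}

# Index of the joint parent configuration (1..prod(nlev[pars])) per row.
parent_config <- function(X, pars, nlev) {
  if (length(pars) == 0L) return(rep(1L, nrow(X)))
  idx <- rep(1L, nrow(X)); stride <- 1L
  for (p in pars) {
    idx <- idx + (X[, p] - 1L) * stride
    stride <- stride * nlev[[p]]
  }
  idx
}

# BDeu family score (log marginal likelihood contribution of one node).
bdeu_family <- function(X, v, pars, nlev, iss) {
  r <- nlev[[v]]
  q <- if (length(pars)) prod(unlist(nlev[pars])) else 1
  if (r * q > 2^24) return(-Inf) # refuse absurd parent sets
  cell <- (parent_config(X, pars, nlev) - 1L) * r + X[, v]
  N <- tabulate(cell, nbins = r * q)
  dim(N) <- c(r, q)
  Nj <- colSums(N)
  aj <- iss / q; ajk <- iss / (r * q)
  use <- Nj > 0
  sum(lgamma(aj) - lgamma(aj + Nj[use])) +
    sum(lgamma(ajk + N[, use, drop = FALSE]) - lgamma(ajk))
}

# ---- constrained score-based structure search ----------------------------

constraint_matrices <- function(nodes, constraints) {
  p <- length(nodes)
  bl <- wl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "vc_constraints") || is.list(constraints))
    fill <- function(m, e) {
      e <- e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
      m[cbind(e$from, e$to)] <- TRUE
      m
    }
    bl <- fill(bl, constraints$blacklist)
    wl <- fill(wl, constraints$whitelist)
  }
  diag(bl) <- TRUE
  assert_that(!any(bl & wl), "blacklist and whitelist overlap")
  list(bl = bl, wl = wl)
}

has_path <- function(A, from, to) {
  if (from == to) return(TRUE)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(u) colnames(A)[A[u, ]])))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# Search state: adjacency + cached family scores.
make_scorer <- function(X, nlev, iss) {
  cache <- new.env(parent = emptyenv())
  function(v, pars) {
    key <- paste(v, paste(sort(pars), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    s <- bdeu_family(X, v, pars, nlev, iss)
    cache[[key]] <- s
    s
  }
}

dag_score <- function(A, scorer) {
  sum(vapply(colnames(A), function(v) scorer(v, rownames(A)[A[, v]]), 0))
}

# Enumerate scored legal moves; returns best (type, from, to, delta).
best_move <- function(A, cm, scorer, maxp, tabu = character(), best_score = -Inf,
                      cur_score = NULL) {
  nodes <- colnames(A)
  best <- NULL
  consider <- function(type, u, v, delta) {
    sig <- paste(type, u, v)
    if (sig %in% tabu &&
        !(is.numeric(cur_score) && cur_score + delta > best_score + 1e-9)) return()
    if (is.null(best) || delta > best$delta + 1e-12 ||
        (abs(delta - best$delta) <= 1e-12 &&
         paste(u, v, type) < paste(best$from, best$to, best$type))) {
      best <<- list(type = type, from = u, to = v, delta = delta)
    }
  }
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    if (!A[u, v]) {
      if (cm$bl[u, v]) next
      if (sum(A[, v]) >= maxp) next
      if (has_path(A, v, u)) next
      old <- scorer(v, nodes[A[, v]])
      new <- scorer(v, c(nodes[A[, v]], u))
      consider("add", u, v, new - old)
    } else {
      if (!cm$wl[u, v]) {
        old <- scorer(v, nodes[A[, v]])
        new <- scorer(v, setdiff(nodes[A[, v]], u))
        consider("delete", u, v, new - old)
        # reversal u->v to v->u
        if (!cm$bl[v, u] && sum(A[, u]) < maxp) {
          A2 <- A; A2[u, v] <- FALSE
          if (!has_path(A2, u, v)) {
            d <- (new - old) +
              scorer(u, c(nodes[A[, u]], v)) - scorer(u, nodes[A[, u]])
            consider("reverse", u, v, d)
          }
        }
      }
    }
  }
  best
}

apply_move <- function(A, m) {
  switch(m$type,
         add = { A[m$from, m$to] <- TRUE },
         delete = { A[m$from, m$to] <- FALSE },
         reverse = { A[m$from, m$to] <- FALSE; A[m$to, m$from] <- TRUE })
  A
}

inverse_sig <- function(m) {
  switch(m$type,
         add = paste("delete", m$from, m$to),
         delete = paste("add", m$from, m$to),
         reverse = paste("reverse", m$to, m$from))
}

hc_search <- function(A, cm, scorer, maxp, max_iter) {
  s <- dag_score(A, scorer)
  for (i in seq_len(max_iter)) {
    m <- best_move(A, cm, scorer, maxp)
    if (is.null(m) || m$delta <= 1e-9) break
    stopifnot(m$delta > 0) # greedy search never accepts a worsening move
    A <- apply_move(A, m)
    s <- s + m$delta
  }
  list(A = A, score = s)
}

tabu_search <- function(A, cm, scorer, maxp, tabu_len, max_iter) {
  cur <- A; cur_s <- dag_score(A, scorer)
  best <- cur; best_s <- cur_s
  tabu <- character(0)
  stall <- 0L
  for (i in seq_len(max_iter)) {
    m <- best_move(cur, cm, scorer, maxp, tabu = tabu, best_score = best_s,
                   cur_score = cur_s)
    if (is.null(m)) break
    cur <- apply_move(cur, m)
    cur_s <- cur_s + m$delta
    tabu <- c(tabu, inverse_sig(m))
    if (length(tabu) > tabu_len) tabu <- tail(tabu, tabu_len)
    if (cur_s > best_s + 1e-9) {
      best <- cur; best_s <- cur_s; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > tabu_len) break
    }
  }
  list(A = best, score = best_s)
}

random_start <- function(cm, maxp) {
  nodes <- colnames(cm$wl)
  A <- cm$wl
  cand <- which(!cm$bl & !A, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      if (runif(1) > 0.15) next
      u <- nodes[cand[k, 1]]; v <- nodes[cand[k, 2]]
      if (sum(A[, v]) >= maxp) next
      if (!has_path(A, v, u)) A[u, v] <- TRUE
    }
  }
  A
}

#' Learn a constrained DAG by score-based local search
#'
#' Maximizes the BDeu score (Bayesian-Dirichlet equivalent uniform marginal
#' likelihood, imaginary sample size `iss`) over DAGs that contain every
#' whitelisted edge and no blacklisted edge, using greedy hill climbing with
#' random restarts or tabu search. Hill climbing restarts from random
#' constraint-respecting DAGs; score ties break on lexicographic edge order so
#' results are deterministic given `seed`.
#'
#' @param data data frame of discrete columns (factors, characters, logicals
#'   or integer codes); must be complete.
#' @param constraints optional [expand_constraints()] result (or a list with
#'   `blacklist`/`whitelist` tibbles).
#' @param algorithm `"hc"` (hill climbing) or `"tabu"`.
#' @param restarts number of random restarts for hill climbing.
#' @param tabu_len tabu-list length (and stall limit) for tabu search.
#' @param max_iter cap on local-search moves.
#' @param iss imaginary sample size of the BDeu score.
#' @param maxp maximum number of parents per node.
#' @param seed RNG seed for restarts.
#' @return A `vc_dag`: list with `nodes`, `edges` (tibble) and `score`.
#' @export
learn_structure <- function(data, constraints = NULL,
                            algorithm = c("hc", "tabu"),
                            restarts = 50, tabu_len = 10, max_iter = 500,
                            iss = 1, maxp = 8, seed = NULL) {
  algorithm <- match.arg(algorithm)
  dd <- as_discrete(data)
  nodes <- colnames(dd$x)
  cm <- constraint_matrices(nodes, constraints)
  # whitelist must itself be acyclic
  wl_par <- purrr::map(setNames(nodes, nodes), ~ nodes[cm$wl[, .x]])
  topo_sort(nodes, wl_par)
  nlev <- setNames(as.list(lengths(dd$levels)), nodes)
  scorer <- make_scorer(dd$x, nlev, iss)

  run <- with_seed(seed, {
    if (algorithm == "hc") {
      best <- hc_search(cm$wl, cm, scorer, maxp, max_iter)
      for (r in seq_len(restarts)) {
        cand <- hc_search(random_start(cm, maxp), cm, scorer, maxp, max_iter)
        if (cand$score > best$score + 1e-9) best <- cand
      }
      best
    } else {
      tabu_search(cm$wl, cm, scorer, maxp, tabu_len, max_iter)
    }
  })
  A <- run$A
  stopifnot(all(A[cm$wl]), !any(A & cm$bl)) # constraints hold post hoc
  idx <- which(A, arr.ind = TRUE)
  edges <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]]) |>
    arrange(.data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, score = run$score,
                 algorithm = algorithm),
            class = "vc_dag")
}

#' @export
print.vc_dag <- function(x, ...) {
  cat("<vc_dag> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$algorithm, " search, score ", format(x$score), ")\n", sep = "")
  invisible(x)
}

#' Fit Dirichlet-smoothed conditional probability tables
#'
#' Given a DAG and complete discrete data, estimates each CPT entry as
#' `(N_xjk + alpha) / (N_j + alpha * L_v)` where `L_v` is the node's level
#' count: the posterior mean under a uniform Dirichlet prior with pseudo-count
#' `alpha` per cell. Parent configurations never observed therefore get a
#' uniform conditional distribution.
#'
#' @param dag a `vc_dag` from [learn_structure()], or an edge tibble.
#' @param data complete discrete data frame.
#' @param alpha pseudo-count, must be > 0.
#' @return A [discrete_bn()].
#' @export
fit_parameters <- function(dag, data, alpha = 1) {
  assert_that(is_scalar_number(alpha) && alpha > 0, "alpha must be > 0")
  edges <- if (inherits(dag, "vc_dag")) dag$edges else as_tibble(dag)
  dd <- as_discrete(data)
  assert_that(all(c(edges$from, edges$to) %in% colnames(dd$x)),
              "edge references unknown node")
  fit_on_levels(dag, data, dd$levels, alpha)
}

#' Log-likelihood of discrete data under a fitted network
#'
#' @param bn a [discrete_bn()].
#' @param data discrete data frame; every value must be a known level of its
#'   node (unseen levels raise an error).
#' @return list with `total` (sum over rows and nodes of
#'   `log p(x_v | x_pa(v))`) and `per_row` (numeric vector).
#' @export
log_likelihood <- function(bn, data) {
  stopifnot(inherits(bn, "discrete_bn"))
  dd <- as_discrete(data[bn$nodes], levels = bn$levels)
  nlev <- setNames(as.list(lengths(bn$levels)), bn$nodes)
  ll <- rep(0, nrow(dd$x))
  for (v in bn$nodes) {
    pars <- bn$parents[[v]]
    r <- nlev[[v]]
    idx <- (parent_config(dd$x, pars, nlev) - 1L) * r + dd$x[, v]
    ll <- ll + log(as.vector(bn$cpts[[v]])[idx])
  }
  list(total = sum(ll), per_row = ll)
}

#' Cross-validated comparison of structure-learning algorithms
#'
#' Ranks structure-learning algorithms by generalization: for each fold the
#' network (structure + parameters) is learned on the remaining folds and the
#' negated mean per-row log-likelihood of the held-out fold is recorded; the
#' algorithm with the lowest mean is selected.
#'
#' @inheritParams learn_structure
#' @param algorithms character vector of algorithms to compare.
#' @param k number of folds (>= 2).
#' @param alpha CPT pseudo-count.
#' @param ... passed to [learn_structure()].
#' @return A `vc_cv` object: list with `scores` tibble
#'   (`algorithm`, `fold`, `neg_loglik`) and `best`.
#' @export
cv_select <- function(data, constraints = NULL, algorithms = c("hc", "tabu"),
                      k = 10, alpha = 1, seed = NULL, ...) {
  assert_that(k >= 2, "k must be >= 2")
  n <- nrow(data)
  assert_that(n >= k, "need at least k rows")
  seeds <- derive_seeds(seed %||% 1L, length(algorithms) * k + 1L)
  folds <- with_seed(seeds[1], sample(rep_len(seq_len(k), n)))
  # fix factor levels globally so held-out folds never contain unseen levels
  glob <- as_discrete(data)
  rows <- list(); si <- 1L
  for (a in algorithms) for (f in seq_len(k)) {
    si <- si + 1L
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    dag <- learn_structure(train, constraints, algorithm = a, seed = seeds[si], ...)
    bn <- fit_on_levels(dag, train, glob$levels, alpha)
    rows[[length(rows) + 1L]] <-
      tibble(algorithm = a, fold = f,
             neg_loglik = -mean(log_likelihood(bn, test)$per_row))
  }
  scores <- bind_rows(rows)
  means <- scores |> group_by(.data$algorithm) |>
    summarise(mean_neg_loglik = mean(.data$neg_loglik), .groups = "drop") |>
    arrange(.data$mean_neg_loglik)
  structure(list(scores = scores, summary = means, best = means$algorithm[1]),
            class = "vc_cv")
}

# fit_parameters with externally fixed level sets (for CV folds)
fit_on_levels <- function(dag, data, levels, alpha) {
  edges <- if (inherits(dag, "vc_dag")) dag$edges else as_tibble(dag)
  dd <- as_discrete(data, levels = levels[names(data)])
  nodes <- colnames(dd$x)
  parents <- purrr::map(setNames(nodes, nodes), ~ sort(edges$from[edges$to == .x]))
  nlev <- setNames(as.list(lengths(dd$levels)), nodes)
  cpts <- list()
  for (v in nodes) {
    pars <- parents[[v]]
    r <- nlev[[v]]
    q <- if (length(pars)) prod(unlist(nlev[pars])) else 1L
    cell <- (parent_config(dd$x, pars, nlev) - 1L) * r + dd$x[, v]
    N <- tabulate(cell, nbins = r * q)
    dim(N) <- c(r, q)
    th <- sweep(N + alpha, 2, colSums(N) + alpha * r, "/")
    dims <- c(r, unlist(lapply(pars, function(p) nlev[[p]])))
    dn <- c(list(dd$levels[[v]]), lapply(pars, function(p) dd$levels[[p]]))
    cpts[[v]] <- array(th, dim = dims, dimnames = dn)
  }
  discrete_bn(dd$levels, parents, cpts, alpha = alpha)
}

#' @export
print.vc_cv <- function(x, ...) {
  cat("<vc_cv> best algorithm:", x$best, "\n")
  print(x$summary)
  invisible(x)
}

#' Bootstrap confidence of network edges
#'
#' Nonparametric bootstrap over patients: `B` times, `n` rows are resampled
#' with replacement and a full structure is learned; the relative frequency of
#' each directed edge across replicates measures its stability.
#'
#' @inheritParams learn_structure
#' @param B number of bootstrap replicates (>= 1).
#' @param ... passed to [learn_structure()] (e.g. `restarts`).
#' @return A `vc_edge_confidence` object: tibble `edges`
#'   (`from`, `to`, `frequency`) plus attribute `B`.
#' @export
bootstrap_edges <- function(data, constraints = NULL, algorithm = "hc",
                            B = 1000, seed = NULL, ...) {
  assert_that(B >= 1, "B must be >= 1")
  seeds <- derive_seeds(seed %||% 1L, 2L * B)
  counts <- new.env(parent = emptyenv())
  n <- nrow(data)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    dag <- learn_structure(data[idx, , drop = FALSE], constraints,
                           algorithm = algorithm, seed = seeds[B + b], ...)
    if (nrow(dag$edges)) {
      keys <- paste(dag$edges$from, dag$edges$to, sep = "\r")
      for (k in keys) counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  edges <- if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    tibble(from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
           frequency = vapply(keys, function(k) counts[[k]], 0) / B) |>
      arrange(dplyr::desc(.data$frequency), .data$from, .data$to)
  } else {
    tibble(from = character(), to = character(), frequency = numeric())
  }
  structure(list(edges = edges, B = B), class = "vc_edge_confidence")
}

#' @export
print.vc_edge_confidence <- function(x, ...) {
  cat("<vc_edge_confidence> ", nrow(x$edges), " edges over ", x$B,
      " bootstrap replicates\n", sep = "")
  print(head(x$edges, 10))
  invisible(x)
}

#' Bootstrap frequency of a specific directed edge
#'
#' @param confidence a [bootstrap_edges()] result.
#' @param from,to node names.
#' @return numeric frequency in `[0, 1]` (0 if never observed).
#' @export
edge_frequency <- function(confidence, from, to) {
  stopifnot(inherits(confidence, "vc_edge_confidence"))
  hit <- confidence$edges$frequency[confidence$edges$from == from &
                                      confidence$edges$to == to]
  if (length(hit)) hit[1] else 0
}
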