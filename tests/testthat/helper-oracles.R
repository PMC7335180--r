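# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths: joint distributions are obtained by
# brute-force enumeration, scores by direct counting, and influence by
# explicit path enumeration.

# Exact joint distribution of a discrete BN by full enumeration.
enum_joint <- function(bn) {
  cfg <- do.call(expand.grid,
                 c(bn$levels, list(stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)))
  p <- rep(1, nrow(cfg))
  for (v in bn$nodes) {
    own <- match(cfg[[v]], bn$levels[[v]])
    pars <- bn$parents[[v]]
    if (length(pars) == 0L) {
      p <- p * as.vector(bn$cpts[[v]])[own]
    } else {
      sub <- cbind(own, vapply(pars, function(q) match(cfg[[q]], bn$levels[[q]]),
                               integer(nrow(cfg))))
      p <- p * bn$cpts[[v]][sub]
    }
  }
  cfg$prob <- p
  cfg
}

# Marginal of one node from an enumerated joint, in level order.
oracle_marginal <- function(joint, node, levels) {
  vapply(levels, function(l) sum(joint$prob[joint[[node]] == l]), 0) /
    sum(joint$prob)
}

# Conditional marginal P(node | cond_node = cond_level) from the joint.
oracle_conditional <- function(joint, node, levels, cond_node, cond_level) {
  sub <- joint[joint[[cond_node]] == cond_level, ]
  vapply(levels, function(l) sum(sub$prob[sub[[node]] == l]), 0) / sum(sub$prob)
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Empirical marginal of a sampled column, in level order.
emp_marginal <- function(x, levels) {
  vapply(levels, function(l) mean(as.character(x) == l), 0)
}

# Gedeon influence by explicit enumeration of all input-to-output paths.
oracle_gedeon <- function(Ws) {
  Ps <- lapply(Ws, function(W) {
    A <- abs(W)
    sweep(A, 2, colSums(A), "/")
  })
  d <- nrow(Ps[[1]]); K <- ncol(Ps[[length(Ps)]])
  out <- matrix(0, d, K)
  for (i in seq_len(d)) {
    step <- function(layer, node, w) {
      if (layer > length(Ps)) {
        out[i, node] <<- out[i, node] + w
        return(invisible())
      }
      for (nxt in seq_len(ncol(Ps[[layer]]))) {
        step(layer + 1L, nxt, w * Ps[[layer]][node, nxt])
      }
    }
    for (h in seq_len(ncol(Ps[[1]]))) step(2L, h, Ps[[1]][i, h])
  }
  out
}

# Independent BDeu log score of a fully specified DAG, by direct counting.
oracle_bdeu <- function(df, parents, iss = 1) {
  df <- as.data.frame(lapply(df, factor))
  total <- 0
  for (v in names(df)) {
    pars <- parents[[v]]
    r <- nlevels(df[[v]])
    q <- if (length(pars)) prod(vapply(pars, function(p) nlevels(df[[p]]), 1L)) else 1L
    cfg <- if (length(pars)) {
      interaction(df[pars], drop = FALSE)
    } else {
      factor(rep(1, nrow(df)))
    }
    tab <- table(cfg, df[[v]])
    aj <- iss / q; ajk <- iss / (r * q)
    for (j in seq_len(nrow(tab))) {
      Nj <- sum(tab[j, ])
      if (Nj == 0) next
      total <- total + lgamma(aj) - lgamma(aj + Nj) +
        sum(lgamma(ajk + tab[j, ]) - lgamma(ajk))
    }
  }
  total
}

# All DAGs over the given nodes (feasible up to ~4 nodes), as parent lists.
all_dags <- function(nodes) {
  subsets <- function(s) {
    if (length(s) == 0L) return(list(character()))
    rest <- subsets(s[-1])
    c(rest, lapply(rest, function(x) c(s[1], x)))
  }
  choices <- lapply(nodes, function(v) subsets(setdiff(nodes, v)))
  names(choices) <- nodes
  grid <- expand.grid(lapply(choices, seq_along))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    parents <- lapply(nodes, function(v) choices[[v]][[grid[i, v]]])
    names(parents) <- nodes
    ok <- tryCatch({
      vcforge:::topo_sort(nodes, parents)
      TRUE
    }, error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- parents
  }
  out
}

# A small random BN with CPT rows bounded away from 0/1.
rand_bn <- function(parents, levels = 2, seed = 1) {
  nodes <- names(parents)
  lev <- as.character(seq_len(levels))
  withr::with_seed(seed, {
    cpts <- lapply(nodes, function(v) {
      q <- prod(c(1, rep(levels, length(parents[[v]]))))
      eps <- min(0.1, 1 / (2 * levels))
      m <- vapply(seq_len(q), function(j) {
        w <- rgamma(levels, 0.7) + 1e-9
        w <- w / sum(w)
        eps + (1 - levels * eps) * w
      }, numeric(levels))
      array(m, dim = c(levels, rep(levels, length(parents[[v]]))),
            dimnames = c(list(lev), rep(list(lev), length(parents[[v]]))))
    })
    names(cpts) <- nodes
    discrete_bn(setNames(rep(list(lev), length(nodes)), nodes), parents, cpts)
  })
}

# Deterministic fixture: a 3-node chain with hand-picked CPTs.
chain3_bn <- function() {
  l2 <- c("0", "1")
  discrete_bn(
    levels = list(A = l2, B = l2, C = l2),
    parents = list(B = "A", C = "B"),
    cpts = list(
      A = array(c(0.3, 0.7), 2, dimnames = list(l2)),
      B = array(c(0.8, 0.2, 0.25, 0.75), c(2, 2), dimnames = list(l2, l2)),
      C = array(c(0.6, 0.4, 0.1, 0.9), c(2, 2), dimnames = list(l2, l2))
    )
  )
}

# Collider A -> C <- B with C strongly informative about (A, B).
collider_bn <- function() {
  l2 <- c("0", "1")
  cptC <- array(0, c(2, 2, 2), dimnames = list(l2, l2, l2))
  # C is close to XOR(A, B)
  cptC[, "0", "0"] <- c(0.9, 0.1)
  cptC[, "1", "0"] <- c(0.1, 0.9)
  cptC[, "0", "1"] <- c(0.1, 0.9)
  cptC[, "1", "1"] <- c(0.9, 0.1)
  discrete_bn(
    levels = list(A = l2, B = l2, C = l2),
    parents = list(C = c("A", "B")),
    cpts = list(
      A = array(c(0.6, 0.4), 2, dimnames = list(l2)),
      B = array(c(0.8, 0.2), 2, dimnames = list(l2)),
      C = cptC
    )
  )
}

# Small longitudinal schema fixture: two temporal groups, one static group.
toy_schema <- function() {
  vc_schema(
    features = tibble::tribble(
      ~name, ~dtype, ~group, ~visit,
      "mmse", "continuous", "cognition", "bl",
      "adas", "continuous", "cognition", "bl",
      "mmse", "continuous", "cognition", "m06",
      "adas", "continuous", "cognition", "m06",
      "hippo", "continuous", "brain", "bl",
      "vent", "continuous", "brain", "bl",
      "hippo", "continuous", "brain", "m06",
      "vent", "continuous", "brain", "m06",
      "age", "continuous", "demo", "static",
      "sex", "categorical", "demo", "static"
    ),
    groups = tibble::tibble(group = c("cognition", "brain", "demo"),
                            class = c("cognition", "imaging", "demographic")),
    schedule = tibble::tibble(visit = c("bl", "m06"), offset = c(0, 6))
  )
}
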