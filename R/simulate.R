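#' Draw virtual patients by ancestral sampling
#'
#' Samples `n` i.i.d. joint configurations from a fitted network by visiting
#' nodes in topological order: roots are drawn from their marginal CPTs,
#' children from the CPT row selected by their already-sampled parents.
#'
#' @param bn a [discrete_bn()].
#' @param n number of samples.
#' @param seed RNG seed.
#' @return tibble of factors, one column per node (columns in `bn$nodes`
#'   order).
#' @export
ancestral_sample <- function(bn, n, seed = NULL) {
  stopifnot(inherits(bn, "discrete_bn"))
  assert_that(is_scalar_number(n) && n >= 0, "n must be a non-negative count")
  nlev <- setNames(as.list(lengths(bn$levels)), bn$nodes)
  X <- matrix(0L, n, length(bn$nodes), dimnames = list(NULL, bn$nodes))
  with_seed(seed, {
    for (v in bn$order) {
      pars <- bn$parents[[v]]
      r <- nlev[[v]]
      cpt <- matrix(bn$cpts[[v]], nrow = r)
      if (n == 0L) next
      cfg <- parent_config(X, pars, nlev)
      for (j in unique(cfg)) {
        rows <- which(cfg == j)
        X[rows, v] <- sample.int(r, length(rows), replace = TRUE, prob = cpt[, j])
      }
    }
  })
  cols <- purrr::map(setNames(bn$nodes, bn$nodes), function(v)
    factor(bn$levels[[v]][X[, v]], levels = bn$levels[[v]]))
  as_tibble(if (n == 0L) purrr::map(cols, ~ factor(character(), levels = levels(.x))) else cols)
}

#' Conservative screening of virtual patients
#'
#' Trains a cost-sensitive random forest to discriminate real from virtual
#' patients with `weight` times more weight on correctly classifying real ones
#' (default 100:1), so that a virtual patient is only called "virtual" when it
#' falls visibly outside the real distribution. The class weight enters twice:
#' it weights the splitting criterion of the forest, and it scales the
#' posterior odds of the out-of-bag leaf frequencies, giving each virtual
#' patient the confidence score
#' `weight * p / (weight * p + 1 - p)` where `p` is the forest's out-of-bag
#' estimate of `P(real | x)`. A virtual patient indistinguishable from real
#' ones therefore scores near the weighted class prior
#' (`weight / (weight + 1)`, about 0.99 at the default) and passes, while a
#' patient in a region containing no real observations scores near 0 and is
#' rejected; with `weight = 1` the score is the plain forest probability.
#' Patients below `threshold` are rejected as outliers.
#'
#' @param real,virtual discrete tables with identical columns.
#' @param weight case weight of real patients relative to virtual ones.
#' @param threshold minimum confidence for acceptance (default 0.5).
#' @param num_trees forest size.
#' @param seed RNG seed.
#' @return A `vc_cohort`: the `virtual` tibble plus columns `.confidence` and
#'   `.accepted`.
#' @export
conservative_filter <- function(real, virtual, weight = 100, threshold = 0.5,
                                num_trees = 500, seed = NULL) {
  real <- as_tibble(real); virtual <- as_tibble(virtual)
  assert_that(identical(sort(names(real)), sort(names(virtual))),
              "real and virtual tables must share columns")
  assert_that(is_scalar_number(weight) && weight > 0, "weight must be > 0")
  virtual_in <- virtual <- virtual[names(real)]
  al <- align_tables(real, virtual)
  train <- bind_rows(mutate(al$real, .label = "real"),
                     mutate(al$virtual, .label = "virtual")) |>
    mutate(.label = factor(.data$.label, levels = c("real", "virtual")))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = as.data.frame(train),
    num.trees = num_trees, probability = TRUE,
    class.weights = c(real = weight, virtual = 1),
    respect.unordered.factors = "order",
    seed = (seed %||% 1L), num.threads = 1
  )
  p <- fit$predictions[seq(nrow(real) + 1L, nrow(train)), "real"]
  p[is.nan(p)] <- 0.5 # rows never out-of-bag carry no evidence
  conf <- weight * p / (weight * p + 1 - p)
  out <- mutate(virtual_in, .confidence = as.numeric(conf),
                .accepted = .data$.confidence >= threshold)
  class(out) <- c("vc_cohort", class(out))
  out
}

#' Iteratively grow a virtual cohort
#'
#' Repeats sample-then-screen rounds — draw `batch` virtual patients by
#' [ancestral_sample()], score them with [conservative_filter()] against the
#' real cohort, keep those accepted — until `n_target` virtual patients have
#' been accepted or `max_rounds` is exhausted.
#'
#' @param bn fitted [discrete_bn()].
#' @param real real discrete table (columns = BN nodes).
#' @param n_target number of accepted virtual patients wanted.
#' @param batch patients sampled per round (default `n_target`).
#' @param max_rounds cap on rounds.
#' @inheritParams conservative_filter
#' @return A `vc_cohort` of exactly `n_target` accepted patients (columns
#'   `.confidence`, `.accepted = TRUE`), with attribute `acceptance_log`: a
#'   tibble (`round`, `sampled`, `accepted`, `rate`).
#' @export
generate_vc <- function(bn, real, n_target, batch = n_target, max_rounds = 50,
                        weight = 100, threshold = 0.5, num_trees = 500,
                        seed = NULL) {
  assert_that(is_scalar_number(n_target) && n_target >= 1, "n_target must be >= 1")
  real <- as_tibble(real)[bn$nodes]
  seeds <- derive_seeds(seed %||% 1L, 2L * max_rounds)
  kept <- list(); log <- list(); total <- 0L
  for (rd in seq_len(max_rounds)) {
    vs <- ancestral_sample(bn, batch, seed = seeds[rd])
    scored <- conservative_filter(real, vs, weight = weight,
                                  threshold = threshold, num_trees = num_trees,
                                  seed = seeds[max_rounds + rd])
    acc <- filter(scored, .data$.accepted)
    kept[[rd]] <- acc
    total <- total + nrow(acc)
    log[[rd]] <- tibble(round = rd, sampled = batch, accepted = nrow(acc),
                        rate = nrow(acc) / batch)
    if (total >= n_target) break
  }
  log <- bind_rows(log)
  if (total == 0L) {
    abort(paste0("no virtual patients accepted after ", nrow(log),
                 " rounds (acceptance rate 0)"), class = "vcforge_error")
  }
  if (total < n_target) {
    warn(paste0("only ", total, " of ", n_target,
                " virtual patients accepted after ", nrow(log), " rounds"))
  }
  out <- head(bind_rows(kept), n_target)
  class(out) <- c("vc_cohort", class(out))
  attr(out, "acceptance_log") <- log
  out
}

#' Mutilate a network for an intervention
#'
#' Implements the graph surgery behind Pearl's do-operator: all incoming edges
#' of each intervention target are removed, making the target a root. When the
#' intervention fixes a single level, the target's CPT becomes a point mass;
#' when per-patient values will be supplied at simulation time, the CPT is
#' left as the target's marginal placeholder (it is overwritten by the
#' supplied values during sampling).
#'
#' @param bn a [discrete_bn()].
#' @param spec an [intervention()].
#' @return The mutilated [discrete_bn()].
#' @export
mutilate <- function(bn, spec) {
  stopifnot(inherits(bn, "discrete_bn"), inherits(spec, "vc_intervention"))
  for (tgt in spec$nodes) {
    assert_that(tgt %in% bn$nodes, paste("unknown node:", tgt))
    r <- length(bn$levels[[tgt]])
    bn$parents[[tgt]] <- character()
    if (!is.null(spec$level)) {
      lv <- match(spec$level[[tgt]], bn$levels[[tgt]])
      assert_that(!is.na(lv), paste0("invalid level for node ", tgt, ": ",
                                     spec$level[[tgt]]),
                  class = "vcforge_level_error")
      cpt <- rep(0, r); cpt[lv] <- 1
    } else {
      # placeholder marginal; overwritten per patient during sampling
      cpt <- rep(1 / r, r)
    }
    bn$cpts[[tgt]] <- array(cpt, dim = r, dimnames = list(bn$levels[[tgt]]))
  }
  bn$order <- topo_sort(bn$nodes, bn$parents)
  bn
}

#' Specify a counterfactual intervention
#'
#' @param nodes character vector of target nodes.
#' @param level optional named list/vector giving one fixed level per target
#'   (`do(X = x)`); omit when per-patient values are passed to
#'   [simulate_intervention()].
#' @return A `vc_intervention` object.
#' @export
intervention <- function(nodes, level = NULL) {
  if (!is.null(level)) {
    if (is.null(names(level)) && length(nodes) == 1L) {
      level <- setNames(as.list(level), nodes)
    }
    level <- as.list(level)
    assert_that(all(nodes %in% names(level)), "need one level per target node")
  }
  structure(list(nodes = nodes, level = level), class = "vc_intervention")
}

#' Simulate a cohort under an intervention
#'
#' Samples from the mutilated network ([mutilate()]): intervention targets are
#' roots, so forward (logic) sampling needs no rejection — targets are set to
#' the intervened values and all other nodes are drawn in topological order
#' from their CPTs. `values` supports the per-patient case in which each
#' virtual subject receives its own intervened level (e.g. individually
#' shifted baseline cognition scores).
#'
#' @param bn a [discrete_bn()] (the observational network; mutilation happens
#'   internally).
#' @param spec an [intervention()].
#' @param n number of virtual subjects; when `values` is given it defaults to
#'   its length.
#' @param values optional tibble/data frame (or named list) of per-patient
#'   target levels, one column per target node.
#' @param seed RNG seed.
#' @return tibble of factors, one row per simulated subject.
#' @export
simulate_intervention <- function(bn, spec, n = NULL, values = NULL, seed = NULL) {
  stopifnot(inherits(bn, "discrete_bn"), inherits(spec, "vc_intervention"))
  mut <- mutilate(bn, spec)
  if (!is.null(values)) {
    values <- as_tibble(as.data.frame(values, check.names = FALSE))
    assert_that(all(spec$nodes %in% names(values)),
                "values must contain one column per target node")
    n <- n %||% nrow(values)
    assert_that(nrow(values) == n, "values must have n rows")
  } else {
    assert_that(!is.null(spec$level), "need either a fixed level or `values`")
    n <- n %||% 1L
  }
  if (n == 0L) return(ancestral_sample(mut, 0L))
  nlev <- setNames(as.list(lengths(mut$levels)), mut$nodes)
  X <- matrix(0L, n, length(mut$nodes), dimnames = list(NULL, mut$nodes))
  with_seed(seed, {
    for (v in mut$order) {
      if (v %in% spec$nodes) {
        lv <- if (!is.null(values)) {
          match(as.character(values[[v]]), mut$levels[[v]])
        } else {
          rep(match(spec$level[[v]], mut$levels[[v]]), n)
        }
        assert_that(!anyNA(lv), paste("invalid level for node", v),
                    class = "vcforge_level_error")
        X[, v] <- lv
        next
      }
      pars <- mut$parents[[v]]
      r <- nlev[[v]]
      cpt <- matrix(mut$cpts[[v]], nrow = r)
      cfg <- parent_config(X, pars, nlev)
      for (j in unique(cfg)) {
        rows <- which(cfg == j)
        X[rows, v] <- sample.int(r, length(rows), replace = TRUE, prob = cpt[, j])
      }
    }
  })
  as_tibble(purrr::map(setNames(mut$nodes, mut$nodes), function(v)
    factor(mut$levels[[v]][X[, v]], levels = mut$levels[[v]])))
}
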