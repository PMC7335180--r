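#' Supervised tree-based discretization
#'
#' Discretizes one numeric variable by the split thresholds of a depth-limited
#' univariate CART classification tree predicting a clinical label (e.g.
#' baseline diagnosis): the tree's leaves become the discrete levels. Used for
#' cohorts with a meaningful outcome label; for label-free cohorts see
#' [gmm_discretize()].
#'
#' @param values numeric vector.
#' @param labels categorical label vector of the same length (>= 2 observed
#'   classes; with a single class the method falls back to [gmm_discretize()]
#'   with a warning).
#' @param max_levels maximum number of levels (leaves).
#' @param min_leaf minimum observations per leaf (default 5% of `n`).
#' @return A `vc_discretization_map` with ordered cut points.
#' @export
tree_discretize <- function(values, labels, max_levels = 4, min_leaf = NULL) {
  assert_that(length(values) == length(labels),
              "labels must match values in length")
  assert_that(all(is.finite(values)), "non-finite values")
  n <- length(values)
  min_leaf <- min_leaf %||% max(1L, ceiling(0.05 * n))
  if (length(unique(values)) == 1L) {
    return(new_cut_map(numeric(), range(values)))
  }
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    warn("single label class; falling back to unsupervised GMM discretization")
    return(gmm_discretize(values, max_components = max_levels))
  }
  fit <- rpart::rpart(
    y ~ x, data = data.frame(x = values, y = labels), method = "class",
    control = rpart::rpart.control(cp = 0, xval = 0, maxdepth = 10,
                                   minbucket = min_leaf,
                                   minsplit = max(2L, 2L * min_leaf))
  )
  # prune back to at most max_levels leaves (leaves = nsplit + 1)
  ct <- fit$cptable
  ok <- ct[, "nsplit"] <= max_levels - 1
  cp <- min(ct[ok, "CP"])
  fit <- rpart::prune(fit, cp = cp + 1e-12)
  cuts <- if (is.null(fit$splits)) numeric() else sort(unique(fit$splits[, "index"]))
  new_cut_map(cuts, range(values))
}

new_cut_map <- function(cuts, rng) {
  structure(list(method = "tree", cuts = as.numeric(cuts),
                 n_levels = length(cuts) + 1L, range = as.numeric(rng)),
            class = "vc_discretization_map")
}

#' Unsupervised Gaussian-mixture discretization
#'
#' Fits univariate Gaussian mixtures with 1 to `max_components` components,
#' selects the component count by BIC, and assigns each value to its
#' maximum-responsibility component; levels are ordered by component mean.
#'
#' @param values numeric vector (>= 10 observations).
#' @param max_components maximum mixture size.
#' @param seed kept for interface symmetry (the EM fit is deterministic given
#'   the data).
#' @return A `vc_discretization_map` with component parameters.
#' @export
gmm_discretize <- function(values, max_components = 5, seed = NULL) {
  assert_that(all(is.finite(values)), "non-finite values")
  if (length(unique(values)) == 1L) {
    return(structure(list(method = "gmm", means = values[1], sds = 1,
                          weights = 1, n_levels = 1L, range = range(values)),
                     class = "vc_discretization_map"))
  }
  assert_that(length(values) >= 10, "need at least 10 observations")
  fit <- with_seed(seed, suppressWarnings(
    Mclust(values, G = seq_len(max_components), verbose = FALSE)
  ))
  par <- fit$parameters
  sds <- sqrt(if (length(par$variance$sigmasq) == 1L) {
    rep(par$variance$sigmasq, fit$G)
  } else par$variance$sigmasq)
  ord <- order(par$mean)
  structure(list(method = "gmm", means = as.numeric(par$mean[ord]),
                 sds = as.numeric(sds[ord]),
                 weights = as.numeric(par$pro[ord]),
                 n_levels = as.integer(fit$G), range = range(values)),
            class = "vc_discretization_map")
}

#' @export
print.vc_discretization_map <- function(x, ...) {
  cat("<vc_discretization_map> ", x$method, ", ", x$n_levels, " level(s)\n",
      sep = "")
  invisible(x)
}

# integer level (1-based) of numeric values under one map
map_levels <- function(map, x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  if (map$n_levels == 1L) {
    out[ok] <- 1L
    return(out)
  }
  if (map$method == "tree") {
    out[ok] <- findInterval(x[ok], map$cuts) + 1L # clamps at the extremes
  } else {
    resp <- vapply(seq_len(map$n_levels), function(k)
      log(map$weights[k]) + stats::dnorm(x[ok], map$means[k], map$sds[k],
                                         log = TRUE),
      numeric(sum(ok)))
    resp <- matrix(resp, ncol = map$n_levels)
    out[ok] <- max.col(resp, ties.method = "first")
  }
  out
}

#' Representative value of each discrete level
#'
#' For cut-point maps, interval midpoints (outer intervals bounded by the
#' training range); for GMM maps, the component means.
#'
#' @param map a `vc_discretization_map`.
#' @return numeric vector of length `n_levels`.
#' @export
discretization_midpoints <- function(map) {
  stopifnot(inherits(map, "vc_discretization_map"))
  if (map$method == "gmm") return(map$means)
  b <- c(map$range[1], map$cuts, map$range[2])
  (head(b, -1) + tail(b, -1)) / 2
}

#' Build discretization maps for every numeric column
#'
#' @param data tibble of module scores (and continuous statics).
#' @param method `"gmm"` (unsupervised) or `"tree"` (supervised; needs
#'   `labels`).
#' @param labels label vector for `method = "tree"`.
#' @param ... passed to [tree_discretize()] / [gmm_discretize()].
#' @return named list of `vc_discretization_map`s (class
#'   `vc_discretization`).
#' @export
build_discretization <- function(data, method = c("gmm", "tree"),
                                 labels = NULL, ...) {
  method <- match.arg(method)
  data <- as_tibble(data)
  cols <- names(data)[vapply(data, is.double, TRUE)]
  cols <- setdiff(cols, "patient_id")
  maps <- purrr::map(setNames(cols, cols), function(j) {
    if (method == "tree") {
      tree_discretize(data[[j]], labels, ...)
    } else {
      gmm_discretize(data[[j]], ...)
    }
  })
  structure(maps, class = "vc_discretization")
}

#' Apply discretization maps to a table
#'
#' Double-typed columns are replaced by their integer level (1-based) under
#' the matching map; values outside the training range clamp to the nearest
#' boundary level; missing cells stay missing. Integer, factor and character
#' columns (already discrete, e.g. auxiliary indicators) pass through
#' unchanged. A double column without a map is an error.
#'
#' @param data tibble (cohort scores or raw continuous columns).
#' @param maps named list of maps from [build_discretization()] (or a single
#'   map when `data` is a bare numeric vector).
#' @return tibble with discretized integer columns.
#' @export
apply_discretization <- function(data, maps) {
  if (is.numeric(data) && is.null(dim(data))) {
    stopifnot(inherits(maps, "vc_discretization_map"))
    return(map_levels(maps, data))
  }
  data <- as_tibble(data)
  for (j in names(data)) {
    if (j == "patient_id") next
    if (!is.null(maps[[j]])) {
      data[[j]] <- map_levels(maps[[j]], data[[j]])
    } else if (is.double(data[[j]])) {
      abort(paste("unseen feature: no discretization map for column", j),
            class = "vcforge_error")
    }
  }
  data
}
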