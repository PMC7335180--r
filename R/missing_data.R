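#' Iterative random-forest imputation of remaining missing cells
#'
#' Completes a cohort by the iterative random-forest scheme: missing cells are
#' initialized with the column mean (continuous) or mode (categorical); then,
#' visiting columns in order of increasing missingness, a forest is fit on the
#' currently-observed rows of each incomplete column (all other columns as
#' one-hot-encoded predictors) and its predictions replace that column's
#' missing cells. Iterations repeat until the convergence statistic first
#' increases (the previous iteration's values are returned) or `max_iter` is
#' reached. The convergence statistic is the sum of squared changes of imputed
#' continuous cells normalized by their current sum of squares, plus the
#' fraction of changed imputed categories.
#'
#' Auxiliary indicator columns (class `"aux"` in the schema, or named
#' `aux_*`) are fully observed by construction; they serve as predictors but
#' are never imputed, so downstream estimates stay conditioned on the
#' missingness pattern. Observed cells are never altered.
#'
#' @param cohort cohort tibble (missing cells `NA`).
#' @param schema optional [vc_schema()]; identifies categorical features and
#'   auxiliary columns. Without it, non-numeric columns are treated as
#'   categorical and `aux_*` columns as auxiliary.
#' @param n_trees forest size per column and iteration (>= 1).
#' @param max_iter iteration cap.
#' @param seed RNG seed.
#' @return A `vc_imputation`: list with `cohort` (completed), `convergence`
#'   (tibble: `iteration`, `continuous`, `categorical`) and `iterations`.
#' @export
rf_impute <- function(cohort, schema = NULL, n_trees = 100, max_iter = 10,
                      seed = NULL) {
  assert_that(n_trees >= 1, "n_trees must be >= 1")
  cohort <- as_tibble(cohort)
  id_cols <- intersect("patient_id", names(cohort))
  aux_cols <- if (!is.null(schema)) {
    auxg <- schema$groups$group[schema$groups$class == "aux"]
    f <- filter(schema$features, .data$group %in% auxg)
    intersect(feature_col(f$name, f$visit), names(cohort))
  } else {
    grep("^aux_", names(cohort), value = TRUE)
  }
  feat_cols <- setdiff(names(cohort), c(id_cols, aux_cols))

  cat_cols <- if (!is.null(schema)) {
    f <- schema$features
    cc <- feature_col(f$name, f$visit)[f$dtype != "continuous"]
    intersect(cc, feat_cols)
  } else {
    feat_cols[!vapply(cohort[feat_cols], is.numeric, TRUE)]
  }

  work <- cohort[c(feat_cols, aux_cols)]
  for (j in cat_cols) work[[j]] <- factor(work[[j]])
  for (j in setdiff(feat_cols, cat_cols)) {
    x <- work[[j]]
    assert_that(all(is.finite(x) | is.na(x)),
                paste("non-finite observed value in column", j))
  }
  n_miss <- vapply(work[feat_cols], function(x) sum(is.na(x)), 0L)
  all_na <- feat_cols[n_miss == nrow(work)]
  assert_that(length(all_na) == 0L,
              paste("column(s) entirely missing:", paste(all_na, collapse = ", ")),
              class = "vcforge_error")

  out <- function(completed, conv, iters) {
    done <- cohort
    for (j in feat_cols) {
      done[[j]] <- if (j %in% cat_cols && is.numeric(cohort[[j]])) {
        as.numeric(as.character(completed[[j]]))
      } else if (j %in% cat_cols && !is.factor(cohort[[j]])) {
        as.character(completed[[j]])
      } else {
        completed[[j]]
      }
    }
    structure(list(cohort = done, convergence = conv, iterations = iters),
              class = "vc_imputation")
  }
  targets <- feat_cols[n_miss > 0]
  if (length(targets) == 0L) {
    return(out(work, tibble(iteration = integer(), continuous = numeric(),
                            categorical = numeric()), 0L))
  }
  targets <- targets[order(n_miss[targets])]
  na_idx <- purrr::map(setNames(targets, targets), ~ which(is.na(work[[.x]])))

  # initial guesses: column mean / mode
  cur <- work
  for (j in targets) {
    if (j %in% cat_cols) {
      tab <- table(cur[[j]])
      cur[[j]][na_idx[[j]]] <- names(tab)[which.max(tab)]
    } else {
      cur[[j]][na_idx[[j]]] <- mean(cur[[j]], na.rm = TRUE)
    }
  }

  one_hot <- function(df) {
    mats <- purrr::imap(df, function(x, j) {
      if (is.numeric(x)) {
        m <- matrix(x, ncol = 1); colnames(m) <- j; m
      } else {
        lev <- levels(factor(x))
        m <- outer(as.character(x), lev, `==`) * 1
        colnames(m) <- paste0(j, "=", lev); m
      }
    })
    do.call(cbind, unname(mats))
  }

  seeds <- derive_seeds(seed %||% 1L, max_iter * length(targets))
  conv <- list(); si <- 0L
  prev <- cur; prev_stat <- Inf
  for (it in seq_len(max_iter)) {
    before <- cur
    for (j in targets) {
      si <- si + 1L
      X <- one_hot(cur[setdiff(names(cur), j)])
      obs <- setdiff(seq_len(nrow(cur)), na_idx[[j]])
      tr <- data.frame(X[obs, , drop = FALSE], check.names = FALSE)
      tr$.y <- cur[[j]][obs]
      fit <- ranger::ranger(dependent.variable.name = ".y", data = tr,
                            num.trees = n_trees, seed = seeds[si],
                            num.threads = 1)
      pr <- predict(fit, data = data.frame(X[na_idx[[j]], , drop = FALSE],
                                           check.names = FALSE),
                    num.threads = 1)$predictions
      cur[[j]][na_idx[[j]]] <- pr
    }
    # convergence statistic over imputed cells only
    dc <- 0; denom <- 0; changed <- 0; ncat <- 0
    for (j in targets) {
      new <- cur[[j]][na_idx[[j]]]; old <- before[[j]][na_idx[[j]]]
      if (j %in% cat_cols) {
        changed <- changed + sum(as.character(new) != as.character(old))
        ncat <- ncat + length(new)
      } else {
        dc <- dc + sum((as.numeric(new) - as.numeric(old))^2)
        denom <- denom + sum(as.numeric(new)^2)
      }
    }
    stat_c <- if (denom > 0) dc / denom else 0
    stat_k <- if (ncat > 0) changed / ncat else 0
    conv[[it]] <- tibble(iteration = it, continuous = stat_c, categorical = stat_k)
    stat <- stat_c + stat_k
    if (stat >= prev_stat) {
      return(out(prev, bind_rows(conv), it - 1L))
    }
    prev <- cur; prev_stat <- stat
  }
  out(cur, bind_rows(conv), max_iter)
}

#' @export
print.vc_imputation <- function(x, ...) {
  cat("<vc_imputation> converged after", x$iterations, "iteration(s)\n")
  invisible(x)
}
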