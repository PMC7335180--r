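#' Standardized partial AUC at high sensitivity for real patients
#'
#' Computes the partial area under the ROC curve of a real-vs-virtual
#' classifier restricted to the sensitivity region `[sens_lo, 1]` for the
#' positive class `"real"` — the operating region where real patients are
#' detected at a rate of at least `sens_lo`. The raw trapezoidal area `A`
#' (of specificity integrated over sensitivity) is standardized by McClish's
#' correction, `A_std = (1 + (A - A_min)/(A_max - A_min)) / 2`, with
#' `A_max = 1 - sens_lo` (perfect separation) and `A_min` the area under the
#' chance diagonal over the same region, so that 0.5 is chance level and 1 is
#' perfect discrimination. Higher scores must indicate the class `"real"`.
#'
#' @param scores numeric classifier scores (probability of being real).
#' @param labels vector with values `"real"`/`"virtual"` (anything other than
#'   `"real"` counts as virtual); both classes must be present.
#' @param sens_lo lower sensitivity bound, in `[0, 1)` (default 0.9).
#' @return scalar standardized pAUC in `(0, 1]`.
#' @export
pauc <- function(scores, labels, sens_lo = 0.9) {
  assert_that(is.numeric(scores) && length(scores) == length(labels),
              "scores and labels must be equal-length")
  assert_that(is_scalar_number(sens_lo) && sens_lo >= 0 && sens_lo < 1,
              "sens_lo must be in [0, 1)")
  is_real <- as.character(labels) == "real"
  assert_that(any(is_real) && any(!is_real), "both classes must be present")
  pos <- scores[is_real]; neg <- scores[!is_real]
  th <- sort(unique(scores), decreasing = TRUE)
  se <- vapply(th, function(t) mean(pos >= t), 0)
  sp <- vapply(th, function(t) mean(neg < t), 0)
  se <- c(0, se); sp <- c(1, sp) # threshold above all scores

  # trapezoidal area of sp over se restricted to [sens_lo, 1]
  area <- 0
  for (i in seq_len(length(se) - 1L)) {
    s0 <- se[i]; s1 <- se[i + 1L]
    if (s1 <= sens_lo || s1 == s0) next
    p0 <- sp[i]; p1 <- sp[i + 1L]
    lo <- max(s0, sens_lo)
    # linear interpolation of specificity at the clipped left endpoint
    pl <- p0 + (p1 - p0) * (lo - s0) / (s1 - s0)
    area <- area + (s1 - lo) * (pl + p1) / 2
  }
  a_max <- 1 - sens_lo
  a_min <- (1 - sens_lo)^2 / 2
  0.5 * (1 + (area - a_min) / (a_max - a_min))
}

#' Cross-validated pAUC of a real-vs-virtual random forest
#'
#' Measures how separable a virtual cohort is from the real one: within each
#' of `repeats` repetitions of a stratified `k`-fold cross-validation, an
#' unweighted random forest is trained to discriminate real from virtual
#' patients on the training folds and the standardized [pauc()] is computed on
#' the held-out fold. A virtual cohort indistinguishable from the real one
#' yields pAUC values concentrated around 0.5 (chance level).
#'
#' @param real,virtual tables with identical columns.
#' @param k folds (each class must have at least `k` rows).
#' @param repeats repetitions of the cross-validation.
#' @param sens_lo lower sensitivity bound for [pauc()].
#' @param num_trees forest size.
#' @param seed RNG seed.
#' @return A `vc_pauc_report`: list with `scores` tibble
#'   (`rep`, `fold`, `pauc`) and `summary` (median and IQR).
#' @export
pauc_cv <- function(real, virtual, k = 10, repeats = 10, sens_lo = 0.9,
                    num_trees = 500, seed = NULL) {
  real <- as_tibble(real); virtual <- as_tibble(virtual)
  assert_that(identical(sort(names(real)), sort(names(virtual))),
              "real and virtual tables must share columns")
  assert_that(nrow(real) >= k && nrow(virtual) >= k,
              "need at least k rows per class")
  virtual <- virtual[names(real)]
  al <- align_tables(real, virtual)
  full <- bind_rows(mutate(al$real, .label = "real"),
                    mutate(al$virtual, .label = "virtual")) |>
    mutate(.label = factor(.data$.label, levels = c("real", "virtual"))) |>
    as.data.frame()
  n_r <- nrow(real); n_v <- nrow(virtual)
  seeds <- derive_seeds(seed %||% 1L, repeats * (k + 1L))
  rows <- list(); si <- 0L
  for (rp in seq_len(repeats)) {
    si <- si + 1L
    folds <- with_seed(seeds[si], c(sample(rep_len(seq_len(k), n_r)),
                                    sample(rep_len(seq_len(k), n_v))))
    for (f in seq_len(k)) {
      si <- si + 1L
      fit <- ranger::ranger(
        dependent.variable.name = ".label",
        data = full[folds != f, , drop = FALSE],
        num.trees = num_trees, probability = TRUE,
        respect.unordered.factors = "order",
        seed = seeds[si], num.threads = 1
      )
      test <- full[folds == f, , drop = FALSE]
      pr <- predict(fit, data = test, num.threads = 1)$predictions[, "real"]
      rows[[length(rows) + 1L]] <-
        tibble(rep = rp, fold = f, pauc = pauc(pr, test$.label, sens_lo))
    }
  }
  scores <- bind_rows(rows)
  structure(list(scores = scores,
                 summary = tibble(median = median(scores$pauc),
                                  iqr = stats::IQR(scores$pauc)),
                 sens_lo = sens_lo),
            class = "vc_pauc_report")
}

#' @export
print.vc_pauc_report <- function(x, ...) {
  cat("<vc_pauc_report> ", nrow(x$scores), " folds; median pAUC ",
      format(x$summary$median, digits = 3), " (IQR ",
      format(x$summary$iqr, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Per-variable homogeneity tests between real and virtual cohorts
#'
#' For every shared column, tests the null hypothesis that real and virtual
#' samples come from the same categorical distribution using a Pearson
#' chi-squared test (no continuity correction) on the 2-by-L contingency table
#' of sample membership against observed levels, followed by multiple-testing
#' correction across variables. Columns with a single observed level overall
#' carry no information and are flagged as skipped.
#'
#' @param real,virtual discrete tables with shared columns.
#' @param correction a [stats::p.adjust()] method (default `"BH"`).
#' @return tibble with columns `feature`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `skipped`.
#' @export
homogeneity_tests <- function(real, virtual, correction = "BH") {
  real <- as_tibble(real); virtual <- as_tibble(virtual)
  cols <- intersect(names(real), names(virtual))
  cols <- setdiff(cols, c("patient_id", ".confidence", ".accepted"))
  assert_that(length(cols) > 0, "no shared columns to test")
  rows <- purrr::map(cols, function(j) {
    x <- c(as.character(real[[j]]), as.character(virtual[[j]]))
    g <- rep(c("real", "virtual"), c(nrow(real), nrow(virtual)))
    keep <- !is.na(x)
    lev <- unique(x[keep])
    if (length(lev) < 2L) {
      return(tibble(feature = j, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, skipped = TRUE))
    }
    tab <- table(factor(g[keep], c("real", "virtual")), factor(x[keep], lev))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble(feature = j, statistic = unname(ct$statistic),
           df = unname(ct$parameter), p_value = unname(ct$p.value),
           skipped = FALSE)
  }) |> bind_rows()
  rows$p_adjusted <- p.adjust(rows$p_value, method = correction)
  select(rows, "feature", "statistic", "df", "p_value", "p_adjusted", "skipped")
}
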