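#' Ground-truth generator for longitudinal cohorts
#'
#' Builds a known generative model with the statistical structure the
#' virtual-cohort method assumes: discrete latent group scores evolving over
#' visits under a random forward-in-time DAG, per-group continuous feature
#' emissions (loading times level plus Gaussian noise), and a monotone
#' missing-not-at-random drop-out model that is logistic in the latent score.
#' Every downstream module can be validated against this model without any
#' real study data.
#'
#' The DAG contains each group's temporal chain (`g@t -> g@t+1`), random
#' within-visit edges following a fixed random group order, and sparse
#' cross-group forward edges. CPT rows are Dirichlet draws rescaled to lie in
#' `[0.05, 0.95]`, so no configuration is deterministic; a small
#' `concentration` gives spiky rows (strong dependence).
#'
#' @param n_groups number of variable groups.
#' @param n_features_per_group continuous raw features emitted per group.
#' @param n_visits number of visits (labels `bl`, `m06`, `m12`, ...).
#' @param levels discrete levels per latent score.
#' @param concentration Dirichlet concentration of CPT rows (small = spiky).
#' @param p_within,p_cross probabilities of within-visit and cross-group
#'   forward edges (temporal self-chains are always present).
#' @param noise_sd emission noise standard deviation.
#' @param seed RNG seed.
#' @return A `vc_ground_truth`: true [discrete_bn()], matching [vc_schema()],
#'   per-group emission loadings, and the drop-out model parameters.
#' @export
make_ground_truth <- function(n_groups = 4, n_features_per_group = 6,
                              n_visits = 3, levels = 3, concentration = 0.5,
                              p_within = 0.3, p_cross = 0.15, noise_sd = 0.3,
                              seed = NULL) {
  assert_that(n_groups >= 1 && n_features_per_group >= 1 && n_visits >= 1 &&
                levels >= 1, "all counts must be >= 1")
  groups <- paste0("g", seq_len(n_groups))
  offs <- 6 * (seq_len(n_visits) - 1)
  visits <- c("bl", paste0("m", sprintf("%02d", offs[-1])))[seq_len(n_visits)]
  schedule <- tibble(visit = visits, offset = offs)
  nodes <- as.vector(outer(groups, visits, node_id))
  lev <- as.character(seq_len(levels))

  with_seed(seed, {
    group_order <- sample(groups) # within-visit topological order
    parents <- purrr::map(setNames(nodes, nodes), ~ character())
    for (t in seq_len(n_visits)) {
      for (i in seq_len(n_groups)) {
        v <- node_id(group_order[i], visits[t])
        if (t > 1) {
          parents[[v]] <- c(parents[[v]], node_id(group_order[i], visits[t - 1]))
          for (gj in setdiff(groups, group_order[i])) {
            if (runif(1) < p_cross) {
              parents[[v]] <- c(parents[[v]], node_id(gj, visits[t - 1]))
            }
          }
        }
        if (i > 1) {
          for (j in seq_len(i - 1)) {
            if (runif(1) < p_within) {
              parents[[v]] <- c(parents[[v]], node_id(group_order[j], visits[t]))
            }
          }
        }
      }
    }
    rdirichlet_row <- function(L) {
      w <- stats::rgamma(L, concentration) + 1e-12
      w <- w / sum(w)
      eps <- min(0.05, 1 / (2 * L))
      eps + (1 - L * eps) * w
    }
    cpts <- purrr::imap(parents, function(pars, v) {
      q <- prod(c(1, rep(levels, length(pars))))
      m <- vapply(seq_len(q), function(j) rdirichlet_row(levels),
                  numeric(levels))
      array(m, dim = c(levels, rep(levels, length(pars))),
            dimnames = c(list(lev), rep(list(lev), length(pars))))
    })
    bn <- discrete_bn(purrr::map(setNames(nodes, nodes), ~ lev), parents, cpts)

    emissions <- purrr::map(setNames(groups, groups), function(g) {
      load <- runif(n_features_per_group, 0.6, 1.4) *
        sample(c(-1, 1), n_features_per_group, replace = TRUE)
      names(load) <- paste0(g, "_f", seq_len(n_features_per_group))
      list(loadings = load, noise_sd = noise_sd)
    })

    features <- tidyr::expand_grid(group = groups,
                                   k = seq_len(n_features_per_group),
                                   visit = visits) |>
      mutate(name = paste0(.data$group, "_f", .data$k),
             dtype = "continuous") |>
      select("name", "dtype", "group", "visit")
    schema <- vc_schema(features,
                        tibble(group = groups, class = "biomarker"),
                        schedule)

    structure(list(bn = bn, schema = schema, emissions = emissions,
                   dropout = list(slope = 2), levels = levels),
              class = "vc_ground_truth")
  })
}

#' @export
print.vc_ground_truth <- function(x, ...) {
  cat("<vc_ground_truth> ", length(x$bn$nodes), " latent nodes, ",
      nrow(x$schema$features), " raw features\n", sep = "")
  invisible(x)
}

#' Sample a raw longitudinal cohort from a ground-truth model
#'
#' Draws latent group levels by ancestral sampling from the true network,
#' emits raw continuous features (`loading * level + noise`), and applies
#' monotone MNAR drop-out: from the second visit on, a patient's group block
#' drops out with probability `dropout_strength * plogis(slope * z)` where `z`
#' is the visit's latent level scaled to `[-1, 1]` — higher scores drive
#' drop-out — and a dropped group stays missing at all later visits. Baseline
#' is always observed.
#'
#' @param gt a [make_ground_truth()] model.
#' @param n number of patients.
#' @param dropout_strength in `[0, 1]`; 0 gives a complete table.
#' @param seed RNG seed.
#' @return cohort tibble (`patient_id`, `feature@visit` columns) with
#'   attributes `latent` (true discrete level tibble) and `mask` (logical
#'   missingness matrix).
#' @export
sample_cohort <- function(gt, n, dropout_strength = 0.5, seed = NULL) {
  stopifnot(inherits(gt, "vc_ground_truth"))
  assert_that(is_scalar_number(n) && n >= 1, "n must be >= 1")
  seeds <- derive_seeds(seed %||% 1L, 2L)
  latent <- ancestral_sample(gt$bn, n, seed = seeds[1])
  groups <- gt$schema$groups$group
  visits <- gt$schema$schedule$visit
  L <- gt$levels

  with_seed(seeds[2], {
    cols <- list(patient_id = sprintf("P%05d", seq_len(n)))
    for (g in groups) {
      em <- gt$emissions[[g]]
      for (v in visits) {
        lv <- as.numeric(as.character(latent[[node_id(g, v)]]))
        for (f in names(em$loadings)) {
          cols[[feature_col(f, v)]] <- em$loadings[[f]] * lv +
            rnorm(n, 0, em$noise_sd)
        }
      }
    }
    cohort <- as_tibble(cols)

    if (dropout_strength > 0 && length(visits) > 1) {
      for (g in groups) {
        dropped <- rep(FALSE, n)
        for (v in visits[-1]) {
          lv <- as.numeric(as.character(latent[[node_id(g, v)]]))
          z <- if (L > 1) 2 * (lv - 1) / (L - 1) - 1 else 0
          p <- dropout_strength * plogis(gt$dropout$slope * z)
          dropped <- dropped | (runif(n) < p)
          if (any(dropped)) {
            for (f in names(gt$emissions[[g]]$loadings)) {
              cohort[[feature_col(f, v)]][dropped] <- NA_real_
            }
          }
        }
      }
    }
    attr(cohort, "latent") <- latent
    attr(cohort, "mask") <- is.na(as.matrix(cohort[-1]))
    cohort
  })
}
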