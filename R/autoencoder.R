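#' Autoencoder hyper-parameter specification
#'
#' Describes one sparse-autoencoder candidate: encoder widths `d -> hidden ...
#' -> q` with activation `activation` on every encoder layer, a mirrored
#' decoder (`decoder_activation` on hidden decoder layers, linear output so
#' standardized inputs can be reconstructed), dropout applied to the *input*
#' layer during training (the sparsity device), and an l2 penalty on all
#' weights. Training minimizes reconstruction MSE + `l2 * sum(W^2)`.
#'
#' @param hidden integer vector of encoder hidden widths (empty for a single
#'   encoding layer `d -> q`).
#' @param q latent dimension (>= 1).
#' @param activation encoder activation: `"sigmoid"`, `"relu"` or `"linear"`.
#' @param decoder_activation activation of decoder hidden layers.
#' @param dropout input dropout rate in `[0, 1)`.
#' @param l2 weight penalty (>= 0).
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param optimizer `"adam"` or plain gradient descent `"gd"`.
#' @param seed weight-initialization / shuffling seed.
#' @return An `ae_spec` object.
#' @export
ae_spec <- function(hidden = integer(), q = 1, activation = "sigmoid",
                    decoder_activation = "linear", dropout = 0.2, l2 = 1e-4,
                    lr = 0.01, epochs = 300, batch_size = 32,
                    optimizer = "adam", seed = 1) {
  assert_that(q >= 1, "q must be >= 1")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assert_that(l2 >= 0, "l2 must be >= 0")
  assert_that(activation %in% c("sigmoid", "relu", "linear"), "unknown activation")
  structure(list(hidden = as.integer(hidden), q = as.integer(q),
                 activation = activation, decoder_activation = decoder_activation,
                 dropout = dropout, l2 = l2, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "ae_spec")
}

#' Default autoencoder search grid
#'
#' Two encoder depths (`d -> q` and `d -> ceiling(d/2) -> q`), sigmoid and
#' relu activations, input dropout in \{0.2, 0.5\} and l2 in \{1e-4, 1e-3\}.
#'
#' @param d input dimension.
#' @param q latent dimension.
#' @param ... overrides passed to every [ae_spec()].
#' @return list of `ae_spec`s.
#' @export
default_ae_grid <- function(d, q = 1, ...) {
  grid <- expand.grid(depth = 1:2, act = c("sigmoid", "relu"),
                      dropout = c(0.2, 0.5), l2 = c(1e-4, 1e-3),
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(depth, act, dropout, l2) {
    hidden <- if (depth == 2 && d > 2) ceiling(d / 2) else integer()
    ae_spec(hidden = hidden, q = q, activation = act, dropout = dropout,
            l2 = l2, ...)
  })
}

act_fun <- function(name) {
  switch(name,
         sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                        df = function(a) a * (1 - a)),
         relu = list(f = function(x) pmax(x, 0),
                     df = function(a) (a > 0) * 1),
         linear = list(f = identity, df = function(a) 1))
}

init_layers <- function(widths, acts) {
  purrr::map(seq_len(length(widths) - 1L), function(i) {
    fan_in <- widths[i]; fan_out <- widths[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = rep(0, fan_out), act = acts[i])
  })
}

forward_layers <- function(A, layers) {
  out <- vector("list", length(layers) + 1L)
  out[[1]] <- A
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    out[[i + 1L]] <- act_fun(L$act)$f(sweep(out[[i]] %*% L$W, 2, L$b, "+"))
  }
  out
}

# Train an MLP autoencoder; returns layers plus loss history.
train_mlp_ae <- function(X, spec) {
  n <- nrow(X); d <- ncol(X)
  widths <- c(d, spec$hidden, spec$q, rev(spec$hidden), d)
  n_enc <- length(spec$hidden) + 1L
  acts <- c(rep(spec$activation, n_enc),
            rep(spec$decoder_activation, length(spec$hidden)), "linear")
  layers <- with_seed(spec$seed, init_layers(widths, acts))
  mom <- purrr::map(layers, ~ list(mW = .x$W * 0, vW = .x$W * 0,
                                   mb = .x$b * 0, vb = .x$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  loss_hist <- numeric(spec$epochs)

  with_seed(spec$seed + 1L, {
    for (ep in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / max(1L, spec$batch_size)))
      for (bt in batches) {
        Xb <- X[bt, , drop = FALSE]
        Xin <- Xb
        if (spec$dropout > 0) {
          mask <- matrix(rbinom(length(Xb), 1, 1 - spec$dropout),
                         nrow(Xb)) / (1 - spec$dropout)
          Xin <- Xb * mask
        }
        acts_out <- forward_layers(Xin, layers)
        Z <- acts_out[[length(acts_out)]]
        delta <- 2 * (Z - Xb) / (nrow(Xb) * d) # d MSE / d Z
        step <- step + 1
        for (i in rev(seq_along(layers))) {
          L <- layers[[i]]
          dact <- act_fun(L$act)$df(acts_out[[i + 1L]])
          delta <- delta * dact
          gW <- crossprod(acts_out[[i]], delta) + 2 * spec$l2 * L$W
          gb <- colSums(delta)
          delta <- delta %*% t(L$W)
          if (spec$optimizer == "adam") {
            m <- mom[[i]]
            m$mW <- b1 * m$mW + (1 - b1) * gW; m$vW <- b2 * m$vW + (1 - b2) * gW^2
            m$mb <- b1 * m$mb + (1 - b1) * gb; m$vb <- b2 * m$vb + (1 - b2) * gb^2
            mom[[i]] <- m
            layers[[i]]$W <- L$W - spec$lr * (m$mW / (1 - b1^step)) /
              (sqrt(m$vW / (1 - b2^step)) + eps)
            layers[[i]]$b <- L$b - spec$lr * (m$mb / (1 - b1^step)) /
              (sqrt(m$vb / (1 - b2^step)) + eps)
          } else {
            layers[[i]]$W <- L$W - spec$lr * gW
            layers[[i]]$b <- L$b - spec$lr * gb
          }
        }
      }
      Zf <- forward_layers(X, layers)[[length(layers) + 1L]]
      loss_hist[ep] <- mean((Zf - X)^2) +
        spec$l2 * sum(vapply(layers, function(L) sum(L$W^2), 0))
    }
  })
  list(layers = layers, loss = loss_hist, n_enc = n_enc)
}

# Build the standardization recipe for one feature block.
make_prep <- function(data) {
  data <- as.data.frame(data)
  cols <- list()
  for (j in names(data)) {
    x <- data[[j]]
    if (is.numeric(x)) {
      assert_that(all(is.finite(x)), paste("non-finite values in column", j))
      s <- sd(x); if (!is.finite(s) || s == 0) s <- 1
      cols[[j]] <- list(type = "continuous", center = mean(x), scale = s)
    } else {
      lev <- sort(unique(as.character(x)))
      cols[[j]] <- list(type = "categorical", levels = lev)
    }
  }
  cols
}

prep_apply <- function(prep, data) {
  data <- as.data.frame(data)
  mats <- purrr::imap(prep, function(p, j) {
    assert_that(j %in% names(data), paste("unseen feature: missing column", j),
                class = "vcforge_error")
    x <- data[[j]]
    if (p$type == "continuous") {
      m <- matrix((x - p$center) / p$scale, ncol = 1)
      colnames(m) <- j
      m
    } else {
      # one-hot (values already in [0, 1], i.e. min-max scaled)
      m <- outer(as.character(x), p$levels, `==`) * 1
      colnames(m) <- paste0(j, "=", p$levels)
      m
    }
  })
  do.call(cbind, unname(mats))
}

prep_invert <- function(prep, Z) {
  out <- list(); at <- 1L
  for (j in names(prep)) {
    p <- prep[[j]]
    if (p$type == "continuous") {
      out[[j]] <- Z[, at] * p$scale + p$center
      at <- at + 1L
    } else {
      k <- length(p$levels)
      block <- Z[, at:(at + k - 1L), drop = FALSE]
      out[[j]] <- p$levels[max.col(block)]
      at <- at + k
    }
  }
  as_tibble(out)
}

#' Train the sparse autoencoder of one variable group at one visit
#'
#' Runs a grid search: every [ae_spec()] candidate is trained on a random 80%
#' of the rows and scored by reconstruction MSE on the held-out 20%; the best
#' candidate is refit on all rows. Continuous inputs are z-scored and
#' categorical inputs one-hot encoded (training-time statistics are stored and
#' reused by [encode_cohort()]). Groups with a single feature bypass training
#' entirely and get an identity (pass-through) encoder with zero MSE.
#'
#' @param data complete data frame/matrix of the block's raw features (no
#'   missing values; impute first).
#' @param grid list of [ae_spec()] candidates (default [default_ae_grid()]).
#' @param holdout held-out fraction for grid selection.
#' @param seed split seed.
#' @return A `vc_encoder`: standardization recipe, encoder/decoder layers,
#'   winning spec, `train_mse`, `valid_mse`, and the per-candidate grid MSEs.
#' @export
train_group_autoencoder <- function(data, grid = NULL, holdout = 0.2,
                                    seed = NULL) {
  data <- as.data.frame(data, check.names = FALSE)
  if (ncol(data) == 1L) {
    return(structure(list(passthrough = TRUE, feature = names(data),
                          prep = make_prep(data), q = 1L,
                          train_mse = 0, valid_mse = 0),
                     class = "vc_encoder"))
  }
  prep <- make_prep(data)
  X <- prep_apply(prep, data)
  assert_that(all(is.finite(X)), "non-finite inputs")
  if (is.null(grid)) grid <- default_ae_grid(ncol(X))
  assert_that(length(grid) > 0, "empty grid")
  n <- nrow(X)
  idx_val <- with_seed(seed %||% 1L,
                       sample.int(n, max(1L, round(holdout * n))))
  Xtr <- X[-idx_val, , drop = FALSE]; Xva <- X[idx_val, , drop = FALSE]
  fits <- purrr::map(grid, ~ train_mlp_ae(Xtr, .x))
  vmse <- vapply(fits, function(f) {
    Z <- forward_layers(Xva, f$layers)[[length(f$layers) + 1L]]
    mean((Z - Xva)^2)
  }, 0)
  best <- which.min(vmse)
  final <- train_mlp_ae(X, grid[[best]])
  Zf <- forward_layers(X, final$layers)[[length(final$layers) + 1L]]
  structure(list(passthrough = FALSE, prep = prep,
                 layers = final$layers, n_enc = final$n_enc,
                 spec = grid[[best]], q = grid[[best]]$q,
                 loss = final$loss,
                 train_mse = mean((Zf - X)^2), valid_mse = vmse[best],
                 grid_mse = vmse),
            class = "vc_encoder")
}

#' @export
print.vc_encoder <- function(x, ...) {
  if (isTRUE(x$passthrough)) {
    cat("<vc_encoder> pass-through (single feature:", x$feature, ")\n")
  } else {
    cat("<vc_encoder> ", length(x$prep), " features -> q=", x$q,
        " (", x$spec$activation, "), train MSE ",
        format(x$train_mse, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

encoder_scores <- function(enc, data) {
  if (isTRUE(enc$passthrough)) {
    m <- matrix(as.numeric(as.data.frame(data)[[enc$feature]]), ncol = 1)
    return(m)
  }
  X <- prep_apply(enc$prep, data)
  forward_layers(X, enc$layers[seq_len(enc$n_enc)])[[enc$n_enc + 1L]]
}

#' Train autoencoders for every variable-group block of a cohort
#'
#' Convenience wrapper: one [train_group_autoencoder()] per (group, visit)
#' block of non-auxiliary features.
#'
#' @param cohort complete cohort tibble.
#' @param schema matching [vc_schema()].
#' @param grid_fn function `(d) -> list of ae_spec` (default
#'   [default_ae_grid()]).
#' @param seed RNG seed.
#' @return named list of `vc_encoder`s keyed by node id (`group@visit`).
#' @export
train_encoders <- function(cohort, schema, grid_fn = default_ae_grid,
                           seed = NULL) {
  blocks <- schema$features |>
    filter(!.data$group %in% schema$groups$group[schema$groups$class == "aux"]) |>
    distinct(.data$group, .data$visit)
  seeds <- derive_seeds(seed %||% 1L, nrow(blocks))
  encs <- purrr::map(seq_len(nrow(blocks)), function(i) {
    cols <- block_columns(schema, blocks$group[i], blocks$visit[i])
    missing_cols <- setdiff(cols, names(cohort))
    assert_that(length(missing_cols) == 0L,
                paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")))
    d <- ncol(cohort[cols])
    grid <- if (d > 1L) grid_fn(d) else NULL
    train_group_autoencoder(cohort[cols], grid = grid, seed = seeds[i])
  })
  names(encs) <- node_id(blocks$group, blocks$visit)
  encs
}

#' Encode a cohort into module scores
#'
#' Maps every variable-group block through its trained encoder, producing one
#' score column per latent dimension (named by the node id, `#k`-suffixed when
#' `q > 1`). Pass-through blocks and auxiliary indicator columns are copied
#' unchanged. Standardization uses the training-time statistics stored in each
#' encoder. Encoding is row-wise, so permuting patients permutes scores
#' identically.
#'
#' @param cohort complete cohort tibble (must contain every trained feature).
#' @param encoders named list from [train_encoders()].
#' @param schema matching [vc_schema()] (used to carry auxiliary columns).
#' @return tibble: `patient_id` (if present), score columns, aux columns.
#' @export
encode_cohort <- function(cohort, encoders, schema = NULL) {
  out <- list()
  if ("patient_id" %in% names(cohort)) out$patient_id <- cohort$patient_id
  for (nd in names(encoders)) {
    sc <- encoder_scores(encoders[[nd]], cohort)
    if (ncol(sc) == 1L) {
      out[[nd]] <- sc[, 1]
    } else {
      for (k in seq_len(ncol(sc))) out[[paste0(nd, "#", k)]] <- sc[, k]
    }
  }
  if (!is.null(schema)) {
    auxg <- schema$groups$group[schema$groups$class == "aux"]
    auxf <- filter(schema$features, .data$group %in% auxg)
    for (i in seq_len(nrow(auxf))) {
      cn <- feature_col(auxf$name[i], auxf$visit[i])
      if (cn %in% names(cohort)) out[[cn]] <- cohort[[cn]]
    }
  }
  as_tibble(out)
}

#' Decode module scores back to feature space
#'
#' Inverse-direction map of [encode_cohort()]: scores are pushed through each
#' decoder and de-standardized (one-hot blocks decode to the argmax level).
#'
#' @param scores tibble of score columns named as produced by
#'   [encode_cohort()].
#' @param encoders named list of `vc_encoder`s.
#' @return tibble of reconstructed raw features.
#' @export
decode_scores <- function(scores, encoders) {
  out <- list()
  for (nd in names(encoders)) {
    enc <- encoders[[nd]]
    want <- if (enc$q == 1L) nd else paste0(nd, "#", seq_len(enc$q))
    assert_that(all(want %in% names(scores)),
                paste("dimension mismatch: missing score columns for", nd))
    S <- as.matrix(scores[want])
    if (isTRUE(enc$passthrough)) {
      out[[enc$feature]] <- S[, 1]
      next
    }
    dec <- enc$layers[seq(enc$n_enc + 1L, length(enc$layers))]
    Z <- forward_layers(S, dec)[[length(dec) + 1L]]
    rec <- prep_invert(enc$prep, Z)
    for (j in names(rec)) out[[j]] <- rec[[j]]
  }
  as_tibble(out)
}

#' Gedeon input influence of a trained encoder
#'
#' Quantifies each input's relative contribution to each latent output by
#' normalizing absolute weights per neuron, `P_ij = |w_ij| / sum_p |w_pj|`,
#' and propagating through deeper layers by summing products along all paths,
#' `P_ik = sum_r P_ir P_rk` (biases are ignored). Computed on the encoder
#' weights only. Influences are non-negative and sum to 1 per latent output.
#'
#' @param encoder a `vc_encoder` (or a single weight matrix / list of weight
#'   matrices, inputs in rows).
#' @return matrix (inputs x latent outputs) of influences.
#' @export
gedeon_influence <- function(encoder) {
  mats <- if (inherits(encoder, "vc_encoder")) {
    if (isTRUE(encoder$passthrough)) {
      return(matrix(1, 1, 1, dimnames = list(encoder$feature, NULL)))
    }
    purrr::map(encoder$layers[seq_len(encoder$n_enc)], "W")
  } else if (is.matrix(encoder)) {
    list(encoder)
  } else {
    encoder
  }
  P <- NULL
  for (W in mats) {
    A <- abs(W)
    A <- sweep(A, 2, colSums(A), "/")
    P <- if (is.null(P)) A else P %*% A
  }
  if (inherits(encoder, "vc_encoder")) {
    rownames(P) <- colnames(prep_apply(encoder$prep,
                                       stub_row(encoder$prep)))
  }
  P
}

# one synthetic row matching a prep recipe (names only; values arbitrary)
stub_row <- function(prep) {
  as.data.frame(purrr::imap(prep, function(p, j) {
    if (p$type == "continuous") p$center else p$levels[1]
  }), check.names = FALSE)
}
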