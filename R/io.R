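#' Serialize a fitted model bundle to JSON
#'
#' Writes the fitted network — and optionally the trained encoders and
#' discretization maps — to a single portable JSON file that [read_model()]
#' restores exactly.
#'
#' @param path output `.json` path.
#' @param bn a [discrete_bn()].
#' @param encoders optional named list of `vc_encoder`s.
#' @param maps optional `vc_discretization` map list.
#' @return `path`, invisibly.
#' @export
write_model <- function(path, bn, encoders = NULL, maps = NULL) {
  stopifnot(inherits(bn, "discrete_bn"))
  bundle <- list(
    bn = list(levels = bn$levels, parents = bn$parents, alpha = bn$alpha,
              cpts = purrr::imap(bn$cpts, ~ list(dim = dim(.x),
                                                 values = as.vector(.x))))
  )
  if (!is.null(encoders)) {
    bundle$encoders <- purrr::map(encoders, function(e) {
      base <- list(passthrough = isTRUE(e$passthrough),
                   prep = e$prep, q = e$q,
                   train_mse = e$train_mse, valid_mse = e$valid_mse)
      if (isTRUE(e$passthrough)) return(c(base, list(feature = e$feature)))
      c(base, list(
        n_enc = e$n_enc,
        spec = unclass(e$spec),
        layers = purrr::map(e$layers, ~ list(W = as.vector(.x$W),
                                             dim = dim(.x$W), b = .x$b,
                                             act = .x$act))
      ))
    })
  }
  if (!is.null(maps)) bundle$maps <- purrr::map(maps, unclass)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model bundle written by [write_model()]
#'
#' @param path `.json` path.
#' @return list with elements `bn`, `encoders` (or `NULL`), `maps` (or
#'   `NULL`).
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  b <- raw$bn
  nodes <- names(b$levels)
  levels <- purrr::map(b$levels, as.character)
  parents <- purrr::map(setNames(nodes, nodes), ~ as.character(b$parents[[.x]] %||% character()))
  cpts <- purrr::map(setNames(nodes, nodes), function(v) {
    e <- b$cpts[[v]]
    array(as.numeric(e$values), dim = as.integer(e$dim),
          dimnames = c(list(levels[[v]]),
                       purrr::map(parents[[v]], ~ levels[[.x]])))
  })
  bn <- discrete_bn(levels, parents, cpts, alpha = b$alpha)

  encoders <- NULL
  if (!is.null(raw$encoders)) {
    encoders <- purrr::map(raw$encoders, function(e) {
      prep <- purrr::map(e$prep, function(p) {
        p$type <- as.character(p$type)
        if (p$type == "categorical") p$levels <- as.character(p$levels)
        p
      })
      if (isTRUE(e$passthrough)) {
        return(structure(list(passthrough = TRUE, feature = e$feature,
                              prep = prep, q = as.integer(e$q),
                              train_mse = e$train_mse, valid_mse = e$valid_mse),
                         class = "vc_encoder"))
      }
      layers <- purrr::map(e$layers, function(L)
        list(W = matrix(as.numeric(L$W), L$dim[[1]], L$dim[[2]]),
             b = as.numeric(L$b), act = as.character(L$act)))
      structure(list(passthrough = FALSE, prep = prep, layers = layers,
                     n_enc = as.integer(e$n_enc),
                     spec = do.call(ae_spec, e$spec[setdiff(names(e$spec),
                                                            character())]),
                     q = as.integer(e$q), train_mse = e$train_mse,
                     valid_mse = e$valid_mse),
                class = "vc_encoder")
    })
  }
  maps <- NULL
  if (!is.null(raw$maps)) {
    maps <- structure(purrr::map(raw$maps, function(m) {
      m$method <- as.character(m$method)
      m$n_levels <- as.integer(m$n_levels)
      for (f in intersect(c("cuts", "means", "sds", "weights", "range"), names(m))) {
        m[[f]] <- as.numeric(m[[f]])
      }
      structure(m, class = "vc_discretization_map")
    }), class = "vc_discretization")
  }
  list(bn = bn, encoders = encoders, maps = maps)
}
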