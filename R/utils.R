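#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols distinct
#'   left_join anti_join group_by summarise ungroup pull rename n across all_of
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats rnorm runif predict sd var median quantile setNames
#'   p.adjust plogis rbinom complete.cases
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one user-facing seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(ok, msg, class = "vcforge_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# Column names follow "<feature>@<visit>"; static features use visit "static".
feature_col <- function(name, visit) {
  ifelse(visit == "static", name, paste0(name, "@", visit))
}

node_id <- function(group, visit) {
  ifelse(visit == "static", group, paste0(group, "@", visit))
}

aux_group <- function(group) paste0("aux_", group)

# Make two tables column-type compatible: columns numeric in both stay
# numeric; anything else becomes a factor over the union of observed levels.
align_tables <- function(real, virtual) {
  for (j in names(real)) {
    if (is.numeric(real[[j]]) && is.numeric(virtual[[j]]) &&
        !is.factor(real[[j]]) && !is.factor(virtual[[j]])) next
    lev <- sort(union(unique(as.character(real[[j]])),
                      unique(as.character(virtual[[j]]))))
    real[[j]] <- factor(as.character(real[[j]]), levels = lev)
    virtual[[j]] <- factor(as.character(virtual[[j]]), levels = lev)
  }
  list(real = real, virtual = virtual)
}
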