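#' Cohort schema: variable groups, visits and feature declarations
#'
#' A `vc_schema` describes the layout of a longitudinal cohort table: which
#' features exist, the variable group each belongs to, the visit schedule, and
#' the structural class of every group (used to expand edge constraints for
#' Bayesian-network structure learning). Every feature belongs to exactly one
#' group; its visit is either `"static"` or a label of the visit schedule.
#'
#' @param features tibble/data frame with columns `name`, `dtype`
#'   (`"continuous"`, `"categorical"` or `"ordinal"`), `group`, `visit`.
#' @param groups tibble with columns `group`, `class`; the class vocabulary is
#'   user-extensible (e.g. `"demographic"`, `"imaging"`, `"biomarker"`,
#'   `"cognition"`, `"diagnosis"`); the class `"aux"` is reserved for
#'   missingness indicator nodes.
#' @param schedule tibble with columns `visit` (unique labels) and `offset`
#'   (months, strictly increasing).
#' @return A `vc_schema` object (list of the three validated tibbles).
#' @seealso [load_group_spec()], [add_auxiliary_nodes()], [expand_constraints()]
#' @export
vc_schema <- function(features, groups, schedule) {
  features <- as_tibble(features)
  groups <- as_tibble(groups)
  schedule <- as_tibble(schedule)

  assert_that(all(c("name", "dtype", "group", "visit") %in% names(features)),
              "`features` needs columns name, dtype, group, visit")
  assert_that(all(c("group", "class") %in% names(groups)),
              "`groups` needs columns group, class")
  assert_that(all(c("visit", "offset") %in% names(schedule)),
              "`schedule` needs columns visit, offset")
  assert_that(!anyDuplicated(schedule$visit),
              "duplicate visit labels in schedule", class = "vcforge_schema_error")
  assert_that(all(diff(schedule$offset) > 0),
              "visit offsets must be strictly increasing", class = "vcforge_schema_error")
  assert_that(!anyDuplicated(groups$group),
              "duplicate group declarations", class = "vcforge_schema_error")
  assert_that(all(features$dtype %in% c("continuous", "categorical", "ordinal")),
              "feature dtype must be continuous, categorical or ordinal",
              class = "vcforge_schema_error")
  assert_that(all(features$group %in% groups$group),
              "feature references an undeclared group", class = "vcforge_schema_error")
  assert_that(all(features$visit %in% c("static", schedule$visit)),
              paste("unknown visit label:",
                    paste(setdiff(features$visit, c("static", schedule$visit)), collapse = ", ")),
              class = "vcforge_schema_error")
  key <- paste(features$name, features$visit)
  assert_that(!anyDuplicated(key),
              paste("duplicate feature declaration:", key[duplicated(key)][1]),
              class = "vcforge_schema_error")
  # a feature name is owned by exactly one group across all visits
  own <- distinct(features, .data$name, .data$group)
  assert_that(!anyDuplicated(own$name),
              paste("feature assigned to more than one group:",
                    own$name[duplicated(own$name)][1]),
              class = "vcforge_schema_error")

  structure(list(features = features, groups = groups, schedule = schedule),
            class = "vc_schema")
}

#' @export
print.vc_schema <- function(x, ...) {
  cat("<vc_schema> ", nrow(x$features), " features, ",
      nrow(x$groups), " groups, ",
      nrow(x$schedule), " visits\n", sep = "")
  invisible(x)
}

#' Read a group specification file
#'
#' Loads a YAML or JSON group specification declaring the visit schedule,
#' variable groups with their structural class, and features. Feature entries
#' may carry either a single `visit` or a `visits` list, which is expanded to
#' one declaration per visit.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` specification.
#' @return A validated [vc_schema()].
#' @export
load_group_spec <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  assert_that(all(c("visits", "groups", "features") %in% names(raw)),
              "group spec needs top-level keys: visits, groups, features",
              class = "vcforge_schema_error")
  schedule <- purrr::map_dfr(raw$visits, ~ tibble(visit = as.character(.x$label),
                                                  offset = as.numeric(.x$offset)))
  groups <- purrr::map_dfr(raw$groups, ~ tibble(group = as.character(.x$name),
                                                class = as.character(.x$class)))
  features <- purrr::map_dfr(raw$features, function(f) {
    visits <- as.character(f$visits %||% f$visit %||% "static")
    tibble(name = as.character(f$name),
           dtype = as.character(f$dtype %||% "continuous"),
           group = as.character(f$group),
           visit = visits)
  })
  vc_schema(features, groups, schedule)
}

#' Write a group specification file
#'
#' Inverse of [load_group_spec()]; the written file loads back to an identical
#' schema.
#'
#' @param schema a [vc_schema()].
#' @param path output path; format chosen by extension (`.json` else YAML).
#' @return `path`, invisibly.
#' @export
write_group_spec <- function(schema, path) {
  stopifnot(inherits(schema, "vc_schema"))
  obj <- list(
    visits = purrr::pmap(schema$schedule, function(visit, offset)
      list(label = visit, offset = offset)),
    groups = purrr::pmap(schema$groups, function(group, class)
      list(name = group, class = class)),
    features = purrr::pmap(schema$features, function(name, dtype, group, visit)
      list(name = name, dtype = dtype, group = group, visit = visit))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

# Data-frame of the cohort columns belonging to one (group, visit) block.
block_columns <- function(schema, group, visit) {
  f <- filter(schema$features, .data$group == !!group, .data$visit == !!visit)
  feature_col(f$name, f$visit)
}

#' Add auxiliary missingness-indicator nodes
#'
#' Missingness in longitudinal studies is frequently systematic (patients drop
#' out, entire test batteries are skipped at a visit) and therefore not
#' ignorable (MNAR). Following the indicator-variable strategy, one binary
#' auxiliary variable is created for every (group, visit) block that contains
#' any missing value: it is `0` when the patient's *entire* block is missing
#' at that visit and `1` otherwise. Partially missing blocks keep indicator 1
#' and are left to imputation ([rf_impute()]). Auxiliary features are fully
#' observed by construction and carry group class `"aux"`.
#'
#' @param cohort cohort tibble (`patient_id` plus `feature@visit` columns,
#'   missing cells `NA`).
#' @param schema the matching [vc_schema()].
#' @return list with elements `cohort` (indicator columns appended) and
#'   `schema` (auxiliary groups/features appended).
#' @export
add_auxiliary_nodes <- function(cohort, schema) {
  stopifnot(inherits(schema, "vc_schema"))
  cohort <- as_tibble(cohort)
  assert_that(!anyDuplicated(cohort$patient_id), "duplicated patient identifiers")

  blocks <- distinct(schema$features[schema$features$group %in%
                                       schema$groups$group[schema$groups$class != "aux"], ],
                     .data$group, .data$visit)
  new_feats <- list(); new_groups <- character()
  for (i in seq_len(nrow(blocks))) {
    g <- blocks$group[i]; v <- blocks$visit[i]
    cols <- intersect(block_columns(schema, g, v), names(cohort))
    if (length(cols) == 0L) next
    miss <- is.na(as.matrix(cohort[cols]))
    if (!any(miss)) next
    ind <- as.integer(rowSums(miss) < length(cols)) # 0 iff whole block missing
    ag <- aux_group(g)
    cohort[[feature_col(ag, v)]] <- ind
    new_feats[[length(new_feats) + 1L]] <-
      tibble(name = ag, dtype = "categorical", group = ag, visit = v)
    new_groups <- union(new_groups, ag)
  }
  if (length(new_feats)) {
    schema <- vc_schema(
      bind_rows(schema$features, bind_rows(new_feats)),
      bind_rows(schema$groups, tibble(group = new_groups, class = "aux")),
      schema$schedule
    )
  }
  list(cohort = cohort, schema = schema)
}

#' Group-class constraint rules
#'
#' Builds a rule table for [expand_constraints()]. Each rule forbids or allows
#' directed influences from one structural class to another; `"*"` is a
#' wildcard. The most specific matching rule wins (fewest wildcards); absent
#' any matching rule an edge is allowed. Temporal ordering and auxiliary-node
#' restrictions are always enforced and need no rules.
#'
#' @param from,to,direction equal-length character vectors; `direction` is
#'   `"allowed"` or `"forbidden"`.
#' @return tibble with columns `from`, `to`, `direction`.
#' @export
group_rules <- function(from, to, direction) {
  assert_that(all(direction %in% c("allowed", "forbidden")),
              "direction must be 'allowed' or 'forbidden'")
  tibble(from = from, to = to, direction = direction)
}

#' Default structural constraint rules for AD/PD-like cohorts
#'
#' The shipped defaults encode the standard clinical-plausibility rules:
#' demographic baseline features influence others but are never influenced;
#' imaging features may relate to each other but do not drive other groups;
#' clinical diagnosis depends on cognition scores, never the reverse.
#' Temporal order and auxiliary-indicator topology are built into
#' [expand_constraints()] itself.
#'
#' @return A rule tibble as produced by [group_rules()].
#' @export
default_group_rules <- function() {
  group_rules(
    from = c("*", "imaging", "imaging", "diagnosis"),
    to = c("demographic", "*", "imaging", "cognition"),
    direction = c("forbidden", "forbidden", "allowed", "forbidden")
  )
}

#' Standard structural class vocabulary
#'
#' The group classes understood by the shipped default rules; users may extend
#' the vocabulary via the `vocabulary` argument of [expand_constraints()].
#'
#' @return character vector of class names.
#' @export
standard_classes <- function() {
  c("demographic", "history", "imaging", "cognition", "diagnosis",
    "biomarker", "outcome", "nonmotor", "motor", "clinical", "aux")
}

#' Read constraint rules from YAML/JSON
#'
#' @param path file with a top-level `rules:` list of
#'   `{from, to, direction}` entries.
#' @return A rule tibble as produced by [group_rules()].
#' @export
load_group_rules <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$rules %||% raw
  purrr::map_dfr(entries, ~ group_rules(.x$from, .x$to, .x$direction))
}

# Decide allowed/forbidden for one ordered class pair under precedence:
# fewest wildcards wins; ties resolve to forbidden; default allowed.
rule_decision <- function(rules, cls_from, cls_to) {
  hit <- rules[(rules$from == cls_from | rules$from == "*") &
                 (rules$to == cls_to | rules$to == "*"), , drop = FALSE]
  if (nrow(hit) == 0L) return("allowed")
  spec <- (hit$from != "*") + (hit$to != "*")
  hit <- hit[spec == max(spec), , drop = FALSE]
  if (any(hit$direction == "forbidden")) "forbidden" else "allowed"
}

#' Expand group-class rules into a node-level edge constraint set
#'
#' Translates class-level rules plus the always-on structural requirements
#' into a directed-edge blacklist and whitelist over the Bayesian-network
#' nodes (one node per group and visit, plus one per auxiliary indicator):
#'
#' * class rules (see [group_rules()]) forbid edges between node classes;
#' * edges pointing backwards in time are forbidden, including edges from
#'   visit-indexed nodes into static nodes;
#' * an auxiliary node may only point to its own group's node at the same
#'   visit and to the same group's auxiliary node at the next visit; those
#'   two edge families are *whitelisted* (forced present) and all other
#'   edges touching auxiliary nodes are forbidden.
#'
#' The expansion is deterministic given (schema, rules).
#'
#' @param schema a [vc_schema()] (run [add_auxiliary_nodes()] first if the
#'   cohort has missing blocks, so auxiliary nodes are part of the node set).
#' @param rules rule tibble from [group_rules()]/[default_group_rules()].
#' @param vocabulary admissible class names in rules; defaults to the schema's
#'   classes plus the standard clinical vocabulary. A rule referencing a class
#'   outside the vocabulary is an error.
#' @return A `vc_constraints` object: list with tibbles `blacklist`,
#'   `whitelist` (columns `from`, `to`) and `nodes` (columns `node`, `group`,
#'   `visit`, `class`).
#' @export
expand_constraints <- function(schema, rules = default_group_rules(),
                               vocabulary = standard_classes()) {
  stopifnot(inherits(schema, "vc_schema"))
  rules <- as_tibble(rules)
  classes <- unique(schema$groups$class)
  bad <- setdiff(unique(c(rules$from, rules$to)),
                 c(classes, vocabulary, "*", "aux"))
  assert_that(length(bad) == 0L,
              paste("rule references undeclared class:", paste(bad, collapse = ", ")),
              class = "vcforge_schema_error")

  nodes <- schema$features |>
    distinct(.data$group, .data$visit) |>
    left_join(schema$groups, by = "group") |>
    mutate(node = node_id(.data$group, .data$visit))
  off <- setNames(schema$schedule$offset, schema$schedule$visit)
  nodes$time <- ifelse(nodes$visit == "static", -Inf, off[nodes$visit])

  is_aux <- nodes$class == "aux"
  p <- nrow(nodes)
  bl <- matrix(FALSE, p, p, dimnames = list(nodes$node, nodes$node))
  wl <- matrix(FALSE, p, p, dimnames = list(nodes$node, nodes$node))

  # class rules over non-aux pairs
  dec <- matrix("allowed", length(classes), length(classes),
                dimnames = list(classes, classes))
  for (a in classes) for (b in classes) dec[a, b] <- rule_decision(rules, a, b)
  for (i in which(!is_aux)) for (j in which(!is_aux)) {
    if (i != j && dec[nodes$class[i], nodes$class[j]] == "forbidden") bl[i, j] <- TRUE
  }
  # temporal order: no edges backwards in time; time-indexed never into static
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j && nodes$time[i] > nodes$time[j]) bl[i, j] <- TRUE
  }
  # auxiliary topology
  for (i in which(is_aux)) {
    g <- sub("^aux_", "", nodes$group[i]); v <- nodes$visit[i]
    own <- nodes$node[!is_aux & nodes$group == g & nodes$visit == v]
    later <- nodes$node[is_aux & nodes$group == nodes$group[i] & nodes$time > nodes$time[i]]
    nxt <- if (length(later)) later[which.min(nodes$time[match(later, nodes$node)])] else character()
    keep_out <- c(own, nxt)
    bl[i, setdiff(nodes$node, c(nodes$node[i], keep_out))] <- TRUE
    bl[setdiff(seq_len(p), i), i] <- TRUE
    if (length(own)) wl[i, own] <- TRUE
    if (length(nxt)) {
      wl[i, nxt] <- TRUE
      bl[i, nxt] <- FALSE
    }
    if (length(own)) bl[i, own] <- FALSE
  }
  # incoming whitelist edges into aux chains must not stay blacklisted
  bl[wl] <- FALSE

  to_edges <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    tibble(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]]) |>
      arrange(.data$from, .data$to)
  }
  structure(list(blacklist = to_edges(bl), whitelist = to_edges(wl),
                 nodes = select(nodes, "node", "group", "visit", "class")),
            class = "vc_constraints")
}

#' @export
print.vc_constraints <- function(x, ...) {
  cat("<vc_constraints> ", nrow(x$nodes), " nodes, ",
      nrow(x$blacklist), " blacklisted, ",
      nrow(x$whitelist), " whitelisted edges\n", sep = "")
  invisible(x)
}

#' Read / write a cohort table
#'
#' Cohort CSV/TSV files carry a `patient_id` column followed by one column per
#' `feature@visit` (static features use the bare feature name); missing cells
#' are empty or `NA`.
#'
#' @param path file path (`.tsv` for tab-separated, otherwise comma).
#' @return `read_cohort()`: a tibble; `write_cohort()`: `path` invisibly.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  assert_that("patient_id" %in% names(df), "cohort file needs a patient_id column")
  as_tibble(df)
}

#' @rdname read_cohort
#' @param cohort cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}
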