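test_that("group specs validate, count nodes, and round-trip through files", {
  sch <- toy_schema()
  blocks <- dplyr::distinct(sch$features, group, visit)
  expect_equal(nrow(blocks), 5) # 2 groups x 2 visits + 1 static group

  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_group_spec(sch, path)
    back <- load_group_spec(path)
    expect_equal(back$features, sch$features)
    expect_equal(back$groups, sch$groups)
    expect_equal(back$schedule, sch$schedule)
  }
})

test_that("schema invariants are enforced", {
  sch <- toy_schema()
  # a feature may not live in two groups
  bad <- sch$features
  bad$group[bad$name == "hippo" & bad$visit == "bl"] <- "cognition"
  expect_error(vc_schema(bad, sch$groups, sch$schedule),
               "more than one group")
  # unknown visit label
  bad2 <- sch$features
  bad2$visit[1] <- "m99"
  expect_error(vc_schema(bad2, sch$groups, sch$schedule), "unknown visit")
  # duplicated declaration
  expect_error(vc_schema(rbind(sch$features, sch$features[1, ]),
                         sch$groups, sch$schedule), "duplicate feature")
  # offsets must increase
  expect_error(vc_schema(sch$features, sch$groups,
                         tibble::tibble(visit = c("bl", "m06"), offset = c(6, 0))),
               "strictly increasing")
})

test_that("auxiliary indicators fire only on whole-block missingness", {
  sch <- toy_schema()
  co <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    `mmse@bl` = c(28, 25, 22), `adas@bl` = c(10, 14, 20),
    `mmse@m06` = c(NA, NA, 21), `adas@m06` = c(NA, 15, 22),
    `hippo@bl` = c(3.1, 2.9, 2.5), `vent@bl` = c(20, 24, 30),
    `hippo@m06` = c(3.0, 2.8, 2.4), `vent@m06` = c(21, 25, 31),
    age = c(70, 75, 80), sex = c("f", "m", "f")
  )
  aug <- add_auxiliary_nodes(co, sch)
  # whole cognition block missing at m06 only for p1
  expect_equal(aug$cohort$`aux_cognition@m06`, c(0L, 1L, 1L))
  # no other aux columns: all other blocks complete
  expect_equal(grep("^aux_", names(aug$cohort), value = TRUE),
               "aux_cognition@m06")
  expect_true("aux_cognition" %in% aug$schema$groups$group)
  expect_equal(aug$schema$groups$class[aug$schema$groups$group == "aux_cognition"],
               "aux")
  # complete cohort gains nothing
  co2 <- co
  co2$`mmse@m06` <- c(20, 20, 21); co2$`adas@m06` <- c(15, 15, 22)
  aug2 <- add_auxiliary_nodes(co2, sch)
  expect_identical(names(aug2$cohort), names(co2))
})

test_that("constraint expansion encodes class rules, time order and aux topology", {
  sch <- toy_schema()
  co <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    `mmse@bl` = c(28, NA, 22, 27), `adas@bl` = c(10, NA, 20, 12),
    `mmse@m06` = c(NA, NA, 21, 26), `adas@m06` = c(NA, NA, 22, 13),
    `hippo@bl` = c(3.1, 2.9, 2.5, 3.2), `vent@bl` = c(20, 24, 30, 19),
    `hippo@m06` = c(3.0, 2.8, 2.4, 3.1), `vent@m06` = c(21, 25, 31, 20),
    age = c(70, 75, 80, 68), sex = c("f", "m", "f", "m")
  )
  aug <- add_auxiliary_nodes(co, sch)
  cs <- expand_constraints(aug$schema)

  bl_key <- paste(cs$blacklist$from, cs$blacklist$to)
  wl_key <- paste(cs$whitelist$from, cs$whitelist$to)

  # aux chain and aux -> own score are whitelisted
  expect_true("aux_cognition@bl aux_cognition@m06" %in% wl_key)
  expect_true("aux_cognition@bl cognition@bl" %in% wl_key)
  expect_true("aux_cognition@m06 cognition@m06" %in% wl_key)
  # blacklist and whitelist are disjoint
  expect_length(intersect(bl_key, wl_key), 0)
  # any edge into a demographic node is blacklisted
  others <- setdiff(cs$nodes$node, "demo")
  expect_true(all(paste(others, "demo") %in% bl_key))
  # backward-in-time edges are blacklisted
  expect_true("cognition@m06 cognition@bl" %in% bl_key)
  expect_true("brain@m06 cognition@bl" %in% bl_key)
  # imaging may not drive other groups but may relate to itself
  expect_true("brain@bl cognition@bl" %in% bl_key)
  expect_false("brain@bl brain@m06" %in% bl_key)
  # aux in-degree: every edge into an aux node except the previous aux is banned
  into_aux <- cs$nodes$node[cs$nodes$node != "aux_cognition@m06"]
  allowed_in <- setdiff(into_aux, "aux_cognition@bl")
  expect_true(all(paste(allowed_in, "aux_cognition@m06") %in% bl_key))
  # expansion is deterministic
  cs2 <- expand_constraints(aug$schema)
  expect_identical(cs, cs2)
  # unknown class in a rule is an error
  expect_error(expand_constraints(sch, group_rules("wibble", "*", "forbidden")),
               "undeclared class")
})

test_that("time-forward consistency holds for every non-blacklisted edge", {
  sch <- toy_schema()
  cs <- expand_constraints(sch)
  off <- c(bl = 0, m06 = 6)
  nodes <- cs$nodes
  bl_key <- paste(cs$blacklist$from, cs$blacklist$to)
  for (i in seq_len(nrow(nodes))) {
    for (j in seq_len(nrow(nodes))) {
      if (i == j) next
      ti <- if (nodes$visit[i] == "static") -Inf else off[[nodes$visit[i]]]
      tj <- if (nodes$visit[j] == "static") -Inf else off[[nodes$visit[j]]]
      if (ti > tj) {
        expect_true(paste(nodes$node[i], nodes$node[j]) %in% bl_key)
      }
    }
  }
})

test_that("cohort tables round-trip through CSV with missing cells", {
  co <- tibble::tibble(patient_id = c("a", "b"),
                       `x@bl` = c(1.5, NA), `y@bl` = c(NA, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co)
})
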