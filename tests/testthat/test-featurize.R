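test_that("feature-space sizes follow the variant definitions", {
  g <- kg_graph(data.frame(subject = c("A", "A"), predicate = c("p1", "p2"),
                           object = c("B", "C"), provenance = "S1"))
  expect_equal(nrow(build_feature_space(g, "baseline")), 3L)
  expect_equal(nrow(build_feature_space(g, "full")), 1L + 4L * 3L)
  expect_equal(nrow(build_feature_space(g, "indirect_only")), 2L * 3L)
  expect_equal(nrow(build_feature_space(g, "predicate")), 1L + 4L * 2L)
  expect_equal(nrow(build_feature_space(g, "provenance")), 1L + 4L * 1L)
  expect_error(build_feature_space(g, "everything"))
  # at the reference vocabulary scale (45 predicates, 25 sources) the full
  # space has 1 + 4 * 70 = 281 indicators
  big <- kg_graph(data.frame(subject = "A", predicate = "p01", object = "B",
                             provenance = "S01"),
                  predicates = sprintf("p%02d", 1:45),
                  sources = sprintf("S%02d", 1:25))
  expect_equal(nrow(build_feature_space(big, "full")), 281L)
  spec <- build_feature_space(g, "full")
  expect_false(is.unsorted(match(spec$slot,
                                 c("OVERLAP_FLAG", "SELF", "DIRECT",
                                   "DTIP", "IPDP"))))
})

test_that("a single direct triple sets exactly its two feature bits", {
  g <- kg_graph(data.frame(subject = "A", predicate = "binds", object = "B",
                           provenance = "S1"),
                predicates = c("binds", "inhibits"), sources = c("S1", "S2"))
  spec <- build_feature_space(g, "full")
  v <- extract_features(combination("x", "A", "B"), g, spec)
  expect_equal(sort(names(v)[v == 1L]),
               c("DIRECT:predicate:binds", "DIRECT:provenance:S1"))
  # no paths at all -> all-zero vector
  v0 <- extract_features(combination("y", "A", "Z"), g, spec)
  expect_true(all(v0 == 0L))
})

test_that("vocabulary mismatch between spec and graph is an error", {
  g1 <- kg_graph(data.frame(subject = "A", predicate = "p1", object = "B",
                            provenance = "S1"))
  g2 <- kg_graph(data.frame(subject = "A", predicate = "p2", object = "B",
                            provenance = "S2"))
  spec <- build_feature_space(g1, "full")
  expect_error(extract_features(combination("x", "A", "B"), g2, spec),
               "vocabulary")
})

test_that("full vectors equal the brute-force path oracle on random data", {
  for (seed in 1:10) {
    g <- random_test_graph(sample(8:20, 1L), sample(20:60, 1L), seed = seed)
    spec <- build_feature_space(g, "full")
    cb <- random_test_combo(g, sample(1:3, 1L), sample(1:3, 1L),
                            seed = seed + 30L)
    expect_identical(extract_features(cb, g, spec), bf_features(cb, g, spec))
  }
})

test_that("baseline flags equal the brute-force co-occurrence oracle", {
  for (seed in 1:5) {
    g <- random_test_graph(10, 25, seed = seed)
    spec <- build_feature_space(g, "baseline")
    cb <- random_test_combo(g, 2, 2, seed = seed + 60L)
    expect_identical(extract_features(cb, g, spec), bf_features(cb, g, spec))
  }
})

test_that("variant vectors are column projections of the full vector", {
  g <- random_test_graph(15, 50, seed = 21)
  full <- build_feature_space(g, "full")
  cb <- random_test_combo(g, 3, 3, seed = 22)
  v_full <- extract_features(cb, g, full)
  for (variant in c("predicate", "provenance", "indirect_only")) {
    sub <- build_feature_space(g, variant)
    v_sub <- extract_features(cb, g, sub)
    expect_true(all(sub$id %in% full$id))
    expect_identical(v_sub, v_full[sub$id])
  }
})

test_that("adding a triple can only flip bits upward", {
  g <- random_test_graph(10, 20, seed = 31)
  spec <- build_feature_space(g, "full")
  cb <- random_test_combo(g, 2, 2, seed = 32)
  v1 <- extract_features(cb, g, spec)
  tr <- raw_triples(g)
  tr <- rbind(tr, data.frame(subject = cb$drug_targets[1L], predicate = "p1",
                             object = cb$disease_proteins[1L],
                             provenance = "S1"))
  g2 <- kg_graph(tr, proteins = g$proteins)
  v2 <- extract_features(cb, g2, spec)
  expect_true(all(v2 >= v1))
})

test_that("flag features are consistent with their slot bits", {
  for (seed in 1:5) {
    g <- random_test_graph(12, 40, seed = seed + 70L)
    cb <- random_test_combo(g, 2, 3, seed = seed + 80L)
    full <- extract_features(cb, g, build_feature_space(g, "full"))
    base <- extract_features(cb, g, build_feature_space(g, "baseline"))
    direct_bits <- full[startsWith(names(full), "DIRECT:")]
    indirect_bits <- full[startsWith(names(full), "DTIP:") |
                            startsWith(names(full), "IPDP:")]
    if (any(direct_bits == 1L))
      expect_equal(unname(base["COOC_DIRECT:flag:has_direct_relationship"]), 1L)
    if (any(indirect_bits == 1L))
      expect_equal(unname(base["COOC_INDIRECT:flag:has_indirect_relationship"]), 1L)
    self_bits <- full[startsWith(names(full), "SELF:")]
    if (any(self_bits == 1L))
      expect_equal(unname(full["OVERLAP_FLAG:flag:overlap"]), 1L)
  }
})

test_that("excluding an absent source only drops its empty columns", {
  g <- kg_graph(data.frame(subject = "A", predicate = "binds", object = "B",
                           provenance = "S1"), sources = c("S1", "S2"))
  spec <- build_feature_space(g, "full")
  combos <- list(combination("x", "A", "B", "positive"))
  res <- restrict_to_sources(spec, combos, g, "S2")
  expect_equal(setdiff(spec$id, res$spec$id),
               paste(c("SELF", "DIRECT", "DTIP", "IPDP"), "provenance", "S2",
                     sep = ":"))
  kept <- intersect(spec$id, res$spec$id)
  orig <- extract_feature_matrix(combos, g, spec)
  expect_equal(res$features[, kept], orig[, kept])
})

test_that("excluding the sole source of a triple removes its support", {
  g <- kg_graph(data.frame(subject = "A", predicate = "binds", object = "B",
                           provenance = "S1"), sources = c("S1", "S2"))
  spec <- build_feature_space(g, "full")
  combos <- list(combination("x", "A", "B", "positive"))
  res <- restrict_to_sources(spec, combos, g, "S1")
  # the binds predicate loses all graph-wide support, so its columns go too
  expect_false(any(grepl("binds", res$spec$id)))
  expect_true(all(res$features == 0L))
})

test_that("source exclusion equals rerunning on a graph without sole-source triples", {
  for (seed in 1:5) {
    g <- random_test_graph(12, 40, n_src = 3L, seed = seed + 90L)
    spec <- build_feature_space(g, "full")
    combos <- lapply(1:6, function(i)
      random_test_combo(g, 2, 2, seed = seed * 10L + i))
    src <- g$sources[1L]
    res <- restrict_to_sources(spec, combos, g, src)
    # oracle: delete sole-source triples, rebuild, project the full pipeline
    tr <- raw_triples(g)
    sole <- tr$provenance == src
    g2 <- kg_graph(tr[!sole, , drop = FALSE], proteins = g$proteins,
                   predicates = g$predicates, sources = g$sources)
    oracle <- extract_feature_matrix(combos, g2, res$spec)
    expect_identical(unname(res$features), unname(oracle))
  }
})
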