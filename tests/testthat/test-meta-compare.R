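test_that("enumeration yields 2^N - N - 1 comparisons with exact intersections", {
  # worked 3-dataset case: sets {A,B}, {B,C}, {B} give 4 comparisons and a
  # 3-way common of {B}
  reg <- make_registry(list(d1 = c("A1", "B1"), d2 = c("B1", "C1"), d3 = "B1"))
  cmp <- enumerate_comparisons(reg)
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$n_parts, c(2L, 2L, 2L, 3L))  # size-ascending order
  expect_equal(cmp$parts[[1]], c("d1", "d2"))
  expect_equal(cmp$common[[which(cmp$n_parts == 3)]], "B1")
  expect_equal(cmp$common[[1]], "B1")

  # N = 2: exactly one comparison
  reg2 <- make_registry(list(a = "P1", b = "P2"))
  cmp2 <- enumerate_comparisons(reg2)
  expect_equal(nrow(cmp2), 1)
  expect_equal(cmp2$n_common, 0L)  # empty intersections are yielded

  expect_error(enumerate_comparisons(reg[1, ]),
               class = "evmeta_validation_error")
  expect_error(enumerate_comparisons(reg, max_n = 2),
               regexp = "cap", class = "evmeta_validation_error")
})

test_that("enumeration order is size-ascending then lexicographic and deterministic", {
  sim <- generate_registry(n_datasets = 5, universe_size = 100,
                           core_size = 5, type_block_size = 10,
                           noise_size = 20, seed = 3)
  cmp <- enumerate_comparisons(sim$registry)
  expect_equal(nrow(cmp), 2^5 - 5 - 1)
  sizes <- cmp$n_parts
  expect_true(all(diff(sizes) >= 0))
  keys <- vapply(cmp$parts, function(p)
    paste(sprintf("%02d", match(p, sim$registry$id)), collapse = ""), "")
  for (k in unique(sizes)) {
    expect_false(is.unsorted(keys[sizes == k]))
  }
  expect_identical(cmp, enumerate_comparisons(sim$registry))
})

test_that("intersections shrink monotonically as parts grow", {
  sim <- generate_registry(n_datasets = 6, universe_size = 150,
                           core_size = 10, type_block_size = 15,
                           noise_size = 30, seed = 9)
  cmp <- enumerate_comparisons(sim$registry)
  key <- vapply(cmp$parts, paste, "", collapse = ";")
  lookup <- stats::setNames(cmp$common, key)
  for (i in which(cmp$n_parts == 3)) {
    parts <- cmp$parts[[i]]
    for (drop in seq_along(parts)) {
      sub <- paste(parts[-drop], collapse = ";")
      expect_true(all(cmp$common[[i]] %in% lookup[[sub]]))
    }
  }
})

test_that("anchor filtering matches brute-force subset counts and the closed form", {
  for (n in c(5, 8, 10)) {
    sets <- stats::setNames(
      lapply(seq_len(n), function(i) sprintf("P%03d", c(1, i + 1))),
      sprintf("d%02d", seq_len(n))
    )
    reg <- make_registry(sets)
    cmp <- enumerate_comparisons(reg)
    for (k in 1:3) {
      anchors <- reg$id[seq_len(k)]
      n_any <- nrow(filter_by_anchor(cmp, anchors, mode = "any"))
      n_all <- nrow(filter_by_anchor(cmp, anchors, mode = "all"))
      expect_equal(n_any, count_subsets(n, intersects = seq_len(k)))
      expect_equal(n_all, count_subsets(n, contains = seq_len(k)))
      # closed form for mode = any
      m <- n - k
      expect_equal(n_any, (2^n - n - 1) - (2^m - m - 1))
    }
  }
})

test_that("anchor filtering validates ids and preserves order", {
  reg <- make_registry(list(a = "P1", b = "P1", c = "P1"))
  cmp <- enumerate_comparisons(reg)
  expect_error(filter_by_anchor(cmp, "zz", reg = reg),
               regexp = "Unknown anchor", class = "evmeta_validation_error")
  expect_error(filter_by_anchor(cmp, character()),
               class = "evmeta_validation_error")
  all_mode <- filter_by_anchor(cmp, reg$id, mode = "all")
  expect_equal(nrow(all_mode), 1)  # only the full set contains every anchor
  filtered <- filter_by_anchor(cmp, "a", mode = "any")
  expect_identical(filtered, cmp[purrr::map_lgl(cmp$parts, ~ "a" %in% .x), ])
})

test_that("redundancy collapse merges the worked example and is sound and idempotent", {
  reg <- worked_example_registry()
  # the worked pair: ((1,2,3,4), {P}) and ((1,2,3), {P}) collapse to one
  pair <- tibble::tibble(
    parts = list(reg$id, reg$id[1:3]),
    common = list("P0001", "P0001"),
    n_parts = c(4L, 3L),
    n_common = c(1L, 1L)
  )
  col <- collapse_redundant(pair, reg)
  expect_equal(nrow(col), 1)
  expect_equal(col$parts_union[[1]], c("ds1", "ds2", "ds3", "ds4"))
  expect_equal(col$common[[1]], "P0001")
  expect_equal(col$n_members, 2L)

  # full enumeration over the same registry: every collapsed record must
  # satisfy the intersection identity (verified internally; re-check here)
  col_all <- collapse_redundant(enumerate_comparisons(reg), reg)
  for (i in seq_len(nrow(col_all))) {
    recomputed <- Reduce(intersect,
                         reg$proteins[match(col_all$parts_union[[i]], reg$id)])
    expect_setequal(recomputed, col_all$common[[i]])
  }
  expect_equal(sum(col_all$n_members),
               sum(lengths(enumerate_comparisons(reg)$common) > 0))

  # idempotence: collapsing the collapsed output changes nothing
  again <- collapse_redundant(col_all, reg)
  expect_equal(again$parts_union, col_all$parts_union)
  expect_equal(again$common, col_all$common)
  expect_true(all(again$n_members == 1))
})

test_that("distinct common sets pass through collapse unchanged", {
  reg <- make_registry(list(a = c("P1", "P2"), b = c("P2", "P3"),
                            c = c("P1", "P3")))
  cmp <- enumerate_comparisons(reg)
  keep <- cmp[lengths(cmp$common) > 0 & cmp$n_parts == 2, ]
  col <- collapse_redundant(keep, reg)
  expect_equal(nrow(col), nrow(keep))
  expect_true(all(col$n_members == 1))
})

test_that("disjoint part tuples sharing a common set merge into one sound record", {
  # P,Q belong to all four sets; ((1,2),{P,Q}) and ((3,4),{P,Q}) merge and
  # the intersection over the union of parts is still {P,Q}
  reg <- make_registry(list(
    d1 = c("P0001", "Q0001", "A1"), d2 = c("P0001", "Q0001", "B1"),
    d3 = c("P0001", "Q0001", "C1"), d4 = c("P0001", "Q0001", "D1")
  ))
  two <- tibble::tibble(
    parts = list(c("d1", "d2"), c("d3", "d4")),
    common = list(c("P0001", "Q0001"), c("P0001", "Q0001")),
    n_parts = c(2L, 2L), n_common = c(2L, 2L)
  )
  col <- collapse_redundant(two, reg)
  expect_equal(nrow(col), 1)
  expect_equal(col$parts_union[[1]], reg$id)
  expect_setequal(col$common[[1]], c("P0001", "Q0001"))

  # a common set that is NOT the true intersection is an internal error
  corrupt <- tibble::tibble(parts = list(c("d1", "d2")),
                            common = list("A1"),
                            n_parts = 2L, n_common = 1L)
  expect_error(collapse_redundant(corrupt, reg),
               class = "evmeta_internal_error")
})

test_that("empty-intersection comparisons are dropped unless kept explicitly", {
  reg <- make_registry(list(a = "P1", b = "P2", c = c("P1", "P2")))
  cmp <- enumerate_comparisons(reg)
  expect_equal(nrow(collapse_redundant(cmp, reg)), 2)  # {P1}, {P2}
  kept <- collapse_redundant(cmp, reg, keep_empty = TRUE)
  expect_equal(nrow(kept), 3)
  expect_true(any(kept$n_common == 0))
})

test_that("ranking is descending with documented deterministic tie-breaks", {
  col <- tibble::tibble(
    parts_union = list(c("b", "c"), c("a", "b"), c("a", "b", "c"), c("a", "d")),
    common = list(c("P1", "P2"), c("P1", "P2"), c("P1", "P2", "P3"), "P1"),
    n_parts = c(2L, 2L, 3L, 2L),
    n_common = c(2L, 2L, 3L, 1L),
    n_members = c(1L, 1L, 1L, 1L)
  )
  top <- rank_comparisons(col, key = "n_common", k = 10)
  expect_equal(top$n_common, c(3L, 2L, 2L, 1L))
  # equal n_common and n_parts: lexicographic parts_union ascending
  expect_equal(top$parts_union[[2]], c("a", "b"))
  expect_equal(top$parts_union[[3]], c("b", "c"))

  by_parts <- rank_comparisons(col, key = "n_parts", k = 2)
  expect_equal(by_parts$n_parts[1], 3L)
  expect_equal(nrow(by_parts), 2)
  expect_equal(nrow(rank_comparisons(col, k = 100)), 4)
  expect_error(rank_comparisons(col, k = 0), class = "evmeta_validation_error")
})

test_that("Simpson index follows the without-replacement pair probability", {
  reg <- make_registry(
    stats::setNames(replicate(5, "P1", simplify = FALSE),
                    c("h1", "h2", "n1", "o1", "s1")),
    types = c("hypoxia", "hypoxia", "normoxia", "OGD", "stroke")
  )
  # all same type -> 1
  expect_equal(simpson_index(c("h1", "h2"), reg)$value, 1)
  # all distinct types -> 0 (without replacement only)
  expect_equal(simpson_index(c("h1", "n1", "o1"), reg)$value, 0)
  expect_gt(simpson_index(c("h1", "n1", "o1"), reg,
                          variant = "with_replacement")$value, 0)
  # (hypoxia, hypoxia, normoxia): one same-type pair of three -> 1/3
  res <- simpson_index(c("h1", "h2", "n1"), reg)
  expect_equal(res$value, 1 / 3)
  expect_equal(res$type_counts, c(hypoxia = 2L, normoxia = 1L))

  expect_error(simpson_index("h1", reg), class = "evmeta_validation_error")
  expect_error(simpson_index(c("h1", "zz"), reg),
               class = "evmeta_validation_error")
})

test_that("Simpson values stay in [0,1] over random type assignments", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    types <- sample(c("normoxia", "hypoxia", "OGD", "stroke", "other"),
                    n, replace = TRUE)
    reg <- make_registry(
      stats::setNames(replicate(n, "P1", simplify = FALSE),
                      sprintf("d%02d", seq_len(n))),
      types = types
    )
    for (variant in c("without_replacement", "with_replacement")) {
      v <- simpson_index(reg$id, reg, variant = variant)$value
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("catalog overlap partitions the query into in-any and in-none", {
  cats <- dplyr::bind_rows(
    catalog("exocarta", c("P1", "P2", "P3")),
    catalog("vesiclepedia", c("P3", "P4"))
  )
  rep <- compare_catalog(c("P1", "P3", "P4", "P9"), cats)
  expect_equal(rep$n_query, 4)
  expect_equal(rep$in_any + rep$in_none, 4)
  expect_equal(rep$in_any, 3)
  expect_equal(rep$novel, "P9")
  expect_equal(rep$per_catalog$n_overlap, c(2L, 2L))

  disjoint <- compare_catalog(c("X1", "X2"), cats)
  expect_equal(disjoint$in_any, 0)
  subset_hit <- compare_catalog(c("P1", "P2"), cats[1, ])
  expect_equal(subset_hit$in_any, 2)

  expect_error(compare_catalog(character(), cats),
               class = "evmeta_validation_error")
  expect_error(compare_catalog("P1", cats[0, ]),
               class = "evmeta_validation_error")
})
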