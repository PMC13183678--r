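allowed_of <- function(L1, L2, L3, ...) {
  sort(allowed_topologies(rule_query(L1, L2, L3, ...))$allowed$topology)
}

test_that("golden loop-length rules", {
  for (x in 1:15) {
    expect_equal(allowed_of(1, x, 1), "parallel", info = x)
  }
  expect_equal(allowed_of(2, 1, 2), "parallel")
  expect_equal(allowed_of(2, 3, 2), "antiparallel-chair")
  expect_equal(allowed_of(2, 4, 2), "antiparallel-basket")
  expect_equal(allowed_of(2, 5, 2), "antiparallel-basket")
  expect_equal(allowed_of(3, 3, 3),
               sort(c("hybrid1", "hybrid3", "antiparallel-chair",
                      "antiparallel-basket2")))
  expect_equal(allowed_of(1, 7, 1), "parallel")
  # (2,2,2): parallel major, chair minor
  p <- allowed_topologies(rule_query(2, 2, 2))
  expect_equal(p$allowed$topology, c("parallel", "antiparallel-chair"))
  expect_match(p$allowed$weight[1], "73")
  expect_match(p$allowed$weight[2], "27")
  # two 1-nt loops anywhere force parallel
  expect_equal(allowed_of(1, 1, 9), "parallel")
  expect_equal(allowed_of(5, 1, 1), "parallel")
})

test_that("strain flags lift the forcing with a caveat", {
  p <- allowed_topologies(rule_query(1, 1, 9,
                                     has_modified_guanines = TRUE))
  expect_gt(nrow(p$allowed), 1)
  expect_true(any(grepl("modified guanines", p$caveats)))
  pl <- allowed_topologies(rule_query(1, 2, 1, has_ligand = TRUE))
  expect_true(any(grepl("ligand", pl$caveats)))
})

test_that("totality and consistency over the loop-length cube", {
  set.seed(11)
  grid <- expand.grid(L1 = 0:15, L2 = 0:15, L3 = 0:15)
  grid <- grid[sample(nrow(grid), 300), ]  # full cube in acceptance
  for (i in seq_len(nrow(grid))) {
    p <- allowed_topologies(rule_query(grid$L1[i], grid$L2[i],
                                       grid$L3[i]))
    expect_gt(nrow(p$allowed), 0)
    expect_length(intersect(p$allowed$topology, p$excluded$topology), 0)
    expect_gte(length(p$matched_rules), 1)
  }
})

test_that("diagonal compatibility and minimum length", {
  expect_true(diagonal_compatible("antiparallel-basket"))
  expect_true(diagonal_compatible("antiparallel-basket2"))
  expect_true(diagonal_compatible("hybrid2"))
  for (t in setdiff(g4topo:::TOPOLOGIES,
                    c("antiparallel-basket", "antiparallel-basket2",
                      "hybrid2"))) {
    expect_false(diagonal_compatible(t), info = t)
  }
  expect_error(diagonal_compatible("sideways"), "unknown")

  expect_false(diagonal_min_length_rule(3)$pass)
  expect_false(diagonal_min_length_rule(0)$pass)
  expect_true(diagonal_min_length_rule(4)$pass)
  expect_match(diagonal_min_length_rule(3)$note, "143D")

  # any allowed basket with L2 >= 4 satisfies the diagonal minimum
  for (L2 in 4:5) {
    p <- allowed_topologies(rule_query(2, L2, 2))
    if ("antiparallel-basket" %in% p$allowed$topology) {
      expect_true(diagonal_min_length_rule(L2)$pass)
    }
  }
})

test_that("extremity-side and tetrad-count tendencies", {
  expect_equal(predict_extremity_sides("parallel"), "opposite")
  expect_equal(predict_extremity_sides("antiparallel-chair"), "same")
  expect_equal(predict_extremity_sides("hybrid1"), "opposite")
  expect_equal(predict_extremity_sides("hybrid2", "RNA"), "same")
  expect_equal(predict_extremity_sides("hybrid3", "RNA"), "same")
  expect_equal(predict_extremity_sides("hybrid3", "DNA"), "opposite")
  expect_equal(predict_extremity_sides("hybrid4", "DNA", TRUE), "middle")
  expect_equal(predict_extremity_sides("hybrid4", "DNA", FALSE), "same")
  expect_error(predict_extremity_sides("spiral"), "unknown")

  expect_equal(tetrad_count_tendency("parallel", "DNA")$n_tetrads, 3L)
  expect_equal(tetrad_count_tendency("antiparallel-chair")$n_tetrads, 2L)
  expect_equal(tetrad_count_tendency("hybrid2", "RNA")$n_tetrads, 2L)
  expect_equal(tetrad_count_tendency("hybrid2", "DNA")$n_tetrads, 3L)
})

test_that("duplex capability and 4-tetrad loop warnings", {
  expect_false(duplex_capable(9))
  expect_true(duplex_capable(10))
  expect_true(duplex_capable(15))

  expect_length(four_tetrad_loop_check(4, c(1, 2, 2)), 1)
  expect_match(four_tetrad_loop_check(4, c(1, 2, 2)), "loop 1")
  expect_length(four_tetrad_loop_check(3, c(1, 2, 1)), 0)
  expect_length(four_tetrad_loop_check(4, c(2, 2, 2)), 0)
})

test_that("annotated synthetic topologies are consistent with the rules", {
  # cross-module consistency: the annotator's topology is allowed for
  # its own loop lengths, or the prediction carries a caveat
  cases <- list(c("parallel", 1, 2, 1),
                c("antiparallel-chair", 2, 3, 2),
                c("antiparallel-basket", 2, 4, 2),
                c("hybrid1", 3, 3, 3),
                c("hybrid3", 3, 3, 3))
  for (cs in cases) {
    ann <- annotate_g4(build_g4(cs[1],
                                loop_lengths = as.numeric(cs[2:4])))
    p <- allowed_topologies(rule_query(as.numeric(cs[2]),
                                       as.numeric(cs[3]),
                                       as.numeric(cs[4])))
    expect_true(ann$topology %in% p$allowed$topology ||
                  length(p$caveats) > 0, info = cs[1])
  }
})
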