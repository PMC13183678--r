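test_that("pattern-to-topology map is the Fig.-1 bijection", {
  expect_equal(topology_from_pattern("dddd"), "parallel")
  expect_equal(topology_from_pattern("dudu"), "antiparallel-chair")
  expect_equal(topology_from_pattern("duud"), "antiparallel-basket")
  expect_equal(topology_from_pattern("dduu"), "antiparallel-basket2")
  expect_equal(topology_from_pattern("ddud"), "hybrid1")
  expect_equal(topology_from_pattern("dddu"), "hybrid2")
  expect_equal(topology_from_pattern("dudd"), "hybrid3")
  expect_equal(topology_from_pattern("duuu"), "hybrid4")
  expect_error(topology_from_pattern("addd"), "invalid")
  expect_error(topology_from_pattern("uddd"), "start with d")
  # bijectivity over the eight legal patterns
  pats <- paste0("d", c("ddd", "udu", "uud", "duu", "dud", "ddu", "udd",
                        "uuu"))
  expect_equal(anyDuplicated(vapply(pats, topology_from_pattern,
                                    character(1))), 0)
})

test_that("strand patterns of synthetic stems start with d", {
  for (topo in ALL_TOPOLOGIES) {
    ann <- cached_annotation(topo)
    expect_equal(substr(ann$strand_pattern, 1, 1), "d", info = topo)
    expect_equal(unname(ann$topology), topo, info = topo)
  }
})

test_that("gc patterns follow the canonical per-tetrad letters", {
  expect_equal(cached_annotation("parallel")$gc_pattern,
               c("aaaa", "aaaa", "aaaa"))
  expect_equal(cached_annotation("antiparallel-chair")$gc_pattern,
               c("sasa", "asas", "asas"))
  a2 <- annotate_g4(build_g4("antiparallel-chair", n_tetrads = 2))
  expect_length(a2$gc_pattern, 2)
  expect_equal(a2$gc_pattern, c("sasa", "asas"))
})

test_that("gc inversion symmetry: chair vs parallel letter swap", {
  # strands running the other way (d<->u with s<->a) keep Hoogsteen
  # detection intact and swap the gc letters on the flipped strands
  chair <- cached_annotation("antiparallel-chair")
  par <- cached_annotation("parallel")
  expect_equal(chair$n_tetrads, par$n_tetrads)
  g1 <- strsplit(chair$gc_pattern[1], "")[[1]]
  gp <- strsplit(par$gc_pattern[1], "")[[1]]
  flipped <- c(2, 4)  # strands that run u in the chair, d in parallel
  expect_true(all(g1[flipped] != "?" & gp[flipped] != "?"))
  expect_equal(g1[flipped], c("a", "a"))
  expect_equal(g1[c(1, 3)], c("s", "s"))
  expect_equal(gp, rep("a", 4))
})

test_that("groove widths map to letters at the published anchors", {
  expect_equal(g4topo:::groove_letter_from_width(17.0), "w")
  expect_equal(g4topo:::groove_letter_from_width(11.0), "n")
  expect_equal(g4topo:::groove_letter_from_width(15.0), "i")
  expect_equal(g4topo:::groove_letter_from_width(12.0), "i")
  expect_equal(g4topo:::groove_letter_from_width(NA), "?")
})

test_that("handedness follows the twist sign; single step undefined", {
  m <- cached_build("parallel")
  stem <- assemble_stem(detect_tetrads(m), m)
  h <- stem_handedness(stem, m)
  expect_equal(h$per_block, "RH")
  expect_equal(mean(h$twist), 30, tolerance = 0.05)

  ml <- build_g4("parallel", twist = -30)
  sl <- assemble_stem(detect_tetrads(ml), ml)
  hl <- stem_handedness(sl, ml)
  expect_equal(hl$per_block, "LH")
  expect_equal(mean(hl$twist), -30, tolerance = 0.05)
  expect_true("platypus_suspect" %in% annotate_g4(ml)$flags)

  # single-tetrad block is undefined
  h1 <- stem_handedness(stem, m, blocks = list(c(1L, 1L), c(2L, 3L)))
  expect_equal(h1$per_block[1], "-")
})

test_that("two-block annotation names both blocks with handedness", {
  ann <- cached_annotation("two-block")
  expect_equal(ann$topology, "two-block:parallel/parallel")
  expect_length(ann$handedness$per_block, 2)
  expect_true(all(ann$handedness$per_block %in% c("RH", "LH")))
  expect_false(is.na(ann$handedness$relative))
  expect_equal(ann$loop_combination, "-p-p-pi+p+p+p")
})
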