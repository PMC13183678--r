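test_that("tetrad detection recovers the generator's composition", {
  m <- cached_build("parallel")
  tets <- detect_tetrads(m)
  expect_length(tets, 3)
  # membership: generator guanines of tetrad t are residues with known
  # numbering; check disjointness and per-tetrad size instead of order
  all_uids <- unlist(lapply(tets, function(t) t$guanines$uid))
  expect_length(all_uids, 12)
  expect_equal(anyDuplicated(all_uids), 0)
  for (t in tets) expect_equal(nrow(t$guanines), 4)
  # tetrad 1 holds the 5'-most stem guanine
  expect_true("A:1" %in% tets[[1]]$guanines$uid)
})

test_that("fewer than four guanines yields an empty list", {
  m <- cached_build("parallel")
  keep <- m$residues$uid[m$residues$parent_base == "G"][1:3]
  atoms <- m$atoms[m$atoms$uid %in% keep,
                   c("atom", "altloc", "resname", "chain", "resno",
                     "x", "y", "z", "element")]
  m3 <- g4topo:::build_model(atoms, "three-gs", 1L, "synthetic")
  expect_identical(detect_tetrads(m3), list())
})

test_that("detection is invariant under rigid motion", {
  m <- cached_build("antiparallel-basket")
  mt <- rigid_transform(m, axis = c(1, -2, 0.5), angle_deg = 63,
                        shift = c(20, -7, 3))
  t0 <- detect_tetrads(m)
  t1 <- detect_tetrads(mt)
  expect_equal(length(t1), length(t0))
  for (k in seq_along(t0)) {
    expect_setequal(t1[[k]]$guanines$uid, t0[[k]]$guanines$uid)
  }
})

test_that("stem assembly: numbering, directions and degeneracy", {
  # chair: the first loop connects strands 1 and 4
  m <- cached_build("antiparallel-chair")
  stem <- assemble_stem(detect_tetrads(m), m)
  lps <- classify_loops(stem, m)$loops
  expect_equal(lps[[1]]$from_strand, 1)
  expect_equal(lps[[1]]$to_strand, 4)
  expect_equal(stem$columns[[1]]$direction, "d")

  # parallel: strand order follows chain order
  mp <- cached_build("parallel")
  sp <- assemble_stem(detect_tetrads(mp), mp)
  first_res <- vapply(sp$columns, function(col)
    min(col$guanines$chain_pos), numeric(1))
  expect_equal(order(first_res), 1:4)

  # single tetrad: degenerate stem
  keep <- sp$tetrads[[1]]$guanines$uid
  atoms <- mp$atoms[mp$atoms$uid %in% keep,
                    c("atom", "altloc", "resname", "chain", "resno",
                      "x", "y", "z", "element")]
  m1 <- g4topo:::build_model(atoms, "one-tetrad", 1L, "synthetic")
  t1 <- detect_tetrads(m1)
  expect_length(t1, 1)
  s1 <- assemble_stem(t1, m1)
  expect_true(s1$degenerate)
  expect_error(strand_direction_pattern(s1), "degenerate|undefined")
})

test_that("bulges, snapbacks and two-block splitting", {
  mb <- build_g4("parallel",
                 bulges = list(list(strand = 2, after_tetrad = 1, n = 1)))
  stem <- assemble_stem(detect_tetrads(mb), mb)
  disc <- detect_discontinuities(stem, mb)
  bulges <- Filter(function(d) d$kind == "bulge", disc$discontinuities)
  expect_length(bulges, 1)
  expect_equal(bulges[[1]]$strand_number, 2)
  expect_equal(bulges[[1]]$inserted_nts, 1)
  expect_equal(bulges[[1]]$between_tetrads, c(1L, 2L))
  expect_equal(annotate_g4(mb)$topology, "parallel")

  # canonical build: no discontinuities, one block
  mc <- cached_build("antiparallel-basket2")
  sc <- assemble_stem(detect_tetrads(mc), mc)
  dc <- detect_discontinuities(sc, mc)
  expect_length(dc$discontinuities, 0)
  expect_length(dc$blocks, 1)

  # two-block layout: >= 3 column breaks between tetrads 2 and 3
  m2 <- cached_build("two-block")
  s2 <- assemble_stem(detect_tetrads(m2), m2)
  d2 <- detect_discontinuities(s2, m2)
  expect_equal(d2$blocks, list(c(1L, 2L), c(3L, 4L)))
  breaks <- Filter(function(d) d$kind == "block-break",
                   d2$discontinuities)
  expect_gte(length(breaks), 3)

  # hybrid4: one 5'-bottom snapback on strand 1
  mh <- cached_build("hybrid4")
  sh <- assemble_stem(detect_tetrads(mh), mh)
  dh <- detect_discontinuities(sh, mh)
  snaps <- Filter(function(d) d$kind == "snapback", dh$discontinuities)
  expect_length(snaps, 1)
  expect_equal(snaps[[1]]$snapback_type, "5'-bottom")
  expect_equal(snaps[[1]]$strand_number, 1)
})
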