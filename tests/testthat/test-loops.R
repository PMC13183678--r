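test_that("loop combinations match the canonical table entries", {
  cases <- list(
    list("parallel", c(1, 2, 1), "-p-p-p"),
    list("antiparallel-chair", c(2, 3, 2), "+l+l+l"),
    list("antiparallel-basket", c(2, 4, 2), "-ld+l"))
  for (cs in cases) {
    ann <- annotate_g4(build_g4(cs[[1]], loop_lengths = cs[[2]]))
    expect_equal(ann$loop_combination, cs[[3]], info = cs[[1]])
    expect_equal(unname(ann$loop_lengths), cs[[2]], info = cs[[1]])
  }
})

test_that("reported loop lengths equal the requested lengths", {
  for (topo in c("hybrid1", "hybrid2", "hybrid3")) {
    req <- switch(topo, hybrid1 = c(2, 3, 1), hybrid2 = c(3, 6, 1),
                  hybrid3 = c(1, 3, 2))
    ann <- annotate_g4(build_g4(topo, loop_lengths = req))
    expect_equal(unname(ann$loop_lengths), req, info = topo)
    expect_equal(ann$topology, topo, info = topo)
  }
})

test_that("taxonomy partitions the strand/tetrad relation space", {
  # enumerate all (strand pair, same/different tetrad) combinations and
  # check exactly one kind fires per combination
  for (from in 1:4) for (to in 1:4) for (same_tet in c(TRUE, FALSE)) {
    rel <- g4topo:::strand_relation(from, to)
    kind <- if (rel == "same") "i"
      else if (rel == "adjacent" && !same_tet) "p"
      else if (rel == "adjacent") "l"
      else "d"
    expect_length(kind, 1)
    expect_true(kind %in% c("p", "l", "d", "i"))
  }
  # spot-check the defining predicates on real annotations
  basket <- cached_annotation("antiparallel-basket")
  kinds <- vapply(basket$loops, `[[`, character(1), "kind")
  expect_equal(kinds, c("l", "d", "l"))
  d <- basket$loops[[2]]
  expect_equal(abs(d$from_strand - d$to_strand), 2)  # opposite strands
  expect_equal(d$from_tetrad, d$to_tetrad)           # same tetrad
  expect_equal(d$progression, "none")
})

test_that("combination grammar round-trips, including snapbacks", {
  for (txt in c("-p-p-p", "+l+l+l", "-ld+l", "[-l]+l+p+p", "-p-p-pi+p+p+p",
                "[d]+p+l+p")) {
    parsed <- parse_loop_combination(txt)
    rendered <- render_loop_combination(lapply(parsed, function(p)
      c(p, list(length_nt = 1))))
    expect_equal(rendered, txt)
  }
  expect_error(parse_loop_combination("-x"), "cannot parse")
})

test_that("1-nt loops on unmodified synthetic structures are propeller", {
  for (topo in ALL_TOPOLOGIES) {
    ann <- cached_annotation(topo)
    for (lp in ann$loops) {
      if (lp$length_nt == 1 && !lp$is_snapback_loop) {
        expect_equal(lp$kind, "p", info = topo)
      }
    }
  }
})

test_that("0-nt loops are propeller, licensed by a discontinuity", {
  m <- cached_build("hybrid4")
  stem <- assemble_stem(detect_tetrads(m), m)
  disc <- detect_discontinuities(stem, m)
  loops <- classify_loops(stem, m, disc)$loops
  zn <- zero_nt_loops(loops, stem, disc)
  expect_length(zn, 1)
  expect_equal(zn[[1]]$loop$kind, "p")
  expect_equal(sort(c(zn[[1]]$loop$from_strand, zn[[1]]$loop$to_strand)),
               c(1, 4))
  expect_false(is.null(zn[[1]]$licensed_by))
  expect_null(zn[[1]]$warning)

  # canonical parallel: no 0-nt loops at all
  mp <- cached_build("parallel")
  sp <- assemble_stem(detect_tetrads(mp), mp)
  dp <- detect_discontinuities(sp, mp)
  expect_length(zero_nt_loops(classify_loops(sp, mp, dp)$loops, sp, dp), 0)

  # contrapositive: a 0-nt loop with no discontinuity anywhere warns
  fake <- list(list(kind = "p", length_nt = 0, progression = "+",
                    from_strand = 1, to_strand = 4, from_tetrad = 1,
                    to_tetrad = 3, is_snapback_loop = FALSE))
  no_disc <- list(discontinuities = list(), blocks = list(c(1L, 3L)))
  zw <- zero_nt_loops(fake, sp, no_disc)
  expect_match(zw[[1]]$warning, "no licensing discontinuity")
})

test_that("V-shaped strand follows the 0-nt loop", {
  ann <- cached_annotation("hybrid4")
  expect_equal(ann$v_shaped_strands, 4L)
  # no 0-nt loop, no V-shaped strand
  expect_length(cached_annotation("parallel")$v_shaped_strands, 0)
})

test_that("extremity sides match the per-topology map", {
  expect_equal(cached_annotation("parallel")$extremity_sides, "opposite")
  expect_equal(cached_annotation("antiparallel-chair")$extremity_sides,
               "same")
  # hybrid4 with 5'-bottom snapback: 5' guanine in the middle tetrad
  expect_equal(cached_annotation("hybrid4")$extremity_sides, "middle")
  # without the snapback the extremities share the top tetrad
  ann <- annotate_g4(build_g4("hybrid4", snapback = FALSE))
  expect_equal(ann$extremity_sides, "same")
})
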