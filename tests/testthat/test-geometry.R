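test_that("loop span model reproduces the printed spans", {
  expect_equal(loop_span_model(0), 6.25)
  expect_equal(loop_span_model(1), 12.5)
  expect_equal(loop_span_model(2), 18.75)
  expect_equal(loop_span_model(3), 25)
  expect_error(loop_span_model(-1), ">= 0")
  # strictly increasing
  spans <- loop_span_model(0:20)
  expect_true(all(diff(spans) > 0))
})

test_that("diagonal feasibility threshold and monotonicity", {
  f3 <- diagonal_feasibility(3)
  expect_false(f3$feasible)
  expect_equal(f3$modeled_length, 25)
  expect_equal(f3$threshold, 21.0 + 2 * 3.42)
  f4 <- diagonal_feasibility(4)
  expect_true(f4$feasible)
  expect_gt(f4$modeled_length, 31)
  expect_true(diagonal_feasibility(100)$feasible)
  feas <- vapply(0:30, function(n) diagonal_feasibility(n)$feasible,
                 logical(1))
  expect_true(all(diff(feas) >= 0))  # once feasible, stays feasible
})

test_that("constant overrides propagate consistently", {
  cst <- g4_constants(mean_c5_step = 7, mean_rise = 4, diagonal_c5 = 20)
  expect_equal(loop_span_model(2, cst), 21)
  f <- diagonal_feasibility(3, cst)
  expect_equal(f$threshold, 20 + 8)
  expect_equal(f$modeled_length, 28)
  expect_true(f$feasible)  # 28 >= 28 under the overridden constants
  expect_error(g4_constants(mean_c5_step = -1))
})

test_that("successive C5' distances on synthetic structures", {
  m <- cached_build("parallel", fn5 = 3, fn3 = 3)  # 22-nt chain
  d <- successive_c5_distances(m)
  expect_equal(d$n_pairs, 21)
  expect_gt(d$mean, 5.5)
  expect_lt(d$mean, 7.0)
  # two residues 6.25 A apart -> [6.25]
  atoms <- data.frame(
    atom = c("C5'", "C5'"), altloc = "", resname = "DT", chain = "A",
    resno = 1:2, x = c(0, 6.25), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE)
  m2 <- g4topo:::build_model(atoms, "pair", 1L, "synthetic")
  d2 <- successive_c5_distances(m2)
  expect_equal(d2$distances, 6.25)
  expect_equal(d2$mean, 6.25)
})

test_that("stem heights scale with tetrad count", {
  m3 <- cached_build("parallel")
  s3 <- assemble_stem(detect_tetrads(m3), m3)
  expect_equal(stem_height(s3, m3), 12, tolerance = 1.5 / 12)
  m4 <- build_g4("parallel", n_tetrads = 4, loop_lengths = c(2, 2, 2))
  s4 <- assemble_stem(detect_tetrads(m4), m4)
  expect_equal(stem_height(s4, m4), 18, tolerance = 1.5 / 18)
  # near-linear scaling in tetrad count at fixed rise (the helical wind
  # makes the chord slightly sub-linear in the angle)
  m2 <- build_g4("parallel", n_tetrads = 2)
  s2 <- assemble_stem(detect_tetrads(m2), m2)
  h <- c(stem_height(s2, m2), stem_height(s3, m3), stem_height(s4, m4))
  steps <- diff(h)
  expect_true(all(steps > 0))
  expect_equal(steps[1], steps[2], tolerance = 0.15)
})

test_that("rise and twist round-trip the generator parameters", {
  m <- build_g4("parallel", rise = 3.42, twist = 30)
  s <- assemble_stem(detect_tetrads(m), m)
  rt <- rise_and_twist(s, m)
  expect_equal(rt$rise, rep(3.42, 2), tolerance = 0.05 / 3.42)
  expect_equal(rt$twist, rep(30, 2), tolerance = 1 / 30)
  ml <- build_g4("parallel", twist = -30)
  sl <- assemble_stem(detect_tetrads(ml), ml)
  expect_true(all(rise_and_twist(sl, ml)$twist < 0))
  # single tetrad: empty
  expect_length(rise_and_twist(
    list(n_tetrads = 1L, degenerate = TRUE), m)$rise, 0)
})

test_that("tetrad planarity: exact plane and ideal template", {
  m <- cached_build("parallel")
  tets <- detect_tetrads(m)
  for (t in tets) expect_lt(tetrad_planarity(t, m), 0.2)
  # coplanar points give rms 0
  expect_equal(g4topo:::fit_plane(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1),
                                        0))$rms, 0)
})

test_that("geometric quantities are rigid-motion invariant", {
  m <- cached_build("antiparallel-chair")
  s <- assemble_stem(detect_tetrads(m), m)
  mt <- rigid_transform(m, axis = c(2, 1, 5), angle_deg = 111,
                        shift = c(-4, 9, 2))
  st <- assemble_stem(detect_tetrads(mt), mt)
  expect_equal(stem_height(st, mt), stem_height(s, m), tolerance = 1e-6)
  expect_equal(rise_and_twist(st, mt)$twist, rise_and_twist(s, m)$twist,
               tolerance = 1e-6)
  expect_equal(groove_signature(st, mt)$widths,
               groove_signature(s, m)$widths, tolerance = 1e-6)
  expect_equal(successive_c5_distances(mt)$mean,
               successive_c5_distances(m)$mean, tolerance = 1e-6)
  expect_equal(tetrad_planarity(st$tetrads[[1]], mt),
               tetrad_planarity(s$tetrads[[1]], m), tolerance = 1e-6)
})
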