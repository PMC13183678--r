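test_that("PDB round trip preserves residues and coordinates", {
  m <- cached_build("parallel", fn5 = 3, fn3 = 3)  # 16 stem/loop + 6 FN
  expect_equal(nrow(m$residues), 22)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  # independent text scan of ATOM records as the residue-count oracle
  lines <- readLines(f)
  atom <- lines[startsWith(lines, "ATOM")]
  n_res <- length(unique(substr(atom, 18, 26)))
  expect_equal(n_res, 22)

  m2 <- read_structure(f)
  expect_s3_class(m2, "g4_model")
  expect_equal(nrow(m2$residues), 22)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 2e-3)
  expect_equal(max(abs(m2$atoms$y - m$atoms$y)), 0, tolerance = 1e-3)
  expect_equal(max(abs(m2$atoms$z - m$atoms$z)), 0, tolerance = 1e-3)
})

test_that("format detection, empty models and model selection", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(protein_only_pdb(), f)
  expect_error(read_structure(f), "no nucleic")

  expect_error(read_structure(tempfile()), "not found")

  # multi-model file: model 2 is shifted; selection picks the right block
  m <- cached_build("parallel")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  a <- m$atoms
  one <- sprintf(paste0("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                        "  1.00  0.00          %2s"),
                 seq_len(nrow(a)),
                 ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                        a$atom),
                 a$resname, a$chain, a$resno, a$x, a$y, a$z, a$element)
  two <- sprintf(paste0("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                        "  1.00  0.00          %2s"),
                 seq_len(nrow(a)),
                 ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                        a$atom),
                 a$resname, a$chain, a$resno, a$x + 100, a$y, a$z,
                 a$element)
  writeLines(c("MODEL     1", one, "ENDMDL",
               "MODEL     2", two, "ENDMDL", "END"), f2)
  m1 <- read_structure(f2, model_index = 1)
  m2 <- read_structure(f2, model_index = 2)
  expect_equal(m1$atoms$x, a$x, tolerance = 1e-3)
  expect_equal(m2$atoms$x, a$x + 100, tolerance = 1e-3)
  expect_error(read_structure(f2, model_index = 3), "out of range")
})

test_that("mmCIF reader agrees with the source model", {
  m <- cached_build("antiparallel-chair")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(model_as_mmcif(m), f)
  m2 <- read_structure(f)
  expect_equal(m2$format, "mmcif")
  expect_equal(nrow(m2$residues), nrow(m$residues))
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  a2 <- annotate_g4(m2)
  expect_equal(a2$topology, "antiparallel-chair")
})

test_that("glycosidic assignment partitions (-180, 180]", {
  expect_equal(assign_glycosidic(180), "anti")
  expect_equal(assign_glycosidic(60), "syn")
  expect_equal(assign_glycosidic(-120), "anti")
  expect_equal(assign_glycosidic(NA), "undefined")
  expect_error(assign_glycosidic(200), "chi")
  # total on the domain and exactly two intervals: syn is one contiguous
  # arc, anti the complement
  grid <- seq(-179.5, 180, by = 0.5)
  states <- assign_glycosidic(grid)
  expect_true(all(states %in% c("syn", "anti")))
  flips <- sum(states[-1] != states[-length(states)])
  expect_equal(flips, 2)  # anti -> syn at -90, syn -> anti past 90
  expect_equal(unname(states[grid == 90]), "syn")
  expect_equal(unname(states[grid == 90.5]), "anti")
})

test_that("modified residues map to their parent base and are flagged", {
  m <- cached_build("parallel")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- readLines(f)
  # rename the first stem guanine to 8-bromo-dG
  i <- grep(" DG ", lines)
  first_res <- substr(lines[i[1]], 23, 26)
  sel <- i[substr(lines[i], 23, 26) == first_res]
  lines[sel] <- sub(" DG ", " BGM", lines[sel])
  writeLines(lines, f)
  m2 <- read_structure(f)
  r1 <- m2$residues[1, ]
  expect_equal(r1$parent_base, "G")
  expect_true(r1$is_modified)
  ann <- annotate_g4(m2)
  expect_true("modified_guanines" %in% ann$flags)
  expect_match(ann$sequence, "\\[BGM\\]")
})
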