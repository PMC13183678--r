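# Generator of idealized intramolecular G4 coordinate models with known
# ground truth. The stem is built from planar stacked G-tetrads (default
# rise 3.42 A, twist +/-30 deg); strand directions, glycosidic patterns,
# loops, bulges, snapbacks and two-block layouts are laid out per the
# canonical chain paths of the eight topologies. The templates are
# idealized: Hoogsteen donor-acceptor distances are ~2.9 A, bases exactly
# planar, and only the atoms the annotator consumes are placed for loop
# nucleotides (P, C5', C1').

# Guanine base + C1' in the standard planar reference frame (Angstrom).
GUANINE_FRAME <- matrix(c(
  -2.477, 5.399, 0.000,  # C1'
  -1.289, 4.551, 0.000,  # N9
   0.023, 4.962, 0.000,  # C8
   0.870, 3.969, 0.000,  # N7
   0.071, 2.833, 0.000,  # C5
   0.424, 1.460, 0.000,  # C6
   1.554, 0.955, 0.000,  # O6
  -0.700, 0.641, 0.000,  # N1
  -1.999, 1.087, 0.000,  # C2
  -2.949, 0.139, 0.000,  # N2
  -2.342, 2.364, 0.000,  # N3
  -1.265, 3.177, 0.000   # C4
), ncol = 3, byrow = TRUE,
dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2",
                  "N2", "N3", "C4"), c("x", "y", "z")))

# Template constants calibrated once on the idealized stem so that the
# annotator's groove letters reproduce the canonical signatures
# (wide >= 16 A between d,u strand pairs; narrow <= 11.5 A between u,d;
# intermediate otherwise) and successive C5' steps fall near 6.25 A.
SYN_C5_RADIUS <- 9.6     # C5' distance from the stem axis
SYN_C5_LEAN <- 18        # azimuthal lean (deg): +lean for u, -lean for d
SYN_C5_ZOFF <- 0.8       # axial offset toward the residue's 5' side
SYN_CHI_ANTI <- -120     # glycosidic torsion written for anti guanines
SYN_CHI_SYN <- 60        # and for syn guanines

# Solve the rigid in-plane placement of the reference guanine such that
# four copies related by 90 deg rotations about z close a Hoogsteen cycle
# (N1->O6 and N2->N7 ~2.9 A). Cached after the first call.
tetrad_template <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rot2 <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)),
                                2, 2, byrow = TRUE)
    xy <- GUANINE_FRAME[, 1:2]
    objective <- function(p, step_sign) {
      placed <- xy %*% t(rot2(p[1])) +
        matrix(p[2:3], nrow(xy), 2, byrow = TRUE)
      nb <- placed %*% t(rot2(step_sign * pi / 2))
      d1 <- vnorm(c(placed["N1", ] - nb["O6", ], 0))
      d2 <- vnorm(c(placed["N2", ] - nb["N7", ], 0))
      r6 <- vnorm(c(placed["O6", ], 0))
      r1 <- vnorm(c(placed["C1'", ], 0))
      # the C1' radius term selects the physical branch (C1'-C1'
      # diagonal ~15 A) over a compact tangential arrangement
      (d1 - 2.90)^2 + (d2 - 2.85)^2 + 0.3 * (r6 - 3.0)^2 +
        0.05 * (r1 - 7.5)^2
    }
    best <- NULL
    for (sgn in c(1, -1)) for (th0 in seq(0, 2 * pi, length.out = 9)) {
      fit <- stats::optim(c(th0, 6, 0), objective, step_sign = sgn,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) {
        best <- fit; best$sign <- sgn
      }
    }
    placed <- xy %*% t(rot2(best$par[1])) +
      matrix(best$par[2:3], nrow(xy), 2, byrow = TRUE)
    cache <<- list(xy = placed, step_sign = best$sign,
                   residual = best$value)
    cache
  }
})

# Canonical chain paths: for each topology, the clockwise strand slot
# visited by each G-tract and the implied loop kinds, reproducing the
# dominant loop combinations of the eight topologies.
TOPOLOGY_CHAIN <- list(
  parallel = list(tracts = c(1, 2, 3, 4)),
  `antiparallel-chair` = list(tracts = c(1, 4, 3, 2)),
  `antiparallel-basket` = list(tracts = c(1, 2, 4, 3)),
  `antiparallel-basket2` = list(tracts = c(1, 4, 2, 3)),
  hybrid1 = list(tracts = c(1, 2, 3, 4)),
  hybrid2 = list(tracts = c(1, 2, 4, 3)),
  hybrid3 = list(tracts = c(1, 2, 3, 4)),
  hybrid4 = list(tracts = c(1, 4, 3, 2))  # no-snapback variant
)

DEFAULT_LOOPS <- list(
  parallel = c(1, 2, 1),
  `antiparallel-chair` = c(2, 3, 2),
  `antiparallel-basket` = c(2, 4, 2),
  `antiparallel-basket2` = c(3, 4, 3),
  hybrid1 = c(3, 3, 3),
  hybrid2 = c(1, 5, 2),
  hybrid3 = c(3, 3, 3),
  hybrid4 = c(2, 1, 4)   # + the 0-nt loop before strand 4 when snapback
)

strand_directions_of <- function(topology) {
  pat <- names(TOPOLOGY_BY_PATTERN)[TOPOLOGY_BY_PATTERN == topology]
  strsplit(pat, "")[[1]]
}

# Glycosidic letter for a stem guanine: in a stem with at least one up
# strand, tetrad 1 carries syn on down strands and anti on up strands,
# inverted from tetrad 2 on; all-parallel stems are all-anti.
syn_gc_letter <- function(direction, tetrad, all_parallel) {
  if (all_parallel) return("a")
  first <- tetrad == 1
  if (direction == "d") (if (first) "s" else "a")
  else (if (first) "a" else "s")
}

# ------------------------------------------------------------ placement

# Coordinates of the stem guanine occupying clockwise slot `slot` (1..4)
# of tetrad `tet` (1 = top, z = 0, stacking toward -z), including base,
# C1', O4' (placed from chi) and C5' (placed from the strand direction).
place_stem_guanine <- function(slot, tet, direction, gc_letter,
                               rise, twist) {
  tmpl <- tetrad_template()
  # clockwise slots advance by -90 deg in standard xy (see axis frame);
  # stacking down rotates by -twist per step for a right-handed stem.
  ang <- -90 * (slot - 1) - twist * (tet - 1)
  R <- rotation_matrix(c(0, 0, 1), ang)
  xyz <- cbind(tmpl$xy, 0) %*% t(R)
  rownames(xyz) <- rownames(tmpl$xy)
  xyz[, 3] <- xyz[, 3] - rise * (tet - 1)

  chi <- if (gc_letter == "s") SYN_CHI_SYN else SYN_CHI_ANTI
  o4 <- place_atom(xyz["C4", ], xyz["N9", ], xyz["C1'", ],
                   1.42, 108.2, chi)
  xyz <- rbind(xyz, `O4'` = o4)

  # C5' on a cylinder about the axis: azimuth of C1' +/- the direction
  # lean, offset toward the residue's 5' side (up for d, down for u).
  az <- atan2(xyz["C1'", 2], xyz["C1'", 1])
  lean <- deg2rad(SYN_C5_LEAN) * (if (direction == "u") -1 else 1)
  # -90 deg steps are clockwise; a clockwise lean is negative in
  # standard angle terms, so u strands lean anticlockwise (+).
  zoff <- if (direction == "d") SYN_C5_ZOFF else -SYN_C5_ZOFF
  c5 <- c(SYN_C5_RADIUS * cos(az + lean), SYN_C5_RADIUS * sin(az + lean),
          xyz["C1'", 3] + zoff)
  rbind(xyz, `C5'` = c5)
}

# Evenly spaced points along a circular arc from a to b bulging toward
# `out`, with total arc length ~ (n + 1) * step. Returns an n x 3 matrix.
arc_points <- function(a, b, out, n, step) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  chord <- vnorm(b - a)
  target <- max((n + 1) * step, chord * 1.02)
  # solve arc half-angle t: arc = chord * t / sin(t)
  f <- function(t) t / sin(t) - target / chord
  tt <- tryCatch(stats::uniroot(f, c(1e-6, pi - 1e-6))$root,
                 error = function(e) 1e-3)
  radius <- chord / (2 * sin(tt))
  mid <- (a + b) / 2
  e1 <- unitv(b - a)
  ov <- out - vdot(out, e1) * e1
  e2 <- if (vnorm(ov) < 1e-6) unitv(vcross(e1, c(0, 0, 1)) + 1e-3)
        else unitv(ov)
  center <- mid - radius * cos(tt) * e2
  # sweep from a (phi = pi/2 + t) over the apex (pi/2) to b (pi/2 - t);
  # valid for minor and major arcs alike
  angs <- seq(pi / 2 + tt, pi / 2 - tt,
              length.out = n + 2)[2:(n + 1)]
  t(vapply(angs, function(th)
    center + radius * (cos(th) * e1 + sin(th) * e2), numeric(3)))
}

# ------------------------------------------------------------ builder

new_atom_rows <- function(resno, resname, atoms) {
  data.frame(atom = rownames(atoms), altloc = "", resname = resname,
             chain = "A", resno = resno,
             x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
             element = substr(gsub("[^A-Za-z]", "", rownames(atoms)), 1, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an idealized G4 coordinate model
#'
#' Generates a synthetic intramolecular G4 with known ground truth:
#' planar G-tetrads stacked with the requested rise and twist, strand
#' directions per the topology's clockwise pattern, glycosidic geometry
#' consistent with the canonical syn/anti letters, and loop nucleotides on
#' smooth arcs with successive C5' spacing near the mean step. Supported
#' extras: bulges, the hybrid4 5'-bottom snapback with its 0-nt loop,
#' two-block layouts, left-handed stems (negative twist), flanking
#' nucleotides and Gaussian coordinate noise.
#'
#' @param topology one of the eight one-block topology names, or
#'   `"two-block"` for a 2+2 dddd/uuuu parallel/parallel layout
#' @param n_tetrads tetrads in the stem (2-4; two-block builds 2+2)
#' @param loop_lengths lengths (nt) of the three loops, in chain order
#'   (defaults per topology; hybrid4 with snapback appends a 0-nt loop)
#' @param rise,twist stacking rise (A) and twist (deg; negative builds a
#'   left-handed stem)
#' @param rna build an RNA chain (resnames G/U) instead of DNA (DG/DT)
#' @param snapback hybrid4 only: start with a 2-nt 5'-bottom snapback and
#'   a 0-nt loop into strand 4 (default TRUE for hybrid4)
#' @param bulges list of `list(strand =, after_tetrad =, n =)` descriptors
#'   inserting `n` non-stem nucleotides within a strand column
#' @param fn5,fn3 number of 5'/3' flanking nucleotides
#' @param noise_sigma isotropic Gaussian displacement (A) applied to all
#'   atoms
#' @param seed RNG seed used when `noise_sigma > 0`
#' @param force bypass the diagonal-loop minimum-length check
#' @param constants a [g4_constants()] list (loop arc spacing)
#' @return a `g4_model`
#' @export
#' @examples
#' m <- build_g4("parallel", n_tetrads = 3, loop_lengths = c(1, 2, 1))
build_g4 <- function(topology, n_tetrads = 3, loop_lengths = NULL,
                     rise = 3.42, twist = 30, rna = FALSE,
                     snapback = identical(topology, "hybrid4"),
                     bulges = NULL, fn5 = 0, fn3 = 0,
                     noise_sigma = 0, seed = NULL, force = FALSE,
                     constants = g4_constants()) {
  two_block <- identical(topology, "two-block")
  if (!two_block && !topology %in% TOPOLOGIES) {
    stop("unknown topology: ", topology)
  }
  if (!two_block) stopifnot(n_tetrads >= 2, n_tetrads <= 4)
  # a 2-tetrad hybrid4 cannot carry the 2-nt 5'-bottom snapback (it
  # would leave no middle tetrad); build the snapback-free variant
  if (identical(topology, "hybrid4") && n_tetrads == 2) snapback <- FALSE
  if (is.null(loop_lengths)) {
    loop_lengths <- if (two_block) c(1, 1, 1, 2, 1, 1, 1)
                    else DEFAULT_LOOPS[[topology]]
  }
  g_res <- if (rna) "G" else "DG"
  l_res <- if (rna) "U" else "DT"

  # Geometric realizability: loops that must be diagonal need >= 4 nt.
  if (!force && !two_block) {
    diag_idx <- switch(topology,
      `antiparallel-basket` = 2L, `antiparallel-basket2` = 2L,
      hybrid2 = 2L, hybrid4 = if (snapback) 3L else NULL, NULL)
    if (!is.null(diag_idx) && loop_lengths[diag_idx] <= 3) {
      stop("diagonal loop of ", loop_lengths[diag_idx], " nt is not ",
           "geometrically realizable (diagonal loops require at least ",
           "4 nts; modeled span ",
           format(loop_span_model(loop_lengths[diag_idx], constants)),
           " A < ", format(constants$diagonal_c5 + 2 * constants$mean_rise),
           " A); pass force = TRUE to override")
    }
  }

  # ---- lay out the chain as a list of elements ----
  # element: list(type = "G", slot, tet, dir, gc) or
  #          list(type = "loop", n) (non-stem nucleotides)
  chain <- list()
  add_tract <- function(slot, dirs, tets, all_par) {
    for (t in tets) {
      chain[[length(chain) + 1L]] <<- list(
        type = "G", slot = slot, tet = t, dir = dirs,
        gc = syn_gc_letter(dirs, t, all_par))
    }
  }
  add_loop <- function(n) {
    if (n > 0) chain[[length(chain) + 1L]] <<- list(type = "loop", n = n)
  }

  if (two_block) {
    # block 1: tetrads 1-2, dddd; block 2: tetrads 3-4, uuuu; a linker
    # (internal loop) joins strand 4 of block 1 to its column in block 2.
    n_total <- 4L
    for (k in 1:4) {
      add_tract(k, "d", 1:2, all_par = TRUE)
      if (k < 4) add_loop(loop_lengths[k])
    }
    add_loop(loop_lengths[4])  # linker
    for (k in 4:1) {
      add_tract(k, "u", c(4L, 3L), all_par = TRUE)
      if (k > 1) add_loop(loop_lengths[4 + (4 - k)])
    }
  } else if (topology == "hybrid4" && snapback) {
    n_total <- n_tetrads
    dirs <- strand_directions_of(topology)  # d u u u
    all_par <- FALSE
    # 5'-bottom snapback: the chain starts in the middle tetrad of
    # strand 1 and runs to the bottom; the top guanine of strand 1 is
    # supplied later, just before the 0-nt loop into strand 4.
    add_tract(1, "d", 2:n_total, all_par)
    add_loop(loop_lengths[1])
    add_tract(2, "u", n_total:1, all_par)
    add_loop(loop_lengths[2])
    add_tract(3, "u", n_total:1, all_par)
    add_loop(loop_lengths[3])
    add_tract(1, "d", 1L, all_par)        # completes strand 1 on top
    # 0-nt loop here (nothing to add), then strand 4 upward (V-shaped)
    add_tract(4, "u", n_total:1, all_par)
  } else {
    n_total <- n_tetrads
    dirs <- strand_directions_of(topology)
    all_par <- topology == "parallel"
    slots <- TOPOLOGY_CHAIN[[topology]]$tracts
    for (j in 1:4) {
      s <- slots[j]
      tets <- if (dirs[s] == "d") 1:n_total else n_total:1
      add_tract(s, dirs[s], tets, all_par)
      if (j < 4) add_loop(loop_lengths[j])
    }
  }

  # ---- bulges: insert non-stem residues inside a strand column ----
  if (!is.null(bulges)) {
    for (b in bulges) {
      ins <- NA_integer_
      for (i in seq_along(chain)[-1]) {
        e0 <- chain[[i - 1L]]; e1 <- chain[[i]]
        if (e0$type == "G" && e1$type == "G" &&
            e0$slot == b$strand && e1$slot == b$strand &&
            min(e0$tet, e1$tet) == b$after_tetrad &&
            abs(e1$tet - e0$tet) == 1) { ins <- i; break }
      }
      if (is.na(ins)) stop("bulge descriptor does not match a strand step")
      chain <- append(chain, list(list(type = "bulge", n = b$n)), ins - 1L)
    }
  }

  # ---- place atoms ----
  rows <- list(); resno <- 0L
  g_atoms <- list()  # placed stem guanine atom sets, by chain element idx
  for (i in seq_along(chain)) {
    e <- chain[[i]]
    if (e$type == "G") {
      # negative twist stacks the tetrads the other way round: a
      # left-handed stem (each tetrad is internally unchanged).
      g_atoms[[as.character(i)]] <-
        place_stem_guanine(e$slot, e$tet, e$dir, e$gc, rise, twist)
    }
  }

  last_g_idx <- NA_integer_
  emit_G <- function(i) {
    resno <<- resno + 1L
    rows[[length(rows) + 1L]] <<- new_atom_rows(resno, g_res,
                                                g_atoms[[as.character(i)]])
    resno
  }

  # first pass: emit residues in order, interpolating loop/bulge atoms
  # between the C5' anchors of the surrounding stem guanines.
  seq_elems <- chain
  # precompute anchor C5' for each G element
  anchor <- function(i) g_atoms[[as.character(i)]]["C5'", ]

  # 5' flanking nucleotides approach the first anchor from above/outside
  first_g <- which(vapply(seq_elems, function(e) e$type == "G",
                          logical(1)))[1]
  if (fn5 > 0) {
    a <- anchor(first_g)
    dirv <- unitv(a - c(0, 0, a[3]) + c(0, 0, 2))
    for (k in fn5:1) {
      p <- a + dirv * constants$mean_c5_step * k
      resno <- resno + 1L
      rows[[length(rows) + 1L]] <- new_atom_rows(
        resno, l_res, rbind(`C5'` = p, `C1'` = p - c(0, 0, 1.5)))
    }
  }

  i <- 1L
  while (i <= length(seq_elems)) {
    e <- seq_elems[[i]]
    if (e$type == "G") {
      emit_G(i)
      last_g_idx <- i
    } else {
      # find next G element for the far anchor
      j <- i + 1L
      while (j <= length(seq_elems) && seq_elems[[j]]$type != "G") {
        j <- j + 1L
      }
      stopifnot(j <= length(seq_elems), !is.na(last_g_idx))
      a <- anchor(last_g_idx); b <- anchor(j)
      mid <- (a + b) / 2
      radial <- mid - c(0, 0, mid[3])
      out <- if (vnorm(radial) > 2.5) unitv(radial) else {
        tets <- c(seq_elems[[last_g_idx]]$tet, seq_elems[[j]]$tet)
        if (mean(tets) <= (n_total + 1) / 2) c(0, 0, 1) else c(0, 0, -1)
      }
      if (e$type == "bulge") out <- unitv(radial + c(0, 0, 0)) # outward
      pts <- arc_points(a, b, out, e$n, constants$mean_c5_step)
      for (k in seq_len(e$n)) {
        p <- pts[k, ]
        inw <- c(0, 0, p[3]) - p
        c1 <- p + (if (vnorm(inw) > 1e-6) unitv(inw) else c(0, 0, 1)) * 1.5
        resno <- resno + 1L
        rows[[length(rows) + 1L]] <- new_atom_rows(
          resno, l_res, rbind(`C5'` = p, `C1'` = c1))
      }
    }
    i <- i + 1L
  }

  if (fn3 > 0) {
    a <- anchor(last_g_idx)
    dirv <- unitv(a - c(0, 0, a[3]) + c(0, 0, -2))
    for (k in 1:fn3) {
      p <- a + dirv * constants$mean_c5_step * k
      resno <- resno + 1L
      rows[[length(rows) + 1L]] <- new_atom_rows(
        resno, l_res, rbind(`C5'` = p, `C1'` = p + c(0, 0, 1.5)))
    }
  }

  atoms <- do.call(rbind, rows)

  # phosphates: P_i sits on the backbone between residue i-1 and i.
  atoms <- add_phosphates(atoms)

  if (noise_sigma > 0) {
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(n, 0, noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(n, 0, noise_sigma)
  }

  label <- if (two_block) "two-block" else topology
  build_model(atoms, paste0("synthetic-", label), 1L, "synthetic")
}

# Place one P atom per residue (except the 5'-most), at a weighted point
# between the previous residue's C5' and the own C5', tracing the
# backbone path (this is what renders V-shaped strands).
add_phosphates <- function(atoms) {
  resnos <- unique(atoms$resno)
  out <- list(atoms)
  for (k in seq_along(resnos)[-1]) {
    cur <- atoms[atoms$resno == resnos[k] & atoms$atom == "C5'", ]
    prev <- atoms[atoms$resno == resnos[k - 1] & atoms$atom == "C5'", ]
    if (nrow(cur) != 1 || nrow(prev) != 1) next
    p <- c(cur$x, cur$y, cur$z) * 0.65 + c(prev$x, prev$y, prev$z) * 0.35
    out[[length(out) + 1L]] <- data.frame(
      atom = "P", altloc = "", resname = cur$resname, chain = cur$chain,
      resno = cur$resno, x = p[1], y = p[2], z = p[3], element = "P",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(match(res$resno, resnos)), ]
}

#' Apply isotropic Gaussian coordinate noise to a model
#'
#' Deterministic given `seed`; `sigma = 0` returns identical coordinates.
#'
#' @param model a `g4_model`
#' @param sigma displacement standard deviation per coordinate (A)
#' @param seed RNG seed
#' @return a new `g4_model` with recomputed torsions
#' @export
perturb <- function(model, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  atoms <- model$atoms[, c("atom", "altloc", "resname", "chain", "resno",
                           "x", "y", "z", "element")]
  if (sigma > 0) {
    set.seed(seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, sigma)
    atoms$y <- atoms$y + stats::rnorm(n, 0, sigma)
    atoms$z <- atoms$z + stats::rnorm(n, 0, sigma)
  }
  build_model(atoms, model$source_id, model$model_index, model$format)
}

#' Apply a rigid-body transform to a model
#'
#' Rotates all coordinates by `angle_deg` about `axis` (through the
#' origin) and then translates by `shift`. Used to check invariance of
#' the annotator under rigid motion.
#'
#' @param model a `g4_model`
#' @param axis rotation axis (length-3)
#' @param angle_deg rotation angle in degrees
#' @param shift translation vector (length-3)
#' @return a transformed `g4_model`
#' @export
rigid_transform <- function(model, axis = c(0, 0, 1), angle_deg = 0,
                            shift = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  atoms <- model$atoms[, c("atom", "altloc", "resname", "chain", "resno",
                           "x", "y", "z", "element")]
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  build_model(atoms, model$source_id, model$model_index, model$format)
}

#' Write a model as a PDB file
#'
#' Standard ATOM records readable by [read_structure()]; coordinates are
#' preserved to PDB precision (1e-3 A).
#'
#' @param model a `g4_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    nm <- a$atom[i]
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    lines[i] <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, nm_fmt, a$resname[i], a$chain[i], a$resno[i],
      a$x[i], a$y[i], a$z[i], 1.00, 0.00, a$element[i])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
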