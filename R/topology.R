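# Strand-direction pattern, topology naming, glycosidic patterns,
# groove-width signatures and handedness.

#' Strand-direction pattern of a stem
#'
#' Four letters over \{d, u\}: letter k is the direction of clockwise
#' strand k (viewed from the top). Letter 1 is always `d` by the
#' orientation convention.
#'
#' @param stem a `g4_stem`
#' @return a 4-character string such as `"dddd"`
#' @export
strand_direction_pattern <- function(stem) {
  if (stem$degenerate || length(stem$columns) != 4) {
    stop("undefined strand pattern: degenerate or incomplete stem")
  }
  dirs <- vapply(stem$columns, `[[`, character(1), "direction")
  if (anyNA(dirs)) stop("undefined strand pattern: ambiguous direction")
  paste(dirs, collapse = "")
}

#' Topology name for a strand-direction pattern
#'
#' Bijective map of the eight one-block patterns (first strand down) to
#' their names: dddd parallel, dudu antiparallel-chair, duud
#' antiparallel-basket, dduu antiparallel-basket2, ddud hybrid1, dddu
#' hybrid2, dudd hybrid3, duuu hybrid4.
#'
#' @param pattern 4-letter string over \{d, u\} starting with `d`
#' @return topology name
#' @export
#' @examples
#' topology_from_pattern("dddd")  # "parallel"
topology_from_pattern <- function(pattern) {
  if (!grepl("^[du]{4}$", pattern)) {
    stop("invalid strand pattern: ", pattern)
  }
  if (substr(pattern, 1, 1) != "d") {
    stop("strand pattern must start with d (strand 1 is down): ", pattern)
  }
  unname(TOPOLOGY_BY_PATTERN[pattern])
}

#' Per-tetrad glycosidic configuration patterns
#'
#' One 4-letter string per tetrad giving the syn (s) / anti (a) state of
#' strands 1..4, read clockwise from the top. An undefined glycosidic
#' state renders as `?` with a warning.
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @return character vector, one string per tetrad
#' @export
gc_pattern <- function(stem, model) {
  if (stem$degenerate) stop("gc pattern undefined for a degenerate stem")
  res <- model$residues
  out <- character(stem$n_tetrads)
  warned <- FALSE
  for (t in seq_len(stem$n_tetrads)) {
    letters4 <- vapply(stem$columns, function(col) {
      uid <- col$guanines$uid[col$guanines$tetrad == t]
      gc <- res$gc[res$uid == uid]
      if (gc == "syn") "s" else if (gc == "anti") "a" else "?"
    }, character(1))
    if (any(letters4 == "?")) warned <- TRUE
    out[t] <- paste(letters4, collapse = "")
  }
  if (warned) warning("undefined glycosidic state on stem guanines")
  out
}

#' Groove-width signature of a stem
#'
#' Groove k lies between clockwise-adjacent strands k and k+1. Its width
#' is the mean over tetrads of the C5'-C5' distance between the two
#' strands' guanines; letters use fixed thresholds (wide >= 16 A, narrow
#' <= 11.5 A, intermediate/medium otherwise). Minimum widths over the
#' tetrads are also reported.
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @return list with `widths` (mean, length 4), `min_widths`, `letters`
#'   (4 of w/n/i, `?` when C5' atoms are missing), `signature` (string)
#' @export
groove_signature <- function(stem, model) {
  if (stem$degenerate) stop("groove signature undefined: degenerate stem")
  widths <- min_widths <- rep(NA_real_, 4)
  for (k in 1:4) {
    k2 <- if (k == 4) 1L else k + 1L
    ds <- numeric(0)
    for (t in seq_len(stem$n_tetrads)) {
      u1 <- stem$columns[[k]]$guanines$uid[
        stem$columns[[k]]$guanines$tetrad == t]
      u2 <- stem$columns[[k2]]$guanines$uid[
        stem$columns[[k2]]$guanines$tetrad == t]
      a <- atom_xyz(model, u1, "C5'"); b <- atom_xyz(model, u2, "C5'")
      if (is.null(a) || is.null(b)) next
      ds <- c(ds, vnorm(b - a))
    }
    if (length(ds)) {
      widths[k] <- mean(ds); min_widths[k] <- min(ds)
    }
  }
  letters <- vapply(widths, groove_letter_from_width, character(1))
  list(widths = widths, min_widths = min_widths, letters = letters,
       signature = paste(letters, collapse = ""))
}

#' Handedness of the stem (per block and relative)
#'
#' Right-handed (RH) when the mean signed inter-tetrad twist about the
#' top-to-bottom axis is positive (+30 deg per step in canonical stems),
#' left-handed (LH) when negative. For a two-block stem the handedness is
#' reported per block, plus the relative handedness across the block
#' junction; single-tetrad blocks are undefined (`"-"`).
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @param blocks list of tetrad-index ranges (default: one block)
#' @return list with `per_block` (character vector of RH/LH/-),
#'   `relative` (RH/LH/NA), `twist` (per-step vector)
#' @export
stem_handedness <- function(stem, model,
                            blocks = list(c(1L, stem$n_tetrads))) {
  rt <- rise_and_twist(stem, model)
  tw <- rt$twist
  hand_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) "-" else if (mean(x) > 0) "RH" else "LH"
  }
  per_block <- vapply(blocks, function(b) {
    if (b[2] - b[1] < 1) return("-")  # single-tetrad block
    steps <- seq(b[1], b[2] - 1L)
    steps <- steps[steps >= 1 & steps <= length(tw)]
    if (length(steps) == 0) "-" else hand_of(tw[steps])
  }, character(1))
  relative <- NA_character_
  if (length(blocks) == 2) {
    j <- blocks[[1]][2]
    if (j >= 1 && j <= length(tw)) relative <- hand_of(tw[j])
  }
  list(per_block = per_block, relative = relative, twist = tw)
}

# Fallback topology assignment when strand directions are broken by
# snapbacks: match the observed gc pattern and groove signature against
# the canonical per-topology expectations.
topology_from_signatures <- function(gc, groove_sig) {
  gc_hit <- groove_hit <- character(0)
  for (topo in TOPOLOGIES) {
    main <- MAIN_GC_FIRST_TETRAD[[topo]]
    flip <- chartr("sa", "as", main)
    expected_gc <- c(main, rep(flip, max(0, length(gc) - 1)))
    if (length(gc) && all(gc == expected_gc[seq_along(gc)] |
                          gc == main | gc == flip)) {
      gc_hit <- c(gc_hit, topo)
    }
    pat <- names(TOPOLOGY_BY_PATTERN)[TOPOLOGY_BY_PATTERN == topo]
    dirs <- strsplit(pat, "")[[1]]
    exp_groove <- paste(vapply(1:4, function(k) {
      k2 <- if (k == 4) 1L else k + 1L
      if (dirs[k] == "d" && dirs[k2] == "u") "w"
      else if (dirs[k] == "u" && dirs[k2] == "d") "n" else "i"
    }, character(1)), collapse = "")
    if (!is.null(groove_sig) && groove_sig == exp_groove) {
      groove_hit <- c(groove_hit, topo)
    }
  }
  both <- intersect(gc_hit, groove_hit)
  if (length(both) == 1) {
    list(topology = both, confidence = "both")
  } else if (length(groove_hit) == 1) {
    list(topology = groove_hit, confidence = "signature")
  } else if (length(gc_hit) == 1) {
    list(topology = gc_hit, confidence = "pattern")
  } else {
    list(topology = "undetermined", confidence = "none")
  }
}
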