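#' Geometric constants of the G4 stem model
#'
#' Returns the default constants used throughout the geometric model:
#' the mean distance between successive C5' atoms along a chain, the mean
#' rise of guanines in the stem, the mean distance between two diagonal C5'
#' atoms of a tetrad, and the reference stem heights of 3- and 4-tetrad
#' parallel structures. All values are in Angstrom. Any constant can be
#' overridden, e.g. `g4_constants(mean_c5_step = 6.5)`; derived quantities
#' (the diagonal-loop feasibility threshold) propagate consistently.
#'
#' @param mean_c5_step mean successive C5'-C5' distance (default 6.25)
#' @param mean_rise mean guanine rise in the stem (default 3.42)
#' @param diagonal_c5 mean distance between diagonal C5' atoms (default 21.0)
#' @param height_3tetrad reference 3-tetrad parallel stem height (default 12)
#' @param height_4tetrad reference 4-tetrad parallel stem height (default 18)
#' @return a named list of class `g4_constants`
#' @export
#' @examples
#' g4_constants()$mean_c5_step  # 6.25
g4_constants <- function(mean_c5_step = 6.25,
                         mean_rise = 3.42,
                         diagonal_c5 = 21.0,
                         height_3tetrad = 12,
                         height_4tetrad = 18) {
  stopifnot(mean_c5_step > 0, mean_rise > 0, diagonal_c5 > 0,
            height_3tetrad > 0, height_4tetrad > 0)
  structure(list(mean_c5_step = mean_c5_step,
                 mean_rise = mean_rise,
                 diagonal_c5 = diagonal_c5,
                 height_3tetrad = height_3tetrad,
                 height_4tetrad = height_4tetrad),
            class = "g4_constants")
}

# The eight one-block topologies keyed by strand-direction pattern
# (strand 1 is always down; strands numbered clockwise seen from the top).
TOPOLOGY_BY_PATTERN <- c(
  dddd = "parallel",
  dudu = "antiparallel-chair",
  duud = "antiparallel-basket",
  dduu = "antiparallel-basket2",
  ddud = "hybrid1",
  dddu = "hybrid2",
  dudd = "hybrid3",
  duuu = "hybrid4"
)

TOPOLOGIES <- unname(TOPOLOGY_BY_PATTERN)

# Main glycosidic-configuration letters per tetrad column (per strand,
# clockwise), implied by the strand directions: anti on down strands and syn
# on up strands in the top tetrad, with the s/a letters swapping in the
# remaining tetrads of antiparallel columns handled by the generator. The
# per-strand first-tetrad pattern below is the canonical "main" pattern with
# a syn-G wherever the neighbouring strand runs the other way.
MAIN_GC_FIRST_TETRAD <- c(
  parallel = "aaaa",
  `antiparallel-chair` = "sasa",
  `antiparallel-basket` = "saas",
  `antiparallel-basket2` = "ssaa",
  hybrid1 = "ssas",
  hybrid2 = "sssa",
  hybrid3 = "sass",
  hybrid4 = "saaa"
)

# Groove-width letter thresholds (Angstrom): wide >= 16, narrow <= 11.5,
# otherwise intermediate/medium.
GROOVE_WIDE_MIN <- 16
GROOVE_NARROW_MAX <- 11.5

groove_letter_from_width <- function(w) {
  if (is.na(w)) return("?")
  if (w >= GROOVE_WIDE_MIN) "w" else if (w <= GROOVE_NARROW_MAX) "n" else "i"
}
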