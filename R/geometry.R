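# Quantitative geometric model of the G4 stem: C5' spacing statistics,
# loop spans, diagonal-loop feasibility, stem height, rise/twist and
# tetrad planarity.

#' Distances between successive C5' atoms
#'
#' One Euclidean distance per pair of consecutive residues of the same
#' chain with both C5' atoms present. Pairs missing a C5' atom are skipped
#' and counted.
#'
#' @param model a `g4_model`
#' @return list with `distances` (numeric vector), `mean`, `n_pairs`,
#'   `n_skipped`
#' @export
successive_c5_distances <- function(model) {
  res <- model$residues
  d <- numeric(0); skipped <- 0L
  for (ch in unique(res$chain)) {
    uids <- res$uid[res$chain == ch]
    if (length(uids) < 2) next
    for (k in seq_len(length(uids) - 1L)) {
      a <- atom_xyz(model, uids[k], "C5'")
      b <- atom_xyz(model, uids[k + 1L], "C5'")
      if (is.null(a) || is.null(b)) skipped <- skipped + 1L
      else d <- c(d, vnorm(b - a))
    }
  }
  if (length(d) == 0) warning("no successive C5' pairs found")
  list(distances = d,
       mean = if (length(d)) mean(d) else NA_real_,
       n_pairs = length(d), n_skipped = skipped)
}

#' Modeled end-to-end span of an n-nucleotide loop
#'
#' A loop of `n` nucleotides bridges `n + 1` successive C5'-C5' steps
#' between the guanosine preceding it and the one following it, so its
#' modeled span is `(n + 1) * mean_c5_step`.
#'
#' @param n_nts number of nucleotides in the loop (>= 0)
#' @param constants a [g4_constants()] list
#' @return span in Angstrom
#' @export
#' @examples
#' loop_span_model(1)  # 12.5
#' loop_span_model(2)  # 18.75
loop_span_model <- function(n_nts, constants = g4_constants()) {
  if (any(n_nts < 0)) stop("loop length must be >= 0")
  (n_nts + 1) * constants$mean_c5_step
}

#' Geometric feasibility of a diagonal loop
#'
#' A diagonal loop must bridge the diagonal C5'-C5' separation of the
#' tetrad while clearing the tetrad plane by one guanine rise at each end,
#' giving the threshold `diagonal_c5 + 2 * mean_rise` (27.84 A under the
#' defaults, ~28 A). The loop is feasible when its modeled span
#' ([loop_span_model()]) reaches the threshold: 3 nts model to 25 A and
#' are infeasible, 4 nts exceed 31 A and are feasible.
#'
#' @param n_nts number of nucleotides in the diagonal loop
#' @param constants a [g4_constants()] list
#' @return list with `feasible` (logical), `modeled_length`, `threshold`
#' @export
diagonal_feasibility <- function(n_nts, constants = g4_constants()) {
  if (any(n_nts < 0)) stop("loop length must be >= 0")
  len <- loop_span_model(n_nts, constants)
  thr <- constants$diagonal_c5 + 2 * constants$mean_rise
  list(feasible = len >= thr, modeled_length = len, threshold = thr)
}

#' Stem height between the extreme tetrads
#'
#' Mean, over the four strand columns, of the C5'-C5' distance between the
#' guanines of the top and bottom tetrads. A single-tetrad stem has height
#' zero. Columns with a missing C5' atom are dropped with a warning.
#'
#' @param stem a `g4_stem`
#' @param model the `g4_model` the stem was assembled from
#' @return height in Angstrom
#' @export
stem_height <- function(stem, model) {
  if (stem$n_tetrads < 2) return(0)
  hs <- numeric(0)
  for (col in stem$columns) {
    g <- col$guanines
    top <- g$uid[g$tetrad == 1]
    bot <- g$uid[g$tetrad == stem$n_tetrads]
    if (length(top) != 1 || length(bot) != 1) next
    a <- atom_xyz(model, top, "C5'")
    b <- atom_xyz(model, bot, "C5'")
    if (is.null(a) || is.null(b)) next
    hs <- c(hs, vnorm(b - a))
  }
  if (length(hs) < 4) warning("stem height computed over ", length(hs),
                              " of 4 strands (missing atoms)")
  if (length(hs) == 0) return(NA_real_)
  mean(hs)
}

#' Per-step rise and signed twist of the stem
#'
#' Rise is the axial separation of consecutive tetrad centroids along the
#' top-to-bottom stem axis. Twist is the mean signed angular advance of the
#' stacked guanines about that axis, positive for right-handed stems
#' (+30 degrees per step in canonical structures).
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @return list with numeric vectors `rise` and `twist` (one entry per
#'   tetrad step; empty for a single tetrad)
#' @export
rise_and_twist <- function(stem, model) {
  n <- stem$n_tetrads
  if (n < 2) return(list(rise = numeric(0), twist = numeric(0)))
  frame <- stem$frame
  ctr <- t(vapply(stem$tetrads, `[[`, numeric(3), "centroid"))
  rise <- vapply(seq_len(n - 1L), function(t)
    abs(vdot(ctr[t + 1L, ] - ctr[t, ], frame$u)), numeric(1))
  twist <- vapply(seq_len(n - 1L), function(t) {
    steps <- numeric(0)
    for (col in stem$columns) {
      g <- col$guanines
      a <- g$uid[g$tetrad == t]; b <- g$uid[g$tetrad == t + 1L]
      if (length(a) != 1 || length(b) != 1) next
      ca <- base_centroid(model, a); cb <- base_centroid(model, b)
      if (is.null(ca) || is.null(cb)) next
      pa <- azimuth_about(ca, ctr[t, ], frame)
      pb <- azimuth_about(cb, ctr[t + 1L, ], frame)
      steps <- c(steps, angle_diff(pa, pb))
    }
    if (length(steps)) mean(steps) else NA_real_
  }, numeric(1))
  list(rise = rise, twist = twist)
}

#' RMS deviation of a tetrad from its best-fit plane
#'
#' Least-squares plane through the base ring atoms of the four guanines;
#' returns the root-mean-square out-of-plane deviation.
#'
#' @param tetrad a `g4_tetrad`
#' @param model the source `g4_model`
#' @return RMS deviation in Angstrom
#' @export
tetrad_planarity <- function(tetrad, model) {
  ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  pts <- NULL
  for (uid in tetrad$guanines$uid) {
    m <- residue_xyz(model, uid)
    pts <- rbind(pts, m[rownames(m) %in% ring, , drop = FALSE])
  }
  fit_plane(pts)$rms
}
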