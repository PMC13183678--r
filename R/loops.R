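# Loop taxonomy: propeller / lateral / diagonal / internal connectors,
# progression signs, the loop-combination string, 0-nt loop licensing,
# V-shaped strands and stem-extremity sides.

strand_of_uid <- function(stem, uid) {
  for (col in stem$columns) {
    hit <- col$guanines$tetrad[col$guanines$uid == uid]
    if (length(hit)) return(list(strand = col$number, tetrad = hit))
  }
  NULL
}

# strand-pair relation on the clockwise square
strand_relation <- function(a, b) {
  if (a == b) return("same")
  d <- (b - a) %% 4
  if (d == 2) "opposite" else "adjacent"
}

# progression: + when the strand transition is clockwise viewed from the
# bottom (i.e. anticlockwise in the top-view numbering: k -> k-1)
progression_sign <- function(from, to) {
  d <- (to - from) %% 4
  if (d == 1) "-" else if (d == 3) "+" else "none"
}

#' Classify the loops of an assembled stem
#'
#' Walks the stem guanines in chain order; every connector between two
#' consecutive stem guanines that is not a vertical strand step (or
#' bulged strand step) is a loop. Kinds follow the broadened taxonomy:
#' propeller (adjacent strands, different tetrads), lateral (adjacent
#' strands, same tetrad), diagonal (opposite strands, same tetrad),
#' internal (same strand bottom to top, or a connector crossing blocks).
#' Loop length counts the non-stem nucleotides between the anchors
#' (guanines of a G-tract that are not in the stem count as loop
#' nucleotides). Progression is + when the transition is clockwise viewed
#' from the bottom; diagonal and internal loops carry no sign. Loops
#' attaching a 5'/3' snapback segment are marked and bracketed in the
#' combination string.
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @param discontinuities optional output of [detect_discontinuities()]
#'   (recomputed when missing), used for block joins and snapback marking
#' @return list with `loops` (list of loop records) and `combination`
#'   (the rendered string, e.g. `"-p-p-p"`)
#' @export
classify_loops <- function(stem, model, discontinuities = NULL) {
  if (stem$degenerate) return(list(loops = list(), combination = ""))
  if (is.null(discontinuities)) {
    discontinuities <- detect_discontinuities(stem, model)
  }
  blocks <- discontinuities$blocks
  block_of <- function(tet) {
    for (bi in seq_along(blocks)) {
      if (tet >= blocks[[bi]][1] && tet <= blocks[[bi]][2]) return(bi)
    }
    NA_integer_
  }
  snaps <- Filter(function(d) d$kind == "snapback",
                  discontinuities$discontinuities)
  has_5p_snap <- any(vapply(snaps, function(d)
    startsWith(d$snapback_type, "5'"), logical(1)))
  has_3p_snap <- any(vapply(snaps, function(d)
    startsWith(d$snapback_type, "3'"), logical(1)))

  allu <- stem$stem_uids
  pos <- chain_position(model, allu)
  ord <- order(pos)
  uids <- allu[ord]; pos <- pos[ord]

  loops <- list()
  for (i in seq_len(length(uids) - 1L)) {
    a <- strand_of_uid(stem, uids[i])
    b <- strand_of_uid(stem, uids[i + 1L])
    n_between <- pos[i + 1L] - pos[i] - 1L
    rel <- strand_relation(a$strand, b$strand)
    vertical <- rel == "same" && abs(b$tetrad - a$tetrad) == 1
    if (vertical) next  # strand step (bulges handled elsewhere)
    cross_block <- length(blocks) > 1 &&
      !is.na(block_of(a$tetrad)) && !is.na(block_of(b$tetrad)) &&
      block_of(a$tetrad) != block_of(b$tetrad)
    kind <- if (cross_block || rel == "same") "i"
      else if (rel == "adjacent" && a$tetrad != b$tetrad) "p"
      else if (rel == "adjacent") "l"
      else if (rel == "opposite" && a$tetrad == b$tetrad) "d"
      else "d"  # opposite strands, different tetrads: diagonal-like
    prog <- if (kind %in% c("d", "i")) "none"
            else progression_sign(a$strand, b$strand)
    loops[[length(loops) + 1L]] <- list(
      kind = kind, length_nt = n_between, progression = prog,
      from_strand = a$strand, to_strand = b$strand,
      from_tetrad = a$tetrad, to_tetrad = b$tetrad,
      is_snapback_loop = FALSE)
  }
  if (length(loops)) {
    if (has_5p_snap) loops[[1]]$is_snapback_loop <- TRUE
    if (has_3p_snap) loops[[length(loops)]]$is_snapback_loop <- TRUE
  }
  list(loops = loops, combination = render_loop_combination(loops))
}

#' Render a loop list as a combination string
#'
#' Signs precede the kind letter (`-p`, `+l`); diagonal and internal
#' loops are bare (`d`, `i`); snapback loops are bracketed (`[-l]`)
#' because the italics convention does not survive plain text.
#'
#' @param loops list of loop records (see [classify_loops()])
#' @return a single string
#' @export
render_loop_combination <- function(loops) {
  paste(vapply(loops, function(lp) {
    s <- if (lp$progression %in% c("+", "-")) lp$progression else ""
    tok <- paste0(s, lp$kind)
    if (isTRUE(lp$is_snapback_loop)) paste0("[", tok, "]") else tok
  }, character(1)), collapse = "")
}

#' Parse a loop-combination string back into tokens
#'
#' Inverse of [render_loop_combination()] at the token level: returns
#' kind, progression and snapback marking per loop.
#'
#' @param text a combination string, e.g. `"-ld+l"` or `"[-l]+l+p+p"`
#' @return list of records with `kind`, `progression`, `is_snapback_loop`
#' @export
parse_loop_combination <- function(text) {
  out <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    snap <- FALSE
    ch <- substr(text, i, i)
    if (ch == "[") { snap <- TRUE; i <- i + 1L; ch <- substr(text, i, i) }
    prog <- "none"
    if (ch %in% c("+", "-")) {
      prog <- ch; i <- i + 1L; ch <- substr(text, i, i)
    }
    if (!ch %in% c("p", "l", "d", "i")) {
      stop("cannot parse loop combination at position ", i, ": ", text)
    }
    kind <- ch; i <- i + 1L
    if (snap) {
      if (substr(text, i, i) != "]") stop("unclosed snapback bracket")
      i <- i + 1L
    }
    out[[length(out) + 1L]] <- list(kind = kind, progression = prog,
                                    is_snapback_loop = snap)
  }
  out
}

#' 0-nt loops with their licensing discontinuities
#'
#' A 0-nt loop (a single phosphate group) is always propeller and only
#' occurs when a discontinuity (snapback, bulge or block break) precedes
#' one of the two guanines it connects. Each returned record carries the
#' licensing discontinuity; a 0-nt loop with no adjacent discontinuity
#' gets a consistency warning.
#'
#' @param loops loop list from [classify_loops()]
#' @param stem a `g4_stem`
#' @param discontinuities output of [detect_discontinuities()]
#' @return list of records with `loop`, `licensed_by` (or NULL),
#'   `warning` (or NULL)
#' @export
zero_nt_loops <- function(loops, stem, discontinuities) {
  zl <- Filter(function(lp) lp$length_nt == 0, loops)
  lapply(zl, function(lp) {
    warn <- NULL
    if (lp$kind != "p") {
      warn <- paste0("0-nt loop between strands ", lp$from_strand, " and ",
                     lp$to_strand, " is not propeller")
    }
    lic <- Filter(function(d)
      d$strand_number %in% c(lp$from_strand, lp$to_strand),
      discontinuities$discontinuities)
    if (length(lic) == 0) {
      warn <- c(warn, paste0("0-nt loop between strands ", lp$from_strand,
        " and ", lp$to_strand, " has no licensing discontinuity"))
      lic <- NULL
    }
    list(loop = lp, licensed_by = if (is.null(lic)) NULL else lic[[1]],
         warning = warn)
  })
}

#' Strands whose backbone forms a V shape
#'
#' Flags each strand that immediately follows a 0-nt loop and whose
#' backbone phosphorus path turns through the stem: the angle at the
#' middle of three successive P atoms of the strand is below
#' `angle_cutoff` degrees.
#'
#' @param stem a `g4_stem`
#' @param loops loop list from [classify_loops()]
#' @param model the source `g4_model`
#' @param angle_cutoff maximum P-P-P angle (deg) still called a V;
#'   the default separates V-shaped strands (~130 deg) from straight
#'   helical strand paths (> 150 deg)
#' @return integer vector of strand numbers
#' @export
v_shaped_strands <- function(stem, loops, model, angle_cutoff = 140) {
  hits <- integer(0)
  for (lp in loops) {
    if (lp$length_nt != 0) next
    col <- stem$columns[[lp$to_strand]]
    cl <- col$guanines[order(col$guanines$chain_pos), ]
    ps <- list()
    for (uid in cl$uid) {
      p <- atom_xyz(model, uid, "P")
      if (!is.null(p)) ps[[length(ps) + 1L]] <- p
    }
    if (length(ps) < 3) next
    for (k in seq_len(length(ps) - 2L)) {
      v1 <- ps[[k]] - ps[[k + 1L]]
      v2 <- ps[[k + 2L]] - ps[[k + 1L]]
      ang <- rad2deg(acos(max(-1, min(1,
        vdot(v1, v2) / (vnorm(v1) * vnorm(v2))))))
      if (ang < angle_cutoff) {
        hits <- c(hits, lp$to_strand)
        break
      }
    }
  }
  sort(unique(hits))
}

#' Relative side of the 5' and 3' stem extremities
#'
#' `same` when the first and last stem guanines lie in the same extreme
#' tetrad; `opposite` when they lie in the two extreme tetrads; `middle`
#' when either lies in a non-extreme tetrad.
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @return `"same"`, `"opposite"` or `"middle"`
#' @export
extremity_sides <- function(stem, model) {
  if (stem$degenerate) stop("extremity sides undefined: degenerate stem")
  allu <- stem$stem_uids
  pos <- chain_position(model, allu)
  t_first <- strand_of_uid(stem, allu[which.min(pos)])$tetrad
  t_last <- strand_of_uid(stem, allu[which.max(pos)])$tetrad
  n <- stem$n_tetrads
  extreme <- c(1L, n)
  if (!(t_first %in% extreme) || !(t_last %in% extreme)) return("middle")
  if (t_first == t_last) "same" else "opposite"
}
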