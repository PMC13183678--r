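# G-tetrad detection from Hoogsteen hydrogen-bond geometry, stem assembly
# (tetrad order, strand columns, clockwise numbering) and discontinuity
# detection (bulges, snapbacks, block breaks).

guanine_uids <- function(model) {
  r <- model$residues
  r$uid[r$parent_base == "G"]
}

# Directed Hoogsteen edge scores between guanines: donor i (N1, N2) to
# acceptor j (O6, N7). Returns a data frame of candidate edges with the
# mean donor-acceptor distance.
hoogsteen_edges <- function(model, guas, cutoff) {
  get <- function(uid, atom) atom_xyz(model, uid, atom)
  edges <- list()
  for (i in guas) {
    n1 <- get(i, "N1"); n2 <- get(i, "N2")
    if (is.null(n1) || is.null(n2)) next
    for (j in guas) {
      if (i == j) next
      o6 <- get(j, "O6"); n7 <- get(j, "N7")
      if (is.null(o6) || is.null(n7)) next
      d1 <- vnorm(n1 - o6); d2 <- vnorm(n2 - n7)
      dm <- (d1 + d2) / 2
      if (dm <= cutoff + 0.75) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = i, to = j, d1 = d1, d2 = d2, dmean = dm,
          strong = dm <= cutoff, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0) return(NULL)
  do.call(rbind, edges)
}

#' Detect G-tetrads from Hoogsteen geometry
#'
#' A G-tetrad is a closed cycle of four guanines in which each guanine's
#' N1 and N2 donate to the next guanine's O6 and N7. Candidate directed
#' pairs are collected with mean donor-acceptor distance up to
#' `hbond_cutoff + 0.75` A; a 4-cycle is accepted when at least three of
#' its four pairs meet the strict cutoff (or all four meet
#' `hbond_cutoff + 0.5`), tolerating deposited-structure distortion.
#' Accepted tetrads are mutually disjoint (best-scoring first) and are
#' ordered by stacking position along the mean helical axis; tetrad 1 is
#' the top (5'-side) tetrad. Tetrads exceeding `planarity_tol` RMS from
#' their best-fit base plane are flagged, not rejected.
#'
#' @param model a `g4_model`
#' @param hbond_cutoff mean donor-acceptor distance cutoff in A
#' @param planarity_tol flag threshold for the tetrad planarity RMS (A)
#' @return list of `g4_tetrad` objects (empty when no closed cycle
#'   exists); each has `guanines` (data frame in Hoogsteen cycle order),
#'   `tetrad_index`, `centroid`, `normal`, `planarity_rms`, `flags`
#' @export
detect_tetrads <- function(model, hbond_cutoff = 3.5, planarity_tol = 0.5) {
  guas <- guanine_uids(model)
  if (length(guas) < 4) return(list())
  edges <- hoogsteen_edges(model, guas, hbond_cutoff)
  if (is.null(edges)) return(list())

  nbr <- split(seq_len(nrow(edges)), edges$from)
  cycles <- list()
  # enumerate directed 4-cycles a -> b -> c -> d -> a
  for (ia in seq_len(nrow(edges))) {
    a <- edges$from[ia]; b <- edges$to[ia]
    for (ib in nbr[[b]] %||% integer(0)) {
      c_ <- edges$to[ib]
      if (c_ == a) next
      for (ic in nbr[[c_]] %||% integer(0)) {
        d <- edges$to[ic]
        if (d %in% c(a, b)) next
        for (id in nbr[[d]] %||% integer(0)) {
          if (edges$to[id] != a) next
          eidx <- c(ia, ib, ic, id)
          n_strong <- sum(edges$strong[eidx])
          all_close <- all(edges$dmean[eidx] <= hbond_cutoff + 0.5)
          if (n_strong >= 3 || all_close) {
            members <- c(a, b, c_, d)
            if (members[1] != min(members)) next  # canonical rotation only
            cycles[[length(cycles) + 1L]] <- list(
              members = members, score = sum(edges$dmean[eidx]),
              n_strong = n_strong)
          }
        }
      }
    }
  }
  if (length(cycles) == 0) return(list())
  ord <- order(vapply(cycles, function(cy) cy$score, numeric(1)) -
                 vapply(cycles, function(cy) cy$n_strong, numeric(1)))
  used <- character(0); picked <- list()
  for (cy in cycles[ord]) {
    if (any(cy$members %in% used)) next
    picked[[length(picked) + 1L]] <- cy
    used <- c(used, cy$members)
  }

  tets <- lapply(picked, function(cy) {
    ctrs <- t(vapply(cy$members, function(u) base_centroid(model, u),
                     numeric(3)))
    ring <- NULL
    for (u in cy$members) {
      m <- residue_xyz(model, u)
      ring <- rbind(ring, m[rownames(m) %in%
        c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"), ,
        drop = FALSE])
    }
    pl <- fit_plane(ring)
    flags <- character(0)
    if (pl$rms > planarity_tol) flags <- "non-planar"
    if (cy$n_strong < 4) flags <- c(flags, "weak-hbond")
    list(guanines = data.frame(uid = cy$members, stringsAsFactors = FALSE),
         centroid = colMeans(ctrs), normal = pl$normal,
         planarity_rms = pl$rms, flags = flags)
  })

  # stacking order along the principal axis of the tetrad centroids
  ctr <- t(vapply(tets, `[[`, numeric(3), "centroid"))
  axis <- if (nrow(ctr) >= 2) principal_axis(ctr) else c(0, 0, 1)
  proj <- as.numeric(ctr %*% axis)
  ord2 <- order(proj)
  tets <- tets[ord2]

  # orient top -> bottom such that the chain's initial stem segment runs
  # downward (the first strand direction is down by convention)
  if (length(tets) >= 2) {
    pos_of <- function(t) min(chain_position(model, tets[[t]]$guanines$uid))
    first_pos <- vapply(seq_along(tets), pos_of, numeric(1))
    g0_t <- which.min(first_pos)                 # tetrad of the 5'-most G
    g0 <- tets[[g0_t]]$guanines$uid[
      which.min(chain_position(model, tets[[g0_t]]$guanines$uid))]
    # the stem guanine next in chain after g0 (its tract continues there)
    all_uids <- unlist(lapply(tets, function(t) t$guanines$uid))
    pos_all <- chain_position(model, all_uids)
    g0_pos <- chain_position(model, g0)
    nxt <- all_uids[pos_all == g0_pos + 1L]
    flip <- if (length(nxt) == 1) {
      t_next <- which(vapply(tets, function(t) nxt %in% t$guanines$uid,
                             logical(1)))
      t_next < g0_t  # chain start runs toward lower index: flip
    } else {
      g0_t > (length(tets) + 1) / 2  # fallback: put the 5' G near the top
    }
    if (flip) tets <- rev(tets)
  }
  for (t in seq_along(tets)) {
    tets[[t]]$tetrad_index <- t
    tets[[t]] <- structure(tets[[t]], class = "g4_tetrad")
  }
  tets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the stem from detected tetrads
#'
#' Builds the four strand columns by vertical stacking adjacency between
#' consecutive tetrads (minimal base-centroid distance, rise bounded in
#' \[2, 6\] A), numbers the strands clockwise when the stem is viewed from
#' the top along its axis (strand 1 is the column holding the 5'-most stem
#' guanine, and always runs down), and assigns each column's direction
#' from its chain progression. A single tetrad yields a degenerate stem
#' with undefined directions.
#'
#' @param tetrads output of [detect_tetrads()]
#' @param model the source `g4_model`
#' @return a `g4_stem`: list with `tetrads`, `n_tetrads`, `columns` (four,
#'   in strand order), `frame` (top-to-bottom axis frame), `degenerate`
#' @export
assemble_stem <- function(tetrads, model) {
  n <- length(tetrads)
  if (n == 0) stop("no tetrads to assemble")
  ctr <- t(vapply(tetrads, `[[`, numeric(3), "centroid"))
  if (n == 1) {
    frame <- axis_frame(tetrads[[1]]$normal)
    stem <- list(tetrads = tetrads, n_tetrads = 1L, columns = list(),
                 frame = frame, origin = ctr[1, ], degenerate = TRUE)
    class(stem) <- "g4_stem"
    return(stem)
  }
  axis_raw <- principal_axis(ctr)
  proj <- as.numeric(ctr %*% axis_raw)
  # orient the axis top (tetrad 1) -> bottom (tetrad n)
  u <- if (proj[n] > proj[1]) axis_raw else -axis_raw
  frame <- axis_frame(u)

  # stacking adjacency: match guanines of tetrad t+1 to tetrad t
  cols <- lapply(tetrads[[1]]$guanines$uid, function(uu)
    data.frame(uid = uu, tetrad = 1L, stringsAsFactors = FALSE))
  for (t in seq_len(n - 1L)) {
    cur <- vapply(cols, function(cl) cl$uid[cl$tetrad == t], character(1))
    nxtu <- tetrads[[t + 1L]]$guanines$uid
    cc <- t(vapply(cur, function(uu) base_centroid(model, uu), numeric(3)))
    nc <- t(vapply(nxtu, function(uu) base_centroid(model, uu), numeric(3)))
    dmat <- outer(seq_along(cur), seq_along(nxtu), Vectorize(function(i, j)
      vnorm(cc[i, ] - nc[j, ])))
    # greedy bijective assignment by increasing distance
    assign <- rep(NA_integer_, 4)
    dd <- dmat
    for (k in 1:4) {
      ij <- arrayInd(which.min(dd), dim(dd))
      assign[ij[1]] <- ij[2]
      dd[ij[1], ] <- Inf; dd[, ij[2]] <- Inf
    }
    dsel <- dmat[cbind(1:4, assign)]
    if (any(dsel < 2.0) || any(dsel > 6.5)) {
      stop("ambiguous guanine stacking between tetrads ", t, " and ",
           t + 1L, " (pair distances ",
           paste(sprintf("%.2f", dsel), collapse = ", "), " A)")
    }
    for (k in 1:4) {
      cols[[k]] <- rbind(cols[[k]],
        data.frame(uid = nxtu[assign[k]], tetrad = t + 1L,
                   stringsAsFactors = FALSE))
    }
  }

  # clockwise numbering from the top; strand 1 holds the 5'-most stem G
  az <- vapply(cols, function(cl) {
    azimuth_about(base_centroid(model, cl$uid[1]), ctr[1, ], frame)
  }, numeric(1))
  allu <- unlist(lapply(cols, `[[`, "uid"))
  pos <- chain_position(model, allu)
  first_uid <- allu[which.min(pos)]
  s1 <- which(vapply(cols, function(cl) first_uid %in% cl$uid, logical(1)))
  rel <- (az - az[s1]) %% 360
  ord <- order(rel)
  stopifnot(ord[1] == s1)
  cols <- cols[ord]

  columns <- lapply(seq_along(cols), function(k) {
    cl <- cols[[k]]
    cl$chain_pos <- chain_position(model, cl$uid)
    # direction from chain-contiguous vertical steps (bulges allowed)
    steps <- integer(0); contiguous <- TRUE
    for (t in seq_len(nrow(cl) - 1L)) {
      dpos <- cl$chain_pos[t + 1L] - cl$chain_pos[t]
      if (abs(dpos) == 1) steps <- c(steps, sign(dpos))
      else if (dpos != 0) {
        # allow short bulges: intervening residues all non-stem
        lo <- min(cl$chain_pos[t], cl$chain_pos[t + 1L])
        hi <- max(cl$chain_pos[t], cl$chain_pos[t + 1L])
        between <- model$residues$uid[(lo + 1):(hi - 1)]
        if (hi - lo <= 4 && !any(between %in% allu)) {
          steps <- c(steps, sign(dpos))
          contiguous <- FALSE
        } else contiguous <- FALSE
      }
    }
    dir <- if (length(steps) == 0) NA_character_
           else if (sum(steps) > 0) "d"
           else if (sum(steps) < 0) "u" else NA_character_
    if (is.na(dir)) {
      # fallback: overall trend of tetrad index with chain position
      sl <- stats::coef(stats::lm(cl$tetrad ~ cl$chain_pos))[2]
      dir <- if (!is.na(sl) && sl < 0) "u" else "d"
    }
    list(number = k, direction = dir, guanines = cl,
         continuous = contiguous &&
           all(abs(diff(cl$chain_pos)) == 1))
  })

  stem <- list(tetrads = tetrads, n_tetrads = n, columns = columns,
               frame = frame, origin = ctr[1, ], degenerate = FALSE)
  stem$stem_uids <- unlist(lapply(columns, function(cl) cl$guanines$uid))
  class(stem) <- "g4_stem"
  stem
}

#' Detect bulges, snapbacks and block breaks in an assembled stem
#'
#' Walks every vertical step of every strand column: a step whose two
#' guanines are chain-consecutive is continuous; a step bridged only by
#' non-stem nucleotides is a bulge (with its inserted nucleotide count); a
#' step whose guanines come from distant chain segments is a break. When
#' at least three columns break between the same two tetrads the stem is
#' split into two blocks there; remaining breaks are snapbacks, typed by
#' the chain end (5'/3') of the folded-back segment and by the extreme
#' tetrad it reaches (top/bottom).
#'
#' @param stem a `g4_stem`
#' @param model the source `g4_model`
#' @return list with `discontinuities` (list of records with `kind`,
#'   `strand_number`, `between_tetrads`, `inserted_nts`, `snapback_type`)
#'   and `blocks` (list of tetrad-index ranges)
#' @export
detect_discontinuities <- function(stem, model) {
  if (stem$degenerate) {
    return(list(discontinuities = list(),
                blocks = list(c(1L, stem$n_tetrads))))
  }
  allu <- stem$stem_uids
  disc <- list()
  breaks_at <- integer(0)
  for (col in stem$columns) {
    cl <- col$guanines
    for (t in seq_len(nrow(cl) - 1L)) {
      p1 <- cl$chain_pos[t]; p2 <- cl$chain_pos[t + 1L]
      lo <- min(p1, p2); hi <- max(p1, p2)
      if (hi - lo == 1) next
      between <- model$residues$uid[(lo + 1):(hi - 1)]
      if (!any(between %in% allu)) {
        disc[[length(disc) + 1L]] <- list(
          kind = "bulge", strand_number = col$number,
          between_tetrads = c(t, t + 1L), inserted_nts = hi - lo - 1L,
          snapback_type = "none")
      } else {
        disc[[length(disc) + 1L]] <- list(
          kind = "break", strand_number = col$number,
          between_tetrads = c(t, t + 1L), inserted_nts = 0L,
          snapback_type = "none")
        breaks_at <- c(breaks_at, t)
      }
    }
  }

  # two-block rule: >= 3 breaks between the same two tetrads
  blocks <- list(c(1L, stem$n_tetrads))
  junction <- NULL
  if (length(breaks_at)) {
    tab <- table(breaks_at)
    big <- as.integer(names(tab)[tab >= 3])
    if (length(big)) {
      junction <- big[1]
      blocks <- list(c(1L, junction), c(junction + 1L, stem$n_tetrads))
    }
  }

  # classify remaining breaks as snapbacks or block breaks
  pos_all <- chain_position(model, allu)
  first_stem <- allu[which.min(pos_all)]
  last_stem <- allu[which.max(pos_all)]
  for (i in seq_along(disc)) {
    d <- disc[[i]]
    if (d$kind != "break") next
    if (!is.null(junction) && d$between_tetrads[1] == junction) {
      disc[[i]]$kind <- "block-break"
      next
    }
    disc[[i]]$kind <- "snapback"
    col <- stem$columns[[d$strand_number]]
    cl <- col$guanines[order(col$guanines$chain_pos), ]
    # split the column into chain-contiguous segments (allowing bulges)
    seg_id <- cumsum(c(1, diff(cl$chain_pos) > 4))
    segs <- split(cl, seg_id)
    which_seg <- NULL; end <- NULL
    for (sg in segs) {
      if (first_stem %in% sg$uid) { which_seg <- sg; end <- "5'" }
    }
    if (is.null(which_seg)) {
      for (sg in segs) if (last_stem %in% sg$uid) {
        which_seg <- sg; end <- "3'"
      }
    }
    if (is.null(which_seg)) {
      # folded segment not at a chain end: type by the shorter segment
      lens <- vapply(segs, nrow, integer(1))
      which_seg <- segs[[which.min(lens)]]
      end <- "5'"
    }
    reach <- if (stem$n_tetrads %in% which_seg$tetrad) "bottom"
             else if (1L %in% which_seg$tetrad) "top"
             else "bottom"
    disc[[i]]$snapback_type <- paste0(end, "-", reach)
  }
  list(discontinuities = disc, blocks = blocks)
}
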