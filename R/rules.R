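# Rule engine: loop-length constraints on G4 topology, with rule
# provenance. The rules encode observed regularities in the deposited
# one-block structures; they are constraints, not a predictor.

#' Build a loop-length rule query
#'
#' @param L1,L2,L3 loop lengths in nucleotides (>= 0); true loop lengths,
#'   not inter-G-tract spacer lengths
#' @param has_modified_guanines TRUE when stem guanines carry modifications
#'   (e.g. 8-bromo-G) that can force a syn configuration
#' @param has_ligand TRUE when a bound ligand may strain the fold
#' @param chain_nature `"DNA"` or `"RNA"`
#' @param n_tetrads_hint optional known tetrad count
#' @return object of class `g4_rule_query`
#' @export
rule_query <- function(L1, L2, L3, has_modified_guanines = FALSE,
                       has_ligand = FALSE, chain_nature = "DNA",
                       n_tetrads_hint = NA_integer_) {
  stopifnot(L1 >= 0, L2 >= 0, L3 >= 0,
            chain_nature %in% c("DNA", "RNA"))
  structure(list(L1 = as.integer(L1), L2 = as.integer(L2),
                 L3 = as.integer(L3),
                 has_modified_guanines = isTRUE(has_modified_guanines),
                 has_ligand = isTRUE(has_ligand),
                 chain_nature = chain_nature,
                 n_tetrads_hint = n_tetrads_hint),
            class = "g4_rule_query")
}

#' Is a loop long enough to fold into a hairpin duplex?
#'
#' The minimum is 10 nucleotides: 3 Watson-Crick base pairs plus 4
#' nucleotides for the hairpin turn.
#'
#' @param loop_length_nt loop length in nucleotides
#' @return logical
#' @export
duplex_capable <- function(loop_length_nt) {
  stopifnot(all(loop_length_nt >= 0))
  loop_length_nt >= 10
}

#' Topologies able to accommodate a (non-snapback) diagonal loop
#'
#' Only antiparallel-basket, antiparallel-basket2 and hybrid2 can; the
#' other five one-block topologies cannot.
#'
#' @param topology a topology name
#' @return logical
#' @export
diagonal_compatible <- function(topology) {
  if (length(topology) != 1) {
    return(vapply(topology, diagonal_compatible, logical(1)))
  }
  if (!topology %in% TOPOLOGIES) stop("unknown topology: ", topology)
  topology %in% c("antiparallel-basket", "antiparallel-basket2", "hybrid2")
}

#' Minimum-length rule for diagonal loops
#'
#' Diagonal loops, even snapback ones, should be at least 4 nucleotides:
#' the modeled span of a 3-nt loop (25 A) falls short of the ~28 A needed
#' to clear a planar tetrad. The only deposited 3-nt diagonal loops (143D
#' and derivatives) have a non-planar first tetrad among other anomalies.
#'
#' @param n_nts diagonal loop length
#' @return list with `pass` (logical) and `note`
#' @export
diagonal_min_length_rule <- function(n_nts) {
  stopifnot(n_nts >= 0)
  if (n_nts <= 3) {
    list(pass = FALSE,
         note = paste0("diagonal loop of ", n_nts, " nt is below the 4-nt ",
                       "minimum; the only deposited 3-nt diagonal loops ",
                       "(143D family) show a non-planar first tetrad and ",
                       "other anomalies"))
  } else {
    list(pass = TRUE, note = "diagonal loop length >= 4 nt")
  }
}

#' Expected side of the 5' and 3' stem extremities for a topology
#'
#' @param topology topology name
#' @param chain_nature `"DNA"` or `"RNA"` (hybrid2/hybrid3 differ by chain)
#' @param has_5p_bottom_snapback does the structure start with a 5'-bottom
#'   snapback (relevant for hybrid4)
#' @return `"same"`, `"opposite"` or `"middle"`
#' @export
predict_extremity_sides <- function(topology, chain_nature = "DNA",
                                    has_5p_bottom_snapback = FALSE) {
  if (!topology %in% TOPOLOGIES) stop("unknown topology: ", topology)
  switch(topology,
    parallel = "opposite",
    `antiparallel-chair` = "same",
    `antiparallel-basket` = "same",
    `antiparallel-basket2` = "same",
    hybrid1 = "opposite",
    hybrid2 = if (chain_nature == "RNA") "same" else "opposite",
    hybrid3 = if (chain_nature == "RNA") "same" else "opposite",
    hybrid4 = if (has_5p_bottom_snapback) "middle" else "same")
}

#' Preferred tetrad count of a topology
#'
#' Parallel and hybrid DNA G4s are mostly 3-tetrad; antiparallel
#' topologies and non-parallel RNA G4s are mostly 2-tetrad.
#'
#' @param topology topology name
#' @param chain_nature `"DNA"` or `"RNA"`
#' @return list with `n_tetrads` (2 or 3) and `rationale`
#' @export
tetrad_count_tendency <- function(topology, chain_nature = "DNA") {
  if (!topology %in% TOPOLOGIES) stop("unknown topology: ", topology)
  anti <- grepl("^antiparallel", topology)
  if (anti || (chain_nature == "RNA" && topology != "parallel")) {
    list(n_tetrads = 2L,
         rationale = paste("antiparallel topologies (and non-parallel RNA",
                           "G4s) are mostly 2-tetrad: the loops H-bond",
                           "below the stem as a proxy third layer, and a",
                           "3-tetrad heteropolar stack would end strands",
                           "with an unfavourable syn-G"))
  } else {
    list(n_tetrads = 3L,
         rationale = paste("parallel and hybrid G4s are mostly 3-tetrad;",
                           "propeller loops cannot stabilize a 2-tetrad",
                           "parallel stem"))
  }
}

#' Loop-length warnings for 4-tetrad stems
#'
#' A 4-tetrad parallel stem is ~18 A tall between the extreme-tetrad C5'
#' atoms; a 1-nt propeller loop models to 12.5 A and cannot bridge it, so
#' 4-tetrad parallel G4s need propeller loops of at least 2 nt.
#'
#' @param n_tetrads tetrad count of the stem
#' @param loop_lengths numeric vector of loop lengths
#' @param constants a [g4_constants()] list
#' @return character vector of warnings (possibly empty)
#' @export
four_tetrad_loop_check <- function(n_tetrads, loop_lengths,
                                   constants = g4_constants()) {
  if (n_tetrads != 4) return(character(0))
  bad <- which(loop_lengths < 2)
  vapply(bad, function(i) {
    paste0("loop ", i, " (", loop_lengths[i], " nt) spans ",
           format(loop_span_model(loop_lengths[i], constants)),
           " A, short of the ~", constants$height_4tetrad,
           " A height of a 4-tetrad stem; 4-tetrad parallel G4s need ",
           ">= 2-nt propeller loops")
  }, character(1))
}

# One matched-rule record.
rule_hit <- function(id, desc) list(id = id, desc = desc)

#' Topologies allowed for a loop-length query
#'
#' Applies, in priority order, the loop-length rules derived from the
#' deposited one-block structures:
#' * R1: two or more 1-nt loops (and no modified-G or ligand strain) force
#'   the parallel topology.
#' * R2: L1 = L3 = 1 nt gives parallel for any L2 up to 15 nt.
#' * R3: L1 = L3 = 2 nt: L2 = 1 parallel; L2 = 2 parallel (major, 73%) or
#'   chair (minor, 27%); L2 = 3 or a duplex-capable long L2 chair;
#'   L2 = 4-5 basket.
#' * R4: L1 = L3 = 3 nt: L2 = 1 parallel; L2 = 2 hybrid3; L2 = 3 any of
#'   hybrid1 (50%), hybrid3 (27%), chair (19%), basket2 (4%);
#'   L2 = 4-5 basket (75%) or basket2 (25%).
#' Modified guanines or a ligand do not force exclusions; they emit a
#' caveat instead. Unmatched queries return all eight topologies with a
#' "no rule" caveat, so the result is never empty.
#'
#' @param q a [rule_query()]
#' @return object of class `g4_rule_prediction`: list with `allowed`
#'   (data frame of topology/weight), `excluded` (data frame of
#'   topology/reason), `matched_rules`, `caveats`
#' @export
allowed_topologies <- function(q) {
  stopifnot(inherits(q, "g4_rule_query"))
  L <- c(q$L1, q$L2, q$L3)
  strained <- q$has_modified_guanines || q$has_ligand
  allowed <- NULL; rules <- list(); caveats <- character(0)

  add <- function(tab, topo, weight) {
    rbind(tab, data.frame(topology = topo, weight = weight,
                          stringsAsFactors = FALSE))
  }

  if (strained) {
    if (q$has_modified_guanines) {
      caveats <- c(caveats, paste("modified guanines (e.g. 8-bromo-G) can",
        "force syn configurations and break the 1-nt-loop parallel rule;",
        "no topology is excluded"))
    }
    if (q$has_ligand) {
      caveats <- c(caveats, paste("a bound ligand can switch the topology",
        "(e.g. parallel to hybrid1); no topology is excluded"))
    }
  }

  if (!strained && sum(L == 1) >= 2) {
    allowed <- add(allowed, "parallel", "100%")
    rules <- c(rules, list(rule_hit("R1",
      "two or more 1-nt loops force the parallel topology")))
  } else if (!strained && q$L1 == 1 && q$L3 == 1 && q$L2 <= 15) {
    allowed <- add(allowed, "parallel", "100%")
    rules <- c(rules, list(rule_hit("R2",
      "L1 = L3 = 1 nt gives parallel for L2 up to 15 nt")))
  } else if (!strained && q$L1 == 2 && q$L3 == 2) {
    if (q$L2 == 1) {
      allowed <- add(allowed, "parallel", "100%")
      rules <- c(rules, list(rule_hit("R3a", "L1 = L3 = 2, L2 = 1: parallel")))
    } else if (q$L2 == 2) {
      allowed <- add(allowed, "parallel", "major (73%)")
      allowed <- add(allowed, "antiparallel-chair", "minor (27%)")
      rules <- c(rules, list(rule_hit("R3b",
        "L1 = L3 = L2 = 2: 73% parallel, 27% chair")))
    } else if (q$L2 == 3 || duplex_capable(q$L2)) {
      allowed <- add(allowed, "antiparallel-chair", "100%")
      rules <- c(rules, list(rule_hit("R3c",
        "L1 = L3 = 2, L2 = 3 (or duplex-capable long L2): chair")))
      if (duplex_capable(q$L2) && q$L2 > 3) {
        caveats <- c(caveats, paste("long central loop assumed to fold into",
          "an intra-loop duplex (>= 3 WC bp + 4-nt turn)"))
      }
    } else if (q$L2 %in% 4:5) {
      allowed <- add(allowed, "antiparallel-basket", "100%")
      rules <- c(rules, list(rule_hit("R3d",
        "L1 = L3 = 2, L2 = 4-5: basket (diagonal central loop)")))
    }
  } else if (!strained && q$L1 == 3 && q$L3 == 3) {
    if (q$L2 == 1) {
      allowed <- add(allowed, "parallel", "100%")
      rules <- c(rules, list(rule_hit("R4a", "L1 = L3 = 3, L2 = 1: parallel")))
    } else if (q$L2 == 2) {
      allowed <- add(allowed, "hybrid3", "100%")
      rules <- c(rules, list(rule_hit("R4b", "L1 = L3 = 3, L2 = 2: hybrid3")))
    } else if (q$L2 == 3) {
      allowed <- add(allowed, "hybrid1", "50%")
      allowed <- add(allowed, "hybrid3", "27%")
      allowed <- add(allowed, "antiparallel-chair", "19%")
      allowed <- add(allowed, "antiparallel-basket2", "4%")
      rules <- c(rules, list(rule_hit("R4c",
        "L1 = L3 = L2 = 3: hybrid1/hybrid3/chair/basket2")))
      caveats <- c(caveats, paste("(3,3,3) percentages exclude structures",
        "resolved in PEG, which are all parallel"))
    } else if (q$L2 %in% 4:5) {
      allowed <- add(allowed, "antiparallel-basket", "75%")
      allowed <- add(allowed, "antiparallel-basket2", "25%")
      rules <- c(rules, list(rule_hit("R4d",
        "L1 = L3 = 3, L2 = 4-5: basket or basket2")))
    }
  }

  if (is.null(allowed)) {
    allowed <- data.frame(topology = TOPOLOGIES, weight = "unconstrained",
                          stringsAsFactors = FALSE)
    rules <- c(rules, list(rule_hit("R0", "no rule matches this query")))
    caveats <- c(caveats, "no rule constrains this loop-length combination")
  }

  excluded <- data.frame(topology = setdiff(TOPOLOGIES, allowed$topology),
                         stringsAsFactors = FALSE)
  excluded$reason <- if (nrow(excluded)) {
    paste("not observed for loop lengths",
          sprintf("(%d,%d,%d)", q$L1, q$L2, q$L3))
  } else character(0)

  structure(list(query = q, allowed = allowed, excluded = excluded,
                 matched_rules = rules, caveats = caveats),
            class = "g4_rule_prediction")
}

#' @export
print.g4_rule_prediction <- function(x, ...) {
  q <- x$query
  cat(sprintf("Loop lengths (%d,%d,%d) [%s]\n", q$L1, q$L2, q$L3,
              q$chain_nature))
  cat("Allowed:", paste(sprintf("%s (%s)", x$allowed$topology,
                                x$allowed$weight), collapse = ", "), "\n")
  for (r in x$matched_rules) cat("  rule", r$id, "-", r$desc, "\n")
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}
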