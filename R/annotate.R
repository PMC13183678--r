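# End-to-end annotation pipeline: from a coordinate model to the full
# per-structure topology report, plus JSON/TSV serialization.

block_pattern <- function(stem, model, block) {
  tets <- seq(block[1], block[2])
  if (length(tets) < 2) return(NULL)
  letters4 <- vapply(stem$columns, function(col) {
    cl <- col$guanines[col$guanines$tetrad %in% tets, , drop = FALSE]
    cl <- cl[order(cl$tetrad), ]
    steps <- integer(0)
    for (t in seq_len(nrow(cl) - 1L)) {
      dpos <- cl$chain_pos[t + 1L] - cl$chain_pos[t]
      if (abs(dpos) <= 4) steps <- c(steps, sign(dpos))
    }
    if (length(steps) == 0 || sum(steps) == 0) NA_character_
    else if (sum(steps) > 0) "d" else "u"
  }, character(1))
  if (anyNA(letters4)) return(NULL)
  paste(letters4, collapse = "")
}

block_name <- function(pattern) {
  if (is.null(pattern)) return("-")
  letters4 <- strsplit(pattern, "")[[1]]
  if (length(unique(letters4)) == 1) return("parallel")
  if (letters4[1] == "u") {
    pattern <- chartr("du", "ud", pattern)
  }
  out <- TOPOLOGY_BY_PATTERN[pattern]
  if (is.na(out)) "-" else unname(out)
}

chain_nature_of <- function(model) {
  rn <- model$residues$resname
  dna <- rn %in% c("DA", "DC", "DG", "DT", "DU", "T", "DI")
  rna <- rn %in% c("A", "C", "G", "U", "I")
  if (any(dna) && any(rna)) "mixed"
  else if (any(rna)) "RNA" else "DNA"
}

sequence_of <- function(model) {
  r <- model$residues
  paste(ifelse(r$is_modified, paste0("[", r$resname, "]"), r$parent_base),
        collapse = "")
}

#' Annotate a G4 structure
#'
#' Runs the full pipeline on a coordinate model: tetrad detection, stem
#' assembly, discontinuity and block detection, strand-direction pattern
#' and topology naming (with a glycosidic/groove signature fallback when
#' snapbacks break the strand directions), glycosidic patterns, groove
#' signature, handedness, loop classification with combination string,
#' 0-nt loop licensing, V-shaped strands, extremity sides, flanking
#' nucleotide lengths and geometric quantities.
#'
#' @param model a `g4_model` (from [read_structure()] or [build_g4()])
#' @param hbond_cutoff Hoogsteen mean donor-acceptor cutoff (A)
#' @param planarity_tol tetrad planarity flag threshold (A)
#' @param constants a [g4_constants()] list
#' @return an object of class `g4_annotation` (a named list; see the
#'   vignette for the field glossary)
#' @export
#' @examples
#' ann <- annotate_g4(build_g4("parallel"))
#' ann$topology         # "parallel"
#' ann$loop_combination # "-p-p-p"
annotate_g4 <- function(model, hbond_cutoff = 3.5, planarity_tol = 0.5,
                        constants = g4_constants()) {
  warnings <- character(0)
  tets <- detect_tetrads(model, hbond_cutoff, planarity_tol)
  base <- list(source_id = model$source_id, n_tetrads = length(tets))
  degenerate_report <- function(why) {
    out <- c(base, list(
      topology = "undetermined", confidence = "none",
      loops = list(), loop_combination = "",
      loop_lengths = numeric(0),
      chain_nature = chain_nature_of(model),
      sequence = sequence_of(model),
      flags = character(0), warnings = why))
    class(out) <- "g4_annotation"
    out
  }
  if (length(tets) == 0) {
    return(degenerate_report("no G-tetrad detected"))
  }
  stem <- assemble_stem(tets, model)
  if (stem$degenerate) {
    return(degenerate_report("single tetrad: degenerate stem"))
  }
  disc <- detect_discontinuities(stem, model)
  lps <- classify_loops(stem, model, disc)
  gc <- gc_pattern(stem, model)
  groove <- groove_signature(stem, model)
  hand <- stem_handedness(stem, model, disc$blocks)

  two_block <- length(disc$blocks) > 1
  confidence <- "pattern"
  pattern <- tryCatch(strand_direction_pattern(stem),
                      error = function(e) NA_character_)
  if (two_block) {
    bn <- vapply(disc$blocks, function(b)
      block_name(block_pattern(stem, model, b)), character(1))
    topology <- paste0("two-block:", bn[1], "/", bn[2])
  } else if (!is.na(pattern) && startsWith(pattern, "d")) {
    topology <- topology_from_pattern(pattern)
  } else {
    fb <- topology_from_signatures(gc, groove$signature)
    topology <- fb$topology
    confidence <- fb$confidence
    warnings <- c(warnings,
      "strand directions unusable; topology from gc/groove signatures")
  }

  zn <- zero_nt_loops(lps$loops, stem, disc)
  for (z in zn) warnings <- c(warnings, z$warning)
  vsh <- v_shaped_strands(stem, lps$loops, model)

  loop_lengths <- vapply(lps$loops, `[[`, numeric(1), "length_nt")
  basic <- Filter(function(lp) !isTRUE(lp$is_snapback_loop), lps$loops)
  warnings <- c(warnings,
    four_tetrad_loop_check(stem$n_tetrads,
      vapply(Filter(function(lp) lp$kind == "p", basic), `[[`,
             numeric(1), "length_nt"), constants))
  for (lp in lps$loops) {
    if (lp$kind == "d" && lp$length_nt <= 3) {
      warnings <- c(warnings, diagonal_min_length_rule(lp$length_nt)$note)
    }
  }

  allu <- stem$stem_uids
  pos <- chain_position(model, allu)
  fn5 <- min(pos) - 1L
  fn3 <- nrow(model$residues) - max(pos)

  stemgs <- model$residues[model$residues$uid %in% allu, ]
  flags <- character(0)
  if (any(stemgs$is_modified)) flags <- c(flags, "modified_guanines")
  if (isTRUE(model$has_ligand)) flags <- c(flags, "ligand_present")
  if (any(hand$per_block == "LH")) flags <- c(flags, "platypus_suspect")

  rt <- rise_and_twist(stem, model)
  snap_types <- vapply(
    Filter(function(d) d$kind == "snapback", disc$discontinuities),
    `[[`, character(1), "snapback_type")

  out <- c(base, list(
    topology = topology,
    confidence = confidence,
    strand_pattern = pattern,
    gc_pattern = gc,
    groove = groove,
    handedness = list(per_block = hand$per_block,
                      relative = hand$relative),
    blocks = disc$blocks,
    loops = lps$loops,
    loop_combination = lps$combination,
    loop_lengths = loop_lengths,
    chain_nature = chain_nature_of(model),
    sequence = sequence_of(model),
    fn5_length = fn5,
    fn3_length = fn3,
    extremity_sides = extremity_sides(stem, model),
    discontinuities = disc$discontinuities,
    snapback_types = snap_types,
    v_shaped_strands = vsh,
    geometry = list(
      stem_height = stem_height(stem, model),
      rise = if (length(rt$rise)) mean(rt$rise) else NA_real_,
      twist = if (length(rt$twist)) mean(rt$twist, na.rm = TRUE)
              else NA_real_,
      planarity_rms = vapply(stem$tetrads, `[[`, numeric(1),
                             "planarity_rms")),
    flags = flags,
    warnings = warnings))
  class(out) <- "g4_annotation"
  out
}

#' @export
print.g4_annotation <- function(x, ...) {
  cat("G4 annotation:", x$source_id, "\n")
  cat("  topology:", x$topology,
      if (!is.null(x$strand_pattern) && !is.na(x$strand_pattern))
        paste0("(", x$strand_pattern, ")") else "", "\n")
  cat("  tetrads:", x$n_tetrads, "\n")
  if (!is.null(x$gc_pattern)) {
    cat("  gc pattern:", paste(x$gc_pattern, collapse = " "), "\n")
  }
  if (!is.null(x$groove)) {
    cat("  grooves:", x$groove$signature, "\n")
  }
  if (!is.null(x$loop_combination)) {
    cat("  loops:", x$loop_combination,
        paste0("(", paste(x$loop_lengths, collapse = ","), " nt)"), "\n")
  }
  if (!is.null(x$extremity_sides)) {
    cat("  extremities:", x$extremity_sides, "\n")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialize an annotation report
#'
#' JSON output preserves the full nested report with a stable key order.
#' TSV output is a two-column key/value table whose complex values are
#' JSON-encoded cells; both round-trip through [read_annotation()].
#'
#' @param report a `g4_annotation`
#' @param format `"json"` or `"tsv"`
#' @param path optional file to write to
#' @return the serialized text, invisibly when `path` is given
#' @export
write_annotation <- function(report, format = c("json", "tsv"),
                             path = NULL) {
  format <- match.arg(format)
  x <- unclass(report)
  if (format == "json") {
    txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10,
                            null = "null", pretty = TRUE)
    txt <- as.character(txt)
  } else {
    keys <- names(x)
    vals <- vapply(keys, function(k) {
      as.character(jsonlite::toJSON(x[[k]], auto_unbox = TRUE,
                                    digits = 10, null = "null"))
    }, character(1))
    txt <- paste(paste(keys, vals, sep = "\t"), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read back a serialized annotation report
#'
#' @param text serialized report (or a file path via `path`)
#' @param format `"json"` or `"tsv"`
#' @param path optional file to read from
#' @return a `g4_annotation`
#' @export
read_annotation <- function(text = NULL, format = c("json", "tsv"),
                            path = NULL) {
  format <- match.arg(format)
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "\n")
  if (format == "json") {
    x <- jsonlite::fromJSON(text, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    x <- stats::setNames(
      lapply(parts, function(p)
        jsonlite::fromJSON(p[2], simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)),
      vapply(parts, `[[`, character(1), 1))
  }
  class(x) <- "g4_annotation"
  x
}
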