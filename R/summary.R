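# Dataset-level aggregation: non-redundant sequence accounting and
# Table-style summaries over many annotations or a characteristics table.

#' Count non-redundant sequences
#'
#' Sequences are redundant only when identical (case-insensitive exact
#' match); a single modified nucleotide (rendered with a distinct code)
#' removes the redundancy.
#'
#' @param seqs character vector of sequences
#' @return integer count of distinct sequences
#' @export
#' @examples
#' nonredundant_sequences(c("AGGG", "AGGG", "TGGG"))  # 2
nonredundant_sequences <- function(seqs) {
  if (length(seqs) == 0) return(0L)
  length(unique(toupper(seqs)))
}

CHARACTERISTICS_COLUMNS <- c("structure_id", "sequence", "topology",
                             "n_blocks", "n_tetrads", "L1", "L2", "L3",
                             "chain_nature")

#' Load a characteristics table from TSV
#'
#' Strict loader for a per-structure characteristics table (one row per
#' deposited structure: sequence, topology, block count, tetrad count,
#' loop lengths, chain nature). Fails loudly when expected columns are
#' missing rather than guessing.
#'
#' @param path TSV file path
#' @return a data frame with the columns of
#'   [synthetic_characteristics_table()]
#' @export
load_characteristics_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(CHARACTERISTICS_COLUMNS, names(df))
  if (length(missing)) {
    stop("characteristics table lacks expected columns: ",
         paste(missing, collapse = ", "))
  }
  df
}

# deterministic synthetic sequence distinct per index
synth_sequence <- function(i) {
  digits <- character(0)
  n <- i
  repeat {
    digits <- c(c("A", "C", "G", "T")[n %% 4 + 1], digits)
    n <- n %/% 4
    if (n == 0) break
  }
  paste0("TT", paste(digits, collapse = ""),
         "AGGGTTAGGGTTAGGGTTAGGG")
}

#' Synthetic stand-in characteristics table
#'
#' A row-level reconstruction of the deposited-structure characteristics
#' dataset, built from printed aggregate counts only: 353 structures (318
#' one-block + 35 two-block), per-topology structure and non-redundant
#' sequence counts, four polymorphic sequences shared between topologies
#' (three with two topologies, one with three), and eleven structures
#' with (2,2,2) loops of which eight are parallel and three are
#' antiparallel-chair. All other row-level details (sequences, loop
#' lengths) are synthetic placeholders; the table is a stand-in for
#' testing the aggregation machinery, not real data.
#'
#' @return data frame with columns `structure_id`, `sequence`,
#'   `topology`, `n_blocks`, `n_tetrads`, `L1`, `L2`, `L3`,
#'   `chain_nature`
#' @export
synthetic_characteristics_table <- function() {
  # one-block: per-topology (structures, unique sequences); the unique
  # totals sum to 197 sequence-topology pairs over 192 distinct
  # sequences once the shared polymorphic sequences are accounted for.
  one_block <- list(
    parallel = c(140, 90),
    `antiparallel-chair` = c(64, 22),
    `antiparallel-basket` = c(24, 21),
    `antiparallel-basket2` = c(16, 10),
    hybrid1 = c(16, 12),
    hybrid2 = c(17, 14),
    hybrid3 = c(24, 15),
    hybrid4 = c(17, 13))
  # polymorphic sequences appearing under several topologies
  poly <- list(
    `22AG` = list(seq = "AGGGTTAGGGTTAGGGTTAGGG",
                  topos = c("antiparallel-basket", "parallel")),
    TAGGG = list(seq = "TAGGGTTAGGGTTAGGGTTAGG",
                 topos = c("antiparallel-basket", "antiparallel-basket2")),
    `23TAG` = list(seq = "TAGGGTTAGGGTTAGGGTTAGGG",
                   topos = c("hybrid1", "antiparallel-chair", "parallel")),
    RET20T = list(seq = "GGGGCGGGGCGGGGCGGGGT",
                  topos = c("parallel", "hybrid4")))
  default_loops <- list(
    parallel = c(1, 2, 1), `antiparallel-chair` = c(2, 3, 2),
    `antiparallel-basket` = c(2, 4, 2),
    `antiparallel-basket2` = c(3, 4, 3), hybrid1 = c(3, 3, 3),
    hybrid2 = c(1, 5, 2), hybrid3 = c(3, 3, 3), hybrid4 = c(2, 1, 4))
  typical_tetrads <- list(
    parallel = 3, `antiparallel-chair` = 2, `antiparallel-basket` = 2,
    `antiparallel-basket2` = 2, hybrid1 = 3, hybrid2 = 3, hybrid3 = 3,
    hybrid4 = 3)

  rows <- list(); counter <- 0L; sid <- 0L
  for (topo in names(one_block)) {
    n_struct <- one_block[[topo]][1]
    n_uni <- one_block[[topo]][2]
    shared <- unlist(lapply(poly, function(p)
      if (topo %in% p$topos) p$seq else NULL))
    n_synth <- n_uni - length(shared)
    seqs <- c(shared, vapply(seq_len(n_synth), function(i) {
      counter <<- counter + 1L
      synth_sequence(counter)
    }, character(1)))
    mult <- c(n_struct - n_uni + 1L, rep(1L, n_uni - 1L))
    all_seqs <- rep(seqs, times = rev(mult))  # repeats on a synthetic seq
    loops <- default_loops[[topo]]
    for (s in all_seqs) {
      sid <- sid + 1L
      rows[[sid]] <- data.frame(
        structure_id = sprintf("SYN%04d", sid), sequence = s,
        topology = topo, n_blocks = 1L,
        n_tetrads = typical_tetrads[[topo]],
        L1 = loops[1], L2 = loops[2], L3 = loops[3],
        chain_nature = "DNA", stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  # (2,2,2)-loop subset: 11 structures, 8 parallel + 3 chair (73% / 27%)
  ip <- which(df$topology == "parallel")[1:8]
  ic <- which(df$topology == "antiparallel-chair")[1:3]
  df[c(ip, ic), c("L1", "L2", "L3")] <- 2

  # two-block: (structures, unique sequences) per layout; 35 rows, 26
  # distinct sequences
  two_block <- list(
    `two-block:parallel/parallel` = list(c(3, 3), c(7, 6), c(2, 2)),
    `two-block:parallel/hybrid2` = list(c(1, 1)),
    `two-block:-/parallel` = list(c(4, 2), c(4, 2)),
    `two-block:parallel/-` = list(c(12, 8), c(2, 2)))
  for (topo in names(two_block)) {
    for (grp in two_block[[topo]]) {
      n_struct <- grp[1]; n_uni <- grp[2]
      seqs <- vapply(seq_len(n_uni), function(i) {
        counter <<- counter + 1L
        synth_sequence(counter)
      }, character(1))
      mult <- c(n_struct - n_uni + 1L, rep(1L, n_uni - 1L))
      for (s in rep(seqs, times = mult)) {
        sid <- sid + 1L
        df <- rbind(df, data.frame(
          structure_id = sprintf("SYN%04d", sid), sequence = s,
          topology = topo, n_blocks = 2L, n_tetrads = 4L,
          L1 = NA_real_, L2 = NA_real_, L3 = NA_real_,
          chain_nature = "RNA", stringsAsFactors = FALSE))
      }
    }
  }
  rownames(df) <- NULL
  df
}

#' Aggregate a characteristics table into a dataset summary
#'
#' Computes the dataset-level accounting: total structures, distinct
#' sequences (overall and per block class), per-topology structure and
#' non-redundant sequence counts (one sequence may appear under several
#' topologies, so the per-topology figures sum to the sequence-topology
#' pair count), tetrad-count histograms per topology and chain-nature
#' breakdown. Rows with an undetermined topology are binned separately.
#'
#' @param df a characteristics data frame
#'   (see [synthetic_characteristics_table()])
#' @return list of class `g4_dataset_summary`
#' @export
aggregate_characteristics <- function(df) {
  stopifnot(all(c("sequence", "topology") %in% names(df)))
  df$topology[is.na(df$topology)] <- "undetermined"
  df$sequence <- toupper(df$sequence)
  one <- df[df$n_blocks == 1, , drop = FALSE]
  two <- df[df$n_blocks == 2, , drop = FALSE]
  per_topo <- lapply(split(df, df$topology), function(sub) {
    list(n_structures = nrow(sub),
         n_sequences = nonredundant_sequences(sub$sequence),
         tetrad_histogram = as.list(table(sub$n_tetrads)),
         chain_nature = as.list(table(sub$chain_nature)))
  })
  pair_count_one <- sum(vapply(split(one, one$topology), function(sub)
    nonredundant_sequences(sub$sequence), integer(1)))
  out <- list(
    n_structures = nrow(df),
    n_sequences = nonredundant_sequences(df$sequence),
    n_one_block_structures = nrow(one),
    n_two_block_structures = nrow(two),
    n_one_block_sequences = nonredundant_sequences(one$sequence),
    n_two_block_sequences = nonredundant_sequences(two$sequence),
    sequence_topology_pairs_one_block = pair_count_one,
    per_topology = per_topo)
  class(out) <- "g4_dataset_summary"
  out
}

#' Aggregate annotation reports into a dataset summary
#'
#' Convenience wrapper turning a list of [annotate_g4()] reports into a
#' characteristics table and aggregating it.
#'
#' @param annotations list of `g4_annotation`
#' @return a `g4_dataset_summary`
#' @export
aggregate_annotations <- function(annotations) {
  if (length(annotations) == 0) {
    return(aggregate_characteristics(data.frame(
      structure_id = character(0), sequence = character(0),
      topology = character(0), n_blocks = integer(0),
      n_tetrads = integer(0), L1 = numeric(0), L2 = numeric(0),
      L3 = numeric(0), chain_nature = character(0),
      stringsAsFactors = FALSE)))
  }
  df <- do.call(rbind, lapply(annotations, function(a) {
    ll <- a$loop_lengths %||% rep(NA_real_, 3)
    data.frame(
      structure_id = a$source_id %||% NA_character_,
      sequence = a$sequence %||% NA_character_,
      topology = a$topology %||% "undetermined",
      n_blocks = length(a$blocks %||% list(1)),
      n_tetrads = a$n_tetrads %||% NA_integer_,
      L1 = ll[1] %||% NA_real_, L2 = if (length(ll) > 1) ll[2] else NA,
      L3 = if (length(ll) > 2) ll[3] else NA,
      chain_nature = a$chain_nature %||% NA_character_,
      stringsAsFactors = FALSE)
  }))
  aggregate_characteristics(df)
}

#' @export
print.g4_dataset_summary <- function(x, ...) {
  cat("G4 dataset summary\n")
  cat(sprintf("  %d structures, %d non-redundant sequences\n",
              x$n_structures, x$n_sequences))
  cat(sprintf("  one-block: %d structures / %d sequences (%d pairs)\n",
              x$n_one_block_structures, x$n_one_block_sequences,
              x$sequence_topology_pairs_one_block))
  cat(sprintf("  two-block: %d structures / %d sequences\n",
              x$n_two_block_structures, x$n_two_block_sequences))
  for (topo in names(x$per_topology)) {
    p <- x$per_topology[[topo]]
    cat(sprintf("  %-22s %4d structures, %3d sequences\n", topo,
                p$n_structures, p$n_sequences))
  }
  invisible(x)
}
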