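# Shared fixtures built in code. Models are cached per test run because
# several test files annotate the same canonical builds.

.model_cache <- new.env(parent = emptyenv())

cached_build <- function(topology, n_tetrads = 3, ...) {
  key <- paste(topology, n_tetrads, ...)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  m <- build_g4(topology, n_tetrads = n_tetrads, ...)
  .model_cache[[key]] <- m
  m
}

cached_annotation <- function(topology, n_tetrads = 3, ...) {
  key <- paste("ann", topology, n_tetrads, ...)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  a <- annotate_g4(cached_build(topology, n_tetrads, ...))
  .model_cache[[key]] <- a
  a
}

ALL_TOPOLOGIES <- c("parallel", "antiparallel-chair", "antiparallel-basket",
                    "antiparallel-basket2", "hybrid1", "hybrid2", "hybrid3",
                    "hybrid4")

# Minimal mmCIF rendering of a model's atoms, to exercise the mmCIF
# reader against a structure of known content.
model_as_mmcif <- function(model) {
  a <- model$atoms
  hdr <- c("data_synthetic", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.type_symbol", "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d \"%s\" . %s %s %d %.3f %.3f %.3f %s 1",
                  seq_len(nrow(a)), a$atom, a$resname, a$chain, a$resno,
                  a$x, a$y, a$z, a$element)
  c(hdr, rows, "#")
}

# A tiny protein-only PDB (no nucleic residues) for empty-model errors.
protein_only_pdb <- function() {
  c(paste0("ATOM      1  CA  ALA A   1      11.104   6.134  -6.504",
           "  1.00  0.00           C"),
    paste0("ATOM      2  CA  GLY A   2      12.560   8.100  -5.100",
           "  1.00  0.00           C"),
    "END")
}
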