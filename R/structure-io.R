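# Coordinate-file parsing into a uniform nucleic-acid model.
#
# No pre-installed R package parses PDB/mmCIF in this stack, so both readers
# are implemented here. Only the information the annotator needs is kept:
# nucleic residues with their atom coordinates, base identity (modified
# residues mapped to a parent base), glycosidic torsion and syn/anti state.
# Non-nucleic residues and waters are dropped; monatomic ions are recorded
# as metadata.

# Chemical-component dictionary: residue code -> parent base. Covers the
# standard codes plus modified nucleosides that occur in deposited G4
# structures (e.g. BGM = 8-bromo-2'-deoxyguanosine).
STANDARD_NUCLEOTIDES <- c(
  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "G",
  A = "A", C = "C", G = "G", U = "U", T = "T", I = "G"
)

MODIFIED_BASE_MAP <- c(
  BGM = "G", BRG = "G", `8OG` = "G", `8OX` = "G", GFL = "G", OMG = "G",
  `2MG` = "G", M2G = "G", `7MG` = "G", GF2 = "G", LCG = "G", GNE = "G",
  MRG = "G", `6OG` = "G", G48 = "G", LG  = "G", GH3 = "G", PGN = "G",
  BRU = "T", `5IU` = "T", `5BU` = "T", UMS = "U", `5MU` = "T", OMU = "U",
  PSU = "U", UFT = "U", US1 = "U",
  `5MC` = "C", OMC = "C", `5CM` = "C", CBR = "C", CFL = "C", LCC = "C",
  `1MA` = "A", `2AD` = "A", A2M = "A", MA6 = "A", AF2 = "A", ADI = "A",
  `6MA` = "A"
)

ION_CODES <- c("K", "NA", "TL", "MG", "CA", "SR", "BA", "LI", "CS", "NH4",
               "ZN", "MN", "CL", "BR", "IOD")

PURINE_BASES <- c("A", "G")

#' Assign the glycosidic configuration from a chi torsion
#'
#' The glycosidic torsion chi is defined as O4'-C1'-N9-C4 for purines
#' (O4'-C1'-N1-C2 for pyrimidines). A residue is called `syn` when chi lies
#' in (-90, 90] and `anti` otherwise; an undefined chi (missing torsion
#' atoms) yields `"undefined"`, never a silent `anti`.
#'
#' @param chi torsion in degrees, in (-180, 180]; may be `NA`
#' @return `"syn"`, `"anti"` or `"undefined"`
#' @export
#' @examples
#' assign_glycosidic(180)  # "anti"
#' assign_glycosidic(60)   # "syn"
assign_glycosidic <- function(chi) {
  if (length(chi) != 1) return(vapply(chi, assign_glycosidic, character(1)))
  if (is.na(chi)) return("undefined")
  if (chi <= -180 || chi > 180) stop("chi must be in (-180, 180]")
  if (chi > -90 && chi <= 90) "syn" else "anti"
}

map_parent_base <- function(resname, atom_names) {
  resname <- toupper(trimws(resname))
  if (resname %in% names(STANDARD_NUCLEOTIDES)) {
    return(list(parent = unname(STANDARD_NUCLEOTIDES[resname]),
                modified = FALSE, nucleic = TRUE))
  }
  if (resname %in% names(MODIFIED_BASE_MAP)) {
    return(list(parent = unname(MODIFIED_BASE_MAP[resname]),
                modified = TRUE, nucleic = TRUE))
  }
  # Heuristic fallback: recognize a nucleotide by its atom content so that
  # unlisted modified residues are not silently dropped.
  has_sugar <- all(c("C1'", "O4'") %in% atom_names)
  if (has_sugar) {
    if (all(c("N9", "O6", "N1", "N2", "N7") %in% atom_names)) {
      return(list(parent = "G", modified = TRUE, nucleic = TRUE))
    }
    if (all(c("N9", "N7", "N6") %in% atom_names)) {
      return(list(parent = "A", modified = TRUE, nucleic = TRUE))
    }
    if (all(c("N1", "O2", "N4") %in% atom_names)) {
      return(list(parent = "C", modified = TRUE, nucleic = TRUE))
    }
    if (all(c("N1", "O2", "O4") %in% atom_names)) {
      base <- if ("C7" %in% atom_names || "C5M" %in% atom_names) "T" else "U"
      return(list(parent = base, modified = TRUE, nucleic = TRUE))
    }
  }
  list(parent = NA_character_, modified = FALSE, nucleic = FALSE)
}

residue_uid <- function(chain, resno) paste(chain, resno, sep = ":")

# ---------------------------------------------------------------- parsers

parse_pdb_text <- function(lines, model_index = 1) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    if (model_index > length(model_starts)) {
      stop("model_index ", model_index, " out of range (file has ",
           length(model_starts), " models)")
    }
    ends <- grep("^ENDMDL", lines)
    from <- model_starts[model_index]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    lines <- lines[from:to]
  } else if (model_index != 1) {
    stop("model_index ", model_index, " out of range (single-model file)")
  }
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0) return(NULL)
  # PDB fixed columns
  data.frame(
    atom = trimws(substr(rec, 13, 16)),
    altloc = trimws(substr(rec, 17, 17)),
    resname = trimws(substr(rec, 18, 20)),
    chain = trimws(substr(rec, 22, 22)),
    resno = as.integer(substr(rec, 23, 26)),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    element = trimws(substr(rec, 77, 78)),
    stringsAsFactors = FALSE
  )
}

# Tokenizer for one mmCIF data line (handles quoted strings).
cif_tokens <- function(line) {
  out <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

parse_mmcif_text <- function(lines, model_index = 1) {
  # Locate the atom_site loop.
  loop_idx <- grep("^\\s*loop_\\s*$", lines)
  for (li in loop_idx) {
    j <- li + 1L
    fields <- character(0)
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      fields <- c(fields, trimws(lines[j]))
      j <- j + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
          startsWith(ln, "_") || startsWith(ln, "data_")) break
      rows[[length(rows) + 1L]] <- cif_tokens(lines[j])
      j <- j + 1L
    }
    if (length(rows) == 0) return(NULL)
    nf <- length(fields)
    ok <- vapply(rows, function(r) length(r) == nf, logical(1))
    mat <- do.call(rbind, rows[ok])
    colnames(mat) <- sub("^_atom_site\\.", "", fields)
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% colnames(mat)) return(mat[, nm])
      rep(NA_character_, nrow(mat))
    }
    mdl <- pick("pdbx_PDB_model_num")
    df <- data.frame(
      atom = gsub('"', "", pick("label_atom_id", "auth_atom_id")),
      altloc = pick("label_alt_id"),
      resname = pick("auth_comp_id", "label_comp_id"),
      chain = pick("auth_asym_id", "label_asym_id"),
      resno = suppressWarnings(as.integer(pick("auth_seq_id",
                                               "label_seq_id"))),
      x = as.numeric(pick("Cartn_x")),
      y = as.numeric(pick("Cartn_y")),
      z = as.numeric(pick("Cartn_z")),
      element = pick("type_symbol"),
      stringsAsFactors = FALSE
    )
    df$altloc[df$altloc %in% c(".", "?")] <- ""
    if (!all(is.na(mdl))) {
      models <- unique(mdl)
      if (model_index > length(models)) {
        stop("model_index ", model_index, " out of range (file has ",
             length(models), " models)")
      }
      df <- df[mdl == models[model_index], , drop = FALSE]
    } else if (model_index != 1) {
      stop("model_index ", model_index, " out of range (single-model file)")
    }
    return(df)
  }
  NULL
}

# ------------------------------------------------------------ model build

compute_chi <- function(atoms_res, parent_base) {
  need <- if (parent_base %in% PURINE_BASES) c("O4'", "C1'", "N9", "C4")
          else c("O4'", "C1'", "N1", "C2")
  idx <- match(need, atoms_res$atom)
  if (anyNA(idx)) return(NA_real_)
  p <- lapply(idx, function(i) c(atoms_res$x[i], atoms_res$y[i],
                                 atoms_res$z[i]))
  torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]])
}

build_model <- function(atoms, source_id, model_index, format) {
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("no atom records found in '", source_id, "'")
  }
  atoms <- atoms[atoms$altloc %in% c("", "A", "1"), , drop = FALSE]
  atoms <- atoms[!toupper(atoms$element) %in% c("H", "D"), , drop = FALSE]
  atoms$resname <- toupper(trimws(atoms$resname))
  atoms <- atoms[atoms$resname != "HOH", , drop = FALSE]
  ions <- sort(unique(atoms$resname[atoms$resname %in% ION_CODES]))
  atoms <- atoms[!atoms$resname %in% ION_CODES, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no nucleic residues in '", source_id, "'")
  atoms$uid <- residue_uid(atoms$chain, atoms$resno)

  first_seen <- !duplicated(atoms$uid)
  res_order <- atoms$uid[first_seen]
  res_info <- lapply(res_order, function(u) {
    sub <- atoms[atoms$uid == u, , drop = FALSE]
    m <- map_parent_base(sub$resname[1], sub$atom)
    chi <- if (m$nucleic) compute_chi(sub, m$parent) else NA_real_
    list(chain = sub$chain[1], resno = sub$resno[1], resname = sub$resname[1],
         nucleic = m$nucleic, parent = m$parent, modified = m$modified,
         chi = chi)
  })
  residues <- data.frame(
    uid = res_order,
    chain = vapply(res_info, `[[`, character(1), "chain"),
    resno = vapply(res_info, `[[`, integer(1), "resno"),
    resname = vapply(res_info, `[[`, character(1), "resname"),
    is_nucleic = vapply(res_info, `[[`, logical(1), "nucleic"),
    parent_base = vapply(res_info, `[[`, character(1), "parent"),
    is_modified = vapply(res_info, `[[`, logical(1), "modified"),
    chi = vapply(res_info, `[[`, numeric(1), "chi"),
    stringsAsFactors = FALSE
  )
  residues$gc <- assign_glycosidic(residues$chi)
  has_ligand <- any(!residues$is_nucleic)
  residues <- residues[residues$is_nucleic, , drop = FALSE]
  if (nrow(residues) == 0) {
    stop("no nucleic residues in '", source_id, "' (empty model)")
  }
  atoms <- atoms[atoms$uid %in% residues$uid, , drop = FALSE]
  atoms$key <- paste(atoms$uid, atoms$atom, sep = "|")

  m <- structure(list(atoms = atoms, residues = residues,
                      source_id = source_id, model_index = model_index,
                      format = format, ions = ions,
                      has_ligand = has_ligand),
                 class = "g4_model")
  m$atom_index <- stats::setNames(seq_len(nrow(atoms)), atoms$key)
  m
}

#' Read a nucleic-acid structure from a PDB or mmCIF file
#'
#' Parses the coordinate file into a uniform model: nucleic residues in
#' chain order with their atoms, parent base (modified residues mapped via
#' a component dictionary and flagged), glycosidic torsion and syn/anti
#' state. Protein residues and waters are dropped; monatomic ions are
#' recorded in `$ions`. For multi-model (NMR) files, `model_index` selects
#' one model (default the first).
#'
#' @param path path to the structure file
#' @param format `"auto"` (by extension/content), `"pdb"` or `"mmcif"`
#' @param model_index 1-based model number for multi-model files
#' @return an object of class `g4_model` with elements `atoms` (data frame),
#'   `residues` (data frame, 5'->3' per chain), `source_id`, `ions`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_index = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else if (any(grepl("^_atom_site\\.", lines))) "mmcif"
              else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_text(lines, model_index)
           else parse_mmcif_text(lines, model_index)
  source_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                   ignore.case = TRUE)
  build_model(atoms, source_id, model_index, format)
}

#' @export
print.g4_model <- function(x, ...) {
  cat("g4_model", x$source_id, "--", nrow(x$residues), "nucleic residues,",
      nrow(x$atoms), "atoms")
  if (length(x$ions)) cat(", ions:", paste(x$ions, collapse = ","))
  cat("\n")
  invisible(x)
}

# Coordinates of one named atom of one residue, or NULL when absent.
atom_xyz <- function(model, uid, atom) {
  i <- model$atom_index[paste(uid, atom, sep = "|")]
  if (is.na(i)) return(NULL)
  c(model$atoms$x[i], model$atoms$y[i], model$atoms$z[i])
}

# All available atoms of a residue as a named n x 3 matrix.
residue_xyz <- function(model, uid) {
  sel <- model$atoms$uid == uid
  m <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  rownames(m) <- model$atoms$atom[sel]
  m
}

# Centroid of the guanine base ring atoms of a residue.
base_centroid <- function(model, uid) {
  ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  m <- residue_xyz(model, uid)
  m <- m[rownames(m) %in% ring, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  colMeans(m)
}

# Chain-order index of every residue uid (across chains, file order).
chain_position <- function(model, uid) {
  match(uid, model$residues$uid)
}
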