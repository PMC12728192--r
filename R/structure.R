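#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd setNames rbinom runif rnorm cor
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Structure: a flat atom table, one row per atom per model.
# Columns mirror the fields of a PDB ATOM/HETATM record plus a model index.
# ---------------------------------------------------------------------------

.atom_cols <- c("serial", "name", "element", "alt_loc", "res_name",
                "chain_id", "res_seq", "i_code", "x", "y", "z",
                "occupancy", "b_factor", "model_index", "is_hetero")

#' Construct a structure object from an atom table
#'
#' A `gatescope_structure` is a flat data frame of atom records (one row per
#' atom per model) carrying coordinates in Angstrom, plus the number of
#' models and a source label. Residue identity is always the triple
#' `(chain_id, res_seq, i_code)`.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `res_name`, `chain_id`, `res_seq`, `i_code`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `model_index`, `is_hetero`.
#' @param source character label (file path or `"synthetic"`).
#' @param metadata optional list of generator metadata (strand tags, seeds).
#' @return an object of class `gatescope_structure`.
#' @export
new_structure <- function(atoms, source = "synthetic", metadata = list()) {
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, .atom_cols]
  atoms$name <- as.character(atoms$name)
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$res_name <- as.character(atoms$res_name)
  atoms$alt_loc <- as.character(atoms$alt_loc)
  atoms$i_code <- as.character(atoms$i_code)
  if (nrow(atoms) > 0 && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  s <- structure(
    list(atoms = atoms,
         n_models = if (nrow(atoms) > 0) max(atoms$model_index) else 1L,
         source = source,
         metadata = metadata),
    class = "gatescope_structure")
  s
}

#' @export
print.gatescope_structure <- function(x, ...) {
  a <- x$atoms
  m1 <- a[a$model_index == 1L, , drop = FALSE]
  cat(sprintf("<gatescope_structure> %d atoms/model, %d model(s), %d chain(s) [%s]\n",
              nrow(m1), x$n_models, length(unique(m1$chain_id)), x$source))
  invisible(x)
}

#' Number of atoms in one model
#' @param s structure
#' @param model_index model to count (default 1)
#' @return integer atom count
#' @export
n_atoms <- function(s, model_index = 1L) {
  sum(s$atoms$model_index == model_index)
}

#' Coordinates of one model as an n x 3 matrix
#' @param s structure
#' @param model_index which model
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(s, model_index = 1L) {
  a <- s$atoms[s$atoms$model_index == model_index, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

.residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$res_seq, atoms$i_code, sep = "|")
}

# ---------------------------------------------------------------------------
# Reading
# ---------------------------------------------------------------------------

.from_bio3d <- function(p, path) {
  nmod <- if (is.matrix(p$xyz)) nrow(p$xyz) else 1L
  at <- p$atom
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  base <- data.frame(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    element = blank(at$elesy),
    alt_loc = blank(at$alt),
    res_name = as.character(at$resid),
    chain_id = blank(at$chain),
    res_seq = as.integer(at$resno),
    i_code = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    model_index = 1L,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  # keep a single conformer: altloc blank or "A"
  keep <- base$alt_loc %in% c("", "A")
  base <- base[keep, , drop = FALSE]
  if (nmod > 1L) {
    xyz <- p$xyz
    tabs <- lapply(seq_len(nmod), function(m) {
      b <- base
      cm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
      b$x <- cm[, 1]; b$y <- cm[, 2]; b$z <- cm[, 3]
      b$model_index <- as.integer(m)
      b
    })
    base <- do.call(rbind, tabs)
  }
  if (nrow(base) == 0)
    stop("no atoms parsed from ", path)
  new_structure(base, source = path)
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Captures all ATOM/HETATM records of all models; insertion codes are
#' preserved. Alternate locations other than blank or "A" are dropped so the
#' structure carries a single deterministic conformer.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  p <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE)
  } else {
    bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE)
  }
  .from_bio3d(p, path)
}

# ---------------------------------------------------------------------------
# Writing
# ---------------------------------------------------------------------------

.write_pdb_structure <- function(s, path) {
  a <- s$atoms
  con <- file(path, "w")
  on.exit(close(con))
  fmt_atom <- function(r) {
    rec <- if (r$is_hetero) "HETATM" else "ATOM  "
    nm <- r$name
    # PDB atom-name column convention: 1-3 char names start in column 14
    nm_f <- if (nchar(nm) >= 4) sprintf("%-4s", nm) else sprintf(" %-3s", nm)
    sprintf("%s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, r$serial %% 100000L, nm_f,
            substr(paste0(r$alt_loc, " "), 1, 1),
            substr(r$res_name, 1, 4),
            substr(paste0(r$chain_id, " "), 1, 1),
            r$res_seq %% 10000L,
            substr(paste0(r$i_code, " "), 1, 1),
            r$x, r$y, r$z, r$occupancy, r$b_factor,
            substr(paste0(r$element, "  "), 1, 2))
  }
  for (m in seq_len(s$n_models)) {
    if (s$n_models > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    am <- a[a$model_index == m, , drop = FALSE]
    for (i in seq_len(nrow(am))) writeLines(fmt_atom(am[i, ]), con)
    if (s$n_models > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.write_cif_structure <- function(s, path) {
  a <- s$atoms
  q <- function(v, blank = ".") ifelse(v == "" | is.na(v), blank, v)
  # canonical PDBx/mmCIF atom_site field order
  lines <- c(
    "data_gatescope",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s %d",
    ifelse(a$is_hetero, "HETATM", "ATOM"),
    a$serial, q(a$element, "?"), a$name, q(a$alt_loc),
    a$res_name, q(a$chain_id, "A"), a$res_seq, q(a$i_code, "?"),
    a$x, a$y, a$z, a$occupancy, a$b_factor,
    a$res_seq, a$res_name, q(a$chain_id, "A"), a$name, a$model_index)
  writeLines(c(lines, rows, "#"), path)
  invisible(path)
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output is fixed-column with MODEL/ENDMDL for multi-model structures;
#' coordinates are printed at the format's native 3-decimal precision.
#'
#' @param s structure.
#' @param path output path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (format == "pdb") .write_pdb_structure(s, path) else .write_cif_structure(s, path)
}

# ---------------------------------------------------------------------------
# Selection
# ---------------------------------------------------------------------------

#' Atom selection criteria
#'
#' All set criteria are combined with AND. Residue ranges are inclusive on
#' `res_seq`.
#'
#' @param chains optional character vector of chain ids.
#' @param residue_ranges optional list of `c(start, end)` integer pairs, or a
#'   2-column matrix.
#' @param atom_names optional character vector (e.g. `"CA"`).
#' @param include_hetero logical, keep HETATM records (default TRUE).
#' @param model_index model to select from (default 1).
#' @return an object of class `gatescope_selection`.
#' @export
selection <- function(chains = NULL, residue_ranges = NULL, atom_names = NULL,
                      include_hetero = TRUE, model_index = 1L) {
  if (is.null(chains) && is.null(residue_ranges) && is.null(atom_names) &&
      isTRUE(include_hetero) && model_index == 1L) {
    # legal: selects everything in model 1
  }
  if (!is.null(residue_ranges)) {
    if (is.matrix(residue_ranges))
      residue_ranges <- split(residue_ranges, row(residue_ranges)[, 1])
    if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
    for (r in residue_ranges) {
      if (length(r) != 2 || r[1] > r[2])
        stop("residue ranges must be (start, end) pairs with start <= end")
    }
  }
  structure(list(chains = chains, residue_ranges = residue_ranges,
                 atom_names = atom_names, include_hetero = include_hetero,
                 model_index = as.integer(model_index)),
            class = "gatescope_selection")
}

#' Apply a selection to a structure
#'
#' @param s structure.
#' @param sel a [selection()].
#' @return a structure containing exactly the atoms matching all criteria, in
#'   original order. An empty result is legal.
#' @export
select_atoms <- function(s, sel) {
  stopifnot(inherits(sel, "gatescope_selection"))
  if (sel$model_index > s$n_models)
    stop("model_index ", sel$model_index, " out of bounds (n_models = ",
         s$n_models, ")")
  a <- s$atoms
  keep <- a$model_index == sel$model_index
  if (!is.null(sel$chains)) keep <- keep & a$chain_id %in% sel$chains
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  if (!sel$include_hetero) keep <- keep & !a$is_hetero
  if (!is.null(sel$residue_ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in sel$residue_ranges)
      in_range <- in_range | (a$res_seq >= r[1] & a$res_seq <= r[2])
    keep <- keep & in_range
  }
  out <- a[keep, , drop = FALSE]
  out$model_index <- rep(1L, nrow(out))
  new_structure(out, source = s$source, metadata = s$metadata)
}
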