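#' @importFrom stats coef lm median rnorm runif setNames aggregate nls predict fitted
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

# Standard 3-letter -> 1-letter amino acid code, incl. MSE -> M.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O", "DIS", "SOL")

#' Construct a structure object from an atom table
#'
#' The atom table is the package's hierarchical structure model: one row per
#' heavy atom, with author residue numbering as the public coordinate system.
#' Most users will obtain structures from [read_structure()] or
#' [make_toy_structure()] rather than building the table by hand.
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `chain`,
#'   `resno` (integer, author numbering), `insert` (insertion code, "" if
#'   none), `resid` (3-letter residue name), `elety` (PDB atom name), `elesy`
#'   (element symbol), `x`, `y`, `z` (Angstrom), `o` (occupancy), `b`
#'   (B-factor).
#' @param id structure identifier.
#' @param source free-form provenance string.
#' @return an object of class `opb_structure`.
#' @export
new_structure <- function(atoms, id = "structure", source = "") {
  req <- c("type", "chain", "resno", "insert", "resid", "elety", "elesy",
           "x", "y", "z", "o", "b")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert[is.na(atoms$insert)] <- ""
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancies must lie in [0, 1]")
  if (any(!nzchar(atoms$elesy)))
    stop("empty element symbol in atom table")
  if (!any(atoms$type == "ATOM"))
    stop("no protein chains: structure contains no ATOM records")
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source = source),
            class = "opb_structure")
}

#' @export
print.opb_structure <- function(x, ...) {
  a <- x$atoms
  prot <- a[a$type == "ATOM", ]
  nres <- nrow(unique(prot[, c("chain", "resno", "insert")]))
  het <- unique(a$resid[a$type == "HETATM"])
  cat(sprintf("<opb_structure> %s: %d atoms, %d protein residues, chains %s",
              x$id, nrow(a), nres,
              paste(unique(prot$chain), collapse = ",")))
  if (length(het)) cat(sprintf(", hetero: %s", paste(het, collapse = ",")))
  cat("\n")
  invisible(x)
}

# Derive an element symbol from a PDB atom name when the element column is
# blank (common in minimal files).  Handles the usual left-justified vs
# right-justified conventions for C/N/O/S/H and two-letter metals.
guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  known2 <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA", "SE", "CU", "NI")
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    if (nchar(nm[i]) >= 2 && two[i] %in% known2 &&
        !(one[i] %in% c("C", "N", "O", "S", "P"))) {
      out[i] <- paste0(substr(two[i], 1, 1), tolower(substr(two[i], 2, 2)))
    } else {
      out[i] <- one[i]
    }
  }
  out
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records through [bio3d::read.pdb()].  Alternate
#' locations are collapsed to the highest-occupancy conformer (ties broken by
#' altloc letter order), waters are excluded, hydrogens are dropped, and
#' author residue numbering is preserved.  Non-water hetero groups (e.g. a
#' covalent inhibitor) are retained.
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @param keep_waters keep water molecules (default `FALSE`).
#' @return an [new_structure()] object.
#' @export
read_structure <- function(path, format = "pdb", keep_waters = FALSE) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  blank <- is.na(a$elesy) | !nzchar(trimws(a$elesy))
  a$elesy[blank] <- guess_element(a$elety[blank])
  a$elesy <- trimws(a$elesy)
  # drop hydrogens and (by default) waters
  a <- a[!(toupper(a$elesy) %in% c("H", "D")), ]
  if (!keep_waters) a <- a[!(a$resid %in% WATER_RESIDS), ]
  if (!nrow(a) || !any(a$type == "ATOM"))
    stop("no protein chains in '", path, "'")
  # altloc collapse: per (chain, resno, insert, atom name) keep the highest
  # occupancy, ties by altloc letter order
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(key, -a$o, a$alt)
  a <- a[ord, ]
  a <- a[!duplicated(key[ord]), ]
  # restore file order
  a <- a[order(a$eleno), ]
  new_structure(
    a[, c("type", "chain", "resno", "insert", "resid", "elety", "elesy",
          "x", "y", "z", "o", "b")],
    id = sub("\\.(pdb|ent)$", "", basename(path)),
    source = path)
}

#' Write a structure to a PDB file
#'
#' Inverse of [read_structure()]; coordinates are written at PDB precision
#' (three decimals), so a write/read round trip preserves them to 1e-3 A.
#'
#' @param structure an `opb_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$type,
    resno = a$resno,
    resid = a$resid,
    eleno = seq_len(nrow(a)),
    elety = a$elety,
    chain = a$chain,
    insert = ifelse(nzchar(a$insert), a$insert, NA),
    o = a$o,
    b = a$b,
    elesy = a$elesy)
  invisible(path)
}

#' Protein chain identifiers of a structure
#' @param structure an `opb_structure`.
#' @return character vector of chain ids carrying ATOM records.
#' @export
protein_chains <- function(structure) {
  unique(structure$atoms$chain[structure$atoms$type == "ATOM"])
}

#' Look up a single atom
#'
#' @param structure an `opb_structure`.
#' @param chain chain id; `NULL` uses the first protein chain.
#' @param resnum author residue number.
#' @param atom_name PDB atom name (e.g. `"OG"`, `"NE2"`).  Ambiguous
#'   carboxylate/guanidinium atoms must be named explicitly (OD1 vs OD2 etc.).
#' @param icode insertion code, default `""`.
#' @return a one-row data.frame (atom record).
#' @export
get_atom <- function(structure, chain = NULL, resnum, atom_name, icode = "") {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  a <- structure$atoms
  hit <- a$chain == chain & a$resno == resnum & a$insert == icode &
    a$elety == atom_name
  if (!any(hit))
    stop(sprintf("atom not found: chain %s, residue %d%s, atom %s",
                 chain, resnum, icode, atom_name))
  a[which(hit)[1], ]
}

#' Look up a residue (all atoms)
#' @inheritParams get_atom
#' @return data.frame of atom records.
#' @export
get_residue <- function(structure, chain = NULL, resnum, icode = "") {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  a <- structure$atoms
  hit <- a$chain == chain & a$resno == resnum & a$insert == icode
  if (!any(hit))
    stop(sprintf("residue not found: chain %s, residue %d%s",
                 chain, resnum, icode))
  a[hit, ]
}

#' One-letter sequence of a protein chain
#'
#' Extracted from CA atoms in residue order; the author residue number of
#' each position is kept in `attr(, "resno")` so sequence indices can be
#' translated back to structure numbering.
#'
#' @inheritParams get_atom
#' @return character scalar; attribute `resno` holds the author numbers.
#' @export
structure_sequence <- function(structure, chain = NULL) {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  a <- structure$atoms
  ca <- a[a$type == "ATOM" & a$chain == chain & a$elety == "CA", ]
  ca <- ca[order(ca$resno, ca$insert), ]
  one <- AA_321[ca$resid]
  one[is.na(one)] <- "X"
  out <- paste(one, collapse = "")
  attr(out, "resno") <- ca$resno
  out
}

#' Residue table of a structure
#' @param structure an `opb_structure`.
#' @param chain chain id or `NULL` for all chains.
#' @return data.frame with one row per residue (chain, resno, insert, resid,
#'   hetero flag).
#' @export
residue_table <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  key <- !duplicated(paste(a$chain, a$resno, a$insert, sep = "\r"))
  out <- a[key, c("chain", "resno", "insert", "resid", "type")]
  out$hetero <- out$type == "HETATM"
  out$type <- NULL
  rownames(out) <- NULL
  out
}

#' Apply a rigid-body motion to a structure
#'
#' @param structure an `opb_structure`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 translation vector (Angstrom).
#' @param subset optional logical/integer index of atom rows to move; default
#'   moves every atom.
#' @return the transformed `opb_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0), subset = NULL) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  idx <- if (is.null(subset)) seq_len(nrow(xyz)) else subset
  xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE] %*% t(rotation), 2,
                      translation, `+`)
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

# internal: coordinates of a subset of atoms as an n x 3 matrix
atom_xyz <- function(structure, idx = NULL) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}
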