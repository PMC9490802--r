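## Structure data model and readers. Internal length unit is nm throughout
## the package; PDB coordinates (Angstrom) are converted on read, GRO files
## are already in nm.

#' Construct a structure model
#'
#' A flat atom table holding one conformation: typically the reference
#' (crystal) structure that trajectory frames are fitted onto.
#'
#' @param atoms data.frame with columns `atom_id` (integer), `atom_name`,
#'   `residue_name`, `residue_number` (integer), `chain_id`, `element`,
#'   and coordinates `x`, `y`, `z` in nm.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("atom_id", "atom_name", "residue_name", "residue_number",
            "chain_id", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in structure")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) records: ",
         key[anyDuplicated(key)][1L])
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("<structure_model> ", nrow(a), " atoms, ",
      length(unique(paste(a$chain_id, a$residue_number))), " residues, ",
      length(unique(a$chain_id)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Coordinates of a structure as a matrix
#'
#' @param x a `structure_model`.
#' @param atom_ids optional atom ids to select (in the given order).
#' @return numeric matrix (n x 3) in nm, rownames = atom ids.
#' @export
coords <- function(x, atom_ids = NULL) {
  a <- x$atoms
  if (!is.null(atom_ids)) {
    idx <- match(atom_ids, a$atom_id)
    if (anyNA(idx))
      stop("atom id(s) absent from structure: ",
           paste(atom_ids[is.na(idx)], collapse = ", "))
    a <- a[idx, , drop = FALSE]
  }
  m <- as.matrix(a[c("x", "y", "z")])
  rownames(m) <- a$atom_id
  m
}

# First non-digit character of the atom name; adequate for protein and
# water atoms (CA is an alpha carbon here, never calcium).
guess_element <- function(atom_name) {
  toupper(substr(sub("^[0-9']+", "", atom_name), 1L, 1L))
}

#' Read a molecular structure file
#'
#' Reads all ATOM/HETATM records of a PDB file (via bio3d) or all atoms of
#' a GRO file, converting coordinates to nm. Chain identifiers and residue
#' numbering are preserved; GRO files (which carry no chain id) get chain
#' `"A"`.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @return a [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (format == "pdb") read_pdb_structure(path) else read_gro_structure(path)
}

read_pdb_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed PDB file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("malformed PDB file '", path, "': no ATOM/HETATM records")
  el <- a$elesy
  bad <- is.na(el) | !nzchar(trimws(el))
  el[bad] <- guess_element(a$elety[bad])
  structure_model(data.frame(
    atom_id = as.integer(a$eleno),
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_number = as.integer(a$resno),
    chain_id = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    element = trimws(el),
    x = a$x / 10, y = a$y / 10, z = a$z / 10,   # Angstrom -> nm
    stringsAsFactors = FALSE))
}

read_gro_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("malformed GRO file '", path, "': fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || length(lines) < n + 3L)
    stop("malformed GRO file '", path, "': bad atom count on line 2")
  body <- lines[3:(2L + n)]
  parse_field <- function(from, to) substr(body, from, to)
  resno <- suppressWarnings(as.integer(parse_field(1, 5)))
  resnm <- trimws(parse_field(6, 10))
  atnm <- trimws(parse_field(11, 15))
  atno <- suppressWarnings(as.integer(parse_field(16, 20)))
  x <- suppressWarnings(as.numeric(parse_field(21, 28)))
  y <- suppressWarnings(as.numeric(parse_field(29, 36)))
  z <- suppressWarnings(as.numeric(parse_field(37, 44)))
  bad <- which(is.na(resno) | is.na(atno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record on line ", bad[1L] + 2L, " of '", path, "'")
  structure_model(data.frame(
    atom_id = atno, atom_name = atnm, residue_name = resnm,
    residue_number = resno, chain_id = "A",
    element = guess_element(atnm),
    x = x, y = y, z = z, stringsAsFactors = FALSE))
}

#' Write a structure as a minimal PDB file
#'
#' Coordinates are converted from nm back to Angstrom. Intended for small
#' synthetic fixtures and stage outputs, not for round-tripping arbitrary
#' PDB metadata.
#'
#' @param x a [structure_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  a <- x$atoms
  rec <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                 a$atom_id,
                 ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name),
                        a$atom_name),
                 a$residue_name, a$chain_id, a$residue_number,
                 a$x * 10, a$y * 10, a$z * 10, a$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Atom ids matching chain / residue / atom-name selectors
#'
#' @param x a [structure_model].
#' @param chain_id,residue_number,atom_name optional filters; `NULL`
#'   matches everything.
#' @return integer atom ids in table order.
#' @export
atom_ids_of <- function(x, chain_id = NULL, residue_number = NULL,
                        atom_name = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain_id)) keep <- keep & a$chain_id %in% chain_id
  if (!is.null(residue_number)) keep <- keep & a$residue_number %in% residue_number
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  a$atom_id[keep]
}
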