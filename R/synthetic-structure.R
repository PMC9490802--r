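## Synthetic stand-in for the GlpF reference (crystal) structure.
##
## The deposited crystal structure cannot be bundled, so this builder
## constructs, from idealised internal coordinates, the sixteen residues
## the gating registry needs, calibrated to the published crystal-state
## geometry: W48 side-chain dihedral CA-CB-CG-CD1 = 103 degrees, R206
## CA-CB-CG-CZ = 311 degrees, M202-L21 minimal side-chain distance
## 0.82 nm, and every descriptor in its open (reference) state. It is a
## synthetic calibration object, not the experimental structure.

#' Synthetic GlpF-like reference structure
#'
#' Builds a heavy-atom model of the nine gating residues, their distance
#' partners and the mutation site V29 (chain A, crystal residue
#' numbering), with side-chain geometry calibrated to the reference
#' (open-pore) state of every gating descriptor. Residue pairs probed by
#' minimal distances are placed at crystal-like separations
#' (M202-L21 = 0.82 nm); unrelated residues are at least 2 nm apart.
#'
#' @return a [structure_model].
#' @export
synthetic_reference_structure <- function() {
  pair_sep <- c(f200 = 0.55, a201 = 0.60, m202 = 0.82, n203 = 0.55,
                n68 = 0.70, h66 = 0.60, v173 = 0.80)
  groups <- list(
    list(res = list(c("TRP", 48))),                 # dihedral residue
    list(res = list(c("ARG", 206))),                # dihedral residue
    list(res = list(c("PHE", 200), c("PRO", 196)), sep = pair_sep["f200"]),
    list(res = list(c("ALA", 201), c("TRP", 48)), sep = pair_sep["a201"],
         alias = TRUE),                             # W48 already built
    list(res = list(c("MET", 202), c("LEU", 21)), sep = pair_sep["m202"]),
    list(res = list(c("ASN", 203), c("ILE", 187)), sep = pair_sep["n203"]),
    list(res = list(c("ASN", 68), c("VAL", 52)), sep = pair_sep["n68"]),
    list(res = list(c("HIS", 66), c("ILE", 183)), sep = pair_sep["h66"]),
    list(res = list(c("VAL", 173), c("LEU", 75)), sep = pair_sep["v173"]),
    list(res = list(c("VAL", 29))))
  built <- list()          # residue number -> atom data.frame
  gx <- 0
  for (grp in groups) {
    offset <- c(gx, 0, 0)
    gx <- gx + 3                                   # 3 nm between groups
    first <- grp$res[[1L]]
    key1 <- as.character(first[2L])
    if (is.null(built[[key1]]))
      built[[key1]] <- build_residue(first[1L], as.integer(first[2L]),
                                     offset)
    if (length(grp$res) > 1L) {
      second <- grp$res[[2L]]
      key2 <- as.character(second[2L])
      if (is.null(built[[key2]]))
        built[[key2]] <- build_residue(second[1L], as.integer(second[2L]),
                                       offset + c(1.2, 0, 0))
      built[[key2]] <- calibrate_pair(built[[key1]], built[[key2]],
                                      grp$sep)
    }
  }
  atoms <- do.call(rbind, built[order(as.integer(names(built)))])
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure_model(atoms)
}

## Translate residue B along the closest side-chain pair direction until
## the minimal heavy side-chain distance to A equals `target` nm.
calibrate_pair <- function(A, B, target) {
  sc <- function(df) {
    m <- as.matrix(df[!(df$atom_name %in% backbone_atoms) &
                        df$element != "H", c("x", "y", "z")])
    m
  }
  for (it in 1:8) {
    a <- sc(A); b <- sc(B)
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
    u <- b[ij[2L], ] - a[ij[1L], ]
    d <- vnorm(u)
    if (abs(d - target) < 1e-9) break
    shift <- (target - d) * u / d
    B$x <- B$x + shift[1L]; B$y <- B$y + shift[2L]; B$z <- B$z + shift[3L]
  }
  B
}

## Idealised heavy-atom residue at a spatial offset. Backbone is fixed;
## side chains use standard bond lengths/angles with the calibrated
## torsions noted below.
build_residue <- function(resname, resno, offset) {
  N <- c(0, 0, 0)
  CA <- c(0.1458, 0, 0)
  C <- CA + 0.1525 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  O <- place_atom(N, CA, C, 0.123, 121, 180)
  CB <- place_atom(C, N, CA, 0.153, 110, -122)
  pos <- list(N = N, CA = CA, C = C, O = O)
  if (resname != "GLY") pos$CB <- CB
  chi1 <- -65
  g <- function(...) place_atom(...)
  add <- switch(resname,
    TRP = {
      CG <- g(N, CA, CB, 0.151, 114, chi1)
      CD1 <- g(CA, CB, CG, 0.137, 127, 103)   # calibrated: 103 degrees
      CD2 <- g(CA, CB, CG, 0.143, 127, -77)
      NE1 <- g(CB, CG, CD1, 0.137, 110, 180)
      CE2 <- g(CB, CG, CD2, 0.141, 107, 180)
      list(CG = CG, CD1 = CD1, CD2 = CD2, NE1 = NE1, CE2 = CE2)
    },
    ARG = {
      CG <- g(N, CA, CB, 0.152, 114, chi1)
      CD <- g(CA, CB, CG, 0.152, 111, 180)
      NE <- g(CB, CG, CD, 0.146, 112, 180)
      CZ <- g(CA, CB, CG, 0.41, 115, 311 - 360)  # calibrated: 311 degrees
      NH1 <- g(CB, CG, CZ, 0.133, 120, 0)
      NH2 <- g(CB, CG, CZ, 0.133, 120, 180)
      list(CG = CG, CD = CD, NE = NE, CZ = CZ, NH1 = NH1, NH2 = NH2)
    },
    MET = {
      CG <- g(N, CA, CB, 0.152, 114, chi1)
      SD <- g(CA, CB, CG, 0.181, 112, 180)
      CE <- g(CB, CG, SD, 0.179, 100, 180)
      list(CG = CG, SD = SD, CE = CE)
    },
    LEU = {
      CG <- g(N, CA, CB, 0.153, 116, chi1)
      CD1 <- g(CA, CB, CG, 0.152, 111, 65)
      CD2 <- g(CA, CB, CG, 0.152, 111, 180)
      list(CG = CG, CD1 = CD1, CD2 = CD2)
    },
    PHE = {
      CG <- g(N, CA, CB, 0.150, 114, chi1)
      CD1 <- g(CA, CB, CG, 0.139, 120, 90)
      CD2 <- g(CA, CB, CG, 0.139, 120, -90)
      CE1 <- g(CB, CG, CD1, 0.139, 120, 180)
      CE2 <- g(CB, CG, CD2, 0.139, 120, 180)
      CZ <- g(CG, CD1, CE1, 0.139, 120, 0)
      list(CG = CG, CD1 = CD1, CD2 = CD2, CE1 = CE1, CE2 = CE2, CZ = CZ)
    },
    PRO = {
      CG <- g(N, CA, CB, 0.149, 104, 30)
      CD <- g(CA, CB, CG, 0.150, 106, -35)
      list(CG = CG, CD = CD)
    },
    ALA = list(),
    ASN = {
      CG <- g(N, CA, CB, 0.152, 113, chi1)
      OD1 <- g(CA, CB, CG, 0.123, 121, -60)
      ND2 <- g(CA, CB, CG, 0.132, 116, 120)
      list(CG = CG, OD1 = OD1, ND2 = ND2)
    },
    ILE = {
      CG1 <- g(N, CA, CB, 0.153, 110, chi1)
      CG2 <- g(N, CA, CB, 0.153, 110, chi1 + 120)
      CD1 <- g(CA, CB, CG1, 0.152, 113, 180)
      list(CG1 = CG1, CG2 = CG2, CD1 = CD1)
    },
    VAL = {
      CG1 <- g(N, CA, CB, 0.153, 110, chi1)
      CG2 <- g(N, CA, CB, 0.153, 110, chi1 + 120)
      list(CG1 = CG1, CG2 = CG2)
    },
    HIS = {
      CG <- g(N, CA, CB, 0.150, 114, chi1)
      ND1 <- g(CA, CB, CG, 0.138, 122, -90)
      CD2 <- g(CA, CB, CG, 0.136, 129, 90)
      CE1 <- g(CB, CG, ND1, 0.132, 109, 180)
      NE2 <- g(CB, CG, CD2, 0.137, 107, 180)
      list(CG = CG, ND1 = ND1, CD2 = CD2, CE1 = CE1, NE2 = NE2)
    },
    stop("no template for residue ", resname))
  pos <- c(pos, add)
  m <- do.call(rbind, pos)
  m <- sweep(m, 2L, offset, "+")
  data.frame(atom_id = NA_integer_, atom_name = rownames(m),
             residue_name = resname, residue_number = resno,
             chain_id = "A", element = guess_element(rownames(m)),
             x = m[, 1L], y = m[, 2L], z = m[, 3L],
             stringsAsFactors = FALSE)
}
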