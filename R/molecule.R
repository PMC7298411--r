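#' @keywords internal
"_PACKAGE"

# Per-element parameter tables used by the field engine.  Radii are
# van-der-Waals radii (Bondi, Angstrom); eps are Tripos-style well depths
# (kcal/mol) for the 12-6 potential; hydro are crude atomic logP-type
# hydrophobicity contributions (dimensionless).  Any table may be
# overridden via the `params` argument of the field functions.
.element_params <- data.frame(
  element = c("H",  "C",  "N",  "O",  "F",  "P",  "S",  "Cl", "Br", "I"),
  vdw     = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
  eps     = c(0.042, 0.107, 0.095, 0.116, 0.109, 0.314, 0.314, 0.314, 0.434, 0.623),
  hydro   = c(0.12, 0.36, -0.60, -0.40, 0.20, -0.20, 0.25, 0.50, 0.60, 0.70),
  stringsAsFactors = FALSE
)

.lookup_element <- function(elements, column) {
  i <- match(elements, .element_params$element)
  if (anyNA(i)) {
    stop("no parameters for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  .element_params[[column]][i]
}

#' Construct a molecule
#'
#' A light container for one small molecule: element symbols, 3D
#' coordinates (Angstrom), partial charges (elementary charge units) and a
#' bond table.  Per-atom field properties (van-der-Waals radius,
#' hydrophobicity weight, hydrogen-bond donor/acceptor flags) are derived
#' at construction from bundled element tables and simple connectivity
#' rules: any N or O is an acceptor, and an N or O bonded to at least one
#' hydrogen is a donor.
#'
#' @param name compound label.
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param charges partial charges, one per atom; defaults to zeros.
#' @param bonds data frame with integer columns `i`, `j` and `order`
#'   (1-based atom indices); may be empty.
#' @param charge_source provenance label for the charges, recorded as an
#'   attribute (e.g. `"file"`, `"mmff94"`, `"none"`).
#' @return An object of class `qsar_molecule`.
#' @export
molecule <- function(name, elements, coords, charges = NULL, bonds = NULL,
                     charge_source = "none") {
  coords <- as.matrix(coords)
  n <- length(elements)
  stopifnot(n >= 1, nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates in ", name)
  if (is.null(charges)) charges <- rep(0, n)
  stopifnot(length(charges) == n)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order))
  }

  hbd <- hba <- rep(FALSE, n)
  is_no <- elements %in% c("N", "O")
  hba[is_no] <- TRUE
  if (nrow(bonds) > 0 && any(is_no)) {
    for (k in which(is_no)) {
      nb <- c(bonds$j[bonds$i == k], bonds$i[bonds$j == k])
      if (any(elements[nb] == "H")) hbd[k] <- TRUE
    }
  }

  atoms <- data.frame(
    element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = as.numeric(charges),
    vdw = .lookup_element(elements, "vdw"),
    eps = .lookup_element(elements, "eps"),
    hydro = .lookup_element(elements, "hydro"),
    hbd = hbd, hba = hba,
    stringsAsFactors = FALSE
  )
  structure(list(name = name, atoms = atoms, bonds = bonds),
            charge_source = charge_source, class = "qsar_molecule")
}

#' @export
print.qsar_molecule <- function(x, ...) {
  cat("<qsar_molecule>", x$name, "-", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds; charges:",
      attr(x, "charge_source") %||% "none", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coords_of <- function(mol) {
  unname(as.matrix(mol$atoms[, c("x", "y", "z")]))
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

#' Write molecules to an SDF (V2000) file
#'
#' Partial charges are stored in a `> <ATOM_PARTIAL_CHARGES>` data field
#' (one `index charge` pair per line) so that a write/read round trip
#' preserves them; the V2000 atom block itself has no charge field.
#'
#' @param mols a `qsar_molecule` or list thereof.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "qsar_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms; bd <- mol$bonds
    writeLines(c(mol$name, "  qsar3d", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$element), con)
    if (nrow(bd) > 0)
      writeLines(sprintf("%3d%3d%3d  0", bd$i, bd$j, bd$order), con)
    writeLines("M  END", con)
    if (any(at$charge != 0)) {
      writeLines("> <ATOM_PARTIAL_CHARGES>", con)
      writeLines(sprintf("%d %.6f", seq_len(nrow(at)), at$charge), con)
      writeLines("", con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Write molecules to a Tripos MOL2 file
#'
#' @inheritParams write_sdf
#' @export
write_mol2 <- function(mols, path) {
  if (inherits(mols, "qsar_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms; bd <- mol$bonds
    writeLines("@<TRIPOS>MOLECULE", con)
    writeLines(c(mol$name,
                 sprintf(" %d %d 1 0 0", nrow(at), nrow(bd)),
                 "SMALL", "USER_CHARGES", ""), con)
    writeLines("@<TRIPOS>ATOM", con)
    writeLines(sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s %5d %-8s %10.6f",
                       seq_len(nrow(at)),
                       paste0(at$element, seq_len(nrow(at))),
                       at$x, at$y, at$z, at$element, 1L, "MOL1", at$charge),
               con)
    writeLines("@<TRIPOS>BOND", con)
    if (nrow(bd) > 0)
      writeLines(sprintf("%6d %5d %5d %s", seq_len(nrow(bd)),
                         bd$i, bd$j, bd$order), con)
  }
  invisible(path)
}
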