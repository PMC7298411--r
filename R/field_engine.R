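# Molecular interaction fields on a shared rectilinear grid.
#
# CoMFA-style fields: a probe atom (sp3 carbon, charge +1 by default) is
# placed at every grid point; the steric energy is a 12-6 Lennard-Jones
# sum over atoms and the electrostatic energy a Coulomb sum with a
# distance-dependent dielectric D(r) = r.  Steric values are truncated to
# +/- `cutoff` kcal/mol; at grid points where the steric field of a
# compound hits the cutoff, that compound's electrostatic value is
# replaced by the column mean over the remaining compounds (the standard
# CoMFA convention, applied in assemble_descriptor_matrix()).
#
# CoMSIA-style fields: Gaussian-attenuated similarity indices
# A_k(q) = -sum_i w_ik exp(-alpha r_iq^2) with unit probe weight; the
# Gaussian has no singularity so no truncation is needed.  Property
# weights w_ik: steric r_vdw^3, electrostatic partial charge, hydrophobic
# atomic contribution, donor/acceptor 0/1 indicator.

COMFA_FIELDS <- c("steric", "electrostatic")
COMSIA_FIELDS <- c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")

#' Build a shared field grid around aligned molecules
#'
#' The box is the union bounding box of all atoms, extended by `margin`
#' on every side and discretised at `spacing`; each axis gets
#' `ceiling(extent / spacing) + 1` points starting at the box corner.
#'
#' @param molecules non-empty list of aligned `qsar_molecule`.
#' @param margin margin in Angstrom on every side (default 4).
#' @param spacing grid step in Angstrom (default 0.6).
#' @return object of class `qsar_grid`: `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(molecules, margin = 4.0, spacing = 0.6) {
  if (length(molecules) == 0) stop("no molecules to grid")
  if (margin <= 0 || spacing <= 0) stop("margin and spacing must be > 0")
  xyz <- do.call(rbind, lapply(molecules, coords_of))
  lo <- unname(apply(xyz, 2, min)) - margin
  hi <- unname(apply(xyz, 2, max)) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "qsar_grid")
}

#' @export
print.qsar_grid <- function(x, ...) {
  cat(sprintf("<qsar_grid> %d x %d x %d points, spacing %.3f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid point coordinates
#'
#' @param grid a `qsar_grid`.
#' @return (nx*ny*nz) x 3 matrix; x varies fastest, then y, then z.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

# squared distances atoms x grid-points
.dist2 <- function(atom_xyz, pts) {
  outer(rowSums(atom_xyz^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(atom_xyz)), rowSums(pts^2)) -
    2 * atom_xyz %*% t(pts)
}

#' Lennard-Jones steric field of one molecule
#'
#' 12-6 potential `sum_i eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ]` with
#' Lorentz-Berthelot combining (`rmin_ij = r_i + r_probe`,
#' `eps_ij = sqrt(eps_i eps_probe)`), truncated to `[-cutoff, +cutoff]`.
#' A grid point coinciding with an atom gets the cutoff, not infinity.
#'
#' @param mol aligned `qsar_molecule`.
#' @param grid `qsar_grid`.
#' @param probe list with `vdw` (Angstrom) and `eps` (kcal/mol); default
#'   an sp3 carbon probe.
#' @param cutoff truncation in kcal/mol (default 30).
#' @return numeric vector, one energy (kcal/mol) per grid point.
#' @export
lennard_jones_field <- function(mol, grid,
                                probe = list(vdw = 1.70, eps = 0.107),
                                cutoff = 30) {
  pts <- grid_points(grid)
  d2 <- .dist2(coords_of(mol), pts)
  rmin <- mol$atoms$vdw + probe$vdw
  eps <- sqrt(mol$atoms$eps * probe$eps)
  inv6 <- (rmin^2 / pmax(d2, 1e-12))^3      # (rmin/r)^6, guarded at r = 0
  e <- colSums(eps * (inv6^2 - 2 * inv6))
  e[!is.finite(e)] <- cutoff
  pmin(pmax(e, -cutoff), cutoff)
}

#' Coulomb electrostatic field of one molecule
#'
#' `sum_i k z_i z_probe / (D(r) r)` with `k = 332.0` kcal A / (mol e^2)
#' and a distance-dependent dielectric `D(r) = r` (so the energy falls as
#' 1/r^2).  Values are truncated to `[-cutoff, +cutoff]`.
#'
#' @inheritParams lennard_jones_field
#' @param probe_charge probe charge in elementary units (default +1).
#' @param dielectric `"distance"` (D(r) = r, default) or `"constant"`
#'   (D = 1).
#' @param cutoff optional truncation in kcal/mol; the bare field is
#'   unbounded near nuclei, so the CoMFA assembly passes +/-30 here while
#'   the default leaves values untruncated.
#' @export
coulomb_field <- function(mol, grid, probe_charge = 1,
                          dielectric = c("distance", "constant"),
                          cutoff = Inf) {
  dielectric <- match.arg(dielectric)
  if (all(mol$atoms$charge == 0) &&
      identical(attr(mol, "charge_source"), "none"))
    stop("molecule '", mol$name, "' has no partial charges")
  pts <- grid_points(grid)
  d2 <- .dist2(coords_of(mol), pts)
  r <- sqrt(pmax(d2, 1e-12))
  denom <- if (dielectric == "distance") r^2 else r
  e <- colSums(332.0 * mol$atoms$charge * probe_charge / denom)
  e[!is.finite(e)] <- cutoff
  pmin(pmax(e, -cutoff), cutoff)
}

#' CoMSIA similarity-index field of one molecule
#'
#' `A_k(q) = -sum_i w_ik exp(-alpha r_iq^2)` with unit probe weight.
#' Property weights: `steric` r_vdw^3, `electrostatic` partial charge,
#' `hydrophobic` atomic hydrophobicity contribution, `donor`/`acceptor`
#' 0/1 flags.
#'
#' @inheritParams lennard_jones_field
#' @param field_kind one of `r COMSIA_FIELDS`.
#' @param alpha Gaussian attenuation factor in 1/Angstrom^2 (default 0.3).
#' @export
comsia_field <- function(mol, grid, field_kind, alpha = 0.3) {
  w <- switch(field_kind,
              steric = mol$atoms$vdw^3,
              electrostatic = mol$atoms$charge,
              hydrophobic = mol$atoms$hydro,
              donor = as.numeric(mol$atoms$hbd),
              acceptor = as.numeric(mol$atoms$hba),
              stop("unknown field_kind: ", field_kind))
  pts <- grid_points(grid)
  if (all(w == 0)) return(numeric(nrow(pts)))
  d2 <- .dist2(coords_of(mol), pts)
  -colSums(w * exp(-alpha * d2))
}

#' Assemble per-field descriptor matrices for an aligned series
#'
#' One compounds x grid-points matrix ("field block") per field kind.
#' For CoMFA the steric block is computed first; wherever a compound's
#' steric value was truncated at the cutoff, its electrostatic entry is
#' replaced by the mean of that column over the non-truncated compounds
#' (dropped entirely when all compounds are truncated there).
#'
#' @param molecules list of aligned `qsar_molecule` (same frame).
#' @param grid `qsar_grid`; built from the molecules when `NULL`.
#' @param method `"comfa"` or `"comsia"`.
#' @param field_kinds which fields to compute; defaults to the method's
#'   standard set (steric + electrostatic for CoMFA; all five for CoMSIA).
#' @param probe,probe_charge,cutoff,alpha forwarded to the per-field
#'   functions.
#' @return named list of `qsar_field_block` objects, each with `values`
#'   (compounds x points), `field_kind`, `method` and `grid`.
#' @export
assemble_descriptor_matrix <- function(molecules, grid = NULL,
                                       method = c("comfa", "comsia"),
                                       field_kinds = NULL,
                                       probe = list(vdw = 1.70, eps = 0.107),
                                       probe_charge = 1, cutoff = 30,
                                       alpha = 0.3) {
  method <- match.arg(method)
  if (length(molecules) == 0) stop("no molecules")
  if (is.null(grid)) grid <- build_grid(molecules)
  if (is.null(field_kinds))
    field_kinds <- if (method == "comfa") COMFA_FIELDS else COMSIA_FIELDS
  ids <- vapply(molecules, function(m) m$name, "")

  one_block <- function(kind) {
    vals <- t(vapply(molecules, function(m) {
      if (method == "comfa") {
        switch(kind,
               steric = lennard_jones_field(m, grid, probe, cutoff),
               electrostatic = coulomb_field(m, grid, probe_charge,
                                             cutoff = cutoff),
               stop("CoMFA supports steric and electrostatic fields only"))
      } else {
        comsia_field(m, grid, kind, alpha)
      }
    }, numeric(prod(grid$dims))))
    rownames(vals) <- ids
    structure(list(values = vals, field_kind = kind, method = method,
                   grid = grid), class = "qsar_field_block")
  }

  blocks <- lapply(field_kinds, one_block)
  names(blocks) <- field_kinds

  if (method == "comfa" && all(c("steric", "electrostatic") %in% field_kinds)) {
    st <- blocks$steric$values
    truncated <- st >= cutoff - 1e-9   # inside the steric envelope
    el <- blocks$electrostatic$values
    for (j in which(colSums(truncated) > 0)) {
      ok <- !truncated[, j]
      el[!ok, j] <- if (any(ok)) mean(el[ok, j]) else 0
    }
    blocks$electrostatic$values <- el
  }
  blocks
}

#' @export
print.qsar_field_block <- function(x, ...) {
  cat(sprintf("<qsar_field_block> %s/%s: %d compounds x %d grid points\n",
              x$method, x$field_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a grid scalar field as a Gaussian cube file
#'
#' Minimal cube writer (no atoms block beyond a single dummy entry;
#' lengths in Angstrom converted to Bohr as the format requires).
#'
#' @param values numeric vector over the grid (x fastest order, as
#'   returned by the field functions).
#' @param grid `qsar_grid`.
#' @param path output path.
#' @param comment header comment line.
#' @export
write_cube <- function(values, grid, path, comment = "qsar3d field") {
  stopifnot(length(values) == prod(grid$dims))
  bohr <- 1 / 0.529177210903
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "scalar field on rectilinear grid"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1L,
                     grid$origin[1] * bohr, grid$origin[2] * bohr,
                     grid$origin[3] * bohr), con)
  step <- grid$spacing * bohr
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[1], step, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[2], 0, step, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[3], 0, 0, step), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0), con)
  # cube order: z fastest, x slowest; our vectors are x fastest
  arr <- array(values, dim = grid$dims)
  out <- as.numeric(aperm(arr, c(3, 2, 1)))
  chunks <- split(out, ceiling(seq_along(out) / 6))
  writeLines(vapply(chunks, function(v) paste(sprintf("%13.5e", v),
                                              collapse = " "), ""), con)
  invisible(path)
}
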