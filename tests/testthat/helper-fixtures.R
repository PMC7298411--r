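# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk except files the helpers themselves write to tempdir.

# methane with ideal tetrahedral geometry
methane <- function(charges = NULL) {
  molecule("methane", c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(0.629, 0.629, 0.629),
                 c(-0.629, -0.629, 0.629), c(-0.629, 0.629, -0.629),
                 c(0.629, -0.629, -0.629)),
           charges = charges,
           bonds = data.frame(i = 1, j = 2:5, order = 1),
           charge_source = if (is.null(charges)) "none" else "file")
}

# a single atom of given element at a position, with an explicit charge
single_atom <- function(element = "C", at = c(0, 0, 0), charge = 0) {
  molecule(paste0("atom_", element), element, rbind(at), charges = charge,
           charge_source = "file")
}

# a 1x1x1 "grid" holding exactly one probe position
point_grid <- function(at) {
  structure(list(origin = as.numeric(at), spacing = 1, dims = c(1L, 1L, 1L)),
            class = "qsar_grid")
}

# rotation matrix about z
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# random proper rotation from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small aligned synthetic series (shared across tests; cheap)
small_series <- function(n = 8, seed = 11) {
  make_aligned_series(synthetic_series_spec(n_compounds = n, seed = seed))
}

# matrix with columns rescaled to exact standard deviations
matrix_with_sds <- function(n, sds, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(sds)), n)
  for (j in seq_along(sds)) {
    x <- X[, j]
    X[, j] <- if (sds[j] == 0) rep(1, n) else (x - mean(x)) / sd(x) * sds[j]
  }
  X
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# package internals exercised directly by the tests
coords_of <- qsar3d:::coords_of
set_coords <- qsar3d:::set_coords
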