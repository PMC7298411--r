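# Synthetic congeneric series with planted field-activity structure.
#
# The generator emulates what the analysis assumes about real data: a
# rigid shared scaffold (so the series is aligned by construction),
# small substituents at two ring positions giving geometric and
# electrostatic variation, and an activity that is an exact linear
# function of interaction-field values plus Gaussian noise.  The planted
# truth (coefficients, influential block, noise level) is emitted next
# to the data so recovery tests never re-derive it.

# with_seed: run code under a seed, restoring the caller's RNG state so
# the generators are pure functions of (spec, seed)
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# crude per-element partial charges, neutralised to zero total charge
.assign_charges <- function(elements) {
  base <- c(H = 0.06, C = 0.00, N = -0.35, O = -0.40, S = 0.05,
            F = -0.20, Cl = -0.10, Br = -0.08, P = 0.10, I = -0.05)
  ch <- unname(base[elements])
  ch - mean(ch)
}

# Fused bicyclic scaffold: a pyridine-like six-ring sharing an edge with
# a thiophene-like five-ring, planar, bond length 1.40 A.  Returns
# elements, coordinates and bonds plus the two substitution sites with
# their outward directions.
.bicyclic_scaffold <- function() {
  s <- 1.40
  hexv <- t(vapply(0:5, function(k)
    s * c(cos(pi / 3 * k), sin(pi / 3 * k), 0), numeric(3)))
  # pentagon fused across the hexagon edge V1-V2, built on the far side
  A <- hexv[2, ]; B <- hexv[3, ]
  mid <- (A + B) / 2
  u <- mid / sqrt(sum(mid^2))            # outward from hexagon centre
  apo <- s / (2 * tan(pi / 5))
  r5 <- s / (2 * sin(pi / 5))
  c5 <- mid + apo * u
  ang0 <- atan2(A[2] - c5[2], A[1] - c5[1])
  penv <- t(vapply(0:4, function(k)
    c(c5[1:2] + r5 * c(cos(ang0 + 2 * pi * k / 5),
                       sin(ang0 + 2 * pi * k / 5)), 0), numeric(3)))
  # penv[1] == A, penv[5] == B; new atoms are penv[2:4]
  coords <- rbind(hexv, penv[2:4, ])
  elements <- c("N", "C", "C", "C", "C", "C", "C", "S", "C")
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 2, 7, 8, 9),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 3),
    order = 1L)
  # substitution sites: outward radials at ring atoms 6 and 5 (the two
  # CH positions furthest from the fused edge)
  sites <- list(
    list(atom = 6L, dir = hexv[6, ] / sqrt(sum(hexv[6, ]^2))),
    list(atom = 5L, dir = hexv[5, ] / sqrt(sum(hexv[5, ]^2))))
  list(elements = elements, coords = coords, bonds = bonds, sites = sites)
}

# substituent vocabulary: atoms in a local frame where +x is the bond
# direction away from the attachment atom
.default_vocabulary <- function() {
  list(
    H   = list(el = "H",  xyz = rbind(c(1.00, 0, 0))),
    Me  = list(el = c("C", "H", "H", "H"),
               xyz = rbind(c(1.50, 0, 0), c(2.10, 0.90, 0),
                           c(2.10, -0.45, 0.78), c(2.10, -0.45, -0.78))),
    Et  = list(el = c("C", "C", "H", "H", "H"),
               xyz = rbind(c(1.50, 0, 0), c(2.25, 1.30, 0),
                           c(1.95, -0.55, -0.85), c(3.35, 1.25, 0),
                           c(1.95, 2.20, 0.40))),
    Pr  = list(el = c("C", "C", "C"),
               xyz = rbind(c(1.50, 0, 0), c(2.25, 1.30, 0),
                           c(3.75, 1.30, 0.10))),
    OH  = list(el = c("O", "H"),
               xyz = rbind(c(1.40, 0, 0), c(1.75, 0.85, 0))),
    NH2 = list(el = c("N", "H", "H"),
               xyz = rbind(c(1.40, 0, 0), c(1.95, 0.82, 0),
                           c(1.95, -0.82, 0))),
    F   = list(el = "F",  xyz = rbind(c(1.35, 0, 0))),
    Cl  = list(el = "Cl", xyz = rbind(c(1.75, 0, 0))))
}

#' Specification for a synthetic congeneric series
#'
#' @param n_compounds number of compounds (>= 6; default 46, the size of
#'   the bundled thienopyridine series).
#' @param noise_sd Gaussian noise on the planted pIC50, log units
#'   (default 0.1).
#' @param seed integer seed; identical seeds give bit-identical series.
#' @param vocabulary substituent vocabulary (named list; see
#'   `qsar3d:::.default_vocabulary`).
#' @param method field method for the planted activity (default
#'   `"comfa"`).
#' @param spacing,margin grid parameters for the planted fields
#'   (defaults 2.0 and 4.0 A; the coarser grid keeps desk-scale runs
#'   small without changing the planted structure).
#' @param influential_block field block carrying the planted
#'   coefficients (default `"steric"`).
#' @param region_size number of high-variance columns of the influential
#'   block given nonzero planted coefficients (default 30).
#' @param min_sigma planting is restricted to columns whose standard
#'   deviation meets this threshold (default 2.0 kcal/mol, the
#'   conventional column-filter setting), so the planted model lives in
#'   the descriptor space the analysis retains.
#' @param planted_ncomp component count at which recovery is asserted
#'   (default 2).
#' @param activity_range target range the planted activities are
#'   linearly rescaled into (default `c(4.77, 7.38)`, the observed range
#'   of the bundled series; cosmetic).
#' @return list of class `synthetic_series_spec`.
#' @export
synthetic_series_spec <- function(n_compounds = 46, noise_sd = 0.1,
                                  seed = 1, vocabulary = NULL,
                                  method = "comfa", spacing = 2.0,
                                  margin = 4.0,
                                  influential_block = "steric",
                                  region_size = 30, min_sigma = 2.0,
                                  planted_ncomp = 2,
                                  activity_range = c(4.77, 7.38)) {
  if (n_compounds < 6) stop("n_compounds must be >= 6")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(vocabulary)) vocabulary <- .default_vocabulary()
  if (length(vocabulary) == 0) stop("empty substituent vocabulary")
  structure(list(n_compounds = as.integer(n_compounds),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 vocabulary = vocabulary, method = method,
                 spacing = spacing, margin = margin,
                 influential_block = influential_block,
                 region_size = region_size, min_sigma = min_sigma,
                 planted_ncomp = planted_ncomp,
                 activity_range = activity_range),
            class = "synthetic_series_spec")
}

#' Generate an aligned synthetic congeneric series
#'
#' All molecules share the scaffold conformation coordinate-for-
#' coordinate (aligned by construction); substituents at the two ring
#' sites are drawn deterministically from the seed.
#'
#' @param spec a [synthetic_series_spec()].
#' @return list of `qsar_molecule` named `cpd01`, `cpd02`, ...
#' @export
make_aligned_series <- function(spec) {
  sc <- .bicyclic_scaffold()
  voc <- spec$vocabulary
  .with_seed(spec$seed, {
    picks <- matrix(sample(length(voc), 2 * spec$n_compounds, replace = TRUE),
                    ncol = 2)
    lapply(seq_len(spec$n_compounds), function(i) {
      elements <- sc$elements
      coords <- sc$coords
      bonds <- sc$bonds
      for (s in 1:2) {
        g <- voc[[picks[i, s]]]
        site <- sc$sites[[s]]
        u <- site$dir
        # local frame: +x along u, +y in-plane perpendicular, +z out of plane
        pz <- c(0, 0, 1)
        py <- c(-u[2], u[1], 0)
        R <- cbind(u, py, pz)
        anchor <- sc$coords[site$atom, ]
        gx <- g$xyz %*% t(R) + matrix(anchor, nrow(g$xyz), 3, byrow = TRUE)
        first_new <- length(elements) + 1L
        elements <- c(elements, g$el)
        coords <- rbind(coords, gx)
        bonds <- rbind(bonds,
                       data.frame(i = site$atom, j = first_new, order = 1L))
        if (length(g$el) > 1)
          bonds <- rbind(bonds, data.frame(i = first_new,
                                           j = first_new + seq_len(length(g$el) - 1L),
                                           order = 1L))
      }
      molecule(sprintf("cpd%02d", i), elements, coords,
               charges = .assign_charges(elements), bonds = bonds,
               charge_source = "assigned")
    })
  })
}

#' Plant a linear field-activity relation on a series
#'
#' Computes interaction fields for the series, draws a sparse coefficient
#' vector over high-variance columns of the influential block, forms
#' `pIC50 = X beta` rescaled into `activity_range`, and adds Gaussian
#' noise of sd `noise_sd`.  The truth needed by recovery tests is
#' attached as the `truth` attribute.
#'
#' @param molecules aligned series from [make_aligned_series()].
#' @param spec the same [synthetic_series_spec()].
#' @return data frame with `compound_id`, `ic50_uM`, `pic50`, `subset`
#'   (all `train`); attributes `truth` (planted coefficients, block,
#'   column indices, noise draw, rescale slope/intercept, planted
#'   component count) and `blocks` (the computed field blocks).
#' @export
make_field_activity <- function(molecules, spec) {
  grid <- build_grid(molecules, margin = spec$margin, spacing = spec$spacing)
  blocks <- assemble_descriptor_matrix(molecules, grid, method = spec$method)
  X <- do.call(cbind, lapply(blocks, function(b) b$values))
  block_index <- rep(names(blocks),
                     vapply(blocks, function(b) ncol(b$values), 0L))
  in_block <- which(block_index == spec$influential_block)
  s <- apply(X[, in_block, drop = FALSE], 2, stats::sd)
  eligible <- in_block[s >= spec$min_sigma]
  if (length(eligible) == 0) stop("influential block has no varying columns")
  region <- eligible[order(s[s >= spec$min_sigma],
                           decreasing = TRUE)[seq_len(min(spec$region_size,
                                                          length(eligible)))]]
  .with_seed(spec$seed + 1L, {
    # plant the response on the leading principal directions of the
    # region, so its latent dimension equals planted_ncomp by construction
    Xr <- scale(X[, region, drop = FALSE], center = TRUE, scale = FALSE)
    k <- min(spec$planted_ncomp, length(region), nrow(Xr) - 1L)
    V <- svd(Xr, nu = 0, nv = k)$v
    beta <- numeric(ncol(X))
    beta[region] <- as.numeric(V %*% (stats::rnorm(k) * 2^(-(seq_len(k) - 1))))
    signal <- as.numeric(X %*% beta)
    if (diff(range(signal)) < 1e-12) stop("degenerate planted signal")
    a <- diff(spec$activity_range) / diff(range(signal))
    b <- spec$activity_range[1] - a * min(signal)
    eps <- stats::rnorm(length(molecules), 0, spec$noise_sd)
    pic50 <- a * signal + b + eps
    out <- data.frame(compound_id = vapply(molecules, function(m) m$name, ""),
                      ic50_uM = 10^(6 - pic50),
                      pic50 = pic50, subset = "train",
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(beta = a * beta, intercept = b,
                               region = region,
                               block = spec$influential_block,
                               noise = eps,
                               planted_ncomp = spec$planted_ncomp)
    attr(out, "blocks") <- blocks
    out
  })
}

#' Generate orbital/population fixtures with known descriptors
#'
#' Frontier energies are sampled in a chemically plausible window
#' (HOMO in -8..-4 eV, LUMO above it but below -0.2 eV); population
#' vectors are consistent with adding/removing exactly one electron, so
#' the condensed Fukui functions sum to 1 by construction.  Ground-truth
#' global descriptors (computed directly from the defining formulas) are
#' attached as the `truth` attribute.
#'
#' @param n number of fixtures.
#' @param seed integer seed.
#' @param plant optional data frame with columns `compound_id`,
#'   `e_homo`, `e_lumo` (eV): fixtures appended with exactly these
#'   frontier energies.
#' @return list of [orbital_data()] with a `truth` data frame attribute.
#' @export
make_orbital_fixtures <- function(n, seed = 1, plant = NULL) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      e_homo <- stats::runif(1, -8, -4)
      e_lumo <- stats::runif(1, e_homo + 0.5, min(e_homo + 5, -0.2))
      n_at <- sample(5:12, 1)
      pN <- stats::runif(n_at, 0.5, 7)
      dplus <- stats::runif(n_at); dplus <- dplus / sum(dplus)
      dminus <- stats::runif(n_at); dminus <- dminus / sum(dminus)
      out[[i]] <- orbital_data(
        sprintf("synth%02d", i), e_homo, e_lumo,
        populations = list(N = pN, N_plus_1 = pN + dplus,
                           N_minus_1 = pN - dminus))
    }
    if (!is.null(plant)) {
      for (k in seq_len(nrow(plant))) {
        out[[n + k]] <- orbital_data(plant$compound_id[k],
                                     plant$e_homo[k], plant$e_lumo[k])
      }
    }
    truth <- do.call(rbind, lapply(out, function(d) {
      I <- -d$e_homo; A <- -d$e_lumo
      mu <- -(I + A) / 2; eta <- I - A
      data.frame(compound_id = d$compound_id, mu = mu, eta = eta,
                 softness = 1 / eta, omega = mu^2 / (2 * eta),
                 stringsAsFactors = FALSE)
    }))
    attr(out, "truth") <- truth
    out
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the aligned series as SDF, the activity table as CSV and the
#' planted truth as JSON (the generator's contract for downstream tools).
#'
#' @param spec a [synthetic_series_spec()].
#' @param dir output directory (created).
#' @return invisibly, a list with the file paths.
#' @export
write_synthetic_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mols <- make_aligned_series(spec)
  act <- make_field_activity(mols, spec)
  truth <- attr(act, "truth")
  paths <- list(structures = file.path(dir, "series.sdf"),
                activities = file.path(dir, "activities.csv"),
                truth = file.path(dir, "truth.json"))
  write_sdf(mols, paths$structures)
  utils::write.csv(act[, c("compound_id", "ic50_uM", "subset")],
                   paths$activities, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(beta = truth$beta, intercept = truth$intercept,
                            region = truth$region, block = truth$block,
                            planted_ncomp = truth$planted_ncomp,
                            noise_sd = spec$noise_sd, seed = spec$seed),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
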