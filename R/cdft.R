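# Conceptual-DFT reactivity descriptors from frontier-orbital energies
# and atomic electron populations.
#
# Global descriptors (all in eV, softness in 1/eV) use the finite
# difference / Koopmans approximations: I = -E_HOMO, A = -E_LUMO,
# chemical potential mu = -(I + A)/2, electronegativity chi = -mu,
# hardness eta = I - A, softness S = 1/eta, electrophilicity
# omega = mu^2 / (2 eta).  Local descriptors are the condensed Fukui
# functions: f+(k) = q_k(N+1) - q_k(N) for nucleophilic attack,
# f-(k) = q_k(N) - q_k(N-1) for electrophilic attack, with q_k the
# electron population at atom k.

HARTREE_EV <- 27.211386

#' Ionization potential and electron affinity by Koopmans' theorem
#'
#' @param e_homo,e_lumo frontier orbital energies in eV.
#' @return list with `I` (= -e_homo) and `A` (= -e_lumo), in eV.
#' @export
koopmans_ia <- function(e_homo, e_lumo) {
  if (!all(is.finite(c(e_homo, e_lumo)))) stop("orbital energies must be finite")
  list(I = -e_homo, A = -e_lumo)
}

#' Global reactivity descriptors from I and A
#'
#' @param I ionization potential, eV.
#' @param A electron affinity, eV.
#' @return list with `mu`, `chi`, `eta` (eV), `softness` (1/eV) and
#'   `omega` (eV).  Zero hardness (degenerate frontier orbitals) is an
#'   error since softness and electrophilicity are then undefined.
#' @export
global_descriptors <- function(I, A) {
  mu <- -(I + A) / 2
  eta <- I - A
  if (any(eta == 0))
    stop("hardness is zero: softness and electrophilicity undefined")
  list(mu = mu, chi = -mu, eta = eta, softness = 1 / eta,
       omega = mu^2 / (2 * eta))
}

#' Frontier orbital energies implied by (mu, eta)
#'
#' Inverts the finite-difference relations: `e_homo = mu - eta/2`,
#' `e_lumo = mu + eta/2`.  Useful for driving the descriptor chain from
#' published (mu, eta) pairs.
#'
#' @param mu chemical potential, eV.
#' @param eta hardness, eV.
#' @return list with `e_homo` and `e_lumo` in eV.
#' @export
frontier_from_mu_eta <- function(mu, eta) {
  list(e_homo = mu - eta / 2, e_lumo = mu + eta / 2)
}

#' Orbital/population data container
#'
#' @param compound_id label.
#' @param e_homo,e_lumo frontier orbital energies in eV
#'   (`e_lumo >= e_homo`).
#' @param populations optional named list with per-atom electron
#'   population vectors `N`, `N_plus_1`, `N_minus_1` (equal length).
#' @param atom_labels optional atom labels (element + index).
#' @return object of class `orbital_data`.
#' @export
orbital_data <- function(compound_id, e_homo, e_lumo, populations = NULL,
                         atom_labels = NULL) {
  stopifnot(is.finite(e_homo), is.finite(e_lumo))
  if (e_lumo < e_homo) stop("e_lumo must be >= e_homo")
  if (!is.null(populations)) {
    lens <- lengths(populations)
    if (length(unique(lens)) > 1)
      stop("population vectors of unequal length")
    if (is.null(atom_labels))
      atom_labels <- paste0("atom", seq_len(lens[1]))
  }
  structure(list(compound_id = compound_id, e_homo = e_homo,
                 e_lumo = e_lumo, populations = populations,
                 atom_labels = atom_labels),
            class = "orbital_data")
}

#' @export
print.orbital_data <- function(x, ...) {
  cat(sprintf("<orbital_data> %s: E_HOMO %.4f eV, E_LUMO %.4f eV%s\n",
              x$compound_id, x$e_homo, x$e_lumo,
              if (is.null(x$populations)) "" else
                sprintf(", populations for %d atoms",
                        length(x$populations[[1]]))))
  invisible(x)
}

#' Condensed Fukui functions
#'
#' Elementwise finite differences of atomic electron populations between
#' the N-electron state and its ions.  The atom with the largest f+ is
#' flagged as the preferred site of nucleophilic attack, the largest f-
#' as the preferred electrophilic-attack site.
#'
#' @param data an [orbital_data()] with populations; `N_plus_1` is
#'   required for f+, `N_minus_1` for f-.
#' @param convention `"population"` (default; q_k are electron
#'   populations) or `"charge"` (q_k are partial charges, which flips the
#'   sign of both differences).
#' @return data frame with `atom`, `f_plus`, `f_minus` plus attributes
#'   `site_nucleophilic` and `site_electrophilic` (argmax labels).
#' @export
fukui_functions <- function(data, convention = c("population", "charge")) {
  convention <- match.arg(convention)
  pop <- data$populations
  if (is.null(pop)) stop("no population data for ", data$compound_id)
  for (need in c("N", "N_plus_1", "N_minus_1"))
    if (is.null(pop[[need]]))
      stop("missing population vector '", need, "' for ", data$compound_id)
  sgn <- if (convention == "population") 1 else -1
  f_plus <- sgn * (pop$N_plus_1 - pop$N)
  f_minus <- sgn * (pop$N - pop$N_minus_1)
  out <- data.frame(atom = data$atom_labels, f_plus = f_plus,
                    f_minus = f_minus, stringsAsFactors = FALSE)
  attr(out, "site_nucleophilic") <- data$atom_labels[which.max(f_plus)]
  attr(out, "site_electrophilic") <- data$atom_labels[which.max(f_minus)]
  out
}

#' Parse an orbital-data file
#'
#' Two formats: the package's native JSON schema
#' (`{compound_id, e_homo_eV | e_homo_hartree, e_lumo_eV | ...,
#' populations: {N, N_plus_1, N_minus_1}, atom_labels}`), or a
#' Gaussian-style quantum-chemistry log (`qm-log`) from which the HOMO
#' and LUMO are read off the occupied/virtual "Alpha" eigenvalue lines
#' (hartree, converted at 27.211386 eV/hartree).
#'
#' @param path file path.
#' @param format `"native-json"` or `"qm-log"`.
#' @return an [orbital_data()].
#' @export
parse_orbital_file <- function(path, format = c("native-json", "qm-log")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "native-json") {
    j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    pick <- function(ev, hartree) {
      if (!is.null(j[[ev]])) return(as.numeric(j[[ev]]))
      if (!is.null(j[[hartree]])) return(as.numeric(j[[hartree]]) * HARTREE_EV)
      stop("missing ", ev, " / ", hartree, " in ", path)
    }
    e_homo <- pick("e_homo_eV", "e_homo_hartree")
    e_lumo <- pick("e_lumo_eV", "e_lumo_hartree")
    pops <- NULL
    if (!is.null(j$populations)) {
      pops <- lapply(j$populations, as.numeric)
      names(pops) <- names(j$populations)
    }
    orbital_data(j$compound_id %||% basename(path), e_homo, e_lumo,
                 pops, j$atom_labels)
  } else {
    lines <- readLines(path, warn = FALSE)
    occ <- grep("Alpha\\s+occ\\. eigenvalues", lines, value = TRUE)
    vir <- grep("Alpha\\s*virt\\. eigenvalues", lines, value = TRUE)
    if (length(occ) == 0 || length(vir) == 0)
      stop("no HOMO/LUMO eigenvalue lines found in ", path)
    nums <- function(s) as.numeric(unlist(regmatches(s,
      gregexpr("-?[0-9]+\\.[0-9]+", s))))
    e_homo <- max(nums(occ)) * HARTREE_EV
    e_lumo <- min(nums(vir)) * HARTREE_EV
    orbital_data(sub("\\.[^.]*$", "", basename(path)), e_homo, e_lumo)
  }
}

#' Global reactivity descriptor report
#'
#' One row per compound with mu, eta, softness and omega, computed
#' through the Koopmans chain from the frontier orbital energies and
#' rounded half-even to 4 decimals for display (full precision is
#' available by setting `digits = NA`).  The row with the largest
#' electrophilicity is flagged in the `max_omega` column.
#'
#' @param data list of [orbital_data()].
#' @param digits decimals for rounding (default 4; `NA` for none).
#' @return data frame: `compound_id`, `mu`, `eta`, `softness`, `omega`,
#'   `max_omega`.
#' @export
descriptor_table <- function(data, digits = 4) {
  if (length(data) == 0) stop("no orbital data")
  rows <- lapply(data, function(d) {
    ia <- koopmans_ia(d$e_homo, d$e_lumo)
    g <- global_descriptors(ia$I, ia$A)
    data.frame(compound_id = d$compound_id, mu = g$mu, eta = g$eta,
               softness = g$softness, omega = g$omega,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$max_omega <- seq_len(nrow(tab)) == which.max(tab$omega)
  if (!is.na(digits))
    for (cl in c("mu", "eta", "softness", "omega"))
      tab[[cl]] <- round(tab[[cl]], digits)
  rownames(tab) <- NULL
  tab
}

#' Check published descriptor values for rounding self-consistency
#'
#' Recomputes softness and electrophilicity from a table's (mu, eta)
#' pairs and compares with the published values at 4 decimals.  Rows
#' whose published omega or S differ from the recomputed value (typically
#' by one unit in the 4th decimal, from rounding of unrounded upstream
#' values) are flagged rather than corrected.
#'
#' @param reference data frame with columns `compound_id`, `mu_eV`,
#'   `eta_eV`, `softness_published`, `omega_published`; defaults to the
#'   bundled thienopyridine reference ([reactivity_reference()]).
#' @return the table augmented with `softness_computed`,
#'   `omega_computed`, `softness_consistent`, `omega_consistent`.
#' @export
reactivity_consistency <- function(reference = reactivity_reference()) {
  fr <- frontier_from_mu_eta(reference$mu_eV, reference$eta_eV)
  out <- reference
  sc <- oc <- numeric(nrow(reference))
  for (i in seq_len(nrow(reference))) {
    ia <- koopmans_ia(fr$e_homo[i], fr$e_lumo[i])
    g <- global_descriptors(ia$I, ia$A)
    sc[i] <- g$softness; oc[i] <- g$omega
  }
  out$softness_computed <- round(sc, 4)
  out$omega_computed <- round(oc, 4)
  out$softness_consistent <-
    abs(out$softness_computed - out$softness_published) < 5e-5
  out$omega_consistent <-
    abs(out$omega_computed - out$omega_published) < 5e-5
  out
}
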