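# Dataset input/output: molecular structure files, activity tables and the
# pIC50 transform.  SDF parsing is delegated to ChemmineR; MOL2 is parsed
# directly because the Tripos ATOM block is the only interchange format
# here that carries partial charges, which a conversion would discard.

#' Read small-molecule structures from SDF or MOL2
#'
#' Returns one [molecule()] per well-formed record.  Records without 3D
#' coordinates (all-zero coordinate block) are rejected per record with a
#' warning rather than failing the whole file.  Partial charges are taken
#' from the file when present (`ATOM_PARTIAL_CHARGES` data field for SDF,
#' the charge column for MOL2); otherwise they are computed with the
#' MMFF94 charge model via Open Babel and the provenance is recorded in
#' the `charge_source` attribute of each molecule.
#'
#' @param path path to an existing file.
#' @param format `"sdf"` (MDL V2000) or `"mol2"` (Tripos).
#' @param compute_charges compute MMFF94 charges when the file has none?
#' @return list of `qsar_molecule`.
#' @export
read_structures <- function(path, format = c("sdf", "mol2"),
                            compute_charges = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0 || !any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    warning("empty structure file: ", path)
    return(list())
  }
  mols <- switch(format, sdf = .read_sdf(path), mol2 = .read_mol2(path))
  kept <- list()
  for (mol in mols) {
    xyz <- coords_of(mol)
    if (all(abs(xyz) < 1e-12)) {
      warning("rejecting record '", mol$name, "': no 3D coordinates")
      next
    }
    if (attr(mol, "charge_source") == "none" && compute_charges) {
      mol <- .mmff94_charges(mol)
    }
    kept[[length(kept) + 1L]] <- mol
  }
  kept
}

.read_sdf <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- if (nrow(bb) > 0) {
      data.frame(i = bb[, 1], j = bb[, 2], order = bb[, 3])
    } else NULL
    name <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(name) || !nzchar(name)) name <- paste0("mol", k)
    charges <- NULL; src <- "none"
    db <- tryCatch(ChemmineR::datablock(sdf), error = function(e) NULL)
    if (!is.null(db) && "ATOM_PARTIAL_CHARGES" %in% names(db)) {
      fields <- strsplit(trimws(db[["ATOM_PARTIAL_CHARGES"]]), "\\s+")[[1]]
      fields <- fields[fields != "__"]   # ChemmineR's multi-line separator
      v <- as.numeric(fields)
      # stored as interleaved "index charge" pairs
      if (length(v) == 2 * nrow(ab)) {
        charges <- v[seq(2, length(v), by = 2)]
        src <- "file"
      }
    }
    out[[k]] <- molecule(name, elements, ab[, 1:3], charges, bonds,
                         charge_source = src)
  }
  out
}

.read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("no @<TRIPOS>MOLECULE record in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    name <- trimws(blk[2])
    a0 <- grep("^@<TRIPOS>ATOM", blk)[1]
    b0 <- grep("^@<TRIPOS>BOND", blk)[1]
    if (is.na(a0)) stop("MOL2 record without ATOM block: ", name)
    aend <- if (!is.na(b0)) b0 - 1L else length(blk)
    arec <- blk[(a0 + 1L):aend]
    arec <- arec[nzchar(trimws(arec)) & !grepl("^@", arec)]
    f <- strsplit(trimws(arec), "\\s+")
    elements <- vapply(f, function(r) sub("\\..*$", "", r[6]), "")
    coords <- t(vapply(f, function(r) as.numeric(r[3:5]), numeric(3)))
    has_charge <- all(vapply(f, length, 0L) >= 9)
    charges <- if (has_charge) vapply(f, function(r) as.numeric(r[9]), 0) else NULL
    bonds <- NULL
    if (!is.na(b0) && b0 < length(blk)) {
      brec <- blk[(b0 + 1L):length(blk)]
      brec <- brec[nzchar(trimws(brec)) & !grepl("^@", brec)]
      if (length(brec) > 0) {
        bf <- strsplit(trimws(brec), "\\s+")
        ord <- vapply(bf, function(r) r[4], "")
        ord[ord %in% c("ar", "am", "Ar")] <- "1"  # aromatic/amide kept as single
        ord[!grepl("^[0-9]+$", ord)] <- "1"
        bonds <- data.frame(i = vapply(bf, function(r) as.integer(r[2]), 0L),
                            j = vapply(bf, function(r) as.integer(r[3]), 0L),
                            order = as.integer(ord))
      }
    }
    out[[k]] <- molecule(name, elements, coords, charges, bonds,
                         charge_source = if (has_charge) "file" else "none")
  }
  out
}

# MMFF94 partial charges through the Open Babel CLI; leaves charges at
# zero (source "none") with a warning when obabel is not on the PATH.
.mmff94_charges <- function(mol) {
  if (!nzchar(Sys.which("obabel"))) {
    warning("obabel not found; charges left at zero for ", mol$name)
    return(mol)
  }
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(fin, fout)))
  write_sdf(mol, fin)
  status <- suppressWarnings(system2(
    "obabel", c(fin, "-omol2", "-O", fout, "--partialcharge", "mmff94"),
    stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(fout)) {
    warning("MMFF94 charge computation failed for ", mol$name)
    return(mol)
  }
  parsed <- .read_mol2(fout)[[1]]
  mol$atoms$charge <- parsed$atoms$charge
  attr(mol, "charge_source") <- "mmff94"
  mol
}

#' Convert IC50 in micromolar to pIC50
#'
#' `pIC50 = -log10(IC50 [mol/L])`, i.e. `-log10(ic50_uM * 1e-6)`.  Full
#' precision is returned; use [format_pic50()] for 2-decimal display.
#'
#' @param ic50_uM IC50 in micromolar, strictly positive.
#' @return pIC50 in log units.
#' @examples
#' to_pic50(1)     # 6
#' to_pic50(16.9)  # 4.7721...
#' @export
to_pic50 <- function(ic50_uM) {
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0))
    stop("ic50_uM must be finite and > 0")
  -log10(ic50_uM * 1e-6)
}

#' Format pIC50 for reporting
#'
#' Published activity tables in this area commonly truncate rather than
#' round (e.g. IC50 12.7 uM, pIC50 4.8962, printed 4.89), so the report
#' writer floors at two decimals by default.
#'
#' @param pic50 numeric vector.
#' @param digits decimals kept.
#' @param truncate floor (TRUE, default) or round?
#' @export
format_pic50 <- function(pic50, digits = 2, truncate = TRUE) {
  m <- 10^digits
  v <- if (truncate) floor(pic50 * m) / m else round(pic50 * m) / m
  sprintf(paste0("%.", digits, "f"), v)
}

#' Read a compound activity table
#'
#' Expects a CSV with columns `compound_id`, `ic50_uM` and optionally
#' `subset` (`train`/`test`; defaults to `train`).  Rows with missing or
#' non-positive IC50 are dropped with a warning; duplicate compound ids
#' are an error.
#'
#' @param path CSV file path.
#' @return data frame with columns `compound_id`, `ic50_uM`, `pic50`,
#'   `subset`.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "ic50_uM")
  if (!all(need %in% names(df)))
    stop("activity table needs columns: ", paste(need, collapse = ", "))
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id: ",
         paste(unique(df$compound_id[duplicated(df$compound_id)]), collapse = ", "))
  bad <- !is.finite(df$ic50_uM) | df$ic50_uM <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with missing/non-positive ic50_uM: ",
            paste(df$compound_id[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable rows in ", path)
  if (is.null(df$subset)) df$subset <- "train"
  df$subset[is.na(df$subset) | !nzchar(df$subset)] <- "train"
  if (!all(df$subset %in% c("train", "test")))
    stop("subset labels must be 'train' or 'test'")
  df$pic50 <- to_pic50(df$ic50_uM)
  rownames(df) <- NULL
  df[, c("compound_id", "ic50_uM", "pic50", "subset")]
}

#' Partition compound records into training and test sets
#'
#' @param records data frame with a `compound_id` column.
#' @param test_ids compound ids forming the test set; must all exist.
#' @return list with elements `train` and `test`; row order preserved.
#' @export
split_train_test <- function(records, test_ids) {
  test_ids <- as.character(test_ids)
  unknown <- setdiff(test_ids, records$compound_id)
  if (length(unknown) > 0)
    stop("unknown test id(s): ", paste(unknown, collapse = ", "))
  is_test <- records$compound_id %in% test_ids
  records$subset <- ifelse(is_test, "test", "train")
  list(train = records[!is_test, , drop = FALSE],
       test = records[is_test, , drop = FALSE])
}

#' Bundled thienopyridine IKK-beta inhibitor data
#'
#' Accessors for the package's curated 46-compound thienopyridine
#' IKK-beta inhibition series: the IC50/subset activity table
#' (`thienopyridine_activity()`, with the published 35/11 train/test
#' split), the published experimental and model-predicted pIC50 values
#' (`thienopyridine_predictions()`) and published global reactivity
#' descriptors for the ten-compound molecular quantum subset
#' (`reactivity_reference()`).
#'
#' @return data frames (see each accessor's columns).
#' @export
thienopyridine_activity <- function() {
  read_activity_table(system.file("extdata", "thienopyridine_activity.csv",
                                  package = "qsar3d", mustWork = TRUE))
}

#' @rdname thienopyridine_activity
#' @export
thienopyridine_predictions <- function() {
  utils::read.csv(system.file("extdata", "thienopyridine_predictions.csv",
                              package = "qsar3d", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname thienopyridine_activity
#' @export
reactivity_reference <- function() {
  utils::read.csv(system.file("extdata", "thienopyridine_reactivity.csv",
                              package = "qsar3d", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
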