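# End-to-end orchestration: dataset -> alignment -> fields -> PLS ->
# reports/contours, and the reactivity-descriptor run, from one flat
# key=value config.  Every output directory gets a JSON manifest with
# the resolved config and its hash so runs are reproducible.

.default_config <- list(
  structures = NULL,        # SDF path (aligned or to be aligned)
  activities = NULL,        # activity CSV path
  synthetic = FALSE,        # generate a synthetic bundle instead
  n_compounds = 46,
  noise_sd = 0.1,
  align = TRUE,             # MCS-align onto the template?
  template = NULL,          # template compound id; default: most active
  method = "comfa",         # comma-separated subset of comfa,comsia
  spacing = 0.6, margin = 4.0, alpha = 0.3,
  min_sigma = 2.0,          # CoMFA column filter, kcal/mol
  min_sigma_comsia = 0.02,  # CoMSIA filter, similarity-index units
  max_components = 10, ncomp = NA,
  favored_pct = 80, disfavored_pct = 20,
  write_contours = TRUE,
  test_ids = NULL,          # comma-separated ids to relabel as test
  orbitals = NULL,          # JSON orbital files (cdft run)
  out = "qsar3d_out", seed = 1)

#' Read a flat key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment.  Unknown keys
#' are an error; values are coerced to the default's type.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file.
#' @return complete config list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- val
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    if (!is.null(overrides[[key]])) cfg[[key]] <- overrides[[key]]
  }
  for (key in c("n_compounds", "max_components", "seed"))
    cfg[[key]] <- as.integer(cfg[[key]])
  for (key in c("noise_sd", "spacing", "margin", "alpha", "min_sigma",
                "min_sigma_comsia", "favored_pct", "disfavored_pct"))
    cfg[[key]] <- as.numeric(cfg[[key]])
  cfg$ncomp <- suppressWarnings(as.integer(cfg$ncomp))
  for (key in c("synthetic", "align", "write_contours"))
    cfg[[key]] <- as.logical(cfg[[key]])
  cfg
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(vapply(names(cfg)[order(names(cfg))], function(k)
    paste0(k, "=", paste(format(cfg[[k]]), collapse = ",")), ""), f)
  unname(tools::md5sum(f))
}

.write_manifest <- function(cfg, dir, extra = list()) {
  jsonlite::write_json(
    c(list(config = cfg[!vapply(cfg, is.null, TRUE)],
           config_hash = .config_hash(cfg),
           package = "qsar3d",
           version = as.character(utils::packageVersion("qsar3d"))),
      extra),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Write the model-statistics report CSV
#'
#' Two-column `item,value` layout in the conventional order: component
#' count, q2, r2, SEE, SEP, F, then one field-fraction row per block.
#'
#' @param model a `qsar_pls`.
#' @param path output CSV path.
#' @export
write_stats_csv <- function(model, path) {
  s <- model$stats
  rows <- data.frame(
    item = c("Optimum Number of Components",
             "Cross-Validated Coefficient (q2)",
             "Non-Cross-Validated Validation Coefficient (r2)",
             "Standard Error of Estimate",
             "Standard Error of Prediction",
             "Fischer Statistic Value",
             paste("Fraction of Field Contribution:",
                   names(s$field_fractions))),
    value = c(s$onc, round(s$q2, 3), round(s$r2, 3), round(s$see, 3),
              round(s$sep, 3), round(s$f_value, 2),
              round(unname(s$field_fractions), 3)),
    stringsAsFactors = FALSE)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the experimental-versus-predicted report CSV
#'
#' Columns `compound_id, experimental_pic50, predicted_pic50, residual,
#' subset`; pIC50 values are displayed with the 2-decimal truncation
#' convention of the bundled activity table, residuals at 2 decimals.
#'
#' @param model a `qsar_pls`.
#' @param path output CSV path.
#' @param truncate floor experimental/predicted at 2 decimals (default
#'   TRUE)?
#' @export
write_predictions_csv <- function(model, path, truncate = TRUE) {
  tab <- prediction_table(model)
  out <- data.frame(
    compound_id = tab$compound_id,
    experimental_pic50 = format_pic50(tab$experimental_pic50,
                                      truncate = truncate),
    predicted_pic50 = format_pic50(tab$predicted_pic50,
                                   truncate = truncate),
    residual = sprintf("%.2f", tab$residual),
    subset = tab$subset, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full 3D-QSAR pipeline
#'
#' Reads (or synthesises) structures and activities, aligns the series
#' onto the template (the most active compound unless configured
#' otherwise), computes the configured field sets, fits one PLS model per
#' method, and writes per-method statistics and prediction CSVs, contour
#' cube files and a manifest into the output directory.
#'
#' @param config a config list ([read_run_config()]), a config file
#'   path, or `NULL` for defaults plus `...` overrides.
#' @param ... individual config overrides (e.g. `synthetic = TRUE`).
#' @return named list of fitted `qsar_pls` models, invisibly; the
#'   written file paths are in the `files` attribute.
#' @export
run_qsar <- function(config = NULL, ...) {
  cfg <- if (is.character(config)) read_run_config(config, list(...))
         else read_run_config(NULL, c(config, list(...)))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(cfg$synthetic)) {
    spec <- synthetic_series_spec(n_compounds = cfg$n_compounds,
                                  noise_sd = cfg$noise_sd, seed = cfg$seed,
                                  spacing = cfg$spacing, margin = cfg$margin)
    mols <- make_aligned_series(spec)
    records <- make_field_activity(mols, spec)
    cfg$align <- FALSE   # the generator emits a common frame already
    message("synthetic series: ", length(mols), " compounds")
  } else {
    if (is.null(cfg$structures) || is.null(cfg$activities))
      stop("config needs 'structures' and 'activities' (or synthetic = TRUE)")
    mols <- read_structures(cfg$structures, "sdf")
    records <- read_activity_table(cfg$activities)
    message("dataset: ", length(mols), " structures, ",
            nrow(records), " activity rows")
  }
  if (!is.null(cfg$test_ids)) {
    ids <- trimws(strsplit(as.character(cfg$test_ids), ",")[[1]])
    parts <- split_train_test(records, ids)
    records <- rbind(parts$train, parts$test)
  }

  if (isTRUE(cfg$align)) {
    tmpl_id <- cfg$template %||%
      records$compound_id[which.max(records$pic50)]
    tmpl_idx <- match(tmpl_id, vapply(mols, function(m) m$name, ""))
    if (is.na(tmpl_idx)) stop("template compound not found: ", tmpl_id)
    mols <- mcs_align_series(mols, mols[[tmpl_idx]])
    align_rep <- attr(mols, "alignment_report")
    utils::write.csv(align_rep, file.path(cfg$out, "alignment.csv"),
                     row.names = FALSE, quote = FALSE)
    message("alignment: ", nrow(align_rep), " compounds, max rmsd ",
            format(max(align_rep$rmsd), digits = 3))
  }

  grid <- build_grid(mols, margin = cfg$margin, spacing = cfg$spacing)
  methods <- trimws(strsplit(cfg$method, ",")[[1]])
  models <- list()
  files <- character(0)
  for (m in methods) {
    blocks <- assemble_descriptor_matrix(mols, grid, method = m,
                                         alpha = cfg$alpha)
    model <- qsar_pls(blocks, records,
                      ncomp = if (is.na(cfg$ncomp)) NULL else cfg$ncomp,
                      max_ncomp = cfg$max_components,
                      min_sigma = if (m == "comsia") cfg$min_sigma_comsia
                                  else cfg$min_sigma)
    message(sprintf("%s: ONC %d, q2 %.3f, r2 %.3f", m,
                    model$stats$onc, model$stats$q2, model$stats$r2))
    f_stats <- file.path(cfg$out, paste0("stats_", m, ".csv"))
    f_pred <- file.path(cfg$out, paste0("predictions_", m, ".csv"))
    write_stats_csv(model, f_stats)
    write_predictions_csv(model, f_pred)
    files <- c(files, f_stats, f_pred)
    if (isTRUE(cfg$write_contours)) {
      model_contours(model, cfg$favored_pct, cfg$disfavored_pct,
                     dir = cfg$out)
    }
    models[[m]] <- model
  }
  .write_manifest(cfg, cfg$out,
                  list(n_compounds = length(mols),
                       grid_dims = grid$dims, files = basename(files)))
  attr(models, "files") <- files
  invisible(models)
}

#' Run the reactivity-descriptor pipeline
#'
#' Parses orbital JSON files, writes the global descriptor table
#' (4-decimal layout, argmax-omega row flagged) and, for records with
#' population vectors, a per-atom Fukui CSV with the preferred attack
#' sites flagged.
#'
#' @param config config list/path as in [run_qsar()]; `orbitals` is a
#'   comma-separated list of native JSON files or a directory of them.
#' @param ... config overrides.
#' @return the descriptor table, invisibly.
#' @export
run_cdft <- function(config = NULL, ...) {
  cfg <- if (is.character(config)) read_run_config(config, list(...))
         else read_run_config(NULL, c(config, list(...)))
  if (is.null(cfg$orbitals)) stop("config needs 'orbitals'")
  paths <- trimws(strsplit(as.character(cfg$orbitals), ",")[[1]])
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.json$", full.names = TRUE)
  if (length(paths) == 0) stop("no orbital input files")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  data <- lapply(paths, parse_orbital_file)
  tab <- descriptor_table(data)
  utils::write.csv(tab, file.path(cfg$out, "descriptors.csv"),
                   row.names = FALSE, quote = FALSE)
  fukui_rows <- list()
  for (d in data) {
    if (is.null(d$populations)) next
    fk <- fukui_functions(d)
    fk$compound_id <- d$compound_id
    fk$site_nucleophilic <- fk$atom == attr(fk, "site_nucleophilic")
    fk$site_electrophilic <- fk$atom == attr(fk, "site_electrophilic")
    fukui_rows[[d$compound_id]] <- fk
  }
  if (length(fukui_rows) > 0) {
    fuk <- do.call(rbind, fukui_rows)
    fuk <- fuk[, c("compound_id", "atom", "f_plus", "f_minus",
                   "site_nucleophilic", "site_electrophilic")]
    utils::write.csv(fuk, file.path(cfg$out, "fukui.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  .write_manifest(cfg, cfg$out, list(n_compounds = length(data)))
  message("reactivity descriptors: ", nrow(tab), " compounds",
          if (length(fukui_rows)) paste0(", Fukui for ",
                                         length(fukui_rows)) else "")
  invisible(tab)
}
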