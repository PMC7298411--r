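#' Fit a field-based 3D-QSAR model
#'
#' The central fitting function of the package.  Takes the field blocks
#' of an aligned congeneric series (from [assemble_descriptor_matrix()])
#' and the activity table, applies minimum-sigma column filtering and
#' CoMFA-standard block scaling, selects the optimal number of PLS
#' components by leave-one-out cross-validation (unless `ncomp` is
#' given), and fits the final model.  The returned object carries the
#' cross-validated statistics (q2, SEP), training statistics (r2, SEE,
#' F), per-field contribution fractions and everything needed for
#' prediction and contour export.
#'
#' @param blocks named list of `qsar_field_block` (all on the same grid,
#'   same compound order), or a single numeric matrix.
#' @param records data frame with `compound_id`, `pic50` and `subset`
#'   columns (see [read_activity_table()]); only `subset == "train"` rows
#'   are used for fitting, in the order of the block rows.  Alternatively
#'   a bare numeric response vector for matrix input.
#' @param ncomp fixed number of components; `NULL` (default) selects the
#'   optimum by LOO q2.
#' @param max_ncomp search bound for the component selection (default 10).
#' @param min_sigma column-filter threshold (kcal/mol; default 2.0).
#'   Use 0 to disable filtering.
#' @return object of class `qsar_pls`.
#' @seealso [predict.qsar_pls()], [summary.qsar_pls()], [contour_maps()]
#' @export
qsar_pls <- function(blocks, records, ncomp = NULL, max_ncomp = 10,
                     min_sigma = 2.0) {
  if (is.matrix(blocks)) {
    blocks <- list(x = structure(list(values = blocks, field_kind = "x",
                                      method = "matrix", grid = NULL),
                                 class = "qsar_field_block"))
  }
  if (is.numeric(records)) {
    records <- data.frame(compound_id = as.character(seq_along(records)),
                          pic50 = records, subset = "train",
                          stringsAsFactors = FALSE)
  }
  ids <- rownames(blocks[[1]]$values)
  n_all <- nrow(blocks[[1]]$values)
  if (is.null(ids)) ids <- as.character(seq_len(n_all))
  rec <- records[match(ids, records$compound_id), , drop = FALSE]
  if (anyNA(rec$pic50))
    stop("activity missing for compound(s): ",
         paste(ids[is.na(rec$pic50)], collapse = ", "))
  train <- which(rec$subset == "train")
  if (length(train) < 3) stop("need at least 3 training compounds")

  X_all <- do.call(cbind, lapply(blocks, function(b) b$values))
  block_index_full <- rep(names(blocks),
                          vapply(blocks, function(b) ncol(b$values), 0L))
  X_train_full <- X_all[train, , drop = FALSE]
  mask <- if (min_sigma > 0) column_filter(X_train_full, min_sigma)
          else rep(TRUE, ncol(X_all))
  X <- X_train_full[, mask, drop = FALSE]
  bidx <- block_index_full[mask]
  y <- rec$pic50[train]

  if (is.null(ncomp)) {
    sel <- select_onc(X, y, max_ncomp, bidx)
    ncomp <- sel$onc
  } else {
    sel <- NULL
  }
  cv <- loo_q2(X, y, ncomp, bidx)
  fit <- fit_pls(X, y, ncomp, bidx)
  stats <- model_stats(fit, X, y)
  contrib <- field_contributions(fit, X)
  # blocks whose every column was filtered out still appear, at zero
  contrib <- stats::setNames(
    ifelse(names(blocks) %in% names(contrib),
           contrib[match(names(blocks), names(contrib))], 0),
    names(blocks))

  structure(list(
    fit = fit,
    method = blocks[[1]]$method,
    blocks = names(blocks),
    grid = blocks[[1]]$grid,
    column_mask = mask,
    records = rec,
    train_index = train,
    X_all_retained = X_all[, mask, drop = FALSE],
    stats = list(onc = ncomp, q2 = cv$q2, sep = cv$sep, press = cv$press,
                 r2 = stats$r2, see = stats$see, f_value = stats$f_value,
                 field_fractions = contrib,
                 q2_profile = if (!is.null(sel)) sel$q2_profile else NULL),
    min_sigma = min_sigma),
    class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  s <- x$stats
  cat(sprintf("3D-QSAR PLS model (%s, %d field block%s)\n", x$method,
              length(x$blocks), if (length(x$blocks) > 1) "s" else ""))
  cat(sprintf("  compounds: %d train / %d test; retained columns: %d\n",
              length(x$train_index), nrow(x$records) - length(x$train_index),
              sum(x$column_mask)))
  cat(sprintf("  components: %d   q2 (LOO): %.3f   r2: %.3f\n",
              s$onc, s$q2, s$r2))
  invisible(x)
}

#' Model summary in the conventional QSAR report layout
#'
#' @param object a `qsar_pls` model.
#' @param ... unused.
#' @export
summary.qsar_pls <- function(object, ...) {
  structure(list(model = object), class = "summary.qsar_pls")
}

#' @export
print.summary.qsar_pls <- function(x, ...) {
  m <- x$model; s <- m$stats
  cat(sprintf("Statistical parameters (%s)\n", toupper(m$method)))
  cat(sprintf("  Optimum Number of Components            %d\n", s$onc))
  cat(sprintf("  Cross-Validated Coefficient (q2)        %.3f\n", s$q2))
  cat(sprintf("  Non-Cross-Validated Coefficient (r2)    %.3f\n", s$r2))
  cat(sprintf("  Standard Error of Estimate              %.3f\n", s$see))
  cat(sprintf("  Standard Error of Prediction            %.3f\n", s$sep))
  cat(sprintf("  Fisher Statistic Value                  %.2f\n", s$f_value))
  cat("  Fraction of Field Contribution\n")
  for (b in names(s$field_fractions))
    cat(sprintf("    %-14s %5.1f %%\n", b, 100 * s$field_fractions[b]))
  invisible(x)
}

#' @export
coef.qsar_pls <- function(object, ...) {
  stats::setNames(object$fit$coefficients,
                  paste0(object$fit$block_index, "_",
                         sequence(table(factor(object$fit$block_index,
                                               levels = unique(object$fit$block_index))))))
}

#' Predict activities from a fitted QSAR model
#'
#' @param object a `qsar_pls` model.
#' @param newdata optional: a list of `qsar_field_block` on the model's
#'   grid, or a matrix over the full (unfiltered) columns, or a matrix
#'   with exactly the retained columns.  Defaults to all compounds the
#'   model was built with (train and test).
#' @param ... unused.
#' @return numeric vector of predicted pIC50.
#' @export
predict.qsar_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$X_all_retained
  } else {
    if (is.list(newdata) && !is.matrix(newdata))
      newdata <- do.call(cbind, lapply(newdata, function(b) b$values))
    newdata <- as.matrix(newdata)
    X <- if (ncol(newdata) == length(object$column_mask))
      newdata[, object$column_mask, drop = FALSE] else newdata
  }
  if (ncol(X) != length(object$fit$coefficients))
    stop("newdata has ", ncol(X), " columns; expected ",
         length(object$column_mask), " (full) or ",
         length(object$fit$coefficients), " (retained)")
  predict(object$fit, X)
}

#' @export
fitted.qsar_pls <- function(object, ...) {
  predict(object$fit,
          object$X_all_retained[object$train_index, , drop = FALSE])
}

#' @export
residuals.qsar_pls <- function(object, ...) {
  object$records$pic50[object$train_index] - fitted(object)
}

#' Experimental-versus-predicted table for a fitted model
#'
#' @param object a `qsar_pls` model.
#' @export
prediction_table <- function(object) {
  stopifnot(inherits(object, "qsar_pls"))
  predict_table(object$fit, object$records, object$X_all_retained)
}

#' Scatter plot of experimental versus predicted activity
#'
#' @param x a `qsar_pls` model.
#' @param ... forwarded to [graphics::plot()].
#' @method plot qsar_pls
#' @export
plot.qsar_pls <- function(x, ...) {
  tab <- prediction_table(x)
  lim <- range(c(tab$experimental_pic50, tab$predicted_pic50))
  graphics::plot(tab$experimental_pic50, tab$predicted_pic50,
                 pch = ifelse(tab$subset == "train", 19, 1),
                 xlim = lim, ylim = lim,
                 xlab = "experimental pIC50", ylab = "predicted pIC50", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", pch = c(19, 1), legend = c("train", "test"),
                   bty = "n")
  invisible(x)
}

#' Contour maps from a fitted QSAR model
#'
#' Convenience wrapper around [contour_maps()] using the model's own grid
#' and column mask; optionally writes one Gaussian cube file per field to
#' `dir`.
#'
#' @param object a `qsar_pls` model fitted from field blocks.
#' @param favored_pct,disfavored_pct percentile iso-levels.
#' @param dir optional output directory for cube files.
#' @export
model_contours <- function(object, favored_pct = 80, disfavored_pct = 20,
                           dir = NULL) {
  stopifnot(inherits(object, "qsar_pls"))
  if (is.null(object$grid)) stop("model was fitted from a bare matrix; no grid")
  maps <- contour_maps(object$fit, object$grid, object$column_mask,
                       object$X_all_retained[object$train_index, , drop = FALSE],
                       favored_pct, disfavored_pct)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (b in names(maps)) {
      write_cube(maps[[b]]$values, object$grid,
                 file.path(dir, paste0("contour_", object$method, "_", b, ".cube")),
                 comment = paste("stdev*coeff field:", b))
    }
  }
  maps
}
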