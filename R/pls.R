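# Partial least squares regression for field-based QSAR.
#
# The descriptor matrix is the column-wise concatenation of field blocks.
# Preprocessing follows the conventional CoMFA protocol: columns whose
# standard deviation falls below the minimum-sigma threshold are removed
# ("column filtering"), then each field block is scaled to equal total
# variance (block scaling) rather than per-column autoscaling, then
# columns and response are mean-centred.  The latent decomposition is
# NIPALS for a single response; with as many components as the rank of
# the centred matrix it reproduces ordinary least squares.

#' Minimum-sigma column filter
#'
#' Retains exactly the columns whose standard deviation is greater than
#' or equal to `min_sigma` (boundary inclusive).
#'
#' @param X numeric matrix (samples x columns).
#' @param min_sigma threshold on the column standard deviation, in the
#'   column's own units (kcal/mol for CoMFA fields); default 2.0.
#' @return logical column mask.
#' @export
column_filter <- function(X, min_sigma = 2.0) {
  if (!all(is.finite(X))) stop("X must be finite")
  sds <- apply(X, 2, stats::sd)
  mask <- sds >= min_sigma - 1e-12
  if (!any(mask))
    stop("column filtering removed every column; lower min_sigma (",
         min_sigma, ")")
  mask
}

# block scaling: divide each block's columns by the square root of the
# block's total variance, so every block contributes unit total variance
.block_scale_factors <- function(X, block_index) {
  sf <- numeric(ncol(X))
  for (b in unique(block_index)) {
    j <- block_index == b
    v <- sum(apply(X[, j, drop = FALSE], 2, stats::var))
    sf[j] <- if (v > 0) 1 / sqrt(v) else 1
  }
  sf
}

#' Fit a PLS regression (NIPALS, single response)
#'
#' @param X samples x columns matrix (already column-filtered if
#'   desired; see [column_filter()]).
#' @param y response vector.
#' @param n_components number of latent components.
#' @param block_index optional integer/character vector mapping each
#'   column to its field block; when given, CoMFA-standard block scaling
#'   is applied (each block scaled to equal total variance).
#' @return object of class `qsar_pls_fit` with weights, loadings,
#'   scores, regression coefficients on the original scale and an
#'   intercept.
#' @export
fit_pls <- function(X, y, n_components, block_index = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 samples")
  if (n_components < 1) stop("n_components must be >= 1")
  if (is.null(block_index)) block_index <- rep(1L, p)
  stopifnot(length(block_index) == p)

  x_center <- colMeans(X)
  x_scale <- .block_scale_factors(X, block_index)
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "*")
  y_center <- mean(y)
  E <- Xs; f <- y - y_center

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (a == 1) stop("response uncorrelated with X; cannot fit")
      stop("n_components = ", n_components,
           " exceeds the effective rank of the centred matrix")
    }
    w <- w / nw
    t_vec <- as.numeric(E %*% w)
    tt <- sum(t_vec^2)
    if (tt < 1e-12)
      stop("n_components = ", n_components,
           " exceeds the effective rank of the centred matrix")
    p_vec <- as.numeric(crossprod(E, t_vec)) / tt
    q[a] <- sum(f * t_vec) / tt
    E <- E - tcrossprod(t_vec, p_vec)
    f <- f - q[a] * t_vec
    W[, a] <- w; P[, a] <- p_vec; Tm[, a] <- t_vec
  }
  B_scaled <- W %*% solve(crossprod(P, W), q)
  coefficients <- as.numeric(B_scaled) * x_scale
  intercept <- y_center - sum(x_center * coefficients)

  structure(list(
    n_components = n_components,
    x_weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    coefficients = coefficients, intercept = intercept,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    block_index = block_index),
    class = "qsar_pls_fit")
}

#' @export
predict.qsar_pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validation
#'
#' Each sample is left out in turn and predicted from a model refitted on
#' the remaining `n - 1`; any column filtering is expected to have been
#' applied once to the full matrix beforehand and is held fixed across
#' folds.  `q2 = 1 - PRESS / sum((y - mean(y))^2)` and
#' `sep = sqrt(PRESS / (n - c - 1))`.
#'
#' @inheritParams fit_pls
#' @return list with `q2`, `sep`, `press` and the vector of LOO
#'   predictions.
#' @export
loo_q2 <- function(X, y, n_components, block_index = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components, block_index)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss,
       sep = sqrt(press / (n - n_components - 1)),
       press = press, predictions = pred)
}

#' Select the optimal number of components by LOO q2
#'
#' Evaluates `q2` for 1..`max_components` components (capped at the data's
#' limit `n - 2`) and returns the count maximising it; ties within
#' `1e-10` are broken toward fewer components.
#'
#' @inheritParams fit_pls
#' @param max_components upper bound on the component count.
#' @return list with `onc`, the `q2` profile and the winning `q2`.
#' @export
select_onc <- function(X, y, max_components, block_index = NULL) {
  if (max_components < 1) stop("max_components must be >= 1")
  n <- nrow(as.matrix(X))
  cmax <- min(max_components, n - 2L, ncol(as.matrix(X)))
  q2s <- rep(NA_real_, cmax)
  for (a in seq_len(cmax)) {
    q2s[a] <- tryCatch(loo_q2(X, y, a, block_index)$q2,
                       error = function(e) NA_real_)
    if (is.na(q2s[a])) { q2s <- q2s[seq_len(a - 1)]; break }
  }
  if (length(q2s) == 0) stop("no component count could be fitted")
  best <- which(q2s > max(q2s) - 1e-10)[1]
  list(onc = best, q2_profile = q2s, q2 = q2s[best])
}

#' Training-set model statistics
#'
#' `r2 = 1 - RSS/TSS`, `see = sqrt(RSS / (n - c - 1))` and the Fisher
#' statistic `F = [r2 / (1 - r2)] [(n - c - 1) / c]` with `c` the number
#' of components.  A perfect fit reports `f_value = Inf`.
#'
#' @param model a `qsar_pls_fit`.
#' @param X,y the training data the model was fitted on.
#' @return list with `r2`, `see`, `f_value`, `rss`, `n`, `n_components`.
#' @export
model_stats <- function(model, X, y) {
  pred <- predict(model, X)
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  n <- length(y); cc <- model$n_components
  see <- sqrt(rss / (n - cc - 1))
  f_value <- if (rss < 1e-300 || (1 - r2) < 1e-15) Inf
             else (r2 / (1 - r2)) * (n - cc - 1) / cc
  list(r2 = r2, see = see, f_value = f_value, rss = rss,
       n = n, n_components = cc)
}

#' Per-block field contribution fractions
#'
#' `fraction_b = sum_{j in b} |coef_j| sd_j / sum_j |coef_j| sd_j`, with
#' coefficients and standard deviations taken on the preprocessed
#' (block-scaled) descriptor scale, as in the conventional CoMFA report.
#'
#' @param model a `qsar_pls_fit`.
#' @param X the training matrix the model was fitted on.
#' @return named numeric vector of fractions summing to 1.
#' @export
field_contributions <- function(model, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, model$x_center), 2, model$x_scale, "*")
  sds <- apply(Xs, 2, stats::sd)
  coef_scaled <- model$coefficients / model$x_scale
  w <- abs(coef_scaled) * sds
  tot <- sum(w)
  fr <- vapply(split(w, model$block_index), sum, 0)
  if (tot > 0) fr / tot else fr * 0
}

#' Experimental-versus-predicted table
#'
#' One row per compound with `residual = experimental - predicted`
#' throughout (a single fixed sign convention for training and test
#' rows alike).
#'
#' @param model a `qsar_pls_fit`.
#' @param records data frame with `compound_id`, `pic50` and `subset`.
#' @param X_all descriptor rows aligned with `records`.
#' @return data frame: `compound_id`, `experimental_pic50`,
#'   `predicted_pic50`, `residual`, `subset`.
#' @export
predict_table <- function(model, records, X_all) {
  X_all <- as.matrix(X_all)
  if (nrow(X_all) != nrow(records))
    stop("X_all rows (", nrow(X_all), ") do not match records (",
         nrow(records), ")")
  pred <- predict(model, X_all)
  data.frame(compound_id = records$compound_id,
             experimental_pic50 = records$pic50,
             predicted_pic50 = pred,
             residual = records$pic50 - pred,
             subset = records$subset,
             stringsAsFactors = FALSE)
}

#' Contour maps of the fitted field model
#'
#' For every retained column the product of its standard deviation and
#' regression coefficient (the "stdev*coeff" field) is mapped back onto
#' the grid; filtered-out columns contribute zero.  Favoured and
#' disfavoured iso-levels are percentiles of the nonzero value
#' distribution (defaults 80 and 20).
#'
#' @param model a `qsar_pls_fit`.
#' @param grid the `qsar_grid` the blocks were computed on.
#' @param column_mask logical mask mapping retained columns back to the
#'   full block columns (as from [column_filter()]), one entry per
#'   original column over all blocks.
#' @param X retained training matrix (for the standard deviations).
#' @param favored_pct,disfavored_pct percentile levels in (0, 100).
#' @return list per field block: grid `values` vector (full grid),
#'   `favored_level`, `disfavored_level`.  Empty (all-zero) maps warn.
#' @export
contour_maps <- function(model, grid, column_mask, X,
                         favored_pct = 80, disfavored_pct = 20) {
  Xs <- sweep(sweep(as.matrix(X), 2, model$x_center), 2, model$x_scale, "*")
  sds <- apply(Xs, 2, stats::sd)
  vals_retained <- sds * (model$coefficients / model$x_scale)
  npts <- prod(grid$dims)
  blocks <- unique(model$block_index)
  mask_block <- rep(blocks, each = npts)[column_mask]
  out <- list()
  for (b in blocks) {
    full <- numeric(npts)
    sel_full <- which(rep(blocks, each = npts) == b & column_mask)
    full[sel_full - (match(b, blocks) - 1L) * npts] <-
      vals_retained[mask_block == b]
    nz <- full[full != 0]
    if (length(nz) == 0) {
      warning("all contour values zero for block ", b)
      out[[as.character(b)]] <- list(values = full,
                                     favored_level = NA_real_,
                                     disfavored_level = NA_real_)
      next
    }
    out[[as.character(b)]] <- list(
      values = full,
      favored_level = as.numeric(stats::quantile(nz, favored_pct / 100)),
      disfavored_level = as.numeric(stats::quantile(nz, disfavored_pct / 100)))
  }
  out
}
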