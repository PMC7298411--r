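test_that("column filtering keeps exactly the columns at or above min sigma", {
  X <- matrix_with_sds(20, c(1.9, 2.0, 2.1, 0))
  mask <- column_filter(X, 2.0)
  expect_identical(unname(mask), c(FALSE, TRUE, TRUE, FALSE))

  # brute-force oracle on a random matrix
  set.seed(8)
  Xr <- matrix(rnorm(200) * rep(runif(10, 0, 4), each = 20), 20)
  expect_identical(unname(column_filter(Xr, 1.0)),
                   unname(apply(Xr, 2, sd) >= 1.0))

  expect_error(column_filter(matrix_with_sds(10, c(0.1, 0.2)), 5), "lower")
})

test_that("PLS reproduces exact low-rank structure and OLS at full rank", {
  # rank-1 X with y an exact linear function: one component suffices
  set.seed(3)
  t1 <- rnorm(12)
  X1 <- outer(t1, c(1, -2, 0.5))
  y1 <- 3 * t1 + 1
  f1 <- fit_pls(X1, y1, 1)
  expect_equal(predict(f1, X1), y1, tolerance = 1e-10)

  # full-component PLS equals least squares on full-rank 10 x 4
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    fit <- fit_pls(X, y, 4)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(fit$intercept, ols[1], tolerance = 1e-8)
    expect_equal(fit$coefficients, ols[-1], tolerance = 1e-8)
  }

  # centring: shifting y shifts predictions by the same constant
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3); y <- rnorm(10)
  p1 <- predict(fit_pls(X, y, 2), X)
  p2 <- predict(fit_pls(X, y + 7, 2), X)
  expect_equal(p2 - p1, rep(7, 10), tolerance = 1e-10)

  expect_error(fit_pls(X, y, 9), "rank")
})

test_that("PLS predictions agree with an independent implementation", {
  set.seed(12)
  X <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(NULL, paste0("V", 1:6)))
  y <- X %*% rnorm(6) + rnorm(15, sd = 0.3)
  for (nc in c(1, 3)) {
    mine <- predict(fit_pls(X, y, nc), X)
    ref <- mixOmics::pls(X, data.frame(y = as.numeric(y)), ncomp = nc,
                         scale = FALSE, mode = "regression")
    theirs <- predict(ref, X)$predict[, 1, nc]
    expect_equal(mine, unname(theirs), tolerance = 1e-8)
  }
})

test_that("leave-one-out q2 equals an explicit n-refit loop", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 14
    X <- matrix(rnorm(n * 6), n, 6)
    y <- X %*% rnorm(6) + rnorm(n, sd = 0.5)
    res <- loo_q2(X, y, 2)
    # oracle: refit-and-predict loop written out longhand
    pred <- vapply(seq_len(n), function(i) {
      f <- fit_pls(X[-i, ], y[-i], 2)
      sum(X[i, ] * f$coefficients) + f$intercept
    }, 0)
    press <- sum((y - pred)^2)
    expect_equal(res$press, press, tolerance = 1e-10)
    expect_equal(res$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-10)
    expect_equal(res$sep, sqrt(press / (n - 3)), tolerance = 1e-10)
  }
})

test_that("q2 separates structure from noise", {
  spec <- synthetic_series_spec(n_compounds = 35, noise_sd = 0, seed = 2)
  mols <- make_aligned_series(spec)
  act <- make_field_activity(mols, spec)
  blocks <- attr(act, "blocks")
  X_full <- do.call(cbind, lapply(blocks, function(b) b$values))
  mask <- column_filter(X_full, 2.0)
  X <- X_full[, mask]
  y <- act$pic50
  expect_gt(loo_q2(X, y, spec$planted_ncomp)$q2, 0.99)

  set.seed(77)
  y_perm <- sample(y)
  expect_lt(loo_q2(X, y_perm, spec$planted_ncomp)$q2, 0.2)
})

test_that("component selection maximises q2 with ties toward fewer", {
  set.seed(5)
  X <- matrix(rnorm(16 * 5), 16, 5)
  y <- X %*% rnorm(5) + rnorm(16, sd = 0.2)
  sel <- select_onc(X, y, 4)
  profile <- vapply(1:4, function(a) loo_q2(X, y, a)$q2, 0)
  expect_equal(sel$q2_profile, profile, tolerance = 1e-12)
  expect_equal(sel$onc, which(profile > max(profile) - 1e-10)[1])
  expect_equal(select_onc(X, y, 1)$onc, 1)
})

test_that("training statistics follow the standard formulas", {
  set.seed(9)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  fit <- fit_pls(X, y, 2)
  s <- model_stats(fit, X, y)
  pred <- predict(fit, X)
  expect_equal(s$rss, sum((y - pred)^2), tolerance = 1e-12)
  expect_equal(s$r2, 1 - s$rss / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(s$see, sqrt(s$rss / (8 - 2 - 1)), tolerance = 1e-12)

  # F from r2: r2 = 0.5, n = 12, c = 1 gives F = 10
  expect_equal((0.5 / 0.5) * (12 - 1 - 1) / 1, 10)
  f_from_stats <- (s$r2 / (1 - s$r2)) * (8 - 2 - 1) / 2
  expect_equal(s$f_value, f_from_stats, tolerance = 1e-12)

  # perfect fit reports infinite F and zero SEE
  t1 <- rnorm(8); Xp <- outer(t1, c(1, 2)); yp <- 2 * t1
  sp <- model_stats(fit_pls(Xp, yp, 1), Xp, yp)
  expect_equal(sp$see, 0, tolerance = 1e-7)
  expect_true(is.infinite(sp$f_value))
  expect_equal(sp$r2, 1, tolerance = 1e-12)
})

test_that("field contributions are |coef|*sd weights normalised per block", {
  set.seed(10)
  Xa <- matrix(rnorm(30), 10, 3)
  X <- cbind(Xa, Xa)  # two identical blocks
  y <- Xa %*% c(1, -1, 0.5) + rnorm(10, sd = 0.1)
  bidx <- rep(c("a", "b"), each = 3)
  fit <- fit_pls(X, y, 2, bidx)
  fr <- field_contributions(fit, X)
  expect_equal(sum(fr), 1, tolerance = 1e-10)
  expect_equal(unname(fr["a"]), 0.5, tolerance = 1e-8)

  # random instances: fractions are a partition of unity
  for (seed in 1:3) {
    set.seed(seed)
    Xr <- matrix(rnorm(60), 10, 6)
    yr <- rnorm(10)
    fitr <- fit_pls(Xr, yr, 2, rep(1:2, each = 3))
    expect_equal(sum(field_contributions(fitr, Xr)), 1, tolerance = 1e-10)
  }
})

test_that("prediction tables keep the experimental-minus-predicted convention", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  rec <- data.frame(compound_id = letters[1:10], pic50 = y,
                    subset = rep(c("train", "test"), 5))
  fit <- fit_pls(X[rec$subset == "train", ], y[rec$subset == "train"], 2)
  tab <- predict_table(fit, rec, X)
  expect_equal(tab$residual, tab$experimental_pic50 - tab$predicted_pic50,
               tolerance = 1e-10)
  expect_identical(tab$subset, rec$subset)
  expect_error(predict_table(fit, rec, X[1:5, ]), "do not match")
})

test_that("contour maps place stdev*coeff values and percentile levels", {
  # planted single influential column in a 2-block layout over a tiny grid
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(2L, 2L, 2L)),
                 class = "qsar_grid")
  npts <- 8
  set.seed(14)
  X_full <- matrix(rnorm(12 * 2 * npts, sd = 0.5), 12, 2 * npts)
  X_full[, 3] <- rnorm(12, sd = 5)      # influential steric column
  y <- 2 * X_full[, 3] + rnorm(12, sd = 0.1)
  mask <- rep(TRUE, 2 * npts)
  bidx <- rep(c("steric", "electrostatic"), each = npts)
  fit <- fit_pls(X_full, y, 2, bidx)
  maps <- contour_maps(fit, g, mask, X_full, 95, 5)
  expect_named(maps, c("steric", "electrostatic"))
  expect_length(maps$steric$values, npts)
  # the planted column dominates the favoured contour
  expect_equal(which.max(abs(maps$steric$values)), 3)
  nz <- maps$steric$values[maps$steric$values != 0]
  expect_equal(maps$steric$favored_level,
               unname(quantile(nz, 0.95)), tolerance = 1e-12)
  expect_equal(maps$steric$disfavored_level,
               unname(quantile(nz, 0.05)), tolerance = 1e-12)

  # all-zero coefficients warn and give empty contours
  fit0 <- fit
  fit0$coefficients <- rep(0, length(fit0$coefficients))
  w <- capture_warnings(m0 <- contour_maps(fit0, g, mask, X_full))
  expect_true(all(grepl("zero", w)))
  expect_true(all(is.na(m0$steric$favored_level)))
})
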