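test_that("a constant-only fit reproduces the time-averaged spectrum", {
  st <- vector_stft(c(1, 2, 3))
  fit <- fit_glm(st, constant_design(3), make_contrasts(list(1), "mean"))
  expect_equal(unname(drop(fit$betas)), 2)
  expect_equal(unname(drop(fit$copes)), unname(welch_spectrum(st)$values[1, 1]))

  set.seed(41)
  st2 <- random_stft(K = 17, nf = 12, nc = 3)
  fit2 <- fit_glm(st2, constant_design(17), make_contrasts(list(1), "mean"))
  w <- welch_spectrum(st2)$values
  expect_lt(max(abs(drop(fit2$copes) - w) / abs(w)), 1e-12)
})

test_that("rank-deficient designs return the minimum-norm solution", {
  # duplicated constant column, data [2, 2]: min-norm splits equally
  dup <- assemble_design(list(
    finalize_regressor(rep(1, 2), "constant", "a"),
    finalize_regressor(rep(1, 2), "constant", "b")))
  fit <- fit_glm(vector_stft(c(2, 2)), dup)
  expect_equal(unname(drop(fit$betas)), c(1, 1))

  skip_if_not_installed("MASS")
  set.seed(42)
  for (i in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    X <- cbind(X, X[, 1] + X[, 2])  # engineered rank deficiency
    y <- rnorm(10)
    dm <- assemble_design(lapply(1:4, function(j) {
      finalize_regressor(X[, j], "confound_nonzero_mean", paste0("r", j))
    }))
    fit <- fit_glm(vector_stft(y), dm)
    oracle <- MASS::ginv(X) %*% y
    expect_equal(unname(drop(fit$betas)), drop(oracle), tolerance = 1e-8)
  }
})

test_that("full-rank fits equal the normal-equations solution with orthogonal residuals", {
  set.seed(43)
  X <- cbind(1, matrix(rnorm(60), 30, 2))
  dm <- assemble_design(list(
    finalize_regressor(rep(1, 30), "constant", "mean"),
    finalize_regressor(X[, 2], "confound_nonzero_mean", "c1"),
    finalize_regressor(X[, 3], "confound_nonzero_mean", "c2")))
  y <- rnorm(30, 5)
  fit <- fit_glm(vector_stft(y), dm)
  oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(drop(fit$betas)), drop(oracle), tolerance = 1e-10)

  r <- drop(glm_residuals(vector_stft(y), dm, fit$betas))
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
})

test_that("residuals are data minus model prediction", {
  st <- vector_stft(c(1, 2, 3))
  fit <- fit_glm(st, constant_design(3))
  expect_equal(drop(glm_residuals(st, fit$design, fit$betas)), c(-1, 0, 1))
  expect_equal(drop(fit$residuals), c(-1, 0, 1))

  # exact linear data leave zero residuals
  X <- cbind(1, c(-1, 0, 1, 2))
  dm <- assemble_design(list(
    finalize_regressor(rep(1, 4), "constant", "mean"),
    finalize_regressor(X[, 2], "parametric_demeaned", "rv")))
  y <- drop(X %*% c(3, 2))
  fit2 <- fit_glm(vector_stft(y), dm)
  expect_lt(max(abs(fit2$residuals)), 1e-12)
})

test_that("varcope equals the squared standard error and matches the full product", {
  st <- vector_stft(c(1, 2, 3))
  fit <- fit_glm(st, constant_design(3), make_contrasts(list(1), "mean"))
  expect_equal(fit$dof, 2)
  expect_equal(unname(drop(fit$sigma2)), 1)   # RSS 2 / dof 2
  expect_equal(unname(drop(fit$varcopes)), 1 / 3)  # SEM^2 of the mean

  # zero residuals give zero varcope
  fitz <- fit_glm(vector_stft(c(4, 4, 4)), constant_design(3),
                  make_contrasts(list(1), "mean"))
  expect_equal(unname(drop(fitz$varcopes)), 0)

  # diagonal-only computation vs the materialised Nc x Nc product
  set.seed(44)
  for (i in 1:10) {
    X <- cbind(1, matrix(rnorm(60), 20, 3))
    dm <- assemble_design(lapply(1:4, function(j) {
      finalize_regressor(X[, j], if (j == 1) "constant" else "confound_nonzero_mean",
                         paste0("r", j))
    }))
    Cm <- matrix(rnorm(12), 4, 3)
    cs <- make_contrasts(Cm, paste0("c", 1:3))
    diag_only <- unname(contrast_variance_weights(dm, cs))
    full <- diag(t(Cm) %*% solve(crossprod(X)) %*% Cm)
    expect_equal(diag_only, full, tolerance = 1e-12)
  }
})

test_that("contrast t-statistics reduce to the classical one- and two-sample tests", {
  fit <- fit_glm(vector_stft(c(1, 2, 3)), constant_design(3),
                 make_contrasts(list(1), "mean"))
  expect_equal(unname(drop(fit$tstats)), 2 / sqrt(1 / 3), tolerance = 1e-10)
  expect_equal(unname(drop(fit$tstats)), one_sample_t_oracle(c(1, 2, 3)))

  a <- c(1, 2, 3); b <- c(2, 3, 4)
  fit2 <- fit_glm(vector_stft(c(a, b)), two_group_design(3, 3),
                  make_contrasts(list(c(1, -1)), "a>b"))
  expect_equal(unname(drop(fit2$tstats)), two_sample_t_oracle(a, b),
               tolerance = 1e-10)
  expect_equal(unname(drop(fit2$tstats)),
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-10)

  set.seed(45)
  for (i in 1:200) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.5)
    fitr <- fit_glm(vector_stft(c(a, b)), two_group_design(n1, n2),
                    make_contrasts(list(c(1, -1)), "d"))
    expect_equal(unname(drop(fitr$tstats)), two_sample_t_oracle(a, b),
                 tolerance = 1e-8)
  }
})

test_that("cope arithmetic and degenerate-bin t flags behave as documented", {
  betas <- array(c(4, 6), dim = c(2, 1, 1))
  expect_equal(unname(drop(compute_cope(betas, make_contrasts(list(c(1, 0)), "sel")))), 4)
  expect_equal(unname(drop(compute_cope(betas, make_contrasts(list(c(1, -1)), "d")))), -2)
  expect_equal(unname(drop(compute_cope(betas, make_contrasts(list(c(0.5, 0.5)), "m")))), 5)

  expect_equal(drop(t_spectrum(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)))), 0)
  expect_equal(drop(t_spectrum(array(2, c(1, 1, 1)), array(0, c(1, 1, 1)))), Inf)
  expect_equal(drop(t_spectrum(array(-2, c(1, 1, 1)), array(0, c(1, 1, 1)))), -Inf)
})

test_that("R-squared uses mean-centred totals and flags zero-variance bins", {
  X <- cbind(1, c(-1, 0, 1, 2))
  dm <- assemble_design(list(
    finalize_regressor(rep(1, 4), "constant", "mean"),
    finalize_regressor(X[, 2], "parametric_demeaned", "rv")))
  y <- drop(X %*% c(3, 2))
  fit <- fit_glm(vector_stft(y), dm)
  expect_equal(unname(drop(fit$r2)), 1)

  fitc <- fit_glm(vector_stft(c(1, 2, 3)), constant_design(3))
  expect_equal(unname(drop(fitc$r2)), 0)

  expect_true(is.na(drop(fit_glm(vector_stft(rep(2, 3)),
                                 constant_design(3))$r2)))

  set.seed(46)
  st <- random_stft(25, 6)
  dm2 <- assemble_design(list(
    finalize_regressor(rep(1, 25), "constant", "mean"),
    finalize_regressor(rnorm(25), "parametric_demeaned", "x")))
  fit2 <- fit_glm(st, dm2)
  Y <- matrix(st$values, 25, 6)
  oracle <- vapply(1:6, function(j) {
    rss <- sum(fit2$residuals[, j, 1]^2)
    1 - rss / sum((Y[, j] - mean(Y[, j]))^2)
  }, numeric(1))
  expect_equal(drop(fit2$r2), oracle, tolerance = 1e-10)
})

test_that("Cohen's f2 compares nested fits and pools condition regressors", {
  # direct arithmetic: engineered R^2 pair 0.6 / 0.4 gives f2 = 0.5
  expect_equal((0.6 - 0.4) / (1 - 0.6), 0.5)

  set.seed(47)
  K <- 40
  open <- rep(c(1, 0), K / 2)
  st <- random_stft(K, 8)
  regs <- list(
    finalize_regressor(open, "categorical", "open"),
    finalize_regressor(1 - open, "categorical", "closed"),
    finalize_regressor(rnorm(K), "parametric_demeaned", "cov1"),
    finalize_regressor(abs(rnorm(K)), "confound_nonzero_mean", "bad"))
  dm <- assemble_design(regs)
  es <- cohens_f2(st, dm, "conditions")

  # brute force: full model vs constant + covariates
  full <- fit_glm(st, dm)
  reduced <- fit_glm(st, assemble_design(c(
    list(finalize_regressor(rep(1, K), "constant", "mu")), regs[3:4])))
  oracle <- pmax((full$r2 - reduced$r2) / (1 - full$r2), 0)
  expect_equal(es$f2, oracle, tolerance = 1e-10)
  expect_true(all(es$f2 >= 0))
  expect_true(all(es$r2_reduced <= es$r2_full + 1e-10))

  # covariate orthogonal to data and intercept explains nothing: f2 = 0
  yv <- c(1, 2, 4, 3, 6, 5)
  basis <- cbind(1, yv)
  z <- rnorm(6)
  z <- drop(z - basis %*% (mppi(basis) %*% z))
  dm0 <- assemble_design(list(
    finalize_regressor(rep(1, 6), "constant", "mean"),
    finalize_regressor(z, "parametric_demeaned", "z")))
  es0 <- cohens_f2(vector_stft(yv), dm0, "z")
  expect_equal(unname(drop(es0$f2)), 0, tolerance = 1e-8)

  expect_error(cohens_f2(st, dm, "nonexistent"), class = "glms_validation_error")
})

test_that("model-projected spectra evaluate the fit at covariate extremes", {
  rv <- c(3, -1, -1, -1)  # mean zero, max 3, min -1
  X <- cbind(1, rv)
  dm <- assemble_design(list(
    finalize_regressor(rep(1, 4), "constant", "mean"),
    finalize_regressor(rv, "parametric_demeaned", "rv")))
  y <- drop(X %*% c(10, 2))
  fit <- fit_glm(vector_stft(y), dm,
                 make_contrasts(list(c(1, 0), c(0, 1)), c("mean", "rv")))
  pr <- project_spectrum(fit, "rv", "mean")
  expect_equal(unname(drop(pr$at_max)), 16)
  expect_equal(unname(drop(pr$at_min)), 8)
  expect_equal(unname(pr$values_used), c(3, -1))

  # zero slope collapses both projections onto the mean spectrum
  fit0 <- fit_glm(vector_stft(rep(7, 4)), dm,
                  make_contrasts(list(c(1, 0), c(0, 1)), c("mean", "rv")))
  pr0 <- project_spectrum(fit0, "rv", "mean")
  expect_equal(pr0$at_max, pr0$at_min)

  # linearity across random fits
  set.seed(48)
  for (i in 1:10) {
    rv <- rnorm(12); rv <- rv - mean(rv)
    dmr <- assemble_design(list(
      finalize_regressor(rep(1, 12), "constant", "mean"),
      finalize_regressor(rv, "parametric_demeaned", "rv")))
    st <- random_stft(12, 5)
    fr <- fit_glm(st, dmr, make_contrasts(list(c(1, 0), c(0, 1)), c("mean", "rv")))
    prr <- project_spectrum(fr, "rv", "mean")
    beta_rv <- fr$betas[2, , 1]
    expect_equal(drop(prr$at_max - prr$at_min),
                 (max(rv) - min(rv)) * beta_rv, tolerance = 1e-10)
  }

  expect_error(project_spectrum(fit, "mean", "mean"), class = "glms_validation_error")
})

test_that("condition copes are invariant to confounds orthogonal to data and design", {
  set.seed(49)
  K <- 30
  open <- rep(c(1, 0), K / 2)
  y <- rnorm(K, 10)
  regs <- list(finalize_regressor(open, "categorical", "open"),
               finalize_regressor(1 - open, "categorical", "closed"))
  dm <- assemble_design(regs)
  cs <- make_contrasts(list(c(1, 0), c(0, 1), c(1, -1)), c("o", "c", "d"))
  fit <- fit_glm(vector_stft(y), dm, cs)

  # residualise a random vector against [X, y] so it is orthogonal to both
  basis <- cbind(dm$X, y)
  z <- rnorm(K)
  z <- z - basis %*% (mppi(basis) %*% z)
  dm2 <- assemble_design(c(regs, list(
    finalize_regressor(drop(z), "confound_nonzero_mean", "z"))))
  cs2 <- make_contrasts(list(c(1, 0, 0), c(0, 1, 0), c(1, -1, 0)), c("o", "c", "d"))
  fit2 <- fit_glm(vector_stft(y), dm2, cs2)
  expect_equal(drop(fit$copes), drop(fit2$copes), tolerance = 1e-8)
})

test_that("the fit rejects misaligned and complex inputs and guards dof = 0", {
  st <- vector_stft(c(1, 2, 3))
  expect_error(fit_glm(st, constant_design(4)), class = "glms_alignment_error")

  tsx <- time_series(rnorm(64), fs = 32)
  stc <- compute_stft(tsx, stft_config(16, 8, mode = "complex"))
  expect_error(fit_glm(stc, constant_design(dim(stc$values)[1])),
               class = "glms_config_error")

  # saturated model: betas are returned, inference is unavailable
  eye <- assemble_design(list(
    finalize_regressor(c(1, 0), "categorical", "a"),
    finalize_regressor(c(0, 1), "categorical", "b")))
  fit <- fit_glm(vector_stft(c(3, 5)), eye, make_contrasts(list(c(1, -1)), "d"))
  expect_equal(unname(drop(fit$betas)), c(3, 5))
  expect_true(all(is.na(fit$varcopes)))
  expect_error(compute_varcope(eye, make_contrasts(list(c(1, -1)), "d"),
                               fit$residuals),
               class = "glms_validation_error")
})
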