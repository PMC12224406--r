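test_that("segment aggregation sums within windows and double-counts overlap", {
  seg <- segment_signal(10, nperseg = 4, noverlap = 2)
  expect_equal(aggregate_to_segments(rep(1, 10), seg), rep(4, 4))

  # a spike inside the overlap of the first two windows lands in both
  seg2 <- segment_signal(8, 4, 2)
  x <- rep(0, 8); x[4] <- 5
  agg <- aggregate_to_segments(x, seg2)
  expect_equal(agg[1], 5)
  expect_equal(agg[2], 5)

  # a {0,1} bad-sample indicator aggregates to a per-segment bad count
  bad <- rep(0, 10); bad[c(2, 3, 9)] <- 1
  expect_equal(aggregate_to_segments(bad, seg), c(2, 1, 0, 1))

  expect_error(aggregate_to_segments(rep(1, 9), seg), class = "glms_alignment_error")
  expect_equal(aggregate_to_segments(rep(2, 10), seg, method = "mean"), rep(2, 4))
})

test_that("regressor finalisation applies the declared semantics", {
  expect_equal(finalize_regressor(c(1, 2, 3), "parametric_zscore", "z")$values,
               c(-1, 0, 1))
  expect_equal(finalize_regressor(c(1, 2, 3), "parametric_demeaned", "d")$values,
               c(-1, 0, 1))
  expect_equal(finalize_regressor(c(4, 4, 4), "constant", "c")$values, c(1, 1, 1))
  expect_equal(finalize_regressor(c(0, 1, 1), "categorical", "g")$values, c(0, 1, 1))
  expect_equal(finalize_regressor(c(-1, 1, 1), "categorical", "g")$values, c(-1, 1, 1))
  expect_equal(finalize_regressor(c(3, 7, 2), "confound_nonzero_mean", "x")$values,
               c(3, 7, 2))

  expect_error(finalize_regressor(c(0, 2, 1), "categorical", "g"),
               class = "glms_validation_error")
  expect_error(finalize_regressor(c(5, 5, 5), "parametric_zscore", "z"),
               class = "glms_validation_error")
  expect_error(finalize_regressor(1:3, "splines", "s"), class = "glms_config_error")
})

test_that("demeaning and z-scoring invariants hold over random draws", {
  set.seed(21)
  for (i in 1:20) {
    raw <- rnorm(sample(5:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 4))
    d <- finalize_regressor(raw, "parametric_demeaned", "d")$values
    z <- finalize_regressor(raw, "parametric_zscore", "z")$values
    expect_lt(abs(sum(d)), 1e-10 * max(abs(raw)))
    expect_equal(sd(z), 1, tolerance = 1e-8)
    expect_lt(abs(mean(z)), 1e-8)
  }
})

test_that("design assembly preserves order, counts columns and reports rank", {
  K <- 24
  open <- rep(rep(c(1, 0), each = 4), 3)
  set.seed(5)
  regs <- list(
    finalize_regressor(open, "categorical", "open"),
    finalize_regressor(1 - open, "categorical", "closed"),
    finalize_regressor(seq_len(K), "parametric_zscore", "linear_trend"),
    finalize_regressor(rpois(K, 2), "confound_nonzero_mean", "bad_segments"),
    finalize_regressor(abs(rnorm(K)), "confound_nonzero_mean", "veog"),
    finalize_regressor(abs(rnorm(K)), "confound_nonzero_mean", "heog")
  )
  dm <- assemble_design(regs)
  expect_equal(ncol(dm$X), 6)
  expect_equal(colnames(dm$X),
               c("open", "closed", "linear_trend", "bad_segments", "veog", "heog"))
  expect_equal(dm$rank, 6)

  # permuting the declaration permutes the columns identically
  dm2 <- assemble_design(regs[c(3, 1, 6, 2, 4, 5)])
  expect_equal(dm2$X, dm$X[, c(3, 1, 6, 2, 4, 5)])

  dup <- assemble_design(list(
    finalize_regressor(open, "categorical", "a"),
    finalize_regressor(open, "categorical", "b")))
  expect_equal(dup$rank, 1)

  orth <- assemble_design(list(
    finalize_regressor(open, "categorical", "a"),
    finalize_regressor(1 - open, "categorical", "b")))
  expect_equal(orth$rank, 2)

  expect_error(assemble_design(list(
    finalize_regressor(rep(1, 3), "constant", "a"),
    finalize_regressor(rep(1, 4), "constant", "b"))),
    class = "glms_alignment_error")
})

test_that("design diagnostics flag collinearity and agree with the lm oracle", {
  # orthogonal zero-mean pair: no shared variance
  dm <- assemble_design(list(
    finalize_regressor(c(1, -1, 1, -1), "parametric_demeaned", "a"),
    finalize_regressor(c(1, 1, -1, -1), "parametric_demeaned", "b")))
  dg <- design_diagnostics(dm)
  expect_equal(unname(dg$vif), c(1, 1))

  # duplicated column: infinite VIF, no exception
  x <- c(0.3, 1.2, -0.5, 2)
  dupl <- assemble_design(list(
    finalize_regressor(x, "confound_nonzero_mean", "a"),
    finalize_regressor(x, "confound_nonzero_mean", "b")))
  expect_true(all(is.infinite(design_diagnostics(dupl)$vif)))

  # identity design: unit singular values, constant-free correlations
  eye <- assemble_design(list(
    finalize_regressor(c(1, 0, 0), "categorical", "a"),
    finalize_regressor(c(0, 1, 0), "categorical", "b"),
    finalize_regressor(c(0, 0, 1), "categorical", "c")))
  expect_equal(design_diagnostics(eye)$singular_values, c(1, 1, 1))

  # constant columns: correlation and VIF undefined, not errors
  wc <- assemble_design(list(
    finalize_regressor(rep(1, 6), "constant", "mean"),
    finalize_regressor(rnorm(6), "confound_nonzero_mean", "x")))
  dgc <- design_diagnostics(wc)
  expect_true(is.na(dgc$vif["mean"]))
  expect_true(is.na(dgc$correlation["mean", "x"]))

  # brute-force agreement with the auxiliary-regression R^2 from lm()
  set.seed(31)
  for (i in 1:8) {
    X <- matrix(rnorm(80), 20, 4)
    dm <- assemble_design(lapply(1:4, function(j) {
      finalize_regressor(X[, j], "confound_nonzero_mean", paste0("r", j))
    }))
    vif <- design_diagnostics(dm)$vif
    oracle <- vapply(1:4, function(j) {
      r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    expect_equal(unname(vif), oracle, tolerance = 1e-8)
  }
})

test_that("contrast sets store weights column-wise with validation and sugar", {
  cs <- make_contrasts(list(c(1, 0, 0), c(0, 0.5, 0.5), c(0, 1, -1)),
                       c("r1", "mean23", "diff23"))
  expect_equal(dim(cs$C), c(3, 3))
  expect_equal(unname(cs$C[, 2]), c(0, 0.5, 0.5))
  expect_equal(unname(cs$C[, 3]), c(0, 1, -1))

  expect_error(make_contrasts(list(c(1, 0), c(0, 0, 1)), c("a", "b")),
               class = "glms_validation_error")
  expect_error(make_contrasts(list(c(0, 0)), "null"), class = "glms_validation_error")

  # proportion-weighted mean over two balanced condition regressors
  open <- rep(c(1, 0), 10)
  dm <- assemble_design(list(
    finalize_regressor(open, "categorical", "open"),
    finalize_regressor(1 - open, "categorical", "closed"),
    finalize_regressor(1:20, "parametric_zscore", "trend"),
    finalize_regressor(abs(rnorm(20)), "confound_nonzero_mean", "bad"),
    finalize_regressor(abs(rnorm(20)), "confound_nonzero_mean", "veog"),
    finalize_regressor(abs(rnorm(20)), "confound_nonzero_mean", "heog")))
  expect_equal(mean_contrast_weights(dm, c("open", "closed")),
               c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(selector_contrast_weights(dm, "trend"), c(0, 0, 1, 0, 0, 0))
  expect_equal(diff_contrast_weights(dm, "open", "closed"),
               c(1, -1, 0, 0, 0, 0))

  # unbalanced proportions
  open2 <- c(rep(1, 12), rep(0, 8))
  dm2 <- assemble_design(list(
    finalize_regressor(open2, "categorical", "open"),
    finalize_regressor(1 - open2, "categorical", "closed")))
  expect_equal(mean_contrast_weights(dm2), c(0.6, 0.4))
})

test_that("designs and contrasts can be declared through the config dialect", {
  cfg <- list(
    regressors = list(
      list(name = "open", rtype = "categorical"),
      list(name = "closed", rtype = "categorical"),
      list(name = "trend", rtype = "parametric_zscore", source = "time"),
      list(name = "bad", rtype = "confound_nonzero_mean")
    ),
    contrasts = list(
      list(name = "mean", mean_of = list("open", "closed")),
      list(name = "open>closed", diff = list("open", "closed")),
      list(name = "bad", weights = c(0, 0, 0, 1))
    )
  )
  open <- rep(c(1, 0), 6)
  dat <- list(open = open, closed = 1 - open, time = 1:12,
              bad = rpois(12, 1))
  dc <- design_from_config(cfg, dat)
  expect_equal(ncol(dc$design$X), 4)
  expect_equal(dc$contrasts$names, c("mean", "open>closed", "bad"))
  expect_equal(unname(dc$contrasts$C[, 1]), c(0.5, 0.5, 0, 0))

  cfg$regressors[[3]]$source <- "missing"
  expect_error(design_from_config(cfg, dat), class = "glms_validation_error")
})
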