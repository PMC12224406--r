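# Mass-univariate GLM over the time-varying spectrum.
#
# One ordinary-least-squares model is fitted per (frequency, channel) target,
# sharing a single pseudo-inverse of the design matrix across all targets.
# With a lone constant regressor the fit reproduces the time-averaged
# (Welch) spectrum exactly; richer designs add condition, covariate and
# confound structure on top of that baseline.

#' Fit the spectrum GLM
#'
#' Fits `S(f, k) = X(k) B(f) + e(f)` independently for every frequency bin
#' and channel of a real-valued STFT, using the Moore-Penrose pseudo-inverse
#' of the design matrix. For a full-column-rank design this equals the
#' normal-equations OLS solution; under rank deficiency the
#' minimum-Euclidean-norm solution is returned and contrast variances are
#' inflated accordingly.
#'
#' Residual variance is `sigma^2(f) = RSS(f) / dof` with
#' `dof = K - rank(X)`, so contrast t-statistics reduce to the classical
#' one-sample / independent-samples t-tests for the corresponding designs.
#'
#' @param stft A real-mode `glms_stft` (magnitude, power or log-power).
#' @param design A `glms_design` whose row count matches the segment count.
#' @param contrasts Optional `glms_contrasts` (P x Nc); when supplied, cope-,
#'   varcope- and t-spectra are computed for each contrast.
#' @param keep_residuals Keep the K x F x C residual array in the result
#'   (default `TRUE`; needed by [glm_residuals()] consumers and effect-size
#'   helpers).
#' @return Object of class `glms_fit` with elements `betas` (P x F x C),
#'   `copes`, `varcopes`, `tstats` (Nc x F x C, `NULL` without contrasts),
#'   `sigma2` and `r2` (F x C), `dof`, `design`, `contrasts`, `freqs`,
#'   `channel_names`, and `residuals`.
#' @examples
#' st <- stft_object(matrix(rnorm(30, 10), 10, 3), freqs = 1:3)
#' dm <- assemble_design(list(finalize_regressor(rep(1, 10), "constant", "mean")))
#' fit <- fit_glm(st, dm, make_contrasts(list(1), "mean"))
#' drop(fit$copes)  # per-frequency mean spectrum
#' @export
fit_glm <- function(stft, design, contrasts = NULL, keep_residuals = TRUE) {
  stopifnot(inherits(stft, "glms_stft"), inherits(design, "glms_design"))
  if (identical(stft$mode, "complex")) {
    .stop_config("fit_glm() requires a real-valued STFT mode (complex spectra are unsupported)")
  }
  d <- dim(stft$values)
  K <- d[1]; nf <- d[2]; nc <- d[3]
  if (nrow(design$X) != K) {
    .stop_alignment(sprintf("design has %d rows but the STFT has %d segments",
                            nrow(design$X), K))
  }
  X <- design$X
  P <- ncol(X)
  Y <- matrix(stft$values, K, nf * nc)

  B <- mppi(X) %*% Y                       # P x (F*C), single MPPI reused
  resid <- Y - X %*% B
  dof <- K - design$rank
  rss <- colSums(resid^2)
  sigma2 <- if (dof >= 1) rss / dof else rep(NA_real_, length(rss))
  ybar <- colMeans(Y)
  tss <- colSums((Y - rep(ybar, each = K))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)

  out <- list(
    betas = array(B, dim = c(P, nf, nc),
                  dimnames = list(colnames(X), NULL, stft$channel_names)),
    copes = NULL, varcopes = NULL, tstats = NULL,
    sigma2 = matrix(sigma2, nf, nc),
    r2 = matrix(r2, nf, nc),
    dof = dof,
    design = design, contrasts = contrasts,
    freqs = stft$freqs, channel_names = stft$channel_names,
    residuals = if (keep_residuals) array(resid, dim = c(K, nf, nc)) else NULL
  )

  if (!is.null(contrasts)) {
    stopifnot(inherits(contrasts, "glms_contrasts"))
    Cm <- contrasts$C
    if (nrow(Cm) != P) {
      .stop_alignment("contrast weight length does not match the design column count")
    }
    Nc <- ncol(Cm)
    copes <- crossprod(Cm, B)              # Nc x (F*C)
    if (dof >= 1) {
      cvar <- contrast_variance_weights(design, contrasts)
      varcopes <- cvar %o% sigma2          # Nc x (F*C)
      tstats <- .safe_t(copes, varcopes)
    } else {
      varcopes <- matrix(NA_real_, Nc, nf * nc)
      tstats <- matrix(NA_real_, Nc, nf * nc)
    }
    dn <- list(contrasts$names, NULL, stft$channel_names)
    out$copes <- array(copes, dim = c(Nc, nf, nc), dimnames = dn)
    out$varcopes <- array(varcopes, dim = c(Nc, nf, nc), dimnames = dn)
    out$tstats <- array(tstats, dim = c(Nc, nf, nc), dimnames = dn)
  }
  structure(out, class = "glms_fit")
}

#' @export
print.glms_fit <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf("<glms_fit> P=%d regressors, %d freqs, %d channel(s), dof=%d\n",
              d[1], d[2], d[3], x$dof))
  if (!is.null(x$contrasts)) {
    cat("  contrasts:", paste(x$contrasts$names, collapse = ", "), "\n")
  }
  invisible(x)
}

# cope / sqrt(varcope) with the degenerate-bin policy: an exactly-fitted bin
# (varcope 0) gives t = 0 when the cope is also 0 and +/-Inf otherwise;
# flags, not errors, so whole-head maps stay rectangular.
.safe_t <- function(copes, varcopes) {
  tstats <- copes / sqrt(varcopes)
  zero_v <- varcopes == 0
  tstats[zero_v & copes == 0] <- 0
  tstats[zero_v & copes != 0] <- sign(copes[zero_v & copes != 0]) * Inf
  tstats
}

#' Per-contrast design variance weights
#'
#' Computes `diag(C' (X'X)^+ C)` without materialising the full Nc x Nc
#' product: each contrast's weight is accumulated as
#' `sum(((X'X)^+ c_j) * c_j)`, i.e. only the multiplications contributing to
#' the diagonal are performed. Multiplying by `sigma^2(f)` gives the varcope.
#'
#' @param design A `glms_design`.
#' @param contrasts A `glms_contrasts`.
#' @return Numeric vector of length Nc.
#' @export
contrast_variance_weights <- function(design, contrasts) {
  Cm <- contrasts$C
  xtx_p <- mppi(crossprod(design$X))
  colSums((xtx_p %*% Cm) * Cm)
}

#' Residuals of a fitted spectrum GLM
#'
#' `R(f) = S(f) - X B-hat(f)` per frequency and channel.
#'
#' @param stft The real-mode `glms_stft` that was fitted.
#' @param design The `glms_design` used.
#' @param betas P x F x C beta array (e.g. `fit$betas`).
#' @return K x F x C residual array.
#' @export
glm_residuals <- function(stft, design, betas) {
  d <- dim(stft$values)
  Y <- matrix(stft$values, d[1], d[2] * d[3])
  B <- matrix(betas, dim(betas)[1], d[2] * d[3])
  array(Y - design$X %*% B, dim = d)
}

#' Contrasts of parameter estimates (cope-spectra)
#'
#' @param betas P x F x C beta array.
#' @param contrasts A `glms_contrasts`.
#' @return Nc x F x C cope array.
#' @export
compute_cope <- function(betas, contrasts) {
  d <- dim(betas)
  B <- matrix(betas, d[1], d[2] * d[3])
  array(crossprod(contrasts$C, B), dim = c(ncol(contrasts$C), d[2], d[3]),
        dimnames = list(contrasts$names, NULL, dimnames(betas)[[3]]))
}

#' Varcope-spectra from residuals
#'
#' Residual variance `sigma^2(f) = RSS(f) / (K - rank(X))` scaled by the
#' diagonal-only contrast variance weights of
#' [contrast_variance_weights()].
#'
#' @param design A `glms_design`.
#' @param contrasts A `glms_contrasts`.
#' @param residuals K x F x C residual array.
#' @return Nc x F x C varcope array.
#' @export
compute_varcope <- function(design, contrasts, residuals) {
  d <- dim(residuals)
  dof <- d[1] - design$rank
  if (dof < 1) {
    .stop_validation("no residual degrees of freedom: inference unavailable (dof = 0)")
  }
  R <- matrix(residuals, d[1], d[2] * d[3])
  sigma2 <- colSums(R^2) / dof
  cvar <- contrast_variance_weights(design, contrasts)
  array(cvar %o% sigma2, dim = c(ncol(contrasts$C), d[2], d[3]),
        dimnames = list(contrasts$names, NULL, NULL))
}

#' t-spectra from cope- and varcope-spectra
#'
#' @param copes,varcopes Matching cope and varcope arrays.
#' @return Array of t-statistics; exactly-fitted bins yield 0 (cope 0) or a
#'   signed `Inf` flag (cope non-zero).
#' @export
t_spectrum <- function(copes, varcopes) {
  if (any(varcopes < 0, na.rm = TRUE)) .stop_validation("varcopes must be non-negative")
  out <- .safe_t(copes, varcopes)
  dim(out) <- dim(copes)
  dimnames(out) <- dimnames(copes)
  out
}

#' Proportion of variance explained
#'
#' `R^2 = 1 - RSS/TSS` with the total sum of squares taken about the segment
#' mean for every design (including constant-free ones), keeping values
#' comparable across models. Bins with zero data variance are `NA`.
#'
#' @param stft The fitted real-mode `glms_stft`.
#' @param design The `glms_design` used.
#' @param betas P x F x C beta array.
#' @return F x C matrix.
#' @export
r_squared <- function(stft, design, betas) {
  d <- dim(stft$values)
  Y <- matrix(stft$values, d[1], d[2] * d[3])
  resid <- matrix(glm_residuals(stft, design, betas), d[1], d[2] * d[3])
  rss <- colSums(resid^2)
  ybar <- colMeans(Y)
  tss <- colSums((Y - rep(ybar, each = d[1]))^2)
  matrix(ifelse(tss > 0, 1 - rss / tss, NA_real_), d[2], d[3])
}

#' Cohen's f-squared effect-size spectrum
#'
#' Nested-model effect size
#' `f^2(f) = (R^2_full(f) - R^2_reduced(f)) / (1 - R^2_full(f))` computed per
#' frequency and channel. For a covariate target the reduced model simply
#' drops that column. For `target = "conditions"` all categorical condition
#' columns are pooled into a single constant column, measuring the gain from
#' modelling each condition with its own mean rather than one shared mean.
#'
#' @param stft A real-mode `glms_stft`.
#' @param design A `glms_design`.
#' @param target A regressor name, or `"conditions"`.
#' @return Object of class `glms_effect_size`: `f2`, `r2_full`, `r2_reduced`
#'   (all F x C), and `target`. Negative floating-point noise is clipped at
#'   zero.
#' @export
cohens_f2 <- function(stft, design, target) {
  full <- fit_glm(stft, design, keep_residuals = FALSE)
  rtypes <- .design_rtypes(design)
  if (identical(target, "conditions")) {
    cat_idx <- which(rtypes == "categorical")
    if (length(cat_idx) == 0) .stop_validation("design has no categorical condition regressors")
    keep <- design$regressors[-cat_idx]
    pooled <- finalize_regressor(rep(1, nrow(design$X)), "constant", ".pooled_mean")
    reduced_dm <- assemble_design(c(list(pooled), keep))
  } else {
    idx <- match(target, colnames(design$X))
    if (is.na(idx)) .stop_validation(sprintf("unknown regressor '%s'", target))
    if (ncol(design$X) == 1) .stop_validation("cannot remove the only regressor")
    reduced_dm <- assemble_design(design$regressors[-idx])
  }
  reduced <- fit_glm(stft, reduced_dm, keep_residuals = FALSE)
  denom <- pmax(1 - full$r2, .Machine$double.eps)
  f2 <- pmax((full$r2 - reduced$r2) / denom, 0)
  structure(list(f2 = f2, r2_full = full$r2, r2_reduced = reduced$r2,
                 target = target, freqs = stft$freqs),
            class = "glms_effect_size")
}

#' Model-projected spectra at a covariate's extremes
#'
#' Evaluates the fitted model at the largest and smallest observed values of
#' a covariate regressor, added to the mean cope:
#' `max(Rv) * B-hat_rv(f) + cope_mean(f)` (and likewise with `min(Rv)`).
#' Demeaned covariates contribute nothing at their reference value, so this
#' visualises the spectral range the covariate spans around the mean
#' spectrum.
#'
#' @param fit A `glms_fit` with contrasts.
#' @param regressor Name of a parametric or confound regressor.
#' @param mean_contrast Name of the contrast giving the mean/intercept
#'   spectrum.
#' @return Object of class `glms_projection`: `at_max`, `at_min` (F x C),
#'   `regressor`, `values_used = c(max, min)`.
#' @export
project_spectrum <- function(fit, regressor, mean_contrast) {
  stopifnot(inherits(fit, "glms_fit"))
  if (is.null(fit$contrasts)) .stop_validation("fit has no contrasts")
  j <- match(regressor, colnames(fit$design$X))
  if (is.na(j)) .stop_validation(sprintf("unknown regressor '%s'", regressor))
  rtype <- .design_rtypes(fit$design)[j]
  if (rtype %in% c("constant", "categorical")) {
    .stop_validation(paste0(
      "'", regressor, "' is a ", rtype, " regressor; use its condition cope ",
      "directly rather than a projected spectrum"))
  }
  mc <- match(mean_contrast, fit$contrasts$names)
  if (is.na(mc)) .stop_validation(sprintf("unknown contrast '%s'", mean_contrast))
  rv <- fit$design$X[, j]
  beta_rv <- fit$betas[j, , , drop = FALSE]
  dim(beta_rv) <- dim(beta_rv)[2:3]
  mean_cope <- fit$copes[mc, , , drop = FALSE]
  dim(mean_cope) <- dim(mean_cope)[2:3]
  structure(list(at_max = max(rv) * beta_rv + mean_cope,
                 at_min = min(rv) * beta_rv + mean_cope,
                 regressor = regressor,
                 values_used = c(max = max(rv), min = min(rv)),
                 freqs = fit$freqs),
            class = "glms_projection")
}
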