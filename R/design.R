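# Design matrices with explicit regressor semantics, contrast sets and
# multicollinearity diagnostics.
#
# Regressor types follow the usual neuroimaging GLM conventions: condition
# indicators are {0,1} dummies, dynamic covariates are demeaned or z-scored
# so they model variation around the mean, and confounds are carried with
# their raw non-zero mean so the condition regressors act as intercepts.

.REGRESSOR_TYPES <- c("constant", "categorical", "parametric_demeaned",
                      "parametric_zscore", "confound_nonzero_mean")

#' Aggregate a sample-level covariate onto the segment grid
#'
#' Regressors recorded at the sampling rate of the data (artefact indicators,
#' EOG traces, ...) are reduced to one value per STFT segment by summing the
#' samples inside each window. Overlapping segments deliberately double-count
#' shared samples, so the covariate is prepared exactly like the data itself.
#'
#' @param x Numeric vector aligned to the original samples.
#' @param segments A `glms_segments` object from [segment_signal()] (also
#'   available as `stft$segments`).
#' @param method `"sum"` (default) or `"mean"` within each window.
#' @return Numeric vector of length K.
#' @export
aggregate_to_segments <- function(x, segments, method = c("sum", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(segments, "glms_segments"))
  if (length(x) != segments$n_samples) {
    .stop_alignment(sprintf(
      "covariate has %d samples but the segmentation covers %d",
      length(x), segments$n_samples))
  }
  out <- vapply(segments$starts, function(s) {
    v <- x[s:(s + segments$nperseg - 1L)]
    if (method == "sum") sum(v) else mean(v)
  }, numeric(1))
  out
}

#' Finalise a regressor
#'
#' Applies the transform implied by the regressor type: constants become ones,
#' categorical indicators are validated as {0,1} (or a signed +/-1 coding),
#' parametric covariates are demeaned or z-scored (sample sd, denominator
#' K - 1), and non-zero-mean confounds pass through untouched.
#'
#' @param values Numeric vector of length K (ignored for `"constant"`, where
#'   only its length is used).
#' @param rtype One of `r paste0('"', .REGRESSOR_TYPES, '"', collapse = ", ")`.
#' @param name Label for the regressor.
#' @return Object of class `glms_regressor` with `name`, `rtype`, `values`.
#' @examples
#' finalize_regressor(c(1, 2, 3), "parametric_zscore", "trend")$values
#' @export
finalize_regressor <- function(values, rtype, name) {
  if (!rtype %in% .REGRESSOR_TYPES) {
    .stop_config(sprintf("unknown regressor type '%s'", rtype))
  }
  values <- as.numeric(values)
  K <- length(values)
  out <- switch(rtype,
    constant = rep(1, K),
    categorical = {
      ok <- all(values %in% c(0, 1)) || all(values %in% c(-1, 1))
      if (!ok) {
        .stop_validation(sprintf(
          "categorical regressor '%s' must contain only {0,1} (or signed {-1,1}) values",
          name))
      }
      values
    },
    parametric_demeaned = values - mean(values),
    parametric_zscore = {
      if (K < 2) .stop_validation("z-scoring needs at least two segments")
      s <- stats::sd(values)
      if (!is.finite(s) || s == 0) {
        .stop_validation(sprintf(
          "degenerate regressor '%s': zero variance, cannot z-score", name))
      }
      (values - mean(values)) / s
    },
    confound_nonzero_mean = values
  )
  structure(list(name = name, rtype = rtype, values = out),
            class = "glms_regressor")
}

#' Assemble a design matrix
#'
#' Stacks finalised regressors column-wise in declaration order and records
#' the numerical rank (SVD, tolerance `max(K, P) * eps * s_max`).
#'
#' @param regressors List of `glms_regressor` objects (or a single one).
#' @return Object of class `glms_design`: `X` (K x P matrix with regressor
#'   names as column names), `regressors` (metadata list), `rank`.
#' @export
assemble_design <- function(regressors) {
  if (inherits(regressors, "glms_regressor")) regressors <- list(regressors)
  stopifnot(length(regressors) >= 1,
            all(vapply(regressors, inherits, logical(1), "glms_regressor")))
  lens <- vapply(regressors, function(r) length(r$values), integer(1))
  if (length(unique(lens)) != 1) {
    .stop_alignment("regressors have mixed lengths; all must equal K")
  }
  X <- do.call(cbind, lapply(regressors, `[[`, "values"))
  colnames(X) <- vapply(regressors, `[[`, character(1), "name")
  if (anyDuplicated(colnames(X))) .stop_validation("regressor names must be unique")
  if (nrow(X) < ncol(X)) {
    warning("design has fewer rows (K) than columns (P); ",
            "the pseudo-inverse fit remains defined but inference will not be",
            call. = FALSE)
  }
  structure(list(X = X, regressors = regressors, rank = .matrix_rank(X)),
            class = "glms_design")
}

#' @export
print.glms_design <- function(x, ...) {
  cat(sprintf("<glms_design> %d x %d, rank %d\n", nrow(x$X), ncol(x$X), x$rank))
  info <- data.frame(
    name = colnames(x$X),
    rtype = vapply(x$regressors, `[[`, character(1), "rtype"),
    mean = round(colMeans(x$X), 4)
  )
  print(info, row.names = FALSE)
  invisible(x)
}

# Regressor types of a design, in column order.
.design_rtypes <- function(dm) vapply(dm$regressors, `[[`, character(1), "rtype")

#' Design-matrix diagnostics
#'
#' Pearson correlations between columns (undefined, i.e. `NA`, for constant
#' columns), the singular-value spectrum of X, and variance inflation factors
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j on
#' all other columns (with an intercept). Perfect collinearity is reported as
#' `Inf`, never raised as an error.
#'
#' @param dm A `glms_design`.
#' @return Object of class `glms_design_diagnostics` with `correlation`,
#'   `singular_values` and `vif`.
#' @export
design_diagnostics <- function(dm) {
  stopifnot(inherits(dm, "glms_design"))
  X <- dm$X
  P <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  corr <- matrix(NA_real_, P, P, dimnames = list(colnames(X), colnames(X)))
  varying <- which(sds > 0)
  if (length(varying) >= 2) {
    corr[varying, varying] <- stats::cor(X[, varying, drop = FALSE])
  }
  diag(corr)[varying] <- 1

  sv <- svd(X, nu = 0, nv = 0)$d

  vif <- rep(NA_real_, P)
  names(vif) <- colnames(X)
  for (j in seq_len(P)) {
    if (sds[j] == 0) next  # constant column: VIF undefined
    others <- cbind(1, X[, -j, drop = FALSE])
    yj <- X[, j]
    fit <- others %*% (mppi(others) %*% yj)
    rss <- sum((yj - fit)^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  structure(list(correlation = corr, singular_values = sv, vif = vif),
            class = "glms_design_diagnostics")
}

#' @export
print.glms_design_diagnostics <- function(x, ...) {
  cat("<design diagnostics>\n singular values:",
      paste(signif(x$singular_values, 4), collapse = " "), "\n VIF:\n")
  print(round(x$vif, 3))
  invisible(x)
}

#' Build a contrast set
#'
#' Contrasts are stored column-wise: `C` is P x Nc and each column weights
#' the P regression parameters of one planned comparison.
#'
#' @param weights List of numeric length-P weight vectors, or a P x Nc
#'   matrix.
#' @param names Character labels, one per contrast.
#' @return Object of class `glms_contrasts` with `C` and `names`.
#' @examples
#' make_contrasts(list(c(1, 0, 0), c(0, 0.5, 0.5), c(0, 1, -1)),
#'                c("r1", "mean23", "diff23"))
#' @export
make_contrasts <- function(weights, names) {
  if (is.list(weights)) {
    lens <- lengths(weights)
    if (length(unique(lens)) != 1) {
      .stop_validation("all contrast weight vectors must have the same length P")
    }
    C <- do.call(cbind, lapply(weights, as.numeric))
  } else {
    C <- as.matrix(weights)
  }
  if (length(names) != ncol(C)) {
    .stop_validation("'names' must supply one label per contrast")
  }
  if (any(colSums(C != 0) == 0)) {
    .stop_validation("every contrast must have at least one non-zero weight")
  }
  colnames(C) <- names
  structure(list(C = C, names = names), class = "glms_contrasts")
}

#' Proportion-weighted mean contrast over condition regressors
#'
#' For indicator condition regressors the overall mean spectrum is the
#' contrast `[K_1/K, K_2/K, ..., 0, ...]` weighting each condition parameter
#' by the proportion of segments in that condition, with zeros on all other
#' regressors.
#'
#' @param dm A `glms_design`.
#' @param condition_names Names of the categorical condition columns; by
#'   default all `"categorical"` regressors.
#' @return Numeric length-P weight vector.
#' @export
mean_contrast_weights <- function(dm, condition_names = NULL) {
  stopifnot(inherits(dm, "glms_design"))
  rtypes <- .design_rtypes(dm)
  if (is.null(condition_names)) {
    condition_names <- colnames(dm$X)[rtypes == "categorical"]
  }
  if (length(condition_names) == 0) {
    .stop_validation("no condition regressors to weight")
  }
  idx <- match(condition_names, colnames(dm$X))
  if (anyNA(idx)) .stop_validation("unknown condition regressor name")
  w <- rep(0, ncol(dm$X))
  counts <- colSums(dm$X[, idx, drop = FALSE] != 0)
  w[idx] <- counts / nrow(dm$X)
  w
}

#' Selector and difference contrast helpers
#'
#' `selector_contrast_weights()` returns a one-sample contrast with a single
#' 1 on the named regressor; `diff_contrast_weights()` returns `+1` on `a`
#' and `-1` on `b`.
#'
#' @param dm A `glms_design`.
#' @param name,a,b Regressor names.
#' @return Numeric length-P weight vector.
#' @export
selector_contrast_weights <- function(dm, name) {
  idx <- match(name, colnames(dm$X))
  if (is.na(idx)) .stop_validation(sprintf("unknown regressor '%s'", name))
  w <- rep(0, ncol(dm$X))
  w[idx] <- 1
  w
}

#' @rdname selector_contrast_weights
#' @export
diff_contrast_weights <- function(dm, a, b) {
  ia <- match(a, colnames(dm$X)); ib <- match(b, colnames(dm$X))
  if (is.na(ia) || is.na(ib)) .stop_validation("unknown regressor in difference contrast")
  w <- rep(0, ncol(dm$X))
  w[ia] <- 1; w[ib] <- -1
  w
}

#' Build a design and contrast set from a configuration list
#'
#' The configuration dialect (typically read from YAML or JSON, see
#' [read_design_config()]) lists regressors as `(name, rtype, source)` where
#' `source` names an entry of `data`, and contrasts as either explicit
#' `weights` or the sugar forms `mean_of` (proportion-weighted mean of
#' condition regressors) and `diff` (first minus second).
#'
#' @param config List with elements `regressors` and `contrasts`.
#' @param data Named list (or data frame) of raw length-K vectors referenced
#'   by the regressor `source` fields. Constant regressors need no source.
#' @param n_obs Observation count K; required when `data` is empty (e.g. a
#'   constant-only recipe), otherwise inferred from `data`.
#' @return List with `design` (`glms_design`) and `contrasts`
#'   (`glms_contrasts`).
#' @export
design_from_config <- function(config, data, n_obs = NULL) {
  if (is.null(config$regressors)) .stop_validation("config lacks a 'regressors' list")
  K <- if (length(data)) length(data[[1]]) else n_obs
  if (is.null(K)) .stop_validation("'n_obs' is required when no covariate data are supplied")
  regs <- lapply(config$regressors, function(r) {
    if (is.null(r$name) || is.null(r$rtype)) {
      .stop_validation("each regressor needs 'name' and 'rtype'")
    }
    vals <- if (identical(r$rtype, "constant")) {
      rep(1, K)
    } else {
      src <- if (is.null(r$source)) r$name else r$source
      if (is.null(data[[src]])) {
        .stop_validation(sprintf("covariate '%s' not found in the supplied data", src))
      }
      data[[src]]
    }
    finalize_regressor(vals, r$rtype, r$name)
  })
  dm <- assemble_design(regs)
  contrasts <- NULL
  if (!is.null(config$contrasts)) {
    wlist <- lapply(config$contrasts, function(cc) {
      if (!is.null(cc$weights)) {
        w <- as.numeric(cc$weights)
        if (length(w) != ncol(dm$X)) {
          .stop_validation(sprintf("contrast '%s' has wrong weight length", cc$name))
        }
        w
      } else if (!is.null(cc$mean_of)) {
        mean_contrast_weights(dm, unlist(cc$mean_of))
      } else if (!is.null(cc$diff)) {
        ab <- unlist(cc$diff)
        diff_contrast_weights(dm, ab[1], ab[2])
      } else {
        .stop_validation(sprintf(
          "contrast '%s' needs 'weights', 'mean_of' or 'diff'", cc$name))
      }
    })
    contrasts <- make_contrasts(wlist,
                                vapply(config$contrasts, `[[`, character(1), "name"))
  }
  list(design = dm, contrasts = contrasts)
}
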