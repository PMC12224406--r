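# Group-level (second-level) modelling: stack one chosen first-level
# cope-spectrum across datasets and fit another GLM over subjects.
# This is the fixed-effects multilevel model: only first-level copes are
# carried forward; each dataset contributes equally and the group design
# models between-subject variability.

#' Group dataset of stacked first-level copes
#'
#' @param data N x F x C array of first-level copes (subjects first).
#' @param freqs Frequency axis shared by every first-level result.
#' @param subject_ids Optional identifiers, one per row.
#' @param source_contrast Name of the first-level contrast the copes came
#'   from.
#' @param channel_names Optional channel labels.
#' @return Object of class `glms_group_dataset`.
#' @export
group_dataset <- function(data, freqs, subject_ids = NULL,
                          source_contrast = NA_character_,
                          channel_names = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3) .stop_validation("'data' must be N x F x C")
  if (dim(data)[2] != length(freqs)) {
    .stop_alignment("'freqs' length does not match dim(data)[2]")
  }
  n <- dim(data)[1]
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(n))
  if (length(subject_ids) != n) .stop_validation("one subject id per row required")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[3]))
  structure(list(data = data, freqs = as.numeric(freqs),
                 subject_ids = subject_ids, source_contrast = source_contrast,
                 channel_names = channel_names),
            class = "glms_group_dataset")
}

#' @export
print.glms_group_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<glms_group_dataset> %d subjects x %d freqs x %d channel(s), contrast '%s'\n",
              d[1], d[2], d[3], x$source_contrast))
  invisible(x)
}

#' Stack first-level results into a group dataset
#'
#' Extracts one named first-level cope-spectrum from each result and stacks
#' them along a subjects axis, preserving input order. All results must share
#' an identical frequency grid (to 1e-9) and channel count; the first
#' mismatching input is named in the error.
#'
#' @param results List of `glms_fit` objects or paths to serialised results
#'   (see [write_glm_result()]).
#' @param contrast Name of the first-level contrast to carry forward.
#' @param subject_ids Optional identifiers (defaults to names/paths or
#'   `subj<i>`).
#' @return A `glms_group_dataset`.
#' @export
stack_first_level <- function(results, contrast, subject_ids = NULL) {
  if (length(results) < 2) .stop_validation("need at least two first-level results")
  labels <- if (!is.null(names(results))) names(results)
    else vapply(seq_along(results), function(i) {
      if (is.character(results[[i]])) results[[i]] else paste0("subj", i)
    }, character(1))
  fits <- lapply(results, function(r) {
    if (is.character(r)) read_glm_result(r) else r
  })
  ref <- fits[[1]]
  if (is.null(ref$copes)) .stop_validation("first-level results carry no contrasts")
  j <- match(contrast, ref$contrasts$names)
  if (is.na(j)) {
    .stop_validation(sprintf("first-level contrast '%s' not found", contrast))
  }
  nf <- length(ref$freqs); nc <- dim(ref$copes)[3]
  data <- array(NA_real_, dim = c(length(fits), nf, nc))
  for (i in seq_along(fits)) {
    fi <- fits[[i]]
    if (length(fi$freqs) != nf || max(abs(fi$freqs - ref$freqs)) > 1e-9) {
      .stop_alignment(sprintf(
        "frequency grid of '%s' does not match the first result", labels[i]))
    }
    if (dim(fi$copes)[3] != nc) {
      .stop_alignment(sprintf(
        "channel count of '%s' does not match the first result", labels[i]))
    }
    ji <- match(contrast, fi$contrasts$names)
    if (is.na(ji)) {
      .stop_validation(sprintf("contrast '%s' missing from '%s'", contrast, labels[i]))
    }
    data[i, , ] <- fi$copes[ji, , ]
  }
  group_dataset(data, ref$freqs,
                subject_ids = if (is.null(subject_ids)) labels else subject_ids,
                source_contrast = contrast, channel_names = ref$channel_names)
}

#' Fit the group-level GLM
#'
#' Reuses the first-level machinery with subjects as observations: the
#' stacked copes play the role of the time-varying spectrum and the group
#' design is fitted per frequency and channel with the pseudo-inverse.
#' Residual degrees of freedom are `N - rank(X_group)`.
#'
#' @param gd A `glms_group_dataset`.
#' @param gdesign A `glms_design` with one row per subject.
#' @param gcontrasts Optional `glms_contrasts` over the group regressors.
#' @return A `glms_fit` (group-level).
#' @export
fit_group <- function(gd, gdesign, gcontrasts = NULL) {
  stopifnot(inherits(gd, "glms_group_dataset"))
  st <- stft_object(gd$data, gd$freqs, mode = "group_cope",
                    channel_names = gd$channel_names)
  fit_glm(st, gdesign, gcontrasts)
}

#' Participant-weighted group mean contrast
#'
#' Weights each group-indicator column by its share of participants
#' (`n_g / sum(n)`) and sets covariate columns to zero, so the contrast
#' estimates the grand mean across all subjects.
#'
#' @param n_per_group Positive participant counts, one per group column.
#' @param n_covariates Number of trailing covariate columns to zero-pad.
#' @return Numeric weight vector of length
#'   `length(n_per_group) + n_covariates`; the group weights sum to 1.
#' @examples
#' group_weighted_mean_contrast(c(100, 106), n_covariates = 3)
#' @export
group_weighted_mean_contrast <- function(n_per_group, n_covariates = 0) {
  if (any(n_per_group <= 0)) .stop_validation("group counts must be positive")
  c(n_per_group / sum(n_per_group), rep(0, n_covariates))
}

#' Group design from a subject table
#'
#' Builds the standard between-subject design: one `{0,1}` indicator column
#' per level of `group_col` (no global intercept) followed by z-scored
#' covariate columns, matching row order of the table.
#'
#' @param table Data frame with one row per subject.
#' @param group_col Name of the categorical group column.
#' @param covariate_cols Character vector of numeric covariate columns
#'   (z-scored across subjects).
#' @return A `glms_design`.
#' @export
group_design_from_table <- function(table, group_col, covariate_cols = character(0)) {
  if (!group_col %in% names(table)) {
    .stop_validation(sprintf("column '%s' not found in subject table", group_col))
  }
  g <- factor(table[[group_col]])
  regs <- lapply(levels(g), function(lv) {
    finalize_regressor(as.numeric(g == lv), "categorical", lv)
  })
  for (cv in covariate_cols) {
    if (!cv %in% names(table)) {
      .stop_validation(sprintf("covariate column '%s' not found in subject table", cv))
    }
    regs <- c(regs, list(finalize_regressor(table[[cv]], "parametric_zscore", cv)))
  }
  assemble_design(regs)
}
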