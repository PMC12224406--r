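# Pipeline entry points tying the modules together: one call from a raw
# recording (plus covariate channels) to a serialised first-level result,
# and one from a set of first-level results to a group fit with cluster
# permutation reports. A JSON provenance sidecar records the configuration
# hash, seed and package version so any run can be reproduced.

.default_stft_settings <- function() {
  list(window_seconds = 2, overlap_seconds = 1, window = "hann",
       mode = "magnitude", freq_range = NULL)
}

.stft_config_from_settings <- function(settings, fs) {
  s <- utils::modifyList(.default_stft_settings(), settings %||% list())
  stft_config(nperseg = round(s$window_seconds * fs),
              noverlap = round(s$overlap_seconds * fs),
              window = s$window, mode = s$mode,
              freq_range = if (is.null(s$freq_range)) NULL else unlist(s$freq_range))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_provenance <- function(path, config, seed = NULL) {
  tmp <- tempfile()
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(config = config, config_md5 = hash, seed = seed,
         package_version = as.character(utils::packageVersion("glmspectrum")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA)
}

#' Run a first-level analysis
#'
#' STFT, design assembly and GLM fit in one step. Covariate sources named in
#' the design recipe are taken from `covariates` (sample-level traces are
#' aggregated to the segment grid by summation; vectors already of length K
#' are used as-is).
#'
#' @param input A `glms_ts`, or a path readable by [read_timeseries()].
#' @param config Design recipe list (see [design_from_config()]), optionally
#'   with an `stft` block (`window_seconds`, `overlap_seconds`, `window`,
#'   `mode`, `freq_range`), or a path readable by [read_design_config()].
#' @param covariates Named list of covariate vectors (per-sample or
#'   per-segment).
#' @param output Optional path; when given, the result and a provenance
#'   sidecar are written there.
#' @param fs Sampling rate override for text inputs.
#' @return The `glms_fit`, invisibly when `output` is given.
#' @export
run_first_level <- function(input, config, covariates = list(),
                            output = NULL, fs = NULL) {
  ts <- if (inherits(input, "glms_ts")) input else read_timeseries(input, fs = fs)
  if (is.character(config)) config <- read_design_config(config)
  cfg <- .stft_config_from_settings(config$stft, ts$fs)
  st <- compute_stft(ts, cfg)
  K <- dim(st$values)[1]
  seg_cov <- lapply(covariates, function(v) {
    if (length(v) == K) v else aggregate_to_segments(v, st$segments)
  })
  # fail before fitting if a named source is missing
  for (r in config$regressors) {
    src <- r$source %||% r$name
    if (!identical(r$rtype, "constant") && is.null(seg_cov[[src]])) {
      .stop_validation(sprintf("covariate '%s' named in the recipe was not supplied", src))
    }
  }
  dc <- design_from_config(config, seg_cov, n_obs = K)
  fit <- fit_glm(st, dc$design, dc$contrasts, keep_residuals = FALSE)
  if (!is.null(output)) {
    write_glm_result(fit, output)
    .write_provenance(output, config, seed = config$seed %||% NULL)
    return(invisible(fit))
  }
  fit
}

#' Run a group-level analysis with permutation inference
#'
#' Stacks one first-level contrast across results, fits the group design,
#' and runs a cluster permutation test for each requested group contrast.
#'
#' @param results List of `glms_fit` objects or result-file paths.
#' @param gdesign Group `glms_design` (e.g. from
#'   [group_design_from_table()]).
#' @param gcontrasts Group `glms_contrasts`.
#' @param first_level_contrast Name of the first-level contrast to carry
#'   forward.
#' @param test_contrasts Names of group contrasts to permutation-test
#'   (default: all).
#' @param perm_config A `glms_perm_config`.
#' @param output Optional path prefix; the group result is written to
#'   `<output>.json` and each cluster report to
#'   `<output>.<contrast>.clusters.json`.
#' @return List with `fit` (group `glms_fit`) and `cluster_results` (named
#'   list of `glms_cluster_result`).
#' @export
run_group <- function(results, gdesign, gcontrasts, first_level_contrast,
                      test_contrasts = NULL, perm_config = NULL,
                      output = NULL) {
  gd <- stack_first_level(results, first_level_contrast)
  fit <- fit_group(gd, gdesign, gcontrasts)
  if (is.null(perm_config)) {
    nchan <- dim(gd$data)[3]
    perm_config <- permutation_config(
      adjacency = if (nchan > 1) adjacency_line(nchan) else NULL)
  }
  if (is.null(test_contrasts)) test_contrasts <- gcontrasts$names
  cluster_results <- list()
  for (cn in test_contrasts) {
    cluster_results[[cn]] <- cluster_permutation_test(gd, gdesign, gcontrasts,
                                                      cn, perm_config)
  }
  if (!is.null(output)) {
    write_glm_result(fit, paste0(output, ".json"))
    for (cn in names(cluster_results)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", cn)
      write_cluster_result(cluster_results[[cn]],
                           paste0(output, ".", safe, ".clusters.json"))
    }
    .write_provenance(paste0(output, ".json"),
                      list(first_level_contrast = first_level_contrast,
                           test_contrasts = test_contrasts,
                           nperms = perm_config$nperms,
                           scheme = perm_config$scheme,
                           cluster_forming_p = perm_config$cluster_forming_p,
                           alpha = perm_config$alpha),
                      seed = perm_config$seed)
  }
  list(fit = fit, cluster_results = cluster_results)
}
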