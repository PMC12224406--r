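# Plain-text I/O: time series as delimited text, fitted results and cluster
# reports as JSON with explicit array dimensions, adjacency as a 0/1 matrix
# or edge list, and design recipes as YAML/JSON.

#' Read and write time series as delimited text
#'
#' Tab-separated samples-by-channels layout with a header row of channel
#' names, preceded by a `# fs=<Hz>` comment line. `read_timeseries()` also
#' accepts plain headered TSV when `fs` is supplied explicitly.
#'
#' @param ts A `glms_ts`.
#' @param path File path.
#' @param fs Sampling rate override when the file has no `# fs=` line.
#' @return `read_timeseries()` returns a `glms_ts`; `write_timeseries()`
#'   returns `path` invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "glms_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", ts$fs), con)
  utils::write.table(ts$data, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, fs = NULL) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (grepl("^#\\s*fs\\s*=", first)) {
    fs_file <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
    if (is.null(fs)) fs <- fs_file
    skip <- 1L
  }
  if (is.null(fs)) .stop_validation("no sampling rate: file has no '# fs=' line and 'fs' was not given")
  dat <- utils::read.delim(path, skip = skip, check.names = FALSE)
  time_series(as.matrix(dat), fs = fs, channel_names = colnames(dat))
}

# Array <-> JSON-friendly list with explicit dims (column-major values).
.pack_array <- function(a) {
  if (is.null(a)) return(NULL)
  list(dim = dim(a), values = as.vector(a), dimnames1 = dimnames(a)[[1]])
}
.unpack_array <- function(p) {
  if (is.null(p)) return(NULL)
  a <- array(p$values, dim = p$dim)
  if (!is.null(p$dimnames1) && length(p$dimnames1)) {
    dn <- vector("list", length(p$dim))
    dn[[1]] <- p$dimnames1
    dimnames(a) <- dn
  }
  a
}

#' Serialise a fitted GLM-spectrum result
#'
#' Writes the beta/cope/varcope/t arrays, residual variance, R-squared,
#' degrees of freedom, frequency axis, and the design and contrast
#' definitions to a single JSON file (arrays stored with explicit
#' dimensions). This file is the unit consumed by the group level.
#' Residuals are not serialised.
#'
#' @param fit A `glms_fit`.
#' @param path Output path.
#' @return `read_glm_result()` returns a `glms_fit`; `write_glm_result()`
#'   returns `path` invisibly.
#' @export
write_glm_result <- function(fit, path) {
  stopifnot(inherits(fit, "glms_fit"))
  payload <- list(
    format = "glmspectrum-result",
    version = as.character(utils::packageVersion("glmspectrum")),
    freqs = fit$freqs,
    channel_names = fit$channel_names,
    dof = fit$dof,
    betas = .pack_array(fit$betas),
    copes = .pack_array(fit$copes),
    varcopes = .pack_array(fit$varcopes),
    tstats = .pack_array(fit$tstats),
    sigma2 = .pack_array(fit$sigma2),
    r2 = .pack_array(fit$r2),
    design = list(
      X = .pack_array(fit$design$X),
      names = colnames(fit$design$X),
      rtypes = .design_rtypes(fit$design)
    ),
    contrasts = if (is.null(fit$contrasts)) NULL else list(
      C = .pack_array(fit$contrasts$C),
      names = fit$contrasts$names
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_glm_result
#' @export
read_glm_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "glmspectrum-result")) {
    .stop_data(sprintf("'%s' is not a glmspectrum result file", path))
  }
  X <- .unpack_array(p$design$X)
  colnames(X) <- p$design$names
  regs <- lapply(seq_along(p$design$names), function(j) {
    structure(list(name = p$design$names[j], rtype = p$design$rtypes[j],
                   values = X[, j]),
              class = "glms_regressor")
  })
  design <- structure(list(X = X, regressors = regs, rank = .matrix_rank(X)),
                      class = "glms_design")
  contrasts <- NULL
  if (!is.null(p$contrasts) && !is.null(p$contrasts$C)) {
    C <- .unpack_array(p$contrasts$C)
    colnames(C) <- p$contrasts$names
    contrasts <- structure(list(C = C, names = p$contrasts$names),
                           class = "glms_contrasts")
  }
  with_chan <- function(a, row_names) {
    if (is.null(a)) return(NULL)
    dimnames(a) <- list(row_names, NULL, p$channel_names)
    a
  }
  cnames <- if (is.null(contrasts)) NULL else contrasts$names
  structure(list(
    betas = with_chan(.unpack_array(p$betas), p$design$names),
    copes = with_chan(.unpack_array(p$copes), cnames),
    varcopes = with_chan(.unpack_array(p$varcopes), cnames),
    tstats = with_chan(.unpack_array(p$tstats), cnames),
    sigma2 = .unpack_array(p$sigma2), r2 = .unpack_array(p$r2), dof = p$dof,
    design = design, contrasts = contrasts,
    freqs = p$freqs, channel_names = p$channel_names, residuals = NULL
  ), class = "glms_fit")
}

#' Read a channel adjacency structure
#'
#' Accepts either a square 0/1 matrix with a channel-name header row, or a
#' two-column edge list of channel names (symmetrised automatically).
#'
#' @param path Delimited text file.
#' @param channel_names Required for the edge-list form: full channel order.
#' @return Symmetric, irreflexive 0/1 matrix.
#' @export
read_adjacency <- function(path, channel_names = NULL) {
  dat <- utils::read.delim(path, check.names = FALSE)
  if (ncol(dat) == 2 && !all(vapply(dat, is.numeric, logical(1)))) {
    if (is.null(channel_names)) {
      .stop_validation("edge-list adjacency needs 'channel_names' for the channel order")
    }
    a <- matrix(0, length(channel_names), length(channel_names),
                dimnames = list(channel_names, channel_names))
    for (i in seq_len(nrow(dat))) {
      u <- as.character(dat[i, 1]); v <- as.character(dat[i, 2])
      if (!(u %in% channel_names) || !(v %in% channel_names)) {
        .stop_validation(sprintf("edge '%s'-'%s' names an unknown channel", u, v))
      }
      a[u, v] <- 1; a[v, u] <- 1
    }
    diag(a) <- 0
    a
  } else {
    a <- as.matrix(dat)
    if (nrow(a) != ncol(a)) .stop_validation("adjacency matrix must be square")
    rownames(a) <- colnames(a)
    diag(a) <- 0
    a
  }
}

#' Export a cluster permutation result
#'
#' Clusters (members, masses, p-values) go to JSON; the null distribution to
#' a one-column delimited text file alongside it.
#'
#' @param res A `glms_cluster_result`.
#' @param path JSON output path; the null distribution is written to
#'   `<path>.null.tsv`.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(res, path) {
  stopifnot(inherits(res, "glms_cluster_result"))
  clusters <- lapply(res$clusters, function(cl) {
    list(freq_bins = cl$points[, "freq_bin"],
         channels = res$channel_names[cl$points[, "channel"]],
         freq_range_hz = range(res$freqs[cl$points[, "freq_bin"]]),
         mass = cl$mass, sign = cl$sign,
         p_value = cl$p_value, significant = cl$significant)
  })
  jsonlite::write_json(
    list(contrast = res$contrast, threshold_t = res$threshold_t, dof = res$dof,
         nperms = length(res$null_distribution),
         alpha = res$config$alpha, clusters = clusters),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(max_cluster_mass = res$null_distribution),
                     paste0(path, ".null.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a design/contrast recipe from YAML or JSON
#'
#' The recipe dialect is the one consumed by [design_from_config()]:
#' a `regressors` list of `(name, rtype, source)` entries and a `contrasts`
#' list of `(name, weights | mean_of | diff)` entries. Unknown top-level keys
#' are rejected.
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return Configuration list.
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("regressors", "contrasts", "stft", "seed", "output",
             "group_col", "covariates")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    .stop_validation(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  cfg
}

#' Export a design matrix and its diagnostics as delimited text
#'
#' @param dm A `glms_design`.
#' @param path TSV output path for the matrix; diagnostics (singular values
#'   and VIFs) go to `<path>.diagnostics.tsv`.
#' @return `path`, invisibly.
#' @export
write_design <- function(dm, path) {
  stopifnot(inherits(dm, "glms_design"))
  utils::write.table(dm$X, path, sep = "\t", row.names = FALSE, quote = FALSE)
  dg <- design_diagnostics(dm)
  diag_df <- data.frame(
    regressor = colnames(dm$X),
    singular_value = c(dg$singular_values,
                       rep(NA, ncol(dm$X) - length(dg$singular_values))),
    vif = dg$vif
  )
  utils::write.table(diag_df, paste0(path, ".diagnostics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
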