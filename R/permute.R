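# Non-parametric permutation inference for group-level contrasts with
# cluster-based correction over the frequency x channel grid.
#
# The null distribution is built by refitting the group GLM after permuting
# only the design columns carrying non-zero weight in the tested contrast
# (Draper-Stoneman column permutation): independent +/-1 sign flips for
# categorical regressors, a single row shuffle for parametric ones. The
# per-permutation summary is the maximum |cluster mass| over both tails, so
# one null controls the two-tailed family-wise error once.

#' Cluster-forming t threshold
#'
#' Upper quantile of Student's t at `1 - p/2`, i.e. the two-tailed critical
#' value. With 205 degrees of freedom and p = 0.001 this is 3.34 (2 d.p.).
#'
#' @param dof Residual degrees of freedom (>= 1).
#' @param two_tailed_p Two-tailed alpha in (0, 1).
#' @return Positive critical t value.
#' @examples
#' critical_t(205, 0.001)
#' @export
critical_t <- function(dof, two_tailed_p) {
  if (dof < 1) .stop_config("'dof' must be at least 1")
  if (two_tailed_p <= 0 || two_tailed_p >= 1) {
    .stop_config("'two_tailed_p' must lie strictly between 0 and 1")
  }
  stats::qt(1 - two_tailed_p / 2, df = dof)
}

#' Permutation test configuration
#'
#' @param nperms Number of permutations (>= 1; default 2500).
#' @param scheme `"sign_flip"` (categorical regressors) or `"row_shuffle"`
#'   (parametric regressors).
#' @param cluster_forming_p Two-tailed alpha defining the t threshold at
#'   which points enter clusters (default 0.001).
#' @param extent_threshold Minimum number of neighbours beyond the point
#'   itself; clusters with fewer than `extent_threshold + 1` points are
#'   discarded (default 1, i.e. at least 2 adjacent points).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed RNG seed; the null distribution is bit-reproducible given the
#'   seed.
#' @param adjacency Symmetric, irreflexive 0/1 channel-adjacency matrix
#'   (required for more than one channel). Frequency bins are adjacent when
#'   consecutive; no diagonal frequency-channel coupling.
#' @return Object of class `glms_perm_config`.
#' @export
permutation_config <- function(nperms = 2500,
                               scheme = c("sign_flip", "row_shuffle"),
                               cluster_forming_p = 0.001,
                               extent_threshold = 1,
                               alpha = 0.05,
                               seed = 1,
                               adjacency = NULL) {
  scheme <- match.arg(scheme)
  if (nperms < 1) .stop_config("'nperms' must be at least 1")
  if (cluster_forming_p <= 0 || cluster_forming_p >= 1) {
    .stop_config("'cluster_forming_p' must lie strictly between 0 and 1")
  }
  if (alpha <= 0 || alpha >= 1) .stop_config("'alpha' must lie strictly between 0 and 1")
  if (!is.null(adjacency)) {
    adjacency <- as.matrix(adjacency)
    if (nrow(adjacency) != ncol(adjacency) ||
        !isTRUE(all.equal(adjacency, t(adjacency))) ||
        any(diag(adjacency) != 0)) {
      .stop_config("'adjacency' must be a symmetric, irreflexive square 0/1 matrix")
    }
  }
  structure(list(nperms = as.integer(nperms), scheme = scheme,
                 cluster_forming_p = cluster_forming_p,
                 extent_threshold = as.integer(extent_threshold),
                 alpha = alpha, seed = seed, adjacency = adjacency),
            class = "glms_perm_config")
}

#' Channel adjacency helpers
#'
#' `adjacency_line()` connects consecutive channels of a linear layout;
#' `adjacency_from_coords()` connects channels whose Euclidean distance is at
#' most `max_dist`. Both return symmetric, irreflexive 0/1 matrices.
#'
#' @param n_channels Channel count.
#' @param coords Numeric matrix of channel coordinates (rows = channels).
#' @param max_dist Neighbour distance cutoff.
#' @return 0/1 adjacency matrix.
#' @export
adjacency_line <- function(n_channels) {
  a <- matrix(0, n_channels, n_channels)
  if (n_channels > 1) {
    idx <- seq_len(n_channels - 1)
    a[cbind(idx, idx + 1)] <- 1
    a[cbind(idx + 1, idx)] <- 1
  }
  a
}

#' @rdname adjacency_line
#' @export
adjacency_from_coords <- function(coords, max_dist) {
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  a <- (d <= max_dist) * 1
  diag(a) <- 0
  a
}

#' Permute contrast-related design columns
#'
#' Applies the Draper-Stoneman manipulation: only columns with non-zero
#' weight in the tested contrast are modified, all other regressors are left
#' bit-identical. `"sign_flip"` multiplies each row's entries by an
#' independent +/-1; `"row_shuffle"` applies one shared random row
#' permutation to the touched columns.
#'
#' @param X Group design matrix (N x Q).
#' @param contrast_weights Length-Q weight vector of the tested contrast.
#' @param scheme `"sign_flip"` or `"row_shuffle"`.
#' @param rtypes Optional character vector of regressor types used to warn
#'   when sign flipping is requested for a purely parametric contrast
#'   (allowed, but logged).
#' @return Permuted copy of `X`.
#' @export
permute_design <- function(X, contrast_weights,
                           scheme = c("sign_flip", "row_shuffle"),
                           rtypes = NULL) {
  scheme <- match.arg(scheme)
  cols <- which(contrast_weights != 0)
  if (length(cols) == 0) .stop_validation("contrast touches no design column")
  if (!is.null(rtypes) && scheme == "sign_flip" &&
      !any(rtypes[cols] %in% c("categorical", "constant"))) {
    warning("sign_flip requested for a purely parametric contrast; ",
            "row_shuffle is the conventional scheme", call. = FALSE)
  }
  n <- nrow(X)
  if (scheme == "sign_flip") {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    X[, cols] <- X[, cols, drop = FALSE] * flips
  } else {
    X[, cols] <- X[sample.int(n), cols, drop = FALSE]
  }
  X
}

#' Form suprathreshold clusters on the frequency x channel grid
#'
#' Points with `t > threshold` (positive tail) and `t < -threshold`
#' (negative tail) are grouped separately into connected components.
#' Neighbours of a point are the same-channel adjacent frequency bins and the
#' same-bin adjacent channels. Components with fewer than
#' `extent_threshold + 1` points are discarded.
#'
#' @param tmap F x C matrix of t values (a vector is a single channel).
#' @param threshold Positive cluster-forming t value.
#' @param adjacency Channel adjacency matrix (required when C > 1).
#' @param extent_threshold Minimum neighbour count beyond the point itself.
#' @return List of clusters, each a list with `points` (two-column matrix of
#'   frequency-bin and channel indices), `mass` (sum of member t values) and
#'   `sign`.
#' @examples
#' form_clusters(c(0, 4, 4, 0), threshold = 3.34)
#' @export
form_clusters <- function(tmap, threshold, adjacency = NULL,
                          extent_threshold = 1) {
  if (is.vector(tmap)) tmap <- matrix(tmap, ncol = 1)
  if (!all(is.finite(tmap))) .stop_data("t map contains non-finite values")
  nchan <- ncol(tmap)
  if (nchan > 1 && is.null(adjacency)) {
    .stop_config("channel adjacency is required for multichannel cluster forming")
  }
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tmap > threshold else tmap < -threshold
    if (!any(mask)) next
    comp <- .connected_components(mask, adjacency)
    for (members in comp) {
      if (length(members) < extent_threshold + 1) next
      pts <- cbind(freq_bin = (members - 1L) %% nrow(tmap) + 1L,
                   channel = (members - 1L) %/% nrow(tmap) + 1L)
      clusters[[length(clusters) + 1L]] <- list(
        points = pts, mass = sum(tmap[members]), sign = sgn)
    }
  }
  clusters
}

# Connected components of a logical F x C mask under the grid adjacency rule.
# Returns a list of integer index vectors (column-major indices into the
# mask).
.connected_components <- function(mask, adjacency) {
  nf <- nrow(mask); nc <- ncol(mask)
  lab <- integer(nf * nc)
  idx <- which(mask)
  comps <- list()
  nb_chan <- if (nc > 1) lapply(seq_len(nc), function(ch) which(adjacency[ch, ] != 0))
             else list(integer(0))
  for (i0 in idx) {
    if (lab[i0] != 0L) next
    id <- length(comps) + 1L
    queue <- i0
    lab[i0] <- id
    members <- integer(0)
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, p)
      f <- (p - 1L) %% nf + 1L
      ch <- (p - 1L) %/% nf + 1L
      nb <- integer(0)
      if (f > 1L) nb <- c(nb, p - 1L)
      if (f < nf) nb <- c(nb, p + 1L)
      if (nc > 1L && length(nb_chan[[ch]])) nb <- c(nb, (nb_chan[[ch]] - 1L) * nf + f)
      for (q in nb) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- id
          queue <- c(queue, q)
        }
      }
    }
    comps[[id]] <- members
  }
  comps
}

# t map for a single contrast: pseudo-inverse fit of X to the N x (F*C) data
# matrix, sigma^2 = RSS / (N - rank), varcope weight via the diagonal-only
# rule. Returns the vector of t values (0 where cope and varcope are both 0).
.contrast_tmap <- function(X, D, cvec) {
  n <- nrow(X)
  B <- mppi(X) %*% D
  resid <- D - X %*% B
  dof <- n - .matrix_rank(X)
  sigma2 <- colSums(resid^2) / dof
  cvar <- sum((mppi(crossprod(X)) %*% cvec) * cvec)
  cope <- drop(crossprod(cvec, B))
  .safe_t(cope, cvar * sigma2)
}

#' Cluster-based permutation test of a group contrast
#'
#' Fits the observed group GLM, forms suprathreshold clusters of its
#' t-spectrum, then builds a max-statistic null by refitting under
#' `nperms` permuted designs and recording the largest absolute cluster mass
#' over both tails (0 when no cluster forms). Each observed cluster receives
#' `p = (1 + #\{null >= |mass|\}) / (nperms + 1)`, so the smallest attainable
#' p is `1 / (nperms + 1)`.
#'
#' @param gd A `glms_group_dataset`.
#' @param gdesign Group `glms_design`.
#' @param gcontrasts Group `glms_contrasts`.
#' @param contrast Name or index of the contrast to test.
#' @param config A `glms_perm_config`.
#' @return Object of class `glms_cluster_result`: `clusters` (each with
#'   `points`, `mass`, `sign`, `p_value`, `significant`), `null_distribution`
#'   (length `nperms`), `observed_t` (F x C), `threshold_t`, `dof`, `config`,
#'   `freqs`, `channel_names`.
#' @export
cluster_permutation_test <- function(gd, gdesign, gcontrasts, contrast, config) {
  stopifnot(inherits(gd, "glms_group_dataset"),
            inherits(config, "glms_perm_config"))
  j <- if (is.character(contrast)) match(contrast, gcontrasts$names) else as.integer(contrast)
  if (is.na(j) || j < 1 || j > ncol(gcontrasts$C)) {
    .stop_validation("unknown group contrast")
  }
  if (1 / (config$nperms + 1) > config$alpha) {
    warning(sprintf(
      "nperms = %d cannot resolve alpha = %g (minimum attainable p is %.4g)",
      config$nperms, config$alpha, 1 / (config$nperms + 1)), call. = FALSE)
  }
  n <- dim(gd$data)[1]
  if (n < 12) {
    warning("Draper-Stoneman permutation can be erratic below N = 12 subjects",
            call. = FALSE)
  }
  d <- dim(gd$data)
  nf <- d[2]; nc <- d[3]
  if (nc > 1 && is.null(config$adjacency)) {
    .stop_config("multichannel data require 'adjacency' in the permutation config")
  }
  D <- matrix(gd$data, n, nf * nc)
  X <- gdesign$X
  cvec <- gcontrasts$C[, j]
  rtypes <- .design_rtypes(gdesign)

  dof <- n - gdesign$rank
  if (dof < 1) .stop_validation("no residual degrees of freedom at the group level")
  thr <- critical_t(dof, config$cluster_forming_p)

  t_obs <- matrix(.contrast_tmap(X, D, cvec), nf, nc)
  obs_clusters <- form_clusters(t_obs, thr, config$adjacency,
                                config$extent_threshold)

  null <- numeric(config$nperms)
  withr::with_seed(config$seed, {
    for (b in seq_len(config$nperms)) {
      Xp <- permute_design(X, cvec, config$scheme, rtypes = NULL)
      tb <- .contrast_tmap(Xp, D, cvec)
      if (any(tb > thr) || any(tb < -thr)) {
        cl <- form_clusters(matrix(tb, nf, nc), thr, config$adjacency,
                            config$extent_threshold)
        null[b] <- if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
      }
    }
  })

  clusters <- lapply(obs_clusters, function(cl) {
    p <- (1 + sum(null >= abs(cl$mass))) / (config$nperms + 1)
    cl$p_value <- p
    cl$significant <- p <= config$alpha
    cl
  })
  structure(list(clusters = clusters, null_distribution = null,
                 observed_t = t_obs, threshold_t = thr, dof = dof,
                 contrast = gcontrasts$names[j], config = config,
                 freqs = gd$freqs, channel_names = gd$channel_names),
            class = "glms_cluster_result")
}

#' @export
print.glms_cluster_result <- function(x, ...) {
  cat(sprintf("<glms_cluster_result> contrast '%s', threshold t = %.3f (dof %d), %d permutation(s)\n",
              x$contrast, x$threshold_t, x$dof, length(x$null_distribution)))
  if (length(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      fr <- range(x$freqs[cl$points[, "freq_bin"]])
      cat(sprintf("  cluster %d: %d points, %g-%g Hz, mass %.2f, p = %.4g%s\n",
                  i, nrow(cl$points), fr[1], fr[2], cl$mass, cl$p_value,
                  if (cl$significant) " *" else ""))
    }
  }
  invisible(x)
}
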