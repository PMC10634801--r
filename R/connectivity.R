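# Layer-specific functional connectivity: seed maps, depth x depth FC
# matrices, laminar connectomes, and paired group statistics with FDR.

#' Fisher z transform of a correlation coefficient
#'
#' @param r Correlation(s), |r| < 1. NA passes through.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Seed-based functional connectivity map
#'
#' With \code{method = "glm"} the seed time course is the regressor of
#' interest in a per-target GLM and the map holds the normal-quantile z of
#' the seed t statistic (the convention for seed FC maps); with
#' \code{method = "pearson"} the map holds Fisher-z-transformed Pearson
#' correlations (the convention for FC matrices). Both are monotone in the
#' underlying correlation.
#'
#' @param seed_ts Seed time course (band-passed).
#' @param target_ts target x time matrix.
#' @param method "glm" or "pearson".
#' @return Numeric vector, one z per target.
#' @export
seed_fc_map <- function(seed_ts, target_ts, method = c("glm", "pearson")) {
  method <- match.arg(method)
  if (stats::sd(seed_ts) == 0) stop("seed time course has zero variance")
  target_ts <- as.matrix(target_ts)
  if (ncol(target_ts) != length(seed_ts))
    stop("target series length does not match the seed")
  if (method == "glm") {
    glm_fit(target_ts, glm_design(cbind(seed = seed_ts)))$z_stat
  } else {
    fisher_z(pmin(pmax(as.vector(stats::cor(seed_ts, t(target_ts))),
                       -1 + 1e-15), 1 - 1e-15))
  }
}

#' Intra-cortical depth-by-depth FC matrix
#'
#' Pairwise Pearson correlations between depth time series, Fisher-z
#' transformed, diagonal masked (self-correlation carries no information).
#' When a list of columns (vertices) is supplied, per-column matrices are
#' averaged, mirroring whole-surface averaging.
#'
#' @param layer_ts depth x time matrix, or list of such matrices.
#' @param condition Optional condition label (e.g. "b0", "b7").
#' @param subject Optional subject id.
#' @return An object of class \code{depth_fc_matrix} with element \code{z}
#'   (depth x depth, NA diagonal). Constant rows yield masked (NA) entries
#'   with a warning.
#' @export
depth_fc_matrix <- function(layer_ts, condition = NA_character_,
                            subject = NA_integer_) {
  if (is.list(layer_ts) && !is.matrix(layer_ts)) {
    zs <- lapply(layer_ts, function(m)
      depth_fc_matrix(m, condition, subject)$z)
    z <- Reduce(`+`, zs) / length(zs)
  } else {
    layer_ts <- as.matrix(layer_ts)
    if (nrow(layer_ts) < 2) stop("need at least 2 depths")
    sds <- apply(layer_ts, 1, stats::sd)
    if (any(sds == 0))
      warning("constant depth row(s) ", paste(which(sds == 0), collapse = ", "),
              ": entries masked")
    suppressWarnings(r <- stats::cor(t(layer_ts)))
    r[abs(r) >= 1] <- NA
    z <- fisher_z(r)
    diag(z) <- NA
  }
  structure(list(z = z, condition = condition, subject = subject),
            class = "depth_fc_matrix")
}

#' @export
print.depth_fc_matrix <- function(x, ...) {
  cat(sprintf("<depth_fc_matrix> %d x %d, condition %s, subject %s\n",
              nrow(x$z), ncol(x$z), x$condition, x$subject))
  invisible(x)
}

# Benjamini-Hochberg over the unmasked cells of a p matrix/vector.
bh_adjust <- function(p) {
  adj <- p
  ok <- !is.na(p)
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  adj
}

#' Paired condition contrast of depth-FC matrices
#'
#' Element-wise paired t-test of Fisher-z matrices across subjects
#' (difference = first condition minus second, so a positive t means the
#' second condition, e.g. VN, reduced connectivity), with Benjamini-Hochberg
#' FDR over the unmasked cells.
#'
#' @param matrices_a,matrices_b Lists (one per subject, same order) of
#'   \code{depth_fc_matrix} objects or raw z matrices.
#' @param q FDR level (default 0.05).
#' @param paired Must be TRUE (subjects matched across conditions).
#' @return An object of class \code{group_stat_result}: \code{mean_diff},
#'   \code{t}, \code{p}, \code{p_adj}, logical \code{significant} mask,
#'   \code{dof}.
#' @export
condition_contrast <- function(matrices_a, matrices_b, q = 0.05,
                               paired = TRUE) {
  if (!paired) stop("only the paired contrast is implemented")
  get_z <- function(m) if (inherits(m, "depth_fc_matrix")) m$z else as.matrix(m)
  za <- lapply(matrices_a, get_z)
  zb <- lapply(matrices_b, get_z)
  n <- length(za)
  if (n != length(zb)) stop("paired conditions need equal subject counts")
  if (n < 3) stop("paired t-test needs at least 3 subjects")
  diffs <- simplify2array(Map(`-`, za, zb))       # cell x cell x subject
  mean_d <- apply(diffs, c(1, 2), mean)
  sd_d <- apply(diffs, c(1, 2), stats::sd)
  tmat <- mean_d / (sd_d / sqrt(n))
  zero <- which(sd_d == 0)
  tmat[zero] <- ifelse(mean_d[zero] == 0, 0, Inf * sign(mean_d[zero]))
  dof <- n - 1
  p <- 2 * stats::pt(abs(tmat), dof, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  structure(list(mean_diff = mean_d, t = tmat, p = p, p_adj = p_adj,
                 significant = !is.na(p_adj) & p_adj < q, q = q, dof = dof),
            class = "group_stat_result")
}

#' @export
print.group_stat_result <- function(x, ...) {
  cat(sprintf("<group_stat_result> dof %d, %d/%d cells significant at q = %g\n",
              x$dof, sum(x$significant, na.rm = TRUE),
              sum(!is.na(x$p)), x$q))
  invisible(x)
}

#' Cross-layer differences of seed FC maps
#'
#' Paired differences of Fisher-z FC maps between layer conditions
#' (superficial vs middle, deep vs middle, superficial vs deep), with group
#' t statistics and BH FDR per layer pair.
#'
#' @param fc_maps Named list of layers; each element is a subject x target
#'   matrix of z values (subjects aligned across layers).
#' @param pairs Optional list of \code{c(layer_a, layer_b)} pairs; default
#'   all unordered pairs of the supplied layers.
#' @param q FDR level.
#' @return Named list (\code{"a_vs_b"}) of \code{group_stat_result}-like
#'   lists with \code{mean_diff}, \code{t}, \code{p}, \code{p_adj},
#'   \code{significant}.
#' @export
cross_layer_difference <- function(fc_maps, pairs = NULL, q = 0.05) {
  layers <- names(fc_maps)
  if (is.null(pairs))
    pairs <- utils::combn(layers, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    A <- as.matrix(fc_maps[[pr[1]]]); B <- as.matrix(fc_maps[[pr[2]]])
    if (!all(dim(A) == dim(B))) stop("maps not aligned over targets")
    D <- A - B
    n <- nrow(D)
    mean_d <- colMeans(D)
    sd_d <- apply(D, 2, stats::sd)
    tvec <- mean_d / (sd_d / sqrt(n))
    tvec[sd_d == 0 & mean_d == 0] <- 0
    p <- 2 * stats::pt(abs(tvec), n - 1, lower.tail = FALSE)
    p_adj <- bh_adjust(p)
    list(pair = pr, mean_diff = mean_d, t = tvec, p = p, p_adj = p_adj,
         significant = !is.na(p_adj) & p_adj < q, dof = n - 1)
  })
  names(out) <- vapply(pairs, function(pr) paste(pr, collapse = "_vs_"), "")
  out
}

#' Laminar (depth-dependent) connectome for ROI pairs
#'
#' For each ROI pair, computes per subject the layers_a x layers_b matrix of
#' Fisher-z correlations between layer-sampled time series, then a
#' one-sample t-test across subjects per cell with BH FDR over the cells of
#' the pair.
#'
#' @param roi_layer_ts List over subjects; each element is a named list over
#'   ROIs of layer x time matrices (rows named by layer).
#' @param roi_pairs Optional list of \code{c(roi_a, roi_b)}; default all
#'   unordered ROI pairs.
#' @param q FDR level.
#' @return Named list (\code{"roiA_roiB"}) with \code{mean_z}, \code{t},
#'   \code{p}, \code{p_adj}, \code{significant}, \code{z_per_subject}.
#' @export
laminar_connectome <- function(roi_layer_ts, roi_pairs = NULL, q = 0.05) {
  rois <- names(roi_layer_ts[[1]])
  for (s in seq_along(roi_layer_ts))
    if (!all(rois %in% names(roi_layer_ts[[s]])))
      stop("subject ", s, " is missing ROI time series: ",
           paste(setdiff(rois, names(roi_layer_ts[[s]])), collapse = ", "))
  if (is.null(roi_pairs))
    roi_pairs <- utils::combn(rois, 2, simplify = FALSE)
  out <- lapply(roi_pairs, function(pr) {
    zs <- lapply(roi_layer_ts, function(subj) {
      A <- as.matrix(subj[[pr[1]]]); B <- as.matrix(subj[[pr[2]]])
      r <- stats::cor(t(A), t(B))
      fisher_z(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    })
    arr <- simplify2array(zs)
    n <- length(zs)
    mean_z <- apply(arr, c(1, 2), mean)
    sd_z <- apply(arr, c(1, 2), stats::sd)
    tmat <- mean_z / (sd_z / sqrt(n))
    p <- 2 * stats::pt(abs(tmat), n - 1, lower.tail = FALSE)
    p_adj <- bh_adjust(p)
    list(pair = pr, mean_z = mean_z, t = tmat, p = p, p_adj = p_adj,
         significant = !is.na(p_adj) & p_adj < q, dof = n - 1,
         z_per_subject = zs)
  })
  names(out) <- vapply(roi_pairs, paste, "", collapse = "_")
  out
}
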