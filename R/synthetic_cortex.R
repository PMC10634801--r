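# Synthetic cortical-column generator: depth-resolved complex-valued BOLD
# with laminar neural sources, penetrating-vein drainage, pial-vein blooming,
# velocity-nulling attenuation and complex Gaussian noise.

#' Block-design stimulation paradigm
#'
#' @param n_blocks Number of ON/OFF cycles (default 18, as in a 30 s ON /
#'   30 s OFF button-pressing protocol of 270 volumes at TR 4 s).
#' @param on_s,off_s Block durations in seconds (default 30/30).
#' @param TR_s Volume repetition time in seconds (default 4).
#' @param press_rate_hz Annotation only: cued movement rate (default 2 Hz).
#' @return An object of class \code{block_paradigm}.
#' @export
block_paradigm <- function(n_blocks = 18, on_s = 30, off_s = 30, TR_s = 4,
                           press_rate_hz = 2) {
  if (n_blocks < 1 || on_s <= 0 || off_s <= 0 || TR_s <= 0)
    stop("paradigm durations must be positive")
  nv <- n_blocks * (on_s + off_s) / TR_s
  if (abs(nv - round(nv)) > 1e-9)
    stop("TR does not divide the block cycle: non-integer volume count")
  structure(list(n_blocks = n_blocks, on_s = on_s, off_s = off_s,
                 TR_s = TR_s, press_rate_hz = press_rate_hz),
            class = "block_paradigm")
}

#' Number of volumes implied by a block paradigm
#'
#' @param paradigm A \code{block_paradigm}.
#' @return Integer volume count, \code{n_blocks * (on_s + off_s) / TR_s}.
#' @examples
#' n_volumes(block_paradigm(18, 30, 30, 4))  # 270
#' @export
n_volumes <- function(paradigm) {
  stopifnot(inherits(paradigm, "block_paradigm"))
  as.integer(round(paradigm$n_blocks * (paradigm$on_s + paradigm$off_s) /
                     paradigm$TR_s))
}

#' Task boxcar sampled at the TR (ON block first)
#' @param paradigm A \code{block_paradigm}.
#' @return 0/1 vector of length \code{n_volumes(paradigm)}.
#' @export
task_boxcar <- function(paradigm) {
  nv <- n_volumes(paradigm)
  t_s <- (seq_len(nv) - 1) * paradigm$TR_s
  cycle <- paradigm$on_s + paradigm$off_s
  as.numeric((t_s %% cycle) < paradigm$on_s)
}

#' Cortical-column forward-model specification
#'
#' Defines the depth grid and the per-depth compartment weights of one
#' cortical column. The depth convention follows equidistant layering over
#' the extended ribbon \code{[-0.125, 1.0625]} with 0 at the GM/WM boundary
#' and 1 at the CSF/GM boundary; depth values are the centres of
#' \code{n_depths} equal bins. Penetrating-vein blood volume increases
#' linearly from deep to superficial cortex, so the default vein weight is
#' \code{max(depth, 0)}. Pial veins sit at the CSF/GM boundary; the distance
#' from a depth to the pial vessel surface is the vessel radius plus the
#' within-ribbon distance to depth 1 scaled by the cortical thickness.
#'
#' @param n_depths Number of depth bins (default 20).
#' @param depth_range Depth span (default \code{c(-0.125, 1.0625)}).
#' @param tissue_weight Per-depth tissue/capillary weight, recycled
#'   (default 1).
#' @param vein_weight Per-depth penetrating-vein weight; default linear
#'   \code{pmax(depth, 0)}.
#' @param drain_fraction Fraction of deeper-layer vein signal carried upward
#'   per depth step, in [0, 1] (default 0.4).
#' @param pial_diameter_mm Pial vessel diameter in mm (default 0.3).
#' @param cortical_thickness_mm Ribbon thickness used to convert depth
#'   fractions to mm (default 2).
#' @param baseline Baseline magnitude, arbitrary units (default 100).
#' @return An object of class \code{cortical_column_spec}.
#' @export
cortical_column_spec <- function(n_depths = 20,
                                 depth_range = c(-0.125, 1.0625),
                                 tissue_weight = 1,
                                 vein_weight = NULL,
                                 drain_fraction = 0.4,
                                 pial_diameter_mm = 0.3,
                                 cortical_thickness_mm = 2,
                                 baseline = 100) {
  if (n_depths < 1) stop("n_depths must be >= 1")
  if (drain_fraction < 0 || drain_fraction > 1)
    stop("drain_fraction must lie in [0, 1]")
  w <- diff(depth_range) / n_depths
  depth <- depth_range[1] + (seq_len(n_depths) - 0.5) * w
  tissue_weight <- rep_len(tissue_weight, n_depths)
  if (is.null(vein_weight)) vein_weight <- pmax(depth, 0)
  vein_weight <- rep_len(vein_weight, n_depths)
  if (any(tissue_weight < 0) || any(vein_weight < 0))
    stop("compartment weights must be non-negative")
  radius <- pial_diameter_mm / 2
  pial_distance_mm <- radius + pmax(1 - depth, 0) * cortical_thickness_mm
  structure(list(
    n_depths = n_depths, depth_range = depth_range, depth = depth,
    tissue_weight = tissue_weight, vein_weight = vein_weight,
    drain_fraction = drain_fraction,
    pial_diameter_mm = pial_diameter_mm,
    cortical_thickness_mm = cortical_thickness_mm,
    pial_distance_mm = pial_distance_mm,
    baseline = baseline
  ), class = "cortical_column_spec")
}

#' @export
print.cortical_column_spec <- function(x, ...) {
  cat(sprintf("<cortical_column_spec> %d depths over [%g, %g], drain %.2f, pial %g mm\n",
              x$n_depths, x$depth_range[1], x$depth_range[2],
              x$drain_fraction, x$pial_diameter_mm))
  invisible(x)
}

#' Draining-vein leakage operator
#'
#' Intracortical (penetrating) veins drain towards the pial surface, so the
#' vein compartment at a depth accumulates signal originating in that depth
#' and all deeper ones: \code{vein[k, ] = vein_weight[k] * sum_{j <= k}
#' drain_fraction^(k - j) * laminar[j, ]} with depth rows ordered from white
#' matter (row 1) to pial surface. The mixing is linear and strictly
#' one-directional (deep activity propagates up, never down).
#'
#' @param laminar_signal depth x time matrix of laminar source signal,
#'   ordered WM to pial.
#' @param drain_fraction Per-step drainage fraction in [0, 1].
#' @param vein_weight Per-depth vein weight (recycled).
#' @return depth x time matrix of vein-compartment signal.
#' @export
leakage_operator <- function(laminar_signal, drain_fraction, vein_weight) {
  laminar_signal <- as.matrix(laminar_signal)
  if (drain_fraction < 0 || drain_fraction > 1)
    stop("drain_fraction must lie in [0, 1]")
  nd <- nrow(laminar_signal)
  vein_weight <- rep_len(vein_weight, nd)
  step <- outer(seq_len(nd), seq_len(nd), "-")  # k - j
  L <- ifelse(step >= 0, drain_fraction^step, 0)
  if (drain_fraction == 0) L <- diag(nd)        # 0^0 ambiguity guard
  vein_weight * (L %*% laminar_signal)
}

#' Extravascular (blooming) perturbation from a pial vein
#'
#' The susceptibility field of a pial vessel contaminates voxels at depth d
#' with weight \code{(radius / pial_distance(d))^2} (inverse-square falloff
#' referenced to the vessel surface). Both a magnitude and a phase
#' perturbation are produced; the phase component is what phase regression
#' exploits to remove the magnitude component.
#'
#' @param column A \code{cortical_column_spec}.
#' @param pial_signal Time course of the pial vessel fluctuation.
#' @param mag_scale,phase_scale Scalars applied to the magnitude (a.u.) and
#'   phase (rad) perturbations.
#' @return List with depth x time matrices \code{magnitude} and \code{phase}.
#' @export
pial_extravascular_term <- function(column, pial_signal,
                                    mag_scale = 1, phase_scale = 1) {
  stopifnot(inherits(column, "cortical_column_spec"))
  r <- column$pial_diameter_mm / 2
  w <- (r / column$pial_distance_mm)^2
  list(magnitude = outer(w, pial_signal) * mag_scale,
       phase = outer(w, pial_signal) * phase_scale)
}

# Wrap angles to (-pi, pi]
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Complex-valued (magnitude + phase) depth-resolved time series
#'
#' @param magnitude site x time matrix (>= 0 after baseline offset).
#' @param phase site x time matrix in radians; wrapped to (-pi, pi] on
#'   construction.
#' @param TR_s Sampling interval in seconds.
#' @param sites data.frame with one row per site (columns \code{roi},
#'   \code{depth}).
#' @return An object of class \code{complex_timeseries}.
#' @export
complex_timeseries <- function(magnitude, phase, TR_s, sites) {
  magnitude <- as.matrix(magnitude); phase <- as.matrix(phase)
  if (!all(dim(magnitude) == dim(phase)))
    stop("magnitude and phase must have congruent shapes")
  if (nrow(sites) != nrow(magnitude))
    stop("site metadata does not match the number of rows")
  structure(list(magnitude = magnitude, phase = wrap_phase(phase),
                 TR_s = TR_s, sites = sites),
            class = "complex_timeseries")
}

#' @export
print.complex_timeseries <- function(x, ...) {
  cat(sprintf("<complex_timeseries> %d sites x %d volumes, TR = %g s\n",
              nrow(x$magnitude), ncol(x$magnitude), x$TR_s))
  invisible(x)
}

#' Laminar network specification for resting-state simulation
#'
#' Ground-truth inter-regional correlation structure between laminar sources.
#' Layers map to cortical-depth sampling windows (superficial 0.85-0.9,
#' middle 0.45-0.5, deep 0.1-0.15, the standard projection-fraction ranges).
#'
#' @param rois Character vector of region labels.
#' @param edges data.frame with columns \code{roi_a}, \code{layer_a},
#'   \code{roi_b}, \code{layer_b}, \code{r} (|r| < 1); may have zero rows.
#' @param layer_windows Named list mapping layer names to depth windows.
#' @param band Fluctuation band in Hz (default \code{c(0.01, 0.1)}).
#' @return An object of class \code{laminar_network_spec}.
#' @export
laminar_network_spec <- function(rois, edges = NULL,
                                 layer_windows = canonical_layer_windows(),
                                 band = c(0.01, 0.1)) {
  if (is.null(edges))
    edges <- data.frame(roi_a = character(), layer_a = character(),
                        roi_b = character(), layer_b = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  need <- c("roi_a", "layer_a", "roi_b", "layer_b", "r")
  if (!all(need %in% names(edges))) stop("edges must have columns ",
                                         paste(need, collapse = ", "))
  if (any(abs(edges$r) >= 1)) stop("edge correlations must satisfy |r| < 1")
  bad_roi <- setdiff(c(edges$roi_a, edges$roi_b), rois)
  if (length(bad_roi)) stop("edge refers to unknown ROI: ",
                            paste(bad_roi, collapse = ", "))
  bad_layer <- setdiff(c(edges$layer_a, edges$layer_b), names(layer_windows))
  if (length(bad_layer)) stop("edge refers to unknown layer: ",
                              paste(bad_layer, collapse = ", "))
  structure(list(rois = rois, edges = edges, layer_windows = layer_windows,
                 band = band),
            class = "laminar_network_spec")
}

#' Canonical depth sampling windows for the three-layer scheme
#' @return Named list of \code{c(lo, hi)} depth windows.
#' @export
canonical_layer_windows <- function() {
  list(superficial = c(0.85, 0.90), middle = c(0.45, 0.50),
       deep = c(0.10, 0.15), overall = c(0.10, 0.90))
}

#' Default two-region laminar network
#'
#' M1 and S1 with superficial-superficial and deep-deep coupling, the kind of
#' sensorimotor laminar structure seed-based layer fMRI aims to resolve.
#' @param r Edge correlation (default 0.5).
#' @return A \code{laminar_network_spec}.
#' @export
default_laminar_network <- function(r = 0.5) {
  laminar_network_spec(
    rois = c("M1", "S1"),
    edges = data.frame(
      roi_a = c("M1", "M1"), layer_a = c("superficial", "deep"),
      roi_b = c("S1", "S1"), layer_b = c("superficial", "deep"),
      r = c(r, r), stringsAsFactors = FALSE))
}

# Band-limited unit-variance Gaussian processes with a target correlation
# matrix R: white noise -> chol mixing -> zero-phase band-pass -> rescale.
bandlimited_sources <- function(n_volumes, R, TR_s, band) {
  k <- nrow(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("source correlation matrix is not positive semi-definite")
  white <- matrix(stats::rnorm(n_volumes * k), n_volumes, k)
  mixed <- white %*% chol(R + diag(1e-10, k))
  filt <- apply(mixed, 2, function(x)
    bandpass(x, low_hz = band[1], high_hz = band[2], TR_s = TR_s))
  scale(filt, center = TRUE, scale = apply(filt, 2, stats::sd))
}

# Correlation matrix over (roi x depth) laminar sources implied by a network
# spec: identity plus edge correlations between depths falling in the linked
# layer windows. Returns the matrix plus the (roi, depth) index table.
network_source_correlation <- function(network, column) {
  nd <- column$n_depths
  idx <- expand.grid(depth_i = seq_len(nd), roi = network$rois,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx$depth <- column$depth[idx$depth_i]
  k <- nrow(idx)
  R <- diag(k)
  in_window <- function(roi, layer) {
    wdw <- network$layer_windows[[layer]]
    which(idx$roi == roi & idx$depth >= wdw[1] & idx$depth <= wdw[2])
  }
  for (e in seq_len(nrow(network$edges))) {
    ed <- network$edges[e, ]
    ia <- in_window(ed$roi_a, ed$layer_a)
    ib <- in_window(ed$roi_b, ed$layer_b)
    if (!length(ia) || !length(ib))
      stop("edge ", ed$roi_a, ":", ed$layer_a, " - ", ed$roi_b, ":",
           ed$layer_b, " maps to no depth bin")
    R[ia, ib] <- ed$r
    R[ib, ia] <- ed$r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("network correlation matrix is not positive semi-definite; ",
         "offending edges: ",
         paste(sprintf("%s:%s-%s:%s r=%g", network$edges$roi_a,
                       network$edges$layer_a, network$edges$roi_b,
                       network$edges$layer_b, network$edges$r),
               collapse = "; "))
  }
  list(R = R, index = idx)
}

# Forward model of one column: laminar (tissue) signal in, complex-valued
# observation out. All vascular terms pass through the VN attenuation of
# their compartment; the pial blooming term is extravascular and does not.
forward_vn_column <- function(column, laminar, b = 0,
                              compartments = canonical_compartments(),
                              noise_sd = 0.5,
                              pial_signal = NULL,
                              arterial_signal = NULL,
                              amp_vein = 1, amp_artery = 0.2, amp_pial = 1,
                              phase_coupling = 0.02,
                              roi = "column") {
  laminar <- as.matrix(laminar)
  nd <- nrow(laminar); nt <- ncol(laminar)
  stopifnot(nd == column$n_depths)
  att_cap  <- vn_attenuation(b, compartments$capillary)
  att_vein <- vn_attenuation(b, compartments$vein)
  att_art  <- vn_attenuation(b, compartments$artery)

  tissue <- att_cap * (column$tissue_weight * laminar)
  vein <- att_vein * amp_vein *
    leakage_operator(laminar, column$drain_fraction, column$vein_weight)
  artery <- if (is.null(arterial_signal)) 0 else
    att_art * amp_artery * outer(rep(1, nd), arterial_signal)
  pial <- if (is.null(pial_signal))
    list(magnitude = matrix(0, nd, nt), phase = matrix(0, nd, nt)) else
    pial_extravascular_term(column, pial_signal, mag_scale = amp_pial,
                            phase_scale = amp_pial)

  macrovascular <- vein + pial$magnitude
  magnitude <- column$baseline + tissue + macrovascular + artery +
    matrix(stats::rnorm(nd * nt, sd = noise_sd), nd, nt)
  # Complex Gaussian noise: at SNR = baseline / noise_sd the phase noise SD
  # is approximately noise_sd / baseline radians.
  phase <- phase_coupling * macrovascular +
    matrix(stats::rnorm(nd * nt, sd = noise_sd / column$baseline), nd, nt)
  complex_timeseries(magnitude, phase, TR_s = NA_real_,
                     sites = data.frame(roi = roi, depth = column$depth,
                                        stringsAsFactors = FALSE))
}

#' Default double-peaked laminar activation profile
#'
#' Motor-output tasks engage the superficial (input) and deep (output) layers
#' of M1 while sparing the middle layers; the resulting double-peak depth
#' profile is the standard spatial-specificity benchmark. Peaks default to
#' depths 0.15 (deep) and 0.85 (superficial).
#'
#' @param column A \code{cortical_column_spec}.
#' @param peaks Depth locations of the two peaks.
#' @param width Gaussian width of each peak in depth units.
#' @return Per-depth weight vector, max 1, with attribute \code{"peaks"}.
#' @export
double_peak_profile <- function(column, peaks = c(0.15, 0.85), width = 0.1) {
  p <- rowSums(sapply(peaks, function(mu) exp(-((column$depth - mu) / width)^2)))
  p <- p / max(p)
  attr(p, "peaks") <- peaks
  p
}

#' Simulate a block-design task run for one cortical column
#'
#' Generates magnitude and phase time series as baseline plus an
#' HRF-convolved laminar tissue response, a drained penetrating-vein term, an
#' arterial term, the extravascular pial blooming term, and complex Gaussian
#' noise. Each intravascular term is attenuated by the VN factor of its
#' compartment; the extravascular pial term is not. Phase carries the
#' macrovascular (vein + pial) contributions only, which is what makes phase
#' regression effective.
#'
#' @param column A \code{cortical_column_spec}.
#' @param paradigm A \code{block_paradigm}.
#' @param activation_profile Per-depth evoked weights (default
#'   \code{double_peak_profile(column)}).
#' @param b VN gradient b value, s/mm^2 (default 0).
#' @param noise_sd Magnitude noise SD in a.u. (baseline 100; default 0.5).
#' @param seed Integer seed; required because the run is stochastic.
#' @param amp_task Peak evoked tissue amplitude, a.u. (default 2, i.e. 2\%
#'   of baseline).
#' @param amp_pial Pial vessel response amplitude at the vessel surface,
#'   a.u. (default 4).
#' @param amp_vein,amp_artery Vein and arterial term scales.
#' @param phase_coupling Radians of phase per a.u. of macrovascular
#'   magnitude (default 0.02).
#' @param compartments Vascular compartment list.
#' @return A \code{complex_timeseries} with attribute \code{ground_truth}
#'   (profile, response, paradigm, b).
#' @export
simulate_task <- function(column, paradigm = block_paradigm(),
                          activation_profile = NULL, b = 0, noise_sd = 0.5,
                          seed, amp_task = 2, amp_pial = 4,
                          amp_vein = 1, amp_artery = 0.2,
                          phase_coupling = 0.02,
                          compartments = canonical_compartments()) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for stochastic simulation")
  set.seed(seed)
  if (is.null(activation_profile)) activation_profile <- double_peak_profile(column)
  activation_profile <- rep_len(activation_profile, column$n_depths)
  box <- task_boxcar(paradigm)
  hrf <- double_gamma_hrf(paradigm$TR_s)
  resp <- stats::convolve(box, rev(hrf), type = "open")[seq_along(box)]
  resp <- resp / max(resp)
  laminar <- amp_task * outer(activation_profile, resp)
  cts <- forward_vn_column(column, laminar, b = b,
                           compartments = compartments, noise_sd = noise_sd,
                           pial_signal = resp, arterial_signal = resp,
                           amp_vein = amp_vein, amp_artery = amp_artery,
                           amp_pial = amp_pial,
                           phase_coupling = phase_coupling, roi = "M1")
  cts$TR_s <- paradigm$TR_s
  attr(cts, "ground_truth") <- list(activation_profile = activation_profile,
                                    response = resp, paradigm = paradigm,
                                    b = b, noise_sd = noise_sd)
  cts
}

# Shared machinery: draw laminar sources + pial fluctuations for every ROI
# (once per subject), to be pushed through the forward model per condition.
rest_sources <- function(network, column, n_volumes, TR_s) {
  src <- network_source_correlation(network, column)
  S <- bandlimited_sources(n_volumes, src$R, TR_s, network$band)
  pial <- sapply(network$rois, function(r) {
    p <- bandpass(stats::rnorm(n_volumes), network$band[1], network$band[2],
                  TR_s)
    p / stats::sd(p)
  })
  list(laminar = S, index = src$index, pial = pial)
}

rest_forward <- function(network, column, sources, b, noise_sd, TR_s,
                         amp_vein = 1, amp_pial = 1, phase_coupling = 0.02,
                         rest_sd = 1,
                         compartments = canonical_compartments()) {
  out <- lapply(network$rois, function(roi) {
    rows <- which(sources$index$roi == roi)
    laminar <- rest_sd * t(sources$laminar[, rows, drop = FALSE])
    cts <- forward_vn_column(column, laminar, b = b,
                             compartments = compartments,
                             noise_sd = noise_sd,
                             pial_signal = sources$pial[, roi],
                             amp_vein = amp_vein, amp_pial = amp_pial,
                             phase_coupling = phase_coupling, roi = roi)
    cts$TR_s <- TR_s
    cts
  })
  names(out) <- network$rois
  out
}

#' Simulate a resting-state run over a laminar network
#'
#' Laminar neural sources are unit-variance Gaussian processes band-limited
#' to the network's fluctuation band (default 0.01-0.1 Hz), one per
#' (region, depth), with the cross-region/cross-layer correlations given by
#' the network edges; depths not linked by an edge are mutually independent.
#' Sources are forwarded through the draining-vein, pial-blooming and VN
#' attenuation model exactly as in \code{\link{simulate_task}}.
#'
#' @param network A \code{laminar_network_spec}.
#' @param column A \code{cortical_column_spec} shared by all regions.
#' @param b VN b value, s/mm^2.
#' @param noise_sd Magnitude noise SD, a.u.
#' @param n_volumes Number of volumes (default 300, a 20-minute run at
#'   TR 4 s).
#' @param TR_s Repetition time, s.
#' @param seed Integer seed (required).
#' @param rest_sd Laminar fluctuation SD in a.u. (default 1).
#' @param amp_vein,amp_pial,phase_coupling Forward-model scales as in
#'   \code{\link{simulate_task}}.
#' @return Named list of \code{complex_timeseries}, one per region, with
#'   attribute \code{ground_truth}.
#' @export
simulate_rest <- function(network = default_laminar_network(),
                          column = cortical_column_spec(),
                          b = 0, noise_sd = 0.5, n_volumes = 300, TR_s = 4,
                          seed, rest_sd = 1, amp_vein = 1, amp_pial = 1,
                          phase_coupling = 0.02) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for stochastic simulation")
  set.seed(seed)
  sources <- rest_sources(network, column, n_volumes, TR_s)
  runs <- rest_forward(network, column, sources, b = b, noise_sd = noise_sd,
                       TR_s = TR_s, amp_vein = amp_vein, amp_pial = amp_pial,
                       phase_coupling = phase_coupling, rest_sd = rest_sd)
  attr(runs, "ground_truth") <- list(network = network, b = b,
                                     noise_sd = noise_sd)
  runs
}

#' Simulate a paired-condition subject cohort
#'
#' Draws a cohort of subjects, each with one parameter jitter (drainage and
#' vein amplitude) applied once, and simulates a paired pair of resting-state
#' runs per subject (default b = 0 and b = 7 s/mm^2). Both conditions share
#' the subject's laminar neural sources, so paired condition contrasts are
#' meaningful; measurement noise is drawn independently per run.
#'
#' @param n_subjects Number of subjects (default 14).
#' @param between_subject_sd Relative SD of the multiplicative parameter
#'   jitter (default 0.1).
#' @param seed Integer seed (required).
#' @param network A \code{laminar_network_spec}.
#' @param column Template \code{cortical_column_spec}.
#' @param b_values Conditions, s/mm^2 (default \code{c(0, 7)}).
#' @param n_volumes,TR_s,noise_sd,rest_sd,amp_vein,amp_pial As in
#'   \code{\link{simulate_rest}}.
#' @return List of subjects; each has \code{id}, \code{params} and
#'   \code{runs} (named "b0", "b7", ... lists of per-region
#'   \code{complex_timeseries}).
#' @export
make_subject_cohort <- function(n_subjects = 14, between_subject_sd = 0.1,
                                seed, network = default_laminar_network(),
                                column = cortical_column_spec(),
                                b_values = c(0, 7), n_volumes = 300,
                                TR_s = 4, noise_sd = 0.5, rest_sd = 1,
                                amp_vein = 1, amp_pial = 1) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for stochastic simulation")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    drain_s <- min(1, max(0, column$drain_fraction *
                            (1 + between_subject_sd * stats::rnorm(1))))
    amp_vein_s <- max(0, amp_vein * (1 + between_subject_sd * stats::rnorm(1)))
    col_s <- column
    col_s$drain_fraction <- drain_s
    sources <- rest_sources(network, col_s, n_volumes, TR_s)
    runs <- lapply(b_values, function(b)
      rest_forward(network, col_s, sources, b = b, noise_sd = noise_sd,
                   TR_s = TR_s, amp_vein = amp_vein_s, amp_pial = amp_pial,
                   rest_sd = rest_sd))
    names(runs) <- paste0("b", b_values)
    list(id = s, params = list(drain_fraction = drain_s,
                               amp_vein = amp_vein_s),
         runs = runs)
  })
}
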