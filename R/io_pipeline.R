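# File formats, pipeline driver and fixture generation. Synthetic data use
# a depth-as-spatial-axis NIfTI convention (sites x 1 x 1 x time) so that
# standard tools can open the outputs; site metadata travel in a TSV table
# and ground truth in a JSON sidecar.

#' Write a complex time series as a magnitude/phase NIfTI pair
#'
#' @param cts A \code{complex_timeseries}.
#' @param mag_path,phase_path Output NIfTI paths (.nii).
#' @param site_path Optional TSV path for the site table.
#' @return Invisibly, the paths written. Phase is stored wrapped to
#'   (-pi, pi]; TR is recorded in the 4th pixdim slot.
#' @export
write_complex_nifti <- function(cts, mag_path, phase_path,
                                site_path = NULL) {
  stopifnot(inherits(cts, "complex_timeseries"))
  if (is.na(cts$TR_s) || cts$TR_s <= 0)
    stop("complex_timeseries has no valid TR to record in the header")
  as_img <- function(m) {
    img <- RNifti::asNifti(array(m, dim = c(nrow(m), 1, 1, ncol(m))))
    RNifti::pixdim(img) <- c(1, 1, 1, cts$TR_s)
    img
  }
  RNifti::writeNifti(as_img(cts$magnitude), mag_path)
  RNifti::writeNifti(as_img(wrap_phase(cts$phase)), phase_path)
  if (!is.null(site_path))
    utils::write.table(cts$sites, site_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(c(mag_path, phase_path))
}

#' Read a magnitude/phase NIfTI pair into a complex time series
#'
#' @param mag_path,phase_path NIfTI paths with congruent shapes and matching
#'   TR in the 4th pixdim slot.
#' @param site_path Optional TSV site table (columns \code{roi},
#'   \code{depth}).
#' @return A \code{complex_timeseries}.
#' @export
read_complex_nifti <- function(mag_path, phase_path, site_path = NULL) {
  mag <- RNifti::readNifti(mag_path)
  ph <- RNifti::readNifti(phase_path)
  if (!all(dim(mag) == dim(ph)))
    stop("magnitude and phase volumes have different shapes")
  tr <- RNifti::pixdim(mag)[4]
  tr2 <- RNifti::pixdim(ph)[4]
  if (is.na(tr) || tr <= 0 || abs(tr - tr2) > 1e-6)
    stop("TR missing or mismatched in NIfTI headers; set pixdim[4] to the ",
         "repetition time in seconds (see write_complex_nifti)")
  d <- dim(mag)
  nt <- d[length(d)]
  nsite <- prod(d[-length(d)])
  m <- matrix(as.vector(mag), nsite, nt)
  p <- matrix(as.vector(ph), nsite, nt)
  sites <- if (!is.null(site_path))
    utils::read.table(site_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(roi = "unknown", depth = NA_real_,
                  stringsAsFactors = FALSE)[rep(1, nsite), , drop = FALSE]
  complex_timeseries(m, p, TR_s = tr, sites = sites)
}

pipeline_defaults <- function() {
  list(seed = NULL, n_subjects = 14, between_subject_sd = 0.1,
       b_values = c(0, 7), n_volumes = 300, TR_s = 4, noise_sd = 0.5,
       network_r = 0.5, drain_fraction = 0.4,
       phase_regression = TRUE, filter = "band", out_dir = NULL)
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed))
    stop("config error: a master seed is required for stochastic stages")
  if (!cfg$filter %in% c("band", "high"))
    stop("config error: filter must be 'band' or 'high'")
  cfg
}

#' Run the end-to-end synthetic pipeline
#'
#' Simulate a paired-condition cohort, condition the signals (phase
#' regression, then temporal filtering), extract depth-resolved time series,
#' compute per-subject depth-FC matrices per condition, and contrast the
#' conditions with a paired test under FDR. Deterministic for a fixed master
#' seed. When \code{out_dir} is set, writes the contrast table
#' (\code{depth_fc_contrast.tsv}), the mean matrices per condition, and a
#' JSON provenance sidecar sufficient to regenerate the outputs.
#'
#' @param config Named list (or path to a JSON file) with any of: \code{seed}
#'   (required), \code{n_subjects}, \code{between_subject_sd},
#'   \code{b_values}, \code{n_volumes}, \code{TR_s}, \code{noise_sd},
#'   \code{network_r}, \code{drain_fraction}, \code{phase_regression},
#'   \code{filter} ("band"/"high"), \code{out_dir}. Unknown keys are
#'   rejected.
#' @return List with \code{cohort_summary}, per-condition mean depth-FC
#'   matrices, the \code{contrast} (\code{group_stat_result}) and the
#'   resolved \code{config}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_pipeline_config(as.list(config))
  column <- cortical_column_spec(drain_fraction = cfg$drain_fraction)
  network <- default_laminar_network(r = cfg$network_r)
  cohort <- make_subject_cohort(
    n_subjects = cfg$n_subjects, between_subject_sd = cfg$between_subject_sd,
    seed = cfg$seed, network = network, column = column,
    b_values = cfg$b_values, n_volumes = cfg$n_volumes, TR_s = cfg$TR_s,
    noise_sd = cfg$noise_sd)

  clean <- function(cts) {
    mag <- cts$magnitude
    if (isTRUE(cfg$phase_regression))
      mag <- phase_regress(mag, unwrap_phase(cts$phase))
    if (cfg$filter == "band")
      bandpass(mag, TR_s = cts$TR_s)
    else
      highpass(mag, TR_s = cts$TR_s)
  }
  cond_names <- paste0("b", cfg$b_values)
  fc <- lapply(cond_names, function(cn)
    lapply(cohort, function(subj) {
      mats <- lapply(subj$runs[[cn]], clean)     # one per ROI (column)
      depth_fc_matrix(mats, condition = cn, subject = subj$id)
    }))
  names(fc) <- cond_names
  mean_fc <- lapply(fc, function(lst)
    Reduce(`+`, lapply(lst, `[[`, "z")) / length(lst))
  contrast <- if (length(cond_names) >= 2)
    condition_contrast(fc[[1]], fc[[2]]) else NULL

  result <- list(
    cohort_summary = data.frame(
      subject = vapply(cohort, `[[`, 0, "id"),
      drain_fraction = vapply(cohort, function(s) s$params$drain_fraction, 0),
      amp_vein = vapply(cohort, function(s) s$params$amp_vein, 0)),
    mean_fc = mean_fc, fc = fc, contrast = contrast, config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv <- function(m, path, what) {
      con <- file(path, "w")
      writeLines(paste0("# ", what), con)
      utils::write.table(round(m, 6), con, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
      close(con)
    }
    for (cn in cond_names)
      write_matrix_tsv(mean_fc[[cn]], file.path(cfg$out_dir,
                                                paste0("mean_fc_", cn, ".tsv")),
                       paste("mean depth-FC Fisher z, condition", cn))
    if (!is.null(contrast)) {
      write_matrix_tsv(contrast$t, file.path(cfg$out_dir,
                                             "depth_fc_contrast.tsv"),
                       sprintf("paired t (%s - %s), dof %d",
                               cond_names[1], cond_names[2], contrast$dof))
      write_matrix_tsv(contrast$p_adj,
                       file.path(cfg$out_dir, "depth_fc_contrast_padj.tsv"),
                       "BH-adjusted p values")
    }
    prov <- list(package = "layervn",
                 version = as.character(utils::packageVersion("layervn")),
                 config = cfg, created = "run_pipeline")
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' Generate the bundled demonstration fixtures
#'
#' Three small deterministic datasets: (1) a single task column with the
#' double-peak laminar response, (2) a two-region laminar network
#' resting-state cohort, (3) the matching null-network cohort (all edge
#' correlations zero). Regenerated bit-identically from the recorded seed.
#'
#' @param seed Integer master seed.
#' @param n_subjects Cohort size for fixtures 2 and 3 (default 6, kept small
#'   so regeneration is fast).
#' @param n_volumes Resting-run length (default 300).
#' @return Named list \code{task_column}, \code{network_cohort},
#'   \code{null_cohort}, plus \code{seed}.
#' @export
make_fixtures <- function(seed, n_subjects = 6, n_volumes = 300) {
  if (missing(seed)) stop("a seed is required")
  column <- cortical_column_spec()
  list(
    task_column = simulate_task(column, block_paradigm(), b = 7,
                                noise_sd = 0.2, seed = seed),
    network_cohort = make_subject_cohort(
      n_subjects = n_subjects, seed = seed + 1, column = column,
      n_volumes = n_volumes),
    null_cohort = make_subject_cohort(
      n_subjects = n_subjects, seed = seed + 2, column = column,
      network = laminar_network_spec(rois = c("M1", "S1")),
      n_volumes = n_volumes),
    seed = seed)
}
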