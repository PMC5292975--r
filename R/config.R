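#' Pipeline configuration
#'
#' Collects every tunable threshold of the QC / imputation / mapping / QTL
#' pipeline in one validated list.  Defaults reproduce the reference
#' analysis settings for a GBS-genotyped F7 RIL population.
#'
#' @param anchor_lod LOD threshold for linkage grouping of anchor markers.
#' @param fisher_alpha significance level of the anchor Fisher filter; a
#'   marker is dropped when any of its nearest-four-anchor tests has
#'   p above this value.
#' @param window_size sliding-window width in markers (odd, >= 3).
#' @param window_threshold window score above which the central call is
#'   removed.
#' @param end_skip markers at each chromosome end left uncorrected by the
#'   sliding window.
#' @param max_missing per-marker missing-fraction cap of the final filter.
#' @param min_maf per-marker minor-allele-frequency floor.
#' @param distortion_alpha family-wise level of the Bonferroni-corrected
#'   segregation-distortion scan.
#' @param hmm_error HMM emission (genotyping-error) rate.
#' @param hmm_het residual-heterozygosity level of the HMM hidden chain.
#' @param hmm_tau posterior threshold below which a missing cell is left
#'   unimputed.
#' @param cm_per_mb physical-to-genetic scale used for HMM transition
#'   distances before a genetic map exists.
#' @param cim_step scan grid step, cM.
#' @param cim_window cofactor exclusion window around the test position, cM.
#' @param n_cofactors number of CIM background cofactors (2-5).
#' @param n_perm permutations for the genome-wide LOD threshold.
#' @param perm_alpha genome-wide false-positive level.
#' @param ci_coverage Bayes credible-interval coverage.
#' @param seed integer seed used by any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(anchor_lod = 10, fisher_alpha = 0.05,
                            window_size = 25L, window_threshold = 0.8,
                            end_skip = 12L, max_missing = 0.10,
                            min_maf = 0.05, distortion_alpha = 0.05,
                            hmm_error = 0.005, hmm_het = 0.015625,
                            hmm_tau = 0.95, cm_per_mb = 3.0,
                            cim_step = 1, cim_window = 10,
                            n_cofactors = 3L, n_perm = 1000L,
                            perm_alpha = 0.05, ci_coverage = 0.95,
                            seed = 1L) {
  cfg <- list(anchor_lod = anchor_lod, fisher_alpha = fisher_alpha,
              window_size = as.integer(window_size),
              window_threshold = window_threshold,
              end_skip = as.integer(end_skip), max_missing = max_missing,
              min_maf = min_maf, distortion_alpha = distortion_alpha,
              hmm_error = hmm_error, hmm_het = hmm_het, hmm_tau = hmm_tau,
              cm_per_mb = cm_per_mb, cim_step = cim_step,
              cim_window = cim_window, n_cofactors = as.integer(n_cofactors),
              n_perm = as.integer(n_perm), perm_alpha = perm_alpha,
              ci_coverage = ci_coverage, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  check_fraction(cfg$fisher_alpha, "fisher_alpha")
  check_fraction(cfg$window_threshold, "window_threshold")
  check_fraction(cfg$max_missing, "max_missing")
  check_fraction(cfg$min_maf, "min_maf", hi = 0.5)
  check_fraction(cfg$distortion_alpha, "distortion_alpha")
  check_fraction(cfg$perm_alpha, "perm_alpha")
  check_fraction(cfg$ci_coverage, "ci_coverage")
  if (cfg$hmm_error <= 0 || cfg$hmm_error >= 0.5)
    stop_gbs("hmm_error must be in (0, 0.5)", class = "gbsmap_validation_error")
  if (cfg$hmm_tau <= 0.5 || cfg$hmm_tau > 1)
    stop_gbs("hmm_tau must be in (0.5, 1]", class = "gbsmap_validation_error")
  if (cfg$window_size < 3L || cfg$window_size %% 2L == 0L)
    stop_gbs("window_size must be odd and >= 3",
             class = "gbsmap_validation_error")
  check_count(cfg$end_skip, "end_skip")
  if (cfg$anchor_lod <= 0) stop_gbs("anchor_lod must be > 0",
                                    class = "gbsmap_validation_error")
  if (cfg$n_cofactors < 1L) stop_gbs("n_cofactors must be >= 1",
                                     class = "gbsmap_validation_error")
  if (cfg$n_perm < 100L) stop_gbs("n_perm must be >= 100",
                                  class = "gbsmap_validation_error")
  if (cfg$cim_step <= 0 || cfg$cim_window < 0 || cfg$cm_per_mb <= 0)
    stop_gbs("cim_step/cim_window/cm_per_mb out of range",
             class = "gbsmap_validation_error")
  invisible(cfg)
}

#' Read / write a pipeline configuration as plain-text YAML
#'
#' Round trips are lossless: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_gbs("config file not found: ", path,
                                   class = "gbsmap_io_error")
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
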