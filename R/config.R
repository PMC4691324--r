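#' Pipeline configuration
#'
#' Creates the configuration object consumed by every analysis stage. The
#' defaults are the thresholds of the published protocol: a mutation is
#' confirmed when its validation allele fraction is at least 5%, a call between
#' 1% and 5% is rescued only by a sibling sample of the same patient carrying
#' the same variant at >= 5%, COSMIC recurrence means two or more confirmed
#' samples, and hotspot proximity is +/- 3 amino acids.
#'
#' @param af_confirm_min Minimum validation allele fraction for an
#'   unconditional confirmation (inclusive). Default 0.05.
#' @param af_rescue_min Lower allele-fraction bound (inclusive) of the rescue
#'   window `[af_rescue_min, af_confirm_min)`. Default 0.01.
#' @param cosmic_recurrent_min Minimum confirmed-sample count in the recurrence
#'   table for a protein change to count as recurrent. Default 2.
#' @param hotspot_window_aa Residue window (in amino acids) for hotspot
#'   proximity rules. Default 3.
#' @param cluster_min_mutations Minimum number of distinct substituted residues
#'   within the window for a mutation cluster ("more than two"). Default 3.
#' @param alpha Two-tailed significance level. Default 0.05.
#' @param rearrangement_bp_tolerance Maximum per-breakpoint distance (bp) for
#'   two rearrangements to match across lesions. Default 500.
#' @param scna_reciprocal_overlap_min Minimum reciprocal overlap in (0, 1] for
#'   two copy-number aberrations to be the same event. Default 0.5.
#' @param strict_homogeneous If `TRUE` (default) a patient is homogeneous only
#'   when every variant is present in every assay-informative sample; if
#'   `FALSE` presence in every lesion (>= 1 sample each) suffices.
#' @param rng_seed Integer seed recorded in the configuration. Default 1.
#'
#' @return An object of class `mfhet_config` (a validated named list).
#' @seealso [write_config()], [read_config()]
#' @export
mfhet_config <- function(af_confirm_min = 0.05,
                         af_rescue_min = 0.01,
                         cosmic_recurrent_min = 2L,
                         hotspot_window_aa = 3L,
                         cluster_min_mutations = 3L,
                         alpha = 0.05,
                         rearrangement_bp_tolerance = 500L,
                         scna_reciprocal_overlap_min = 0.5,
                         strict_homogeneous = TRUE,
                         rng_seed = 1L) {
  cfg <- list(
    af_confirm_min = as.numeric(af_confirm_min),
    af_rescue_min = as.numeric(af_rescue_min),
    cosmic_recurrent_min = as.integer(cosmic_recurrent_min),
    hotspot_window_aa = as.integer(hotspot_window_aa),
    cluster_min_mutations = as.integer(cluster_min_mutations),
    alpha = as.numeric(alpha),
    rearrangement_bp_tolerance = as.integer(rearrangement_bp_tolerance),
    scna_reciprocal_overlap_min = as.numeric(scna_reciprocal_overlap_min),
    strict_homogeneous = isTRUE(strict_homogeneous),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$af_confirm_min > 0, cfg$af_confirm_min <= 1,
    cfg$af_rescue_min >= 0, cfg$af_rescue_min <= cfg$af_confirm_min,
    cfg$cosmic_recurrent_min >= 1,
    cfg$hotspot_window_aa >= 0,
    cfg$cluster_min_mutations >= 2,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$rearrangement_bp_tolerance >= 0,
    cfg$scna_reciprocal_overlap_min > 0, cfg$scna_reciprocal_overlap_min <= 1
  )
  class(cfg) <- "mfhet_config"
  cfg
}

#' @export
print.mfhet_config <- function(x, ...) {
  cat("mfhet pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a pipeline configuration
#'
#' The configuration round-trips losslessly through a YAML key-value file.
#'
#' @param config An `mfhet_config` object.
#' @param path File path.
#' @return `read_config()` returns an `mfhet_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mfhet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(mfhet_config, vals)
}
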