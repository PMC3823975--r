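#' Classifier configuration
#'
#' Collects every numeric threshold of the classification scheme in one
#' object.  Defaults follow the published scheme where the scheme states a
#' number (1% CD34 cutoff, 1.4/1.7 scatter ratio bounds, 5% sample-level
#' ALDH positivity, 25-cell reporting floor, 0.99 DEAB quantile); the
#' remaining knobs (gate geometry, antigen-threshold quantile, Pearce
#' operationalization) are this package's own, documented in the methods
#' vignette.
#'
#' @param cd34_pos_cutoff Percent; a sample whose CD34+ fraction of blasts is
#'   strictly below this is CD34-negative AML.  Default 1.
#' @param fsc_ratio_max,ssc_ratio_max Upper bounds of the HSC (scatter-low)
#'   band for the lymphocyte-referenced FSC and SSC ratios.  Defaults 1.4 and
#'   1.7; values exactly at the bound classify as low.
#' @param aldh_pos_sample_cutoff Percent; a sample is ALDH-positive (Cheung)
#'   when its DEAB-defined ALDH+ fraction of all events strictly exceeds
#'   this.  Default 5.
#' @param deab_quantile Quantile of the DEAB-treated aliquot's ALDH signal
#'   used as the ALDH positivity threshold.  Default 0.99.
#' @param min_reportable_events Reporting floor: fractions whose numerator
#'   holds fewer events than this are flagged (never suppressed).  Default 25.
#' @param pearce_rare_max_pct,pearce_negative_max_pct,pearce_ssc_confinement
#'   Knobs of the rare/numerous/negative ALDH pattern rule: below
#'   `pearce_negative_max_pct` percent ALDH+ the sample is negative; below
#'   `pearce_rare_max_pct` percent with at least `pearce_ssc_confinement` of
#'   ALDH+ events SSC-confined it is rare; otherwise numerous.
#' @param antigen_threshold_quantile Quantile of the lymphocyte (negative
#'   reference) distribution defining CD34/CD38/marker positivity.  Default
#'   0.995.
#' @param cd45dim_band Length-2 numeric; the CD45dim blast band as fractions
#'   of the lymphocyte CD45 median.  Default `c(0.05, 0.6)`.
#' @param lymph_cd45_quantile,lymph_cd45_scale CD45 threshold of the
#'   lymphocyte gate: events must exceed `lymph_cd45_scale` times the
#'   `lymph_cd45_quantile` sample quantile of CD45.
#' @param lymph_ssc_quantile,lymph_ssc_scale SSC threshold of the lymphocyte
#'   gate: events must fall below `lymph_ssc_scale` times the
#'   `lymph_ssc_quantile` sample quantile of SSC.
#' @param mfi_statistic `"arithmetic"` (default) or `"geometric"` mean for
#'   MFI computations.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(cd34_pos_cutoff = 1,
                              fsc_ratio_max = 1.4,
                              ssc_ratio_max = 1.7,
                              aldh_pos_sample_cutoff = 5,
                              deab_quantile = 0.99,
                              min_reportable_events = 25,
                              pearce_rare_max_pct = 5,
                              pearce_negative_max_pct = 0.1,
                              pearce_ssc_confinement = 0.8,
                              antigen_threshold_quantile = 0.995,
                              cd45dim_band = c(0.05, 0.6),
                              lymph_cd45_quantile = 0.99,
                              lymph_cd45_scale = 0.45,
                              lymph_ssc_quantile = 0.99,
                              lymph_ssc_scale = 0.45,
                              mfi_statistic = c("arithmetic", "geometric")) {
  mfi_statistic <- match.arg(mfi_statistic)
  cfg <- list(
    cd34_pos_cutoff = as.numeric(cd34_pos_cutoff),
    fsc_ratio_max = as.numeric(fsc_ratio_max),
    ssc_ratio_max = as.numeric(ssc_ratio_max),
    aldh_pos_sample_cutoff = as.numeric(aldh_pos_sample_cutoff),
    deab_quantile = as.numeric(deab_quantile),
    min_reportable_events = as.integer(min_reportable_events),
    pearce_rare_max_pct = as.numeric(pearce_rare_max_pct),
    pearce_negative_max_pct = as.numeric(pearce_negative_max_pct),
    pearce_ssc_confinement = as.numeric(pearce_ssc_confinement),
    antigen_threshold_quantile = as.numeric(antigen_threshold_quantile),
    cd45dim_band = as.numeric(cd45dim_band),
    lymph_cd45_quantile = as.numeric(lymph_cd45_quantile),
    lymph_cd45_scale = as.numeric(lymph_cd45_scale),
    lymph_ssc_quantile = as.numeric(lymph_ssc_quantile),
    lymph_ssc_scale = as.numeric(lymph_ssc_scale),
    mfi_statistic = mfi_statistic
  )
  validate_classifier_config(cfg)
  structure(cfg, class = "classifier_config")
}

validate_classifier_config <- function(cfg) {
  scalars <- c("cd34_pos_cutoff", "fsc_ratio_max", "ssc_ratio_max",
               "aldh_pos_sample_cutoff", "pearce_rare_max_pct",
               "pearce_negative_max_pct")
  for (k in scalars) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("configuration value '", k, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (cfg$cd34_pos_cutoff >= 100) {
    stop("cd34_pos_cutoff must be below 100", call. = FALSE)
  }
  for (k in c("deab_quantile", "antigen_threshold_quantile",
              "lymph_cd45_quantile", "lymph_ssc_quantile")) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      stop("configuration value '", k, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$pearce_ssc_confinement <= 0 || cfg$pearce_ssc_confinement > 1) {
    stop("pearce_ssc_confinement must lie in (0, 1]", call. = FALSE)
  }
  if (length(cfg$cd45dim_band) != 2L || any(!is.finite(cfg$cd45dim_band)) ||
      cfg$cd45dim_band[1L] <= 0 || diff(cfg$cd45dim_band) <= 0) {
    stop("cd45dim_band must be an increasing positive pair", call. = FALSE)
  }
  if (cfg$min_reportable_events < 1L) {
    stop("min_reportable_events must be at least 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a classifier configuration file
#'
#' Plain-text `key = value` file; unknown keys are an error, omitted keys keep
#' their defaults.  `cd45dim_band` is written as two comma-separated numbers.
#'
#' @param path Path to the configuration file.
#' @return A [classifier_config()] object.
#' @export
read_classifier_config <- function(path) {
  kv <- read_keyvalue_file(path)
  defaults <- classifier_config()
  unknown <- setdiff(names(kv), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- list()
  for (k in names(kv)) {
    args[[k]] <- if (k == "mfi_statistic") {
      kv[[k]]
    } else if (k == "cd45dim_band") {
      as.numeric(strsplit(kv[[k]], ",")[[1L]])
    } else {
      as.numeric(kv[[k]])
    }
  }
  do.call(classifier_config, args)
}

#' Write a classifier configuration file
#'
#' @param cfg A [classifier_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "classifier_config"))
  fmt <- function(v) {
    if (is.character(v)) v else paste(format(v, digits = 15), collapse = ",")
  }
  writeLines(paste(names(cfg), "=", vapply(cfg, fmt, character(1L))), path)
  invisible(path)
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("Classifier configuration:\n")
  for (k in names(x)) {
    cat(sprintf("  %-27s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
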