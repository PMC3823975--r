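# ALDH activity: DEAB-derived positivity threshold, bright/low segregation,
# lymphocyte-standardized MFI and HSC/LSC fold differences.

#' Derive the ALDH positivity threshold from the DEAB aliquot
#'
#' The DEAB-treated aliquot defines the fluorescence background of the
#' Aldefluor assay; the threshold is an upper quantile (default 0.99, pure
#' order statistic) of the ALDH intensities of the scoped DEAB events.
#'
#' @param deab The DEAB-treated [event_table()].
#' @param scope Index set of DEAB events to derive the threshold from
#'   (typically the same compartment being split; nonempty).
#' @param cfg A [classifier_config()] supplying `deab_quantile`.
#' @return Object of class `aldh_threshold` with fields `value`,
#'   `quantile_used` and `n_reference_events`.
#' @export
deab_threshold <- function(deab, scope, cfg = classifier_config()) {
  stopifnot(inherits(deab, "event_table"))
  if (deab$treatment != "DEAB") {
    stop("ALDH threshold must be derived from the DEAB-treated aliquot",
         call. = FALSE)
  }
  if (length(scope) == 0L) {
    stop("empty DEAB reference scope; cannot derive ALDH threshold",
         call. = FALSE)
  }
  structure(
    list(value = gate_quantile(channel(deab, "ALDH")[scope],
                               cfg$deab_quantile),
         quantile_used = cfg$deab_quantile,
         n_reference_events = length(scope)),
    class = "aldh_threshold"
  )
}

#' @export
print.aldh_threshold <- function(x, ...) {
  cat(sprintf("ALDH threshold %.4g (q = %.3f over %d DEAB events)\n",
              x$value, x$quantile_used, x$n_reference_events))
  invisible(x)
}

#' Segregate a subset into ALDH-bright and ALDH-low events
#'
#' An event is bright iff its ALDH intensity strictly exceeds the
#' DEAB-derived threshold; low otherwise.  Bright/low is a partition of the
#' subset.
#'
#' @param native The native [event_table()].
#' @param subset Index set to split (nonempty).
#' @param thr An [deab_threshold()] object.
#' @return Factor of length `length(subset)` with levels `bright`, `low`.
#' @export
split_aldh_compartments <- function(native, subset, thr) {
  stopifnot(inherits(native, "event_table"), inherits(thr, "aldh_threshold"))
  if (length(subset) == 0L) {
    stop("cannot split an empty subset", call. = FALSE)
  }
  bright <- channel(native, "ALDH")[subset] > thr$value
  factor(ifelse(bright, "bright", "low"), levels = c("bright", "low"))
}

population_mfi <- function(x, statistic) {
  if (statistic == "geometric") exp(mean(log(x))) else mean(x)
}

#' Lymphocyte-standardized ALDH MFI
#'
#' The ALDH mean fluorescence intensity of a subset divided by the ALDH MFI
#' of the lymphocytes of the same sample.  Lymphocytes are ALDH-negative, so
#' their MFI is the sample's background signal; the ratio is comparable
#' across samples and instruments.
#'
#' @param native The native [event_table()].
#' @param subset Index set of the population of interest (nonempty).
#' @param lymphocytes Lymphocyte reference index set (nonempty).
#' @param cfg A [classifier_config()]; `mfi_statistic` selects the
#'   arithmetic (default) or geometric mean.
#' @return Object of class `standardized_mfi` with fields `raw_mfi`,
#'   `lymph_mfi` and `ratio`.
#' @export
standardized_mfi <- function(native, subset, lymphocytes,
                             cfg = classifier_config()) {
  stopifnot(inherits(native, "event_table"))
  if (length(subset) == 0L || length(lymphocytes) == 0L) {
    stop("standardized MFI is undefined for an empty subset or reference",
         call. = FALSE)
  }
  aldh <- channel(native, "ALDH")
  raw <- population_mfi(aldh[subset], cfg$mfi_statistic)
  ref <- population_mfi(aldh[lymphocytes], cfg$mfi_statistic)
  if (!is.finite(ref) || ref <= 0) {
    stop("lymphocyte ALDH MFI is zero; standardization impossible",
         call. = FALSE)
  }
  structure(list(raw_mfi = raw, lymph_mfi = ref, ratio = raw / ref),
            class = "standardized_mfi")
}

#' @export
print.standardized_mfi <- function(x, ...) {
  cat(sprintf("Standardized ALDH MFI %.4g (raw %.4g / lymphocyte %.4g)\n",
              x$ratio, x$raw_mfi, x$lymph_mfi))
  invisible(x)
}

#' Fold difference in ALDH activity between two compartments
#'
#' Ratio of two lymphocyte-standardized MFIs, conventionally HSC over LSC.
#' The lymphocyte standardization cancels algebraically, so this equals the
#' raw MFI ratio of the two compartments.
#'
#' @param hsc,lsc [standardized_mfi()] objects.
#' @return The dimensionless fold (HSC over LSC).
#' @export
fold_difference <- function(hsc, lsc) {
  stopifnot(inherits(hsc, "standardized_mfi"),
            inherits(lsc, "standardized_mfi"))
  if (!is.finite(lsc$ratio) || lsc$ratio <= 0) {
    stop("fold difference undefined: LSC standardized MFI is not positive",
         call. = FALSE)
  }
  hsc$ratio / lsc$ratio
}

#' ALDH-positive fraction of a scope
#'
#' Percentage of scoped native events whose ALDH intensity strictly exceeds
#' the DEAB-derived threshold.
#'
#' @param native The native [event_table()].
#' @param scope Index set (nonempty).
#' @param thr An [deab_threshold()] object.
#' @param cfg A [classifier_config()].
#' @return A [fraction_report()].
#' @export
aldh_positive_fraction <- function(native, scope, thr,
                                   cfg = classifier_config()) {
  stopifnot(inherits(native, "event_table"), inherits(thr, "aldh_threshold"))
  if (length(scope) == 0L) {
    stop("ALDH-positive fraction is undefined for an empty scope",
         call. = FALSE)
  }
  n_pos <- sum(channel(native, "ALDH")[scope] > thr$value)
  fraction_report(n_pos, length(scope), cfg)
}
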