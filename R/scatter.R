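# Lymphocyte-referenced scatter ratios.  HSC scatter is close to that of
# lymphocytes (at most 1.4x FSC and 1.7x SSC); LSC exceed those bounds.

#' Lymphocyte-referenced scatter ratios of a subset
#'
#' The median FSC (respectively SSC) of the subset divided by the median FSC
#' (SSC) of the lymphocyte reference.  The median is used for robustness.
#'
#' @param events An [event_table()].
#' @param subset Index set of the population of interest (nonempty).
#' @param lymphocytes Lymphocyte reference index set (nonempty).
#' @return Object of class `scatter_ratios` with fields `fsc_ratio` and
#'   `ssc_ratio`.
#' @export
scatter_ratios <- function(events, subset, lymphocytes) {
  stopifnot(inherits(events, "event_table"))
  if (length(subset) == 0L || length(lymphocytes) == 0L) {
    stop("scatter ratios are undefined for an empty subset or reference",
         call. = FALSE)
  }
  fsc <- channel(events, "FSC")
  ssc <- channel(events, "SSC")
  out <- list(
    fsc_ratio = stats::median(fsc[subset]) / stats::median(fsc[lymphocytes]),
    ssc_ratio = stats::median(ssc[subset]) / stats::median(ssc[lymphocytes])
  )
  if (!all(vapply(out, is.finite, logical(1L))) || any(unlist(out) <= 0)) {
    stop("scatter ratios must be finite and positive", call. = FALSE)
  }
  structure(out, class = "scatter_ratios")
}

#' @export
print.scatter_ratios <- function(x, ...) {
  cat(sprintf("Scatter ratios: FSC %.3f, SSC %.3f\n", x$fsc_ratio,
              x$ssc_ratio))
  invisible(x)
}

#' Classify scatter ratios as low (HSC-like) or high (LSC-like)
#'
#' `low` iff the FSC ratio is at most `fsc_ratio_max` (1.4) AND the SSC
#' ratio is at most `ssc_ratio_max` (1.7); `high` otherwise.  Values exactly
#' at a bound classify as low ("high" is defined strictly as exceeding the
#' bound).  Ratios below 1 also classify as low.
#'
#' @param r A [scatter_ratios()] object.
#' @param cfg A [classifier_config()].
#' @return `"low"` or `"high"`.
#' @export
classify_scatter <- function(r, cfg = classifier_config()) {
  stopifnot(inherits(r, "scatter_ratios"))
  if (r$fsc_ratio <= cfg$fsc_ratio_max && r$ssc_ratio <= cfg$ssc_ratio_max) {
    "low"
  } else {
    "high"
  }
}
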