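# Sample-level and per-event classification: CD34-positive vs CD34-negative
# AML, HSC vs LSC calls, and the sample-level ALDH classifications
# (5%-positivity and rare/numerous/negative pattern).

#' Classify a sample as CD34-positive or CD34-negative AML
#'
#' CD34-negative AML carries only a small, normal CD34+ population: a sample
#' is `CD34_negative` iff the CD34+ percentage of its blasts is strictly
#' below `cd34_pos_cutoff` (default 1%); exactly at the cutoff is
#' `CD34_positive`.
#'
#' @param labels A `gate_labels` object from [partition_stem_compartments()].
#' @param cfg A [classifier_config()].
#' @return `"CD34_positive"` or `"CD34_negative"`.
#' @export
classify_cd34_status <- function(labels, cfg = classifier_config()) {
  stopifnot(inherits(labels, "gate_labels"))
  n_blast <- length(labels$blasts)
  if (n_blast == 0L) {
    stop("cannot classify CD34 status: blast compartment is empty",
         call. = FALSE)
  }
  n_cd34 <- sum(labels$compartment %in% c("blast_CD34pos_CD38neg",
                                          "blast_CD34pos_CD38pos"))
  pct <- 100 * n_cd34 / n_blast
  if (pct < cfg$cd34_pos_cutoff) "CD34_negative" else "CD34_positive"
}

#' Per-event HSC/LSC calls on stem-cell candidates
#'
#' Stem-cell candidates are the CD34+CD38- gated events and, in CD34-negative
#' AML, additionally the CD34- blasts (where the LSC reside).  ALDH has
#' priority: within the CD34+CD38- gate a bright, marker-negative event is
#' HSC; a low event is LSC; bright with aberrant marker expression is
#' ambiguous.  Among CD34- blasts (CD34-negative samples only) a low event is
#' LSC and a bright event is ambiguous (normal progenitor vs LSC is
#' undecidable without molecular data).  Scatter is recorded as evidence and
#' never overrides ALDH.
#'
#' @param native The native [event_table()].
#' @param labels `gate_labels` from [partition_stem_compartments()].
#' @param thr An [deab_threshold()]; supplies the per-event bright/low split.
#' @param status CD34 status from [classify_cd34_status()].
#' @param scatter_class Optional sample-level `"low"`/`"high"` scatter call
#'   recorded as evidence.
#' @return Object of class `stem_cell_calls`: per-event `call` factor
#'   (`HSC`, `LSC`, `ambiguous`, `not_stem`) plus evidence flags
#'   `aldh_bright` and `marker_positive` (NA outside candidates) and the
#'   candidate index set.
#' @export
call_stem_cells <- function(native, labels, thr, status,
                            scatter_class = NULL) {
  stopifnot(inherits(native, "event_table"),
            inherits(labels, "gate_labels"))
  if (!inherits(thr, "aldh_threshold")) {
    stop("missing ALDH bright/low split: 'thr' must be an aldh_threshold",
         call. = FALSE)
  }
  status <- match.arg(status, c("CD34_positive", "CD34_negative"))
  n <- native$n_events
  call <- factor(rep("not_stem", n),
                 levels = c("HSC", "LSC", "ambiguous", "not_stem"))
  stem_gate <- compartment_indices(labels, "blast_CD34pos_CD38neg")
  cd34neg <- if (status == "CD34_negative") {
    compartment_indices(labels, "blast_CD34neg")
  } else {
    integer(0L)
  }
  candidates <- c(stem_gate, cd34neg)
  bright <- rep(NA, n)
  bright[candidates] <- channel(native, "ALDH")[candidates] > thr$value
  marker <- labels$marker_positive

  if (length(stem_gate) > 0L) {
    b <- bright[stem_gate]
    m <- marker[stem_gate]
    call[stem_gate] <- ifelse(!b, "LSC", ifelse(m, "ambiguous", "HSC"))
  }
  if (length(cd34neg) > 0L) {
    b <- bright[cd34neg]
    call[cd34neg] <- ifelse(!b, "LSC", "ambiguous")
  }
  structure(
    list(call = call, aldh_bright = bright, marker_positive = marker,
         candidates = sort(candidates), status = status,
         scatter_class = scatter_class),
    class = "stem_cell_calls"
  )
}

#' @export
print.stem_cell_calls <- function(x, ...) {
  cat("Stem-cell calls (", length(x$candidates), " candidate events, ",
      x$status, "):\n", sep = "")
  print(table(call = x$call[x$candidates]))
  invisible(x)
}

#' Sample-level ALDH positivity (5% rule)
#'
#' A sample is ALDH-positive when the DEAB-defined ALDH+ percentage of all
#' its events strictly exceeds `aldh_pos_sample_cutoff` (default 5%).
#'
#' @param aldh_pos_pct ALDH+ percentage of the total sample.
#' @param cfg A [classifier_config()].
#' @return `"positive"` or `"negative"`.
#' @export
cheung_classification <- function(aldh_pos_pct, cfg = classifier_config()) {
  stopifnot(is.finite(aldh_pos_pct))
  if (aldh_pos_pct > cfg$aldh_pos_sample_cutoff) "positive" else "negative"
}

#' Qualitative pattern of the ALDH-positive compartment
#'
#' Operationalizes the rare/numerous/negative description of the ALDH+
#' compartment: `negative` when the ALDH+ percentage of the sample falls
#' below `pearce_negative_max_pct` (default 0.1%); `rare` when it is below
#' `pearce_rare_max_pct` (default 5%) AND at least `pearce_ssc_confinement`
#' (default 80%) of ALDH+ events are SSC-confined (SSC at most
#' `ssc_ratio_max` times the lymphocyte SSC median); `numerous` otherwise.
#' The three knobs are this package's own quantification of a visual
#' classification; by construction every ALDH-positive (5%) sample is
#' numerous.
#'
#' @param native The native [event_table()].
#' @param thr An [deab_threshold()].
#' @param lymphocytes Lymphocyte reference index set.
#' @param cfg A [classifier_config()].
#' @return `"rare"`, `"numerous"` or `"negative"`.
#' @export
pearce_pattern <- function(native, thr, lymphocytes,
                           cfg = classifier_config()) {
  stopifnot(inherits(native, "event_table"), inherits(thr, "aldh_threshold"))
  aldh <- channel(native, "ALDH")
  pos <- which(aldh > thr$value)
  pct <- 100 * length(pos) / native$n_events
  if (pct < cfg$pearce_negative_max_pct) {
    return("negative")
  }
  ssc <- channel(native, "SSC")
  ssc_bound <- cfg$ssc_ratio_max * stats::median(ssc[lymphocytes])
  confined <- mean(ssc[pos] <= ssc_bound)
  if (pct < cfg$pearce_rare_max_pct && confined >= cfg$pearce_ssc_confinement) {
    "rare"
  } else {
    "numerous"
  }
}
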