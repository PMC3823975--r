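# Event gating: lymphocyte reference gate, CD45dim blast gate, CD34/CD38
# stem/progenitor partition, and marker-positivity fractions.
#
# All thresholds are data-driven: the lymphocyte gate anchors to upper sample
# quantiles of CD45 and SSC, and every antigen threshold (CD34, CD38, marker)
# is a quantile of the gated lymphocytes, which serve as the sample-internal
# negative reference.  Quantiles are pure order statistics (type 1).  Values
# exactly at a threshold count as negative (strict inequality for
# positivity).

gate_quantile <- function(x, p) {
  stats::quantile(x, p, type = 1L, names = FALSE)
}

#' Gate lymphocytes
#'
#' Lymphocytes are the CD45-bright, SSC-low population and serve as the
#' internal reference for ALDH-MFI standardization, scatter ratios and
#' antigen thresholds.  Events are gated when CD45 exceeds
#' `lymph_cd45_scale` times the `lymph_cd45_quantile` sample quantile of
#' CD45 and SSC falls below `lymph_ssc_scale` times the
#' `lymph_ssc_quantile` sample quantile of SSC.
#'
#' @param events An [event_table()].
#' @param cfg A [classifier_config()].
#' @return Integer vector of gated event indices.
#' @export
gate_lymphocytes <- function(events, cfg = classifier_config()) {
  stopifnot(inherits(events, "event_table"))
  if (events$n_events == 0L) {
    stop("cannot gate lymphocytes in an empty event table", call. = FALSE)
  }
  cd45 <- channel(events, "CD45")
  ssc <- channel(events, "SSC")
  cd45_thr <- cfg$lymph_cd45_scale * gate_quantile(cd45, cfg$lymph_cd45_quantile)
  ssc_thr <- cfg$lymph_ssc_scale * gate_quantile(ssc, cfg$lymph_ssc_quantile)
  idx <- which(cd45 > cd45_thr & ssc < ssc_thr)
  if (length(idx) == 0L) {
    stop("lymphocyte reference population is empty; ",
         "downstream standardization is impossible", call. = FALSE)
  }
  idx
}

#' Gate CD45dim blasts
#'
#' Blasts are events whose CD45 lies in the dim band, expressed as fractions
#' of the lymphocyte CD45 median (`cd45dim_band`, default 0.05-0.6), and
#' that are not in the lymphocyte gate.  May be empty.
#'
#' @param events An [event_table()].
#' @param lymphocytes Lymphocyte index set from [gate_lymphocytes()].
#' @param cfg A [classifier_config()].
#' @return Integer vector of blast event indices (possibly empty).
#' @export
gate_blasts <- function(events, lymphocytes, cfg = classifier_config()) {
  stopifnot(inherits(events, "event_table"))
  if (events$n_events == 0L) return(integer(0L))
  cd45 <- channel(events, "CD45")
  ref <- stats::median(cd45[lymphocytes])
  band <- cfg$cd45dim_band * ref
  idx <- which(cd45 >= band[1L] & cd45 <= band[2L])
  setdiff(idx, lymphocytes)
}

# antigen positivity threshold: upper quantile of a negative reference
# population (lymphocytes by default)
antigen_threshold <- function(events, reference, role,
                              cfg = classifier_config()) {
  if (length(reference) == 0L) {
    stop("empty negative-reference population for ", role, " threshold",
         call. = FALSE)
  }
  gate_quantile(channel(events, role)[reference],
                cfg$antigen_threshold_quantile)
}

#' Partition events into stem-cell compartments
#'
#' Within the blast gate, events split by CD34 and (within CD34+) CD38 into
#' `blast_CD34pos_CD38neg`, `blast_CD34pos_CD38pos` and `blast_CD34neg`;
#' lymphocytes keep their own compartment and everything else is `other`.
#' Antigen thresholds are quantiles of the lymphocyte reference
#' (`antigen_threshold_quantile`); ties count as negative.
#'
#' @param events An [event_table()].
#' @param blasts Blast index set from [gate_blasts()].
#' @param lymphocytes Lymphocyte index set (the negative reference).
#' @param cfg A [classifier_config()].
#' @return An object of class `gate_labels`: per-event `compartment` factor,
#'   per-event `marker_positive` logical (NA outside blasts), and the
#'   thresholds used.
#' @export
partition_stem_compartments <- function(events, blasts, lymphocytes,
                                        cfg = classifier_config()) {
  stopifnot(inherits(events, "event_table"))
  n <- events$n_events
  levels <- c("lymphocyte", "blast_CD34pos_CD38neg", "blast_CD34pos_CD38pos",
              "blast_CD34neg", "other")
  comp <- factor(rep("other", n), levels = levels)
  comp[lymphocytes] <- "lymphocyte"
  thr <- list(
    cd34 = antigen_threshold(events, lymphocytes, "CD34", cfg),
    cd38 = antigen_threshold(events, lymphocytes, "CD38", cfg),
    marker = antigen_threshold(events, lymphocytes, "MARKER", cfg)
  )
  if (length(blasts) > 0L) {
    cd34 <- channel(events, "CD34")[blasts]
    cd38 <- channel(events, "CD38")[blasts]
    lab <- ifelse(cd34 > thr$cd34,
                  ifelse(cd38 > thr$cd38, "blast_CD34pos_CD38pos",
                         "blast_CD34pos_CD38neg"),
                  "blast_CD34neg")
    comp[blasts] <- lab
  }
  marker_positive <- rep(NA, n)
  marker_positive[blasts] <- channel(events, "MARKER")[blasts] > thr$marker
  structure(
    list(compartment = comp, marker_positive = marker_positive,
         thresholds = thr, lymphocytes = lymphocytes, blasts = blasts),
    class = "gate_labels"
  )
}

#' @export
print.gate_labels <- function(x, ...) {
  cat("Gate labels:\n")
  print(table(compartment = x$compartment))
  invisible(x)
}

# index helper: events in a given compartment
compartment_indices <- function(labels, compartment) {
  which(labels$compartment %in% compartment)
}

#' Build a fraction report
#'
#' Fractions are reported as percentages with their numerator and
#' denominator; a numerator below the reporting floor raises
#' `low_count_flag` but never suppresses the value.
#'
#' @param numerator,denominator Event counts.
#' @param cfg A [classifier_config()] supplying `min_reportable_events`.
#' @return Object of class `fraction_report` with fields `fraction`
#'   (percent, NA when the denominator is 0), `numerator`, `denominator`,
#'   `low_count_flag`.
#' @export
fraction_report <- function(numerator, denominator,
                            cfg = classifier_config()) {
  numerator <- as.integer(numerator)
  denominator <- as.integer(denominator)
  stopifnot(numerator >= 0L, denominator >= 0L, numerator <= denominator ||
              denominator == 0L)
  structure(
    list(
      fraction = if (denominator > 0L) 100 * numerator / denominator else NA_real_,
      numerator = numerator,
      denominator = denominator,
      low_count_flag = numerator < cfg$min_reportable_events
    ),
    class = "fraction_report"
  )
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("%s%% (%d/%d)%s\n",
              if (is.na(x$fraction)) "NA" else format(x$fraction, digits = 4),
              x$numerator, x$denominator,
              if (isTRUE(x$low_count_flag)) " [low count]" else ""))
  invisible(x)
}

#' Marker-positive fraction of a subset
#'
#' Percentage of subset events whose marker intensity strictly exceeds the
#' given threshold (a negative-reference quantile, see
#' [partition_stem_compartments()]).
#'
#' @param events An [event_table()].
#' @param subset Index set to evaluate (may be empty: fraction is NA).
#' @param threshold Marker positivity threshold on the linear scale.
#' @param cfg A [classifier_config()].
#' @return A [fraction_report()].
#' @export
marker_positive_fraction <- function(events, subset, threshold,
                                     cfg = classifier_config()) {
  stopifnot(inherits(events, "event_table"))
  n_pos <- sum(channel(events, "MARKER")[subset] > threshold)
  fraction_report(n_pos, length(subset), cfg)
}
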