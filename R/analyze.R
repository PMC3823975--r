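#' Analyze a paired native/DEAB sample
#'
#' Runs the full discrimination pipeline on one specimen: lymphocyte and
#' CD45dim blast gating on both aliquots, CD34/CD38 stem and progenitor
#' partition, DEAB-derived ALDH threshold (scoped to the DEAB aliquot's
#' CD34+CD38- gate, falling back to all DEAB events when that gate holds
#' fewer than `min_reportable_events` events), bright/low segregation,
#' lymphocyte-standardized MFIs and the HSC-over-LSC fold,
#' lymphocyte-referenced scatter ratios, per-event HSC/LSC calls, and the
#' sample-level classifications (CD34 status, 5% ALDH positivity,
#' rare/numerous/negative pattern).
#'
#' The HSC compartment is the ALDH-bright part of the CD34+CD38- gate.  The
#' LSC compartment is the ALDH-low part of the CD34+CD38- gate in
#' CD34-positive samples, and the ALDH-low CD34- blasts in CD34-negative
#' samples.  An MFI (and hence the fold) is reported only when its
#' compartment meets the reporting floor.
#'
#' @param pair A [sample_pair()] (or an `aldh_simulation`, whose pair is
#'   used).
#' @param cfg A [classifier_config()].
#' @return An object of class `aldh_analysis`; see [summarize_sample()] for
#'   the one-row condensation and `print`/`summary` methods for display.
#' @examples
#' sim <- simulate(aldh_scenario("aml_cd34pos", n_events = 20000), seed = 1)
#' fit <- aldh_analyze(sim)
#' fit
#' summary(fit)
#' @export
aldh_analyze <- function(pair, cfg = classifier_config()) {
  if (inherits(pair, "aldh_simulation")) pair <- pair$pair
  stopifnot(inherits(pair, "sample_pair"))
  native <- pair$native
  deab <- pair$deab

  # gating, native aliquot
  lymph <- gate_lymphocytes(native, cfg)
  blasts <- gate_blasts(native, lymph, cfg)
  labels <- partition_stem_compartments(native, blasts, lymph, cfg)

  # gating, DEAB aliquot (for the threshold scope)
  deab_lymph <- gate_lymphocytes(deab, cfg)
  deab_blasts <- gate_blasts(deab, deab_lymph, cfg)
  deab_labels <- partition_stem_compartments(deab, deab_blasts, deab_lymph,
                                             cfg)
  deab_gate <- compartment_indices(deab_labels, "blast_CD34pos_CD38neg")
  scope <- if (length(deab_gate) >= cfg$min_reportable_events) {
    deab_gate
  } else {
    seq_len(deab$n_events)
  }
  thr <- deab_threshold(deab, scope, cfg)

  # ALDH compartments over the blast gate
  aldh_bright_evt <- channel(native, "ALDH") > thr$value
  stem_gate <- compartment_indices(labels, "blast_CD34pos_CD38neg")
  bright_blasts <- blasts[aldh_bright_evt[blasts]]
  low_blasts <- setdiff(blasts, bright_blasts)
  bright_stem <- stem_gate[aldh_bright_evt[stem_gate]]
  low_stem <- setdiff(stem_gate, bright_stem)

  status <- classify_cd34_status(labels, cfg)
  cd34neg_blasts <- compartment_indices(labels, "blast_CD34neg")
  lsc_compartment <- if (status == "CD34_positive") {
    low_stem
  } else {
    setdiff(cd34neg_blasts, blasts[aldh_bright_evt[blasts]])
  }

  # standardized MFIs and fold (reporting floor applies)
  hsc_mfi <- if (length(bright_stem) >= cfg$min_reportable_events) {
    standardized_mfi(native, bright_stem, lymph, cfg)
  } else NULL
  lsc_mfi <- if (length(lsc_compartment) >= cfg$min_reportable_events) {
    standardized_mfi(native, lsc_compartment, lymph, cfg)
  } else NULL
  fold <- if (!is.null(hsc_mfi) && !is.null(lsc_mfi)) {
    fold_difference(hsc_mfi, lsc_mfi)
  } else NA_real_

  # scatter evidence
  hsc_scatter <- if (length(bright_stem) > 0L) {
    scatter_ratios(native, bright_stem, lymph)
  } else NULL
  lsc_scatter <- if (length(lsc_compartment) > 0L) {
    scatter_ratios(native, lsc_compartment, lymph)
  } else NULL
  scatter_class <- if (!is.null(lsc_scatter)) {
    classify_scatter(lsc_scatter, cfg)
  } else NULL

  calls <- call_stem_cells(native, labels, thr, status, scatter_class)
  total_pos <- aldh_positive_fraction(native, seq_len(native$n_events), thr,
                                      cfg)
  cheung <- cheung_classification(total_pos$fraction, cfg)
  pearce <- pearce_pattern(native, thr, lymph, cfg)

  out <- structure(
    list(
      pair = pair, config = cfg, lymphocytes = lymph, blasts = blasts,
      labels = labels, deab_labels = deab_labels, threshold = thr,
      bright_blasts = bright_blasts, low_blasts = low_blasts,
      bright_stem = bright_stem, low_stem = low_stem,
      lsc_compartment = lsc_compartment, cd34_status = status,
      hsc_mfi = hsc_mfi, lsc_mfi = lsc_mfi, fold = fold,
      hsc_scatter = hsc_scatter, lsc_scatter = lsc_scatter,
      scatter_class = scatter_class, calls = calls,
      aldh_pos_total = total_pos, cheung_class = cheung,
      pearce_pattern = pearce
    ),
    class = "aldh_analysis"
  )
  out$manifest <- run_manifest(out)
  out
}

#' Condense an analysis into a sample summary
#'
#' Compartment percentages use the ALDH compartment (of the blast gate) as
#' denominator: e.g. the CD34+CD38- events as a percentage of all
#' ALDH-bright blasts.  Marker-positive percentages are evaluated within the
#' bright and low CD34+CD38- cells.  Every fraction below the reporting
#' floor is flagged, never suppressed.
#'
#' @param analysis An [aldh_analyze()] result.
#' @return An [aldh_summary()].
#' @export
summarize_sample <- function(analysis) {
  stopifnot(inherits(analysis, "aldh_analysis"))
  a <- analysis
  cfg <- a$config
  native <- a$pair$native
  thr_marker <- a$labels$thresholds$marker

  in_bright <- fraction_report(length(a$bright_stem),
                               length(a$bright_blasts), cfg)
  in_low <- fraction_report(length(a$low_stem), length(a$low_blasts), cfg)
  mk_bright <- marker_positive_fraction(native, a$bright_stem, thr_marker,
                                        cfg)
  mk_low <- marker_positive_fraction(native, a$low_stem, thr_marker, cfg)

  flags <- c(
    pct_cd34cd38neg_in_aldh_bright = in_bright$low_count_flag,
    pct_cd34cd38neg_in_aldh_low = in_low$low_count_flag,
    marker_pos_pct_bright = mk_bright$low_count_flag,
    marker_pos_pct_low = mk_low$low_count_flag
  )
  aldh_summary(
    sample_id = native$source_id,
    marker_name = native$panel$marker_name,
    cd34_status = a$cd34_status,
    pct_cd34cd38neg_in_aldh_bright = in_bright$fraction,
    pct_cd34cd38neg_in_aldh_low = in_low$fraction,
    marker_pos_pct_bright = mk_bright$fraction,
    marker_pos_pct_low = mk_low$fraction,
    hsc_std_mfi = if (is.null(a$hsc_mfi)) NA_real_ else a$hsc_mfi$ratio,
    lsc_std_mfi = if (is.null(a$lsc_mfi)) NA_real_ else a$lsc_mfi$ratio,
    fold = a$fold,
    aldh_pos_pct_total = a$aldh_pos_total$fraction,
    cheung_class = a$cheung_class,
    pearce_pattern = a$pearce_pattern,
    low_count_flags = flags
  )
}

#' @export
summary.aldh_analysis <- function(object, ...) {
  summarize_sample(object)
}

#' @export
print.aldh_analysis <- function(x, ...) {
  cat("ALDH HSC/LSC analysis of '", x$pair$source_id, "'\n", sep = "")
  cat(sprintf("  %d native / %d DEAB events; %s\n", x$pair$native$n_events,
              x$pair$deab$n_events, x$cd34_status))
  cat(sprintf("  lymphocytes %d, blasts %d, CD34+CD38- gate %d\n",
              length(x$lymphocytes), length(x$blasts),
              length(x$bright_stem) + length(x$low_stem)))
  cat(sprintf("  ALDH threshold %.4g; bright %d / low %d in the stem gate\n",
              x$threshold$value, length(x$bright_stem), length(x$low_stem)))
  if (!is.na(x$fold)) {
    cat(sprintf("  standardized MFI: HSC %.3g, LSC %.3g  (fold %.3g)\n",
                x$hsc_mfi$ratio, x$lsc_mfi$ratio, x$fold))
  }
  cat(sprintf("  ALDH+ %.3g%% of sample [%s, %s pattern]\n",
              x$aldh_pos_total$fraction, x$cheung_class, x$pearce_pattern))
  invisible(x)
}

# machine-readable provenance: inputs, config snapshot, per-stage event
# counts (every fraction traceable to numerator/denominator), warnings
run_manifest <- function(a) {
  native <- a$pair$native
  ambiguous <- sum(a$calls$call[a$calls$candidates] == "ambiguous")
  list(
    software = paste("aldhgate",
                     as.character(utils::packageVersion("aldhgate"))),
    source_id = a$pair$source_id,
    config = unclass(a$config),
    counts = list(
      native_raw = attr(native, "n_raw") %||% native$n_events,
      native_dropped = attr(native, "n_dropped") %||% 0L,
      native = native$n_events,
      deab_raw = attr(a$pair$deab, "n_raw") %||% a$pair$deab$n_events,
      deab_dropped = attr(a$pair$deab, "n_dropped") %||% 0L,
      deab = a$pair$deab$n_events,
      lymphocytes = length(a$lymphocytes),
      blasts = length(a$blasts),
      compartments = as.list(table(a$labels$compartment)),
      aldh_bright_blasts = length(a$bright_blasts),
      aldh_low_blasts = length(a$low_blasts),
      stem_gate_bright = length(a$bright_stem),
      stem_gate_low = length(a$low_stem),
      lsc_compartment = length(a$lsc_compartment),
      deab_threshold_reference = a$threshold$n_reference_events,
      aldh_pos_total = a$aldh_pos_total$numerator,
      stem_candidates = length(a$calls$candidates)
    ),
    warnings = list(
      ambiguous_call_fraction = if (length(a$calls$candidates) > 0L) {
        ambiguous / length(a$calls$candidates)
      } else 0,
      low_count_flags = {
        s <- summarize_sample(a)
        as.list(s$low_count_flags)
      }
    )
  )
}

#' Run the pipeline end-to-end from files
#'
#' Reads the native and DEAB event files, panel and (optionally) classifier
#' configuration, runs [aldh_analyze()], and writes `summary.json`,
#' `manifest.json` and a per-event `labels.csv` (compartment, HSC/LSC call,
#' bright flag) into the output directory.  Any stage error is propagated
#' with its stage name and partial outputs are removed.
#'
#' @param native_path,deab_path Event files (FCS 3.0/3.1 or CSV).
#' @param panel_path Panel configuration file.
#' @param config_path Optional classifier configuration file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `summary`, the `analysis` and the
#'   `manifest`.
#' @export
orchestrate_run <- function(native_path, deab_path, panel_path,
                            config_path = NULL, out_dir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  panel <- stage("read_panel", read_panel_config(panel_path))
  cfg <- if (is.null(config_path)) {
    classifier_config()
  } else {
    stage("read_config", read_classifier_config(config_path))
  }
  native <- stage("read_native",
                  read_events(native_path, panel, treatment = "native"))
  deab <- stage("read_deab",
                read_events(deab_path, panel, treatment = "DEAB"))
  deab$source_id <- native$source_id   # aliquots of one specimen
  pair <- stage("pair", sample_pair(native, deab))
  analysis <- stage("analyze", aldh_analyze(pair, cfg))
  summary <- stage("summarize", summarize_sample(analysis))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("summary.json", "manifest.json",
                                  "labels.csv"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))
  write_sample_summary(summary, outputs[1L])
  jsonlite::write_json(analysis$manifest, outputs[2L], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(
      compartment = as.character(analysis$labels$compartment),
      call = as.character(analysis$calls$call),
      aldh_bright = channel(native, "ALDH") > analysis$threshold$value
    ),
    outputs[3L], row.names = FALSE
  )
  ok <- TRUE
  invisible(list(summary = summary, analysis = analysis,
                 manifest = analysis$manifest))
}

#' Aggregate per-sample summary files into a cohort table
#'
#' Globs `summary.json` files under a directory (one per analyzed sample),
#' stacks them with [build_cohort_table()] and optionally writes the TSV.
#'
#' @param in_dir Directory searched recursively for `summary.json` files.
#' @param out_path Optional TSV output path.
#' @return The [build_cohort_table()] result.
#' @export
cohort_from_dir <- function(in_dir, out_path = NULL) {
  files <- sort(list.files(in_dir, pattern = "^summary\\.json$",
                           recursive = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no summary.json files found under ", in_dir, call. = FALSE)
  }
  cohort <- build_cohort_table(lapply(files, read_sample_summary))
  if (!is.null(out_path)) write_cohort_table(cohort, out_path)
  cohort
}
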