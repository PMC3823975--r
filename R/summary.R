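# Per-sample summaries and cohort tables with median rows.

#' Median over non-missing values
#'
#' Standard median (midpoint average for even counts) computed after
#' dropping missing entries; the median of an all-missing or empty vector is
#' missing.  This is the convention the cohort median rows use: a dash in a
#' per-patient column never counts as zero.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return Numeric scalar, or `NA` when no values remain.
#' @export
column_median <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  stats::median(values)
}

summary_numeric_fields <- function() {
  c("pct_cd34cd38neg_in_aldh_bright", "pct_cd34cd38neg_in_aldh_low",
    "marker_pos_pct_bright", "marker_pos_pct_low",
    "hsc_std_mfi", "lsc_std_mfi", "fold", "aldh_pos_pct_total")
}

#' Construct a sample summary
#'
#' One row of the cohort table: compartment percentages (with the ALDH
#' compartment as denominator), marker-positive fractions of the bright and
#' low CD34+CD38- cells, lymphocyte-standardized MFIs and their fold, the
#' sample-level ALDH+ percentage, and the class labels.  Usually produced by
#' [summarize_sample()]; exposed so transcribed published cohorts can be
#' entered as fixture rows.
#'
#' @param sample_id Specimen identifier.
#' @param marker_name Aberrant marker carried on the MARKER channel.
#' @param cd34_status `"CD34_positive"` or `"CD34_negative"`.
#' @param pct_cd34cd38neg_in_aldh_bright,pct_cd34cd38neg_in_aldh_low
#'   CD34+CD38- events as a percentage of the ALDH-bright (resp. -low)
#'   compartment.
#' @param marker_pos_pct_bright,marker_pos_pct_low Marker-positive
#'   percentage of the bright (resp. low) CD34+CD38- cells; `NA` when the
#'   compartment is empty.
#' @param hsc_std_mfi,lsc_std_mfi Standardized ALDH MFI of the HSC and LSC
#'   compartments; `NA` when undefined.
#' @param fold HSC-over-LSC fold; present iff both MFIs are defined.
#' @param aldh_pos_pct_total ALDH+ percentage of the total sample.
#' @param cheung_class,pearce_pattern Sample-level ALDH classifications.
#' @param low_count_flags Named logical vector of reporting-floor flags.
#' @return Object of class `aldh_summary`.
#' @export
aldh_summary <- function(sample_id, marker_name = NA_character_,
                         cd34_status = NA_character_,
                         pct_cd34cd38neg_in_aldh_bright = NA_real_,
                         pct_cd34cd38neg_in_aldh_low = NA_real_,
                         marker_pos_pct_bright = NA_real_,
                         marker_pos_pct_low = NA_real_,
                         hsc_std_mfi = NA_real_, lsc_std_mfi = NA_real_,
                         fold = NA_real_, aldh_pos_pct_total = NA_real_,
                         cheung_class = NA_character_,
                         pearce_pattern = NA_character_,
                         low_count_flags = logical(0L)) {
  out <- list(
    sample_id = as.character(sample_id),
    marker_name = as.character(marker_name),
    cd34_status = as.character(cd34_status),
    pct_cd34cd38neg_in_aldh_bright = as.numeric(pct_cd34cd38neg_in_aldh_bright),
    pct_cd34cd38neg_in_aldh_low = as.numeric(pct_cd34cd38neg_in_aldh_low),
    marker_pos_pct_bright = as.numeric(marker_pos_pct_bright),
    marker_pos_pct_low = as.numeric(marker_pos_pct_low),
    hsc_std_mfi = as.numeric(hsc_std_mfi),
    lsc_std_mfi = as.numeric(lsc_std_mfi),
    fold = as.numeric(fold),
    aldh_pos_pct_total = as.numeric(aldh_pos_pct_total),
    cheung_class = as.character(cheung_class),
    pearce_pattern = as.character(pearce_pattern),
    low_count_flags = low_count_flags
  )
  pct <- unlist(out[c("pct_cd34cd38neg_in_aldh_bright",
                      "pct_cd34cd38neg_in_aldh_low",
                      "marker_pos_pct_bright", "marker_pos_pct_low",
                      "aldh_pos_pct_total")])
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("summary percentages must lie in [0, 100]", call. = FALSE)
  }
  if (is.na(out$fold) != (is.na(out$hsc_std_mfi) || is.na(out$lsc_std_mfi))) {
    stop("fold must be present exactly when both MFIs are defined",
         call. = FALSE)
  }
  structure(out, class = "aldh_summary")
}

#' @export
print.aldh_summary <- function(x, ...) {
  cat("Sample summary '", x$sample_id, "' (", x$cd34_status, ", marker ",
      x$marker_name, ")\n", sep = "")
  fmt <- function(v) if (is.na(v)) "-" else format(v, digits = 4)
  cat("  CD34+CD38- % of ALDH-bright:", fmt(x$pct_cd34cd38neg_in_aldh_bright),
      "\n  CD34+CD38- % of ALDH-low:   ", fmt(x$pct_cd34cd38neg_in_aldh_low),
      "\n  marker+ % (bright / low):   ", fmt(x$marker_pos_pct_bright), "/",
      fmt(x$marker_pos_pct_low),
      "\n  std MFI (HSC / LSC):        ", fmt(x$hsc_std_mfi), "/",
      fmt(x$lsc_std_mfi), "  fold:", fmt(x$fold),
      "\n  ALDH+ % of sample:          ", fmt(x$aldh_pos_pct_total),
      "  [", x$cheung_class, ", ", x$pearce_pattern, "]\n", sep = " ")
  if (any(x$low_count_flags)) {
    cat("  low-count flags:",
        paste(names(x$low_count_flags)[x$low_count_flags], collapse = ", "),
        "\n")
  }
  invisible(x)
}

summary_to_row <- function(s) {
  flags <- s$low_count_flags
  data.frame(
    sample_id = s$sample_id, marker_name = s$marker_name,
    cd34_status = s$cd34_status,
    pct_cd34cd38neg_in_aldh_bright = s$pct_cd34cd38neg_in_aldh_bright,
    pct_cd34cd38neg_in_aldh_low = s$pct_cd34cd38neg_in_aldh_low,
    marker_pos_pct_bright = s$marker_pos_pct_bright,
    marker_pos_pct_low = s$marker_pos_pct_low,
    hsc_std_mfi = s$hsc_std_mfi, lsc_std_mfi = s$lsc_std_mfi,
    fold = s$fold, aldh_pos_pct_total = s$aldh_pos_pct_total,
    cheung_class = s$cheung_class, pearce_pattern = s$pearce_pattern,
    low_count_flags = paste(names(flags)[flags], collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Stack sample summaries into a cohort table
#'
#' Rows are preserved in input order; a medians row (per-column
#' [column_median()], missing entries excluded) is carried alongside.
#'
#' @param rows List of [aldh_summary()] objects (at least one).
#' @return Object of class `cohort_table`: a list with the `rows` data frame
#'   and the named `medians` vector.
#' @export
build_cohort_table <- function(rows) {
  if (length(rows) == 0L) {
    stop("cohort table needs at least one sample summary", call. = FALSE)
  }
  stopifnot(all(vapply(rows, inherits, logical(1L), "aldh_summary")))
  df <- do.call(rbind, lapply(rows, summary_to_row))
  medians <- vapply(summary_numeric_fields(), function(f) {
    column_median(df[[f]])
  }, numeric(1L))
  structure(list(rows = df, medians = medians), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x$rows), "samples\n")
  print(x$rows[, c("sample_id", "cd34_status",
                   "pct_cd34cd38neg_in_aldh_bright",
                   "pct_cd34cd38neg_in_aldh_low", "fold")],
        row.names = FALSE)
  cat("Medians:\n")
  print(round(x$medians, 4))
  invisible(x)
}

#' Write a cohort table as TSV
#'
#' One row per sample plus a final `Median` row holding the per-column
#' medians (missing-excluded).
#'
#' @param cohort A [build_cohort_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$rows
  med <- df[1L, ]
  med[1L, ] <- NA
  med$sample_id <- "Median"
  for (f in names(cohort$medians)) med[[f]] <- cohort$medians[[f]]
  out <- rbind(df, med)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write a sample summary as JSON
#'
#' Structured key/value document containing every summary field; missing
#' numeric fields serialize as JSON `null`.  Round-trips through
#' [read_sample_summary()] at full precision.
#'
#' @param summary An [aldh_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_summary <- function(summary, path) {
  stopifnot(inherits(summary, "aldh_summary"))
  x <- unclass(summary)
  x$low_count_flags <- as.list(summary$low_count_flags)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a sample summary written by [write_sample_summary()]
#'
#' @param path Path to the JSON document.
#' @return An [aldh_summary()].
#' @export
read_sample_summary <- function(path) {
  x <- jsonlite::read_json(path)
  flags <- unlist(x$low_count_flags)
  if (is.null(flags)) flags <- logical(0L)
  x$low_count_flags <- flags
  x <- lapply(x, function(v) if (is.null(v)) NA else v)
  do.call(aldh_summary, x)
}

#' Transcribed reference cohorts
#'
#' Published per-patient measurements of 19 CD34-positive and 13
#' CD34-negative AML cases (CD34+CD38- percentages of the ALDH-bright and
#' ALDH-low compartments and their aberrant-marker-positive percentages),
#' shipped as plain-text fixtures.  Low-count annotations are carried in the
#' `*_n` columns; missing entries are `NA` and are excluded from medians.
#'
#' @param which `"cd34pos"` or `"cd34neg"`.
#' @return Data frame, one row per patient.
#' @export
reference_cohort <- function(which = c("cd34pos", "cd34neg")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("cohort_", which, ".csv"),
                      package = "aldhgate", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
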