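#' Construct an event table
#'
#' An event table is the pipeline's universal currency: an `n_events x 7`
#' matrix of nonnegative, finite, linear-scale intensities, columns ordered
#' as [panel_roles()].
#'
#' @param values Numeric matrix (or data frame) with one row per event and
#'   one column per role; columns may be named by role (any order) or
#'   unnamed in role order.
#' @param panel The [flow_panel()] the measurements were acquired with.
#' @param source_id Specimen identifier.
#' @param treatment `"native"` or `"DEAB"`.
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, panel, source_id = "sample",
                        treatment = c("native", "DEAB")) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(panel, "flow_panel"))
  roles <- panel_roles()
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(roles)) {
    stop("event values must have exactly ", length(roles), " columns",
         call. = FALSE)
  }
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), roles)) {
      stop("event value columns must be named by role", call. = FALSE)
    }
    values <- values[, roles, drop = FALSE]
  } else {
    colnames(values) <- roles
  }
  if (nrow(values) > 0L && (any(!is.finite(values)) || any(values < 0))) {
    stop("event values must be finite and nonnegative", call. = FALSE)
  }
  structure(
    list(values = values, n_events = nrow(values), panel = panel,
         source_id = as.character(source_id), treatment = treatment),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table '%s' (%s): %d events x %d channels\n",
              x$source_id, x$treatment, x$n_events, ncol(x$values)))
  invisible(x)
}

# column accessor by role
channel <- function(events, role) {
  events$values[, role]
}

#' Read event data from an FCS or delimited-text file
#'
#' FCS 3.0/3.1 files are recognized by their magic bytes; anything else is
#' read as a comma-separated table with a header row of channel names.
#' Channels are selected and reordered per the panel; channels the panel
#' declares `log10` (and FCS channels with a log amplification keyword) are
#' back-transformed to the linear scale.  Events carrying a negative or
#' non-finite value in any mapped channel are dropped; the dropped and raw
#' counts are attached as attributes `n_dropped` and `n_raw`.
#'
#' @param path Path to the event file.
#' @param panel A [flow_panel()] mapping roles to the file's channel names.
#' @param treatment `"native"` or `"DEAB"`.
#' @param source_id Specimen identifier; defaults to the file name.
#' @return An [event_table()] with attributes `n_dropped` and `n_raw`.
#' @export
read_events <- function(path, panel, treatment = c("native", "DEAB"),
                        source_id = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(panel, "flow_panel"))
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is_fcs_file(path)) {
    fcs <- read_fcs(path)
    raw <- fcs$data
    logged <- character(0L)    # FCS log amplification already undone
  } else {
    raw <- read_events_csv(path)
    logged <- names(panel$transform)[panel$transform == "log10"]
  }
  missing <- setdiff(panel$channels, colnames(raw))
  if (length(missing) > 0L) {
    stop("channel '", missing[[1L]], "' not present in ", path,
         call. = FALSE)
  }
  mat <- raw[, panel$channels, drop = FALSE]
  colnames(mat) <- names(panel$channels)
  for (role in logged) {
    mat[, role] <- 10^mat[, role]
  }
  keep <- rowSums(!is.finite(mat) | mat < 0) == 0L
  out <- event_table(mat[keep, , drop = FALSE], panel = panel,
                     source_id = source_id, treatment = treatment)
  attr(out, "n_raw") <- nrow(mat)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

read_events_csv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!nzchar(first) || !grepl(",", first)) {
    stop("unrecognized event file format: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  mat
}

#' Write an event table as CSV
#'
#' One event per row, header row of instrument channel names (so the file
#' round-trips through [read_events()] with the same panel).  Values are
#' written at full precision on the linear scale.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  mat <- events$values
  colnames(mat) <- events$panel$channels[colnames(mat)]
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}

#' Pair a native and a DEAB-treated event table
#'
#' The Aldefluor assay is run on two aliquots of the same specimen, one with
#' the ALDH inhibitor DEAB defining the fluorescence background.  Both tables
#' must share the specimen identifier and panel.
#'
#' @param native [event_table()] with `treatment = "native"`.
#' @param deab [event_table()] with `treatment = "DEAB"`.
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(native, deab) {
  stopifnot(inherits(native, "event_table"), inherits(deab, "event_table"))
  if (native$treatment != "native" || deab$treatment != "DEAB") {
    stop("sample_pair needs one native and one DEAB event table",
         call. = FALSE)
  }
  if (native$source_id != deab$source_id) {
    stop("native and DEAB aliquots come from different specimens: '",
         native$source_id, "' vs '", deab$source_id, "'", call. = FALSE)
  }
  if (!identical(native$panel$channels, deab$panel$channels)) {
    stop("native and DEAB aliquots were acquired with different panels",
         call. = FALSE)
  }
  structure(list(native = native, deab = deab,
                 source_id = native$source_id),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf("Sample pair '%s': native %d events, DEAB %d events\n",
              x$source_id, x$native$n_events, x$deab$n_events))
  invisible(x)
}
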