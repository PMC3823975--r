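#' Channel roles used throughout the pipeline
#'
#' Every event table carries exactly these seven channels, in this order:
#' forward scatter, side scatter, CD45, CD34, CD38, one leukemia-associated
#' aberrant marker (CLL-1, CD7, CD56, ...) and the Aldefluor (ALDH substrate)
#' signal.
#'
#' @return Character vector of the seven role names.
#' @export
panel_roles <- function() {
  c("FSC", "SSC", "CD45", "CD34", "CD38", "MARKER", "ALDH")
}

#' Construct a panel configuration
#'
#' A panel configuration maps the seven channel roles to instrument channel
#' names and declares the scale each channel was exported on.  Channels
#' declared `log10` are back-transformed to the linear scale on read.
#'
#' @param channels Named character vector mapping every role in
#'   [panel_roles()] to an instrument channel name.  No two roles may share a
#'   channel.
#' @param marker_name Free-text name of the aberrant marker carried on the
#'   MARKER channel (e.g. `"CLL-1"`, `"CD7"`).
#' @param transform Optional named character vector (`"linear"` or `"log10"`
#'   per role); roles not mentioned default to `"linear"`.
#' @return An object of class `flow_panel`.
#' @examples
#' flow_panel(c(FSC = "FSC-A", SSC = "SSC-A", CD45 = "CD45 PerCP",
#'              CD34 = "CD34 PC7", CD38 = "CD38 APC", MARKER = "CLL1 PE",
#'              ALDH = "FITC-A"), marker_name = "CLL-1")
#' @export
flow_panel <- function(channels, marker_name = "MARKER", transform = NULL) {
  roles <- panel_roles()
  channels <- unlist(channels)
  missing <- setdiff(roles, names(channels))
  if (length(missing) > 0L) {
    stop("role ", paste(missing, collapse = ", "), " unmapped", call. = FALSE)
  }
  extra <- setdiff(names(channels), roles)
  if (length(extra) > 0L) {
    stop("unknown role(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  channels <- channels[roles]
  dup <- channels[duplicated(channels)]
  if (length(dup) > 0L) {
    stop("channel '", dup[[1L]], "' mapped to more than one role",
         call. = FALSE)
  }
  tr <- stats::setNames(rep("linear", length(roles)), roles)
  if (!is.null(transform)) {
    transform <- unlist(transform)
    bad <- setdiff(names(transform), roles)
    if (length(bad) > 0L) {
      stop("transform given for unknown role(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(transform %in% c("linear", "log10"))) {
      stop("transform must be 'linear' or 'log10'", call. = FALSE)
    }
    tr[names(transform)] <- transform
  }
  structure(
    list(channels = channels, marker_name = as.character(marker_name),
         transform = tr),
    class = "flow_panel"
  )
}

#' Read a panel configuration file
#'
#' The file is plain text with one `key = value` pair per line (`:` is also
#' accepted as separator; blank lines and lines starting with `#` are
#' ignored).  Keys are the seven role names, optionally `marker_name`, and
#' optionally `transform.<ROLE> = log10`.
#'
#' @param path Path to the configuration file.
#' @return A [flow_panel()] object.
#' @export
read_panel_config <- function(path) {
  kv <- read_keyvalue_file(path)
  roles <- panel_roles()
  channels <- kv[names(kv) %in% roles]
  marker_name <- if ("marker_name" %in% names(kv)) kv[["marker_name"]] else "MARKER"
  tr_keys <- grep("^transform\\.", names(kv), value = TRUE)
  transform <- NULL
  if (length(tr_keys) > 0L) {
    transform <- stats::setNames(unlist(kv[tr_keys]),
                                 sub("^transform\\.", "", tr_keys))
  }
  flow_panel(channels = unlist(channels), marker_name = marker_name,
             transform = transform)
}

#' Write a panel configuration file
#'
#' @param panel A [flow_panel()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "flow_panel"))
  lines <- c(
    paste(names(panel$channels), "=", panel$channels),
    paste("marker_name =", panel$marker_name)
  )
  nonlin <- names(panel$transform)[panel$transform != "linear"]
  if (length(nonlin) > 0L) {
    lines <- c(lines, paste0("transform.", nonlin, " = ",
                             panel$transform[nonlin]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.flow_panel <- function(x, ...) {
  cat("Flow panel (marker:", x$marker_name, ")\n")
  for (r in names(x$channels)) {
    cat(sprintf("  %-7s -> %s [%s]\n", r, x$channels[[r]], x$transform[[r]]))
  }
  invisible(x)
}

# shared 'key = value' / 'key: value' reader used by panel and classifier
# configuration files; returns a named list of character scalars.
read_keyvalue_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regexpr("[=:]", ln)
    if (m < 0L) {
      stop("malformed configuration line: '", ln, "'", call. = FALSE)
    }
    key <- trimws(substr(ln, 1L, m - 1L))
    val <- trimws(substr(ln, m + 1L, nchar(ln)))
    if (key %in% names(out)) {
      stop("duplicate configuration key: '", key, "'", call. = FALSE)
    }
    out[[key]] <- val
  }
  out
}
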