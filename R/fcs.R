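# Minimal FCS 3.0/3.1 reader.
#
# Covers the subset of the standard that cytometer exports in practice use:
# a single data set, list-mode data ($MODE L), $DATATYPE F (32-bit float),
# D (64-bit float) or I (unsigned integer, common bit width), and
# little-endian (1,2,3,4) or big-endian (4,3,2,1) $BYTEORD.  Channels with a
# log amplification keyword $PnE "decades,f2" are back-transformed to the
# linear scale as f2 * 10^(decades * x / $PnR) (f2 of 0 is read as 1, per
# common vendor practice).

is_fcs_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 6L))
  magic %in% c("FCS3.0", "FCS3.1")
}

fcs_offsets <- function(header) {
  # header bytes 11..58: six right-justified ASCII integers
  field <- function(i) {
    s <- trimws(substr(header, 11L + (i - 1L) * 8L, 10L + i * 8L))
    if (!nzchar(s)) 0 else as.numeric(s)
  }
  list(text_begin = field(1L), text_end = field(2L),
       data_begin = field(3L), data_end = field(4L))
}

parse_fcs_text <- function(txt) {
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substr(txt, 2L, nchar(txt)), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(trimws(vals)), toupper(trimws(keys)))
}

#' Read an FCS 3.0/3.1 file
#'
#' Returns the raw event matrix (one row per event, columns named by the
#' `$PnN` short channel names) with any per-channel log amplification undone,
#' plus the TEXT-segment keywords.  See [read_events()] for the panel-aware
#' entry point.
#'
#' @param path Path to an FCS 3.0 or 3.1 file.
#' @return List with elements `data` (numeric matrix) and `keywords`
#'   (named list).
#' @export
read_fcs <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = size)
  version <- rawToChar(bytes[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("not an FCS 3.0/3.1 file: ", path, call. = FALSE)
  }
  header <- rawToChar(bytes[1:58])
  off <- fcs_offsets(header)
  txt <- rawToChar(bytes[(off$text_begin + 1L):(off$text_end + 1L)])
  kw <- parse_fcs_text(txt)

  data_begin <- off$data_begin
  data_end <- off$data_end
  if (data_begin == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_begin <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  if (data_begin == 0 || data_end == 0) {
    stop("FCS file has no locatable DATA segment: ", path, call. = FALSE)
  }

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  mode <- toupper(kw[["$MODE"]] %||% "L")
  if (mode != "L") {
    stop("only list-mode ($MODE L) FCS data is supported", call. = FALSE)
  }
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"

  data_raw <- bytes[(data_begin + 1L):(data_end + 1L)]
  n_values <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(data_raw, "double", n = n_values, size = 4L,
                endian = endian),
    D = readBin(data_raw, "double", n = n_values, size = 8L,
                endian = endian),
    I = {
      bits <- unique(vapply(seq_len(n_par), function(i) {
        as.integer(kw[[sprintf("$P%dB", i)]])
      }, integer(1L)))
      if (length(bits) != 1L || !bits %in% c(16L, 32L)) {
        stop("integer FCS data requires a common $PnB of 16 or 32",
             call. = FALSE)
      }
      v <- readBin(data_raw, "integer", n = n_values, size = bits / 8L,
                   signed = bits < 32L, endian = endian)
      # 16-bit values are read signed-free already; 32-bit reads are signed,
      # negative wraps are restored to their unsigned magnitude
      if (bits == 32L) v <- ifelse(v < 0, v + 2^32, v)
      if (bits == 16L) v <- ifelse(v < 0, v + 2^16, v)
      as.double(v)
    },
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  )
  if (length(vals) < n_values) {
    stop("FCS DATA segment shorter than $PAR * $TOT", call. = FALSE)
  }
  mat <- matrix(vals[seq_len(n_values)], ncol = n_par, byrow = TRUE)
  nm <- vapply(seq_len(n_par), function(i) {
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
  }, character(1L))
  colnames(mat) <- nm

  # undo log amplification channel by channel
  for (i in seq_len(n_par)) {
    pe <- kw[[sprintf("$P%dE", i)]]
    if (is.null(pe)) next
    ef <- as.numeric(strsplit(pe, ",")[[1L]])
    if (length(ef) == 2L && is.finite(ef[1L]) && ef[1L] > 0) {
      f2 <- if (is.finite(ef[2L]) && ef[2L] > 0) ef[2L] else 1
      rng <- as.numeric(kw[[sprintf("$P%dR", i)]])
      mat[, i] <- f2 * 10^(ef[1L] * mat[, i] / rng)
    }
  }
  list(data = mat, keywords = kw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
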