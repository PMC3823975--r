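# Fixtures are built in code: small event tables with hand-set channel
# values, and binary FCS files written from scratch so the reader is tested
# against the wire format rather than against itself.

test_panel <- function(marker_name = "CLL-1") {
  flow_panel(stats::setNames(panel_roles(), panel_roles()),
             marker_name = marker_name)
}

# event table from a named list of channel vectors; unspecified channels
# default to a constant 100
make_events <- function(..., n = NULL, treatment = "native",
                        source_id = "fixture") {
  ch <- list(...)
  if (is.null(n)) n <- max(vapply(ch, length, integer(1L)))
  mat <- matrix(100, nrow = n, ncol = 7,
                dimnames = list(NULL, panel_roles()))
  for (role in names(ch)) mat[, role] <- ch[[role]]
  event_table(mat, test_panel(), source_id = source_id,
              treatment = treatment)
}

# minimal FCS 3.0 writer (independent of the package reader)
write_test_fcs <- function(path, mat, datatype = "F", endian = "little",
                           pne = NULL, pnr = NULL) {
  n_par <- ncol(mat)
  n_tot <- nrow(mat)
  if (is.null(pne)) pne <- rep("0,0", n_par)
  if (is.null(pnr)) pnr <- rep(262144, n_par)
  bits <- switch(datatype, F = 32L, D = 64L, I = 16L)
  kw <- c("$MODE", "L", "$PAR", n_par, "$TOT", n_tot,
          "$DATATYPE", datatype,
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1")
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), colnames(mat)[i],
            sprintf("$P%dB", i), bits,
            sprintf("$P%dR", i), pnr[i],
            sprintf("$P%dE", i), pne[i])
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  tb <- 58L
  te <- tb + nchar(text) - 1L
  db <- te + 1L
  de <- db + n_tot * n_par * (bits / 8L) - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", tb, te, db, de, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  vals <- as.vector(t(mat))
  if (datatype == "I") {
    writeBin(as.integer(vals), con, size = 2L, endian = endian)
  } else {
    writeBin(as.double(vals), con, size = bits / 8L, endian = endian)
  }
  invisible(path)
}

# truth label -> compartment the gating is expected to assign
expected_compartment <- function(truth) {
  c(lymphocyte = "lymphocyte",
    monocyte_granulocyte = "other",
    HSC = "blast_CD34pos_CD38neg",
    LSC_cd34pos = "blast_CD34pos_CD38neg",
    LSC_cd34neg = "blast_CD34neg",
    progenitor = "blast_CD34pos_CD38pos",
    other = "other")[[truth]]
}
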