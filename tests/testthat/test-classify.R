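# build a gate_labels object with a prescribed CD34+ fraction of blasts
fake_labels <- function(n_cd34pos, n_blasts) {
  comp <- factor(
    c(rep("blast_CD34pos_CD38neg", n_cd34pos),
      rep("blast_CD34neg", n_blasts - n_cd34pos)),
    levels = c("lymphocyte", "blast_CD34pos_CD38neg",
               "blast_CD34pos_CD38pos", "blast_CD34neg", "other")
  )
  structure(list(compartment = comp, marker_positive = rep(NA, n_blasts),
                 thresholds = list(), lymphocytes = integer(0L),
                 blasts = seq_len(n_blasts)),
            class = "gate_labels")
}

test_that("CD34 status follows the strict 1% rule", {
  # published instances: 0.03% -> negative, 72% -> positive
  expect_identical(classify_cd34_status(fake_labels(3, 10000)),
                   "CD34_negative")
  expect_identical(classify_cd34_status(fake_labels(7200, 10000)),
                   "CD34_positive")
  # boundary: exactly 1% is positive ("less than 1%" defines negative)
  expect_identical(classify_cd34_status(fake_labels(100, 10000)),
                   "CD34_positive")
  expect_identical(classify_cd34_status(fake_labels(99, 10000)),
                   "CD34_negative")
  expect_error(classify_cd34_status(fake_labels(0, 0)), "empty")

  # grid vs direct rule evaluation
  for (n_pos in c(0, 1, 50, 99, 100, 101, 500, 10000)) {
    want <- if (100 * n_pos / 10000 < 1) "CD34_negative" else "CD34_positive"
    expect_identical(classify_cd34_status(fake_labels(n_pos, 10000)), want)
  }
})

test_that("stem-cell calls combine ALDH, marker and gate as documented", {
  # six events: 1-3 in the CD34+CD38- gate, 4-5 CD34- blasts, 6 other
  ev <- make_events(ALDH = c(500, 50, 500, 50, 500, 500),
                    MARKER = c(10, 900, 900, 10, 10, 10))
  comp <- factor(c("blast_CD34pos_CD38neg", "blast_CD34pos_CD38neg",
                   "blast_CD34pos_CD38neg", "blast_CD34neg",
                   "blast_CD34neg", "other"),
                 levels = levels(fake_labels(1, 1)$compartment))
  labels <- structure(
    list(compartment = comp,
         marker_positive = c(FALSE, TRUE, TRUE, FALSE, FALSE, NA),
         thresholds = list(marker = 100), lymphocytes = integer(0L),
         blasts = 1:5),
    class = "gate_labels")
  thr <- structure(list(value = 200, quantile_used = 0.99,
                        n_reference_events = 50L), class = "aldh_threshold")

  pos <- call_stem_cells(ev, labels, thr, "CD34_positive")
  expect_identical(as.character(pos$call[1:3]), c("HSC", "LSC", "ambiguous"))
  expect_identical(as.character(pos$call[4:6]),
                   c("not_stem", "not_stem", "not_stem"))

  neg <- call_stem_cells(ev, labels, thr, "CD34_negative")
  expect_identical(as.character(neg$call[4:5]), c("LSC", "ambiguous"))

  # invariants: HSC => bright and marker-negative; LSC => not bright
  for (calls in list(pos, neg)) {
    hsc <- which(calls$call == "HSC")
    expect_true(all(calls$aldh_bright[hsc]))
    expect_false(any(calls$marker_positive[hsc]))
    lsc <- intersect(which(calls$call == "LSC"),
                     which(comp == "blast_CD34pos_CD38neg"))
    expect_false(any(calls$aldh_bright[lsc]))
  }
  expect_error(call_stem_cells(ev, labels, NULL, "CD34_positive"),
               "aldh_threshold")
})

test_that("sample-level ALDH positivity uses the strict 5% rule", {
  expect_identical(cheung_classification(8.2), "positive")
  expect_identical(cheung_classification(4.9), "negative")
  expect_identical(cheung_classification(5.0), "negative")
  for (pct in c(0, 0.5, 4.99, 5, 5.01, 12.6, 100)) {
    expect_identical(cheung_classification(pct),
                     if (pct > 5) "positive" else "negative")
  }
  # raising the cutoff never converts a negative sample to positive: over
  # increasing cutoffs the class sequence is positives followed by negatives
  for (pct in c(2, 5, 7, 20)) {
    classes <- vapply(c(3, 5, 8, 25), function(cut) {
      cheung_classification(pct, classifier_config(aldh_pos_sample_cutoff = cut))
    }, character(1L))
    neg_from <- which(classes == "negative")
    if (length(neg_from) > 0L) {
      expect_true(all(classes[min(neg_from):length(classes)] == "negative"))
    }
  }
})

test_that("the ALDH pattern rule reproduces its truth table on constructed samples", {
  make_sample <- function(n, pct_pos, confined_frac) {
    n_pos <- round(n * pct_pos / 100)
    ssc <- rep(100, n)                      # lymphocyte-level SSC
    aldh <- rep(50, n)
    if (n_pos > 0L) {
      pos <- seq_len(n_pos)
      aldh[pos] <- 500
      n_conf <- round(n_pos * confined_frac)
      # confined: SSC at the lymphocyte median; unconfined: above 1.7x
      if (n_conf < n_pos) ssc[pos[(n_conf + 1L):n_pos]] <- 400
    }
    make_events(ALDH = aldh, SSC = ssc, CD45 = rep(1000, n))
  }
  thr <- structure(list(value = 200, quantile_used = 0.99,
                        n_reference_events = 100L), class = "aldh_threshold")
  cfg <- classifier_config()
  for (pct in c(0, 0.05, 2, 4, 8)) {
    for (conf in c(0.5, 0.9, 1)) {
      ev <- make_sample(4000, pct, conf)
      got <- pearce_pattern(ev, thr, lymphocytes = which(ev$values[, "SSC"] <= 100),
                            cfg)
      n_pos <- round(4000 * pct / 100)
      real_pct <- 100 * n_pos / 4000
      real_conf <- if (n_pos > 0) round(n_pos * conf) / n_pos else 1
      want <- if (real_pct < 0.1) "negative"
              else if (real_pct < 5 && real_conf >= 0.8) "rare"
              else "numerous"
      expect_identical(got, want)
    }
  }
  # a sample with no ALDH+ events is negative
  expect_identical(pearce_pattern(make_sample(1000, 0, 1), thr, 1:1000, cfg),
                   "negative")
  # any 5%-positive sample is numerous by construction
  expect_identical(pearce_pattern(make_sample(4000, 8, 1), thr,
                                  which(make_sample(4000, 8, 1)$values[, "SSC"] <= 100),
                                  cfg),
                   "numerous")
})
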