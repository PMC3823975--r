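test_that("the lymphocyte gate isolates the CD45-bright SSC-low event", {
  ev <- make_events(CD45 = c(1000, 100, 120, 80),
                    SSC = c(100, 600, 700, 650))
  expect_identical(gate_lymphocytes(ev), 1L)
})

test_that("a sample without CD45 signal has no lymphocyte reference", {
  ev <- make_events(CD45 = rep(0, 50), SSC = runif(50, 50, 500))
  expect_error(gate_lymphocytes(ev), "reference population is empty")
  expect_error(gate_lymphocytes(make_events(n = 0)), "empty event table")
})

test_that("gated lymphocytes are pure on simulated normal marrow", {
  sim <- simulate(aldh_scenario("normal_bm", n_events = 2e4), seed = 21)
  idx <- gate_lymphocytes(sim$pair$native)
  expect_gt(mean(sim$truth[idx] == "lymphocyte"), 0.9)
})

test_that("the CD45dim blast gate recovers blast-lineage events and excludes lymphocytes", {
  sim <- simulate(aldh_scenario("aml_cd34pos", n_events = 2e4), seed = 22)
  ev <- sim$pair$native
  lymph <- gate_lymphocytes(ev)
  blasts <- gate_blasts(ev, lymph)
  expect_length(intersect(blasts, lymph), 0L)
  lineage <- which(sim$truth %in% c("HSC", "LSC_cd34pos", "LSC_cd34neg",
                                    "progenitor"))
  expect_gt(length(intersect(blasts, lineage)) / length(lineage), 0.9)
  expect_identical(gate_blasts(make_events(n = 0), integer(0L)), integer(0L))
})

test_that("stem compartments partition the events", {
  sim <- simulate(aldh_scenario("aml_cd34pos", n_events = 1e4), seed = 23)
  ev <- sim$pair$native
  lymph <- gate_lymphocytes(ev)
  blasts <- gate_blasts(ev, lymph)
  labels <- partition_stem_compartments(ev, blasts, lymph)
  expect_equal(length(labels$compartment), ev$n_events)
  expect_false(any(is.na(labels$compartment)))
  blast_labels <- c("blast_CD34pos_CD38neg", "blast_CD34pos_CD38pos",
                    "blast_CD34neg")
  # compartment counts within blasts sum to the blast count
  expect_equal(sum(labels$compartment %in% blast_labels), length(blasts))
  expect_true(all(which(labels$compartment %in% blast_labels) %in% blasts))
})

test_that("raising the CD34 threshold never increases the CD34+ count", {
  sim <- simulate(aldh_scenario("aml_cd34pos", n_events = 1e4), seed = 24)
  ev <- sim$pair$native
  lymph <- gate_lymphocytes(ev)
  blasts <- gate_blasts(ev, lymph)
  counts <- vapply(c(0.9, 0.95, 0.99, 0.995, 0.9995), function(q) {
    cfg <- classifier_config(antigen_threshold_quantile = q)
    lab <- partition_stem_compartments(ev, blasts, lymph, cfg)
    sum(lab$compartment %in% c("blast_CD34pos_CD38neg",
                               "blast_CD34pos_CD38pos"))
  }, numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("marker-positive fractions count strictly-above-threshold events", {
  marker <- c(rep(10, 197), 50, 60, 70)
  ev <- make_events(MARKER = marker)
  rep200 <- marker_positive_fraction(ev, seq_len(200), threshold = 20)
  expect_equal(rep200$fraction, 1.5)
  expect_equal(rep200$numerator, 3L)
  expect_true(rep200$low_count_flag)

  none <- marker_positive_fraction(ev, seq_len(200), threshold = 1e6)
  expect_equal(none$fraction, 0)

  all_pos <- marker_positive_fraction(ev, seq_len(200), threshold = 0)
  expect_equal(all_pos$fraction, 100)
  expect_false(all_pos$low_count_flag)

  # ties at the threshold count as negative
  tie <- marker_positive_fraction(ev, seq_len(200), threshold = 10)
  expect_equal(tie$numerator, 3L)

  empty <- marker_positive_fraction(ev, integer(0L), threshold = 20)
  expect_true(is.na(empty$fraction))
  expect_true(empty$low_count_flag)
})

test_that("fraction reports flag numerators below the 25-event floor", {
  expect_true(fraction_report(24, 1000)$low_count_flag)
  expect_false(fraction_report(25, 1000)$low_count_flag)
  r <- fraction_report(3, 200)
  expect_equal(r$fraction, 1.5)
  expect_equal(r$denominator, 200L)
})
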