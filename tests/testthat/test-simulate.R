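test_that("presets encode the documented configurations", {
  expect_equal(aldh_scenario("aml_cd34pos")$aldh_fold, 6.9)
  expect_equal(aldh_scenario("aml_cd34neg")$aldh_fold, 4.3)
  norm <- aldh_scenario("normal_bm")
  expect_false(any(grepl("LSC",
    vapply(norm$populations, `[[`, character(1L), "truth_label"))))
  hsc <- Filter(function(p) p$truth_label == "HSC", norm$populations)
  expect_true(all(vapply(hsc, `[[`, character(1L), "aldh_state") == "bright"))
  expect_error(aldh_scenario("aml_cd34pos", overrides = list(bogus = 1)),
               "unknown scenario override")
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- aldh_scenario("aml_cd34pos", n_events = 2000)
  a <- simulate(sc, seed = 11)
  b <- simulate(sc, seed = 11)
  expect_identical(a$pair$native$values, b$pair$native$values)
  expect_identical(a$pair$deab$values, b$pair$deab$values)
  expect_identical(a$truth, b$truth)
  c <- simulate(sc, seed = 12)
  expect_false(identical(a$pair$native$values, c$pair$native$values))
})

test_that("realized population frequencies match the scenario multinomially", {
  n <- 1e5
  for (preset in c("normal_bm", "aml_cd34pos", "aml_cd34neg")) {
    sc <- aldh_scenario(preset, n_events = n)
    sim <- simulate(sc, seed = 5)
    expect_equal(length(sim$truth), n)   # frequency conservation
    counts <- table(sim$truth)
    labs <- vapply(sc$populations, `[[`, character(1L), "truth_label")
    freqs <- tapply(vapply(sc$populations, `[[`, numeric(1L), "frequency"),
                    labs, sum)
    # binomial z per truth label; 4 SE bound because ~17 labels are checked
    # simultaneously across the presets (a misconfigured frequency would
    # give z in the hundreds)
    for (t in names(freqs)) {
      se <- sqrt(n * freqs[[t]] * (1 - freqs[[t]]))
      expect_lt(abs(counts[[t]] - n * freqs[[t]]), 4 * se + 1e-9)
    }
  }
})

test_that("the ALDH effect size is encoded as the bright/low median ratio", {
  for (fold in c(3, 6.9)) {
    sc <- aldh_scenario("aml_cd34pos", n_events = 1e5, aldh_fold = fold)
    sim <- simulate(sc, seed = 8)
    aldh <- sim$pair$native$values[, "ALDH"]
    ratio <- stats::median(aldh[sim$truth == "HSC"]) /
      stats::median(aldh[sim$truth == "LSC_cd34pos"])
    expect_lt(abs(ratio - fold) / fold, 0.10)
  }
})

test_that("DEAB collapses every population's ALDH to the shared background", {
  sc <- aldh_scenario("aml_cd34pos", n_events = 5e4)
  sim <- simulate(sc, seed = 9)
  deab_aldh <- sim$pair$deab$values[, "ALDH"]
  # background is log-normal(log 100, 0.3); compare quartiles
  expect_lt(abs(stats::median(deab_aldh) - 100) / 100, 0.05)
  expect_lt(stats::quantile(deab_aldh, 0.999),
            stats::qlnorm(0.99999, log(100), sc$aldh_scale) * 1.5)
})

test_that("the CD34-negative preset keeps CD34+ cells under 1% of blasts", {
  sim <- simulate(aldh_scenario("aml_cd34neg", n_events = 1e5), seed = 13)
  blast_lineage <- sim$truth %in% c("HSC", "progenitor", "LSC_cd34pos",
                                    "LSC_cd34neg")
  cd34pos_truth <- sim$truth %in% c("HSC", "progenitor", "LSC_cd34pos")
  expect_lt(100 * sum(cd34pos_truth) / sum(blast_lineage), 1)
})

test_that("in normal marrow, simulated HSC ALDH exceeds the background 99th percentile", {
  sc <- aldh_scenario("normal_bm", n_events = 1e5)
  sim <- simulate(sc, seed = 2)
  bg99 <- stats::qlnorm(0.99, log(sc$aldh_background_loc), sc$aldh_scale)
  hsc_aldh <- sim$pair$native$values[sim$truth == "HSC", "ALDH"]
  expect_gt(mean(hsc_aldh > bg99), 0.99)
})

test_that("invalid scenarios are rejected", {
  sc <- aldh_scenario("normal_bm", n_events = 1000)
  bad_pops <- sc$populations
  bad_pops[[1L]]$frequency <- 0.9   # frequencies no longer sum to 1
  expect_error(aldh_scenario("normal_bm", overrides = list(populations = bad_pops)),
               "sum to 1")
  expect_error(aldh_scenario("normal_bm", n_events = 0), "positive")
})

test_that("write_simulation emits the native/deab/truth file trio", {
  sim <- simulate(aldh_scenario("normal_bm", n_events = 300), seed = 4)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("native.csv", "deab.csv", "truth.csv", "panel.txt"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 300L)
  panel <- read_panel_config(file.path(dir, "panel.txt"))
  native <- read_events(file.path(dir, "native.csv"), panel, "native")
  expect_equal(native$n_events, 300L)
})
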