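test_that("the DEAB threshold is the scoped order-statistic quantile", {
  const <- make_events(ALDH = rep(7.5, 40), treatment = "DEAB")
  thr <- deab_threshold(const, 1:40)
  expect_equal(thr$value, 7.5)
  expect_equal(thr$n_reference_events, 40L)

  set.seed(41)
  bg <- rlnorm(1000, log(100), 0.3)
  ev <- make_events(ALDH = bg, treatment = "DEAB")
  thr99 <- deab_threshold(ev, 1:1000)
  expect_equal(thr99$value, sort(bg)[ceiling(0.99 * 1000)])

  # raising the quantile never lowers the threshold
  vals <- vapply(c(0.9, 0.95, 0.99, 0.999), function(q) {
    deab_threshold(ev, 1:1000, classifier_config(deab_quantile = q))$value
  }, numeric(1L))
  expect_true(all(diff(vals) >= 0))

  expect_error(deab_threshold(ev, integer(0L)), "empty DEAB reference")
  native <- make_events(ALDH = bg, treatment = "native")
  expect_error(deab_threshold(native, 1:1000), "DEAB-treated")
})

test_that("bright/low segregation partitions the subset at the threshold", {
  ev <- make_events(ALDH = c(1, 2, 3, 10, 20))
  thr <- structure(list(value = 5, quantile_used = 0.99,
                        n_reference_events = 100L),
                   class = "aldh_threshold")
  split <- split_aldh_compartments(ev, 1:5, thr)
  expect_identical(as.character(split), c("low", "low", "low", "bright",
                                          "bright"))
  expect_equal(sum(split == "bright") + sum(split == "low"), 5L)
  all_low <- split_aldh_compartments(ev, 1:3, thr)
  expect_true(all(all_low == "low"))
  # a value exactly at the threshold is low
  at <- split_aldh_compartments(make_events(ALDH = 5), 1L, thr)
  expect_identical(as.character(at), "low")
})

test_that("standardized MFI divides subset MFI by lymphocyte MFI", {
  ev <- make_events(ALDH = c(10, 10, 20, 40))
  m <- standardized_mfi(ev, subset = 3:4, lymphocytes = 1:2)
  expect_equal(m$ratio, 3)        # mean(20,40)/mean(10,10)
  expect_equal(m$raw_mfi, 30)
  expect_equal(standardized_mfi(ev, 1:2, 1:2)$ratio, 1)

  # scaling every ALDH value leaves the ratio unchanged
  ev_k <- make_events(ALDH = 17 * c(10, 10, 20, 40))
  expect_equal(standardized_mfi(ev_k, 3:4, 1:2)$ratio, 3)

  # geometric-mean option
  gm <- standardized_mfi(ev, 3:4, 1:2,
                         classifier_config(mfi_statistic = "geometric"))
  expect_equal(gm$ratio, sqrt(20 * 40) / 10)

  ev0 <- make_events(ALDH = c(0, 0, 5, 5))
  expect_error(standardized_mfi(ev0, 3:4, 1:2), "zero")
})

test_that("fold differences behave arithmetically and cancel the standardization", {
  mk <- function(r) structure(list(raw_mfi = r * 10, lymph_mfi = 10,
                                   ratio = r), class = "standardized_mfi")
  expect_equal(fold_difference(mk(2), mk(2)), 1)
  expect_equal(fold_difference(mk(6.9), mk(1)), 6.9)
  expect_error(fold_difference(mk(1), mk(0)), "not positive")

  # lymphocyte standardization cancels: fold equals the raw MFI ratio
  set.seed(42)
  ev <- make_events(ALDH = rlnorm(400, log(150), 0.6))
  lymph <- 1:100
  a <- standardized_mfi(ev, 101:250, lymph)
  b <- standardized_mfi(ev, 251:400, lymph)
  expect_equal(fold_difference(a, b), a$raw_mfi / b$raw_mfi,
               tolerance = 1e-12)
})

test_that("the recovered HSC/LSC fold tracks the injected effect size", {
  for (fold in c(2, 10)) {
    sim <- simulate(aldh_scenario("aml_cd34pos", n_events = 5e4,
                                  aldh_fold = fold), seed = 43)
    nat <- sim$pair$native
    lymph <- gate_lymphocytes(nat)
    hsc <- standardized_mfi(nat, which(sim$truth == "HSC"), lymph)
    lsc <- standardized_mfi(nat, which(sim$truth == "LSC_cd34pos"), lymph)
    expect_lt(abs(fold_difference(hsc, lsc) - fold) / fold, 0.15)
  }
})

test_that("ALDH-positive fractions count scoped events above threshold", {
  thr <- structure(list(value = 100, quantile_used = 0.99,
                        n_reference_events = 1000L),
                   class = "aldh_threshold")
  set.seed(44)
  aldh <- runif(1e4, 0, 99)
  pos_idx <- sample.int(1e4, 850)
  aldh[pos_idx] <- runif(850, 101, 500)
  ev <- make_events(ALDH = aldh)
  rep <- aldh_positive_fraction(ev, seq_len(1e4), thr)
  expect_equal(rep$fraction, 8.5)
  expect_equal(rep$numerator, 850L)

  below <- aldh_positive_fraction(ev, setdiff(seq_len(1e4), pos_idx), thr)
  expect_equal(below$fraction, 0)
  expect_error(aldh_positive_fraction(ev, integer(0L), thr), "empty")
})

test_that("the sample ALDH-positive rate matches its distributional expectation", {
  # oracle: expected exceedance per population from the log-normal tails at
  # the realized threshold
  sc <- aldh_scenario("normal_bm", n_events = 1e5)
  sim <- simulate(sc, seed = 45)
  fit <- aldh_analyze(sim)
  thr <- fit$threshold$value
  expected <- 0
  for (p in sc$populations) {
    loc <- if (p$aldh_state == "bright") sc$aldh_fold * sc$aldh_background_loc
           else sc$aldh_background_loc
    expected <- expected +
      p$frequency * (1 - stats::plnorm(thr, log(loc), sc$aldh_scale))
  }
  se <- sqrt(expected * (1 - expected) / sc$n_events)
  got <- fit$aldh_pos_total$fraction / 100
  expect_lt(abs(got - expected), 3 * se + 1e-4)
})
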