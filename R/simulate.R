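#' Describe one simulated cell population
#'
#' Per-channel intensities are log-normal: `location` is the median on the
#' linear scale (arbitrary units; only ratios between populations are
#' meaningful) and `scale` the log-sd.  The ALDH channel is not parameterized
#' here: it is set by `aldh_state` together with the scenario-level background
#' location and fold (bright populations are centred at
#' `aldh_fold * background`, low and background populations at the
#' background itself).
#'
#' @param name Population name.
#' @param frequency Expected fraction of events in `[0, 1]`.
#' @param truth_label One of `lymphocyte`, `monocyte_granulocyte`, `HSC`,
#'   `LSC_cd34pos`, `LSC_cd34neg`, `progenitor`, `other`.
#' @param aldh_state `"bright"`, `"low"` or `"background"`.
#' @param channel_loc Named numeric, location per role for FSC, SSC, CD45,
#'   CD34, CD38, MARKER.
#' @param channel_scale Named numeric, log-sd per the same roles (all > 0).
#' @param marker_pos_frac Fraction of this population's events carrying
#'   elevated marker intensity (drawn at `marker_pos_loc` instead of the
#'   population's MARKER location).
#' @param marker_pos_loc Location of the elevated marker intensity.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, frequency, truth_label,
                            aldh_state = c("background", "bright", "low"),
                            channel_loc, channel_scale,
                            marker_pos_frac = 0, marker_pos_loc = 500) {
  aldh_state <- match.arg(aldh_state)
  truth_label <- match.arg(truth_label, truth_levels())
  roles <- setdiff(panel_roles(), "ALDH")
  stopifnot(is.numeric(frequency), frequency >= 0, frequency <= 1)
  channel_loc <- unlist(channel_loc)[roles]
  channel_scale <- unlist(channel_scale)[roles]
  if (any(is.na(channel_loc)) || any(is.na(channel_scale))) {
    stop("channel_loc and channel_scale must cover roles ",
         paste(roles, collapse = ", "), call. = FALSE)
  }
  if (any(channel_scale <= 0)) {
    stop("channel scales must be positive", call. = FALSE)
  }
  stopifnot(marker_pos_frac >= 0, marker_pos_frac <= 1, marker_pos_loc > 0)
  structure(
    list(name = name, frequency = frequency, truth_label = truth_label,
         aldh_state = aldh_state, channel_loc = channel_loc,
         channel_scale = channel_scale, marker_pos_frac = marker_pos_frac,
         marker_pos_loc = marker_pos_loc),
    class = "population_spec"
  )
}

#' Ground-truth population labels
#' @return Character vector of recognized truth labels.
#' @export
truth_levels <- function() {
  c("lymphocyte", "monocyte_granulocyte", "HSC", "LSC_cd34pos",
    "LSC_cd34neg", "progenitor", "other")
}

# fixed channel parameters of the stock populations; scatter locations encode
# the published lymphocyte-referenced bands (HSC 1.2x/1.35x, LSC 1.6x/2.0x;
# the low/high boundary sits at 1.4x/1.7x)
stock_population <- function(which, frequency, aldh_state,
                             marker_pos_frac = 0) {
  p <- switch(which,
    lymphocyte = list(
      loc = c(FSC = 100, SSC = 100, CD45 = 1000, CD34 = 50, CD38 = 50,
              MARKER = 50),
      scale = c(FSC = 0.15, SSC = 0.15, CD45 = 0.15, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "lymphocyte"),
    monocyte = list(
      loc = c(FSC = 200, SSC = 500, CD45 = 900, CD34 = 50, CD38 = 400,
              MARKER = 50),
      scale = c(FSC = 0.2, SSC = 0.2, CD45 = 0.15, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "monocyte_granulocyte"),
    erythroid = list(
      loc = c(FSC = 130, SSC = 150, CD45 = 20, CD34 = 50, CD38 = 50,
              MARKER = 50),
      scale = c(FSC = 0.2, SSC = 0.25, CD45 = 0.25, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "other"),
    hsc = list(
      loc = c(FSC = 120, SSC = 135, CD45 = 250, CD34 = 1000, CD38 = 50,
              MARKER = 50),
      scale = c(FSC = 0.15, SSC = 0.2, CD45 = 0.25, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "HSC"),
    progenitor = list(
      loc = c(FSC = 130, SSC = 160, CD45 = 250, CD34 = 1000, CD38 = 1000,
              MARKER = 50),
      scale = c(FSC = 0.15, SSC = 0.2, CD45 = 0.25, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "progenitor"),
    progenitor_leukemic = list(
      loc = c(FSC = 150, SSC = 200, CD45 = 250, CD34 = 1000, CD38 = 1000,
              MARKER = 50),
      scale = c(FSC = 0.15, SSC = 0.2, CD45 = 0.25, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "progenitor"),
    lsc_cd34pos = list(
      loc = c(FSC = 160, SSC = 200, CD45 = 250, CD34 = 1000, CD38 = 50,
              MARKER = 50),
      scale = c(FSC = 0.15, SSC = 0.2, CD45 = 0.25, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "LSC_cd34pos"),
    lsc_cd34neg = list(
      loc = c(FSC = 160, SSC = 200, CD45 = 250, CD34 = 40, CD38 = 600,
              MARKER = 50),
      scale = c(FSC = 0.15, SSC = 0.2, CD45 = 0.25, CD34 = 0.3, CD38 = 0.3,
                MARKER = 0.3),
      truth = "lsc"),
    stop("unknown stock population: ", which, call. = FALSE)
  )
  truth <- if (identical(p$truth, "lsc")) "LSC_cd34neg" else p$truth
  population_spec(name = which, frequency = frequency, truth_label = truth,
                  aldh_state = aldh_state, channel_loc = p$loc,
                  channel_scale = p$scale, marker_pos_frac = marker_pos_frac)
}

#' Build a simulation scenario
#'
#' The three presets emulate the population structure the classifier assumes:
#'
#' * `normal_bm` — healthy marrow mononuclear cells: lymphocytes, monocytes,
#'   CD45-negative erythroid precursors, ALDH-bright CD34+CD38- HSC and
#'   ALDH-bright CD34+CD38+ progenitors; no leukemic populations.
#' * `aml_cd34pos` — CD34-positive AML: ALDH-bright HSC coexist with
#'   ALDH-low CD34+CD38- LSC, a large leukemic CD34+CD38+ bulk and CD34-
#'   blasts; default `aldh_fold` 6.9.
#' * `aml_cd34neg` — CD34-negative AML: the rare CD34+ cells (under 1% of
#'   blasts) are all normal (HSC/progenitors); LSC are CD34- and ALDH-low;
#'   default `aldh_fold` 4.3.
#'
#' `aldh_fold` is the ratio of the bright populations' ALDH location to the
#' ALDH background location, i.e. the HSC-over-LSC activity effect size.
#'
#' @param preset One of `"normal_bm"`, `"aml_cd34pos"`, `"aml_cd34neg"`.
#' @param n_events Number of events per aliquot (default 1e5).
#' @param aldh_fold Optional override of the preset's fold.
#' @param seed Optional integer seed stored with the scenario.
#' @param overrides Optional named list merged last over the scenario fields
#'   (`n_events`, `aldh_fold`, `seed`, `aldh_background_loc`, `aldh_scale`,
#'   `deab_residual_fraction`, `populations`).
#' @return An object of class `aldh_scenario`.
#' @examples
#' sc <- aldh_scenario("aml_cd34pos", n_events = 1000, seed = 1)
#' sim <- simulate(sc)
#' table(sim$truth)
#' @export
aldh_scenario <- function(preset = c("normal_bm", "aml_cd34pos",
                                     "aml_cd34neg"),
                          n_events = 1e5, aldh_fold = NULL, seed = NULL,
                          overrides = list()) {
  preset <- match.arg(preset)
  pops <- switch(preset,
    normal_bm = list(
      stock_population("lymphocyte", 0.400, "background"),
      stock_population("monocyte", 0.250, "background"),
      stock_population("erythroid", 0.305, "background"),
      stock_population("hsc", 0.005, "bright"),
      stock_population("progenitor", 0.040, "bright")
    ),
    aml_cd34pos = list(
      stock_population("lymphocyte", 0.150, "background"),
      stock_population("monocyte", 0.050, "background"),
      stock_population("erythroid", 0.050, "background"),
      stock_population("hsc", 0.005, "bright"),
      stock_population("lsc_cd34pos", 0.020, "low", marker_pos_frac = 0.75),
      stock_population("progenitor_leukemic", 0.500, "low"),
      stock_population("lsc_cd34neg", 0.225, "low", marker_pos_frac = 0.75)
    ),
    aml_cd34neg = list(
      stock_population("lymphocyte", 0.150, "background"),
      stock_population("monocyte", 0.050, "background"),
      stock_population("erythroid", 0.050, "background"),
      stock_population("hsc", 0.002, "bright"),
      stock_population("progenitor", 0.003, "bright"),
      stock_population("lsc_cd34neg", 0.745, "low", marker_pos_frac = 0.75)
    )
  )
  default_fold <- switch(preset, normal_bm = 6.9, aml_cd34pos = 6.9,
                         aml_cd34neg = 4.3)
  sc <- list(
    preset = preset,
    populations = pops,
    n_events = as.integer(n_events),
    aldh_fold = if (is.null(aldh_fold)) default_fold else as.numeric(aldh_fold),
    aldh_background_loc = 100,
    aldh_scale = 0.30,
    deab_residual_fraction = 0,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  for (k in names(overrides)) {
    if (!k %in% names(sc)) {
      stop("unknown scenario override: '", k, "'", call. = FALSE)
    }
    sc[[k]] <- overrides[[k]]
  }
  validate_scenario(sc)
  structure(sc, class = "aldh_scenario")
}

validate_scenario <- function(sc) {
  freqs <- vapply(sc$populations, `[[`, numeric(1L), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("population frequencies must sum to 1 (got ",
         format(sum(freqs), digits = 12), ")", call. = FALSE)
  }
  if (sc$n_events <= 0L) stop("n_events must be positive", call. = FALSE)
  if (sc$aldh_fold <= 0) stop("aldh_fold must be positive", call. = FALSE)
  if (sc$deab_residual_fraction < 0 || sc$deab_residual_fraction > 1) {
    stop("deab_residual_fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(sc)
}

#' @export
print.aldh_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d events, ALDH fold %.2f\n", x$preset,
              x$n_events, x$aldh_fold))
  for (p in x$populations) {
    cat(sprintf("  %-20s %6.2f%%  ALDH %-10s truth %s\n", p$name,
                100 * p$frequency, p$aldh_state, p$truth_label))
  }
  invisible(x)
}

aldh_location <- function(sc, state) {
  switch(state,
    bright = sc$aldh_fold * sc$aldh_background_loc,
    low = sc$aldh_background_loc,
    background = sc$aldh_background_loc
  )
}

draw_population <- function(pop, n, sc, inhibit) {
  roles <- panel_roles()
  mat <- matrix(0, nrow = n, ncol = length(roles),
                dimnames = list(NULL, roles))
  if (n == 0L) return(mat)
  for (role in setdiff(roles, c("ALDH", "MARKER"))) {
    mat[, role] <- stats::rlnorm(n, log(pop$channel_loc[[role]]),
                                 pop$channel_scale[[role]])
  }
  pos <- stats::runif(n) < pop$marker_pos_frac
  mk <- stats::rlnorm(n, log(pop$channel_loc[["MARKER"]]),
                      pop$channel_scale[["MARKER"]])
  if (any(pos)) {
    mk[pos] <- stats::rlnorm(sum(pos), log(pop$marker_pos_loc),
                             pop$channel_scale[["MARKER"]])
  }
  mat[, "MARKER"] <- mk
  state <- pop$aldh_state
  if (inhibit && state == "bright" && sc$deab_residual_fraction < 1) {
    resid <- stats::runif(n) < sc$deab_residual_fraction
    loc <- ifelse(resid, aldh_location(sc, "bright"),
                  aldh_location(sc, "background"))
    mat[, "ALDH"] <- stats::rlnorm(n, log(loc), sc$aldh_scale)
  } else {
    eff <- if (inhibit) "background" else state
    mat[, "ALDH"] <- stats::rlnorm(n, log(aldh_location(sc, eff)),
                                   sc$aldh_scale)
  }
  mat
}

draw_aliquot <- function(sc, inhibit) {
  freqs <- vapply(sc$populations, `[[`, numeric(1L), "frequency")
  counts <- drop(stats::rmultinom(1L, sc$n_events, freqs))
  blocks <- vector("list", length(sc$populations))
  for (i in seq_along(sc$populations)) {
    blocks[[i]] <- draw_population(sc$populations[[i]], counts[i], sc,
                                   inhibit)
  }
  mat <- do.call(rbind, blocks)
  truth <- factor(rep(vapply(sc$populations, `[[`, character(1L),
                             "truth_label"), counts),
                  levels = truth_levels())
  ord <- sample.int(nrow(mat))
  list(values = mat[ord, , drop = FALSE], truth = truth[ord])
}

#' Simulate a paired native/DEAB sample from a scenario
#'
#' Draws population sizes from a multinomial at the scenario frequencies and
#' per-channel intensities from the populations' log-normal distributions.
#' In the DEAB aliquot the ALDH channel of every population collapses to the
#' shared background distribution (unless `deab_residual_fraction` models
#' incomplete inhibition); all other channels are regenerated from the same
#' distributions.  Output is bit-identical for a fixed seed.
#'
#' @param object An [aldh_scenario()].
#' @param nsim Number of sample pairs to draw (default 1).
#' @param seed Integer seed; falls back to the scenario's stored seed.
#' @param ... Unused.
#' @return For `nsim = 1` an object of class `aldh_simulation`: a list with
#'   the [sample_pair()] `pair`, the per-native-event `truth` factor, and the
#'   scenario.  For `nsim > 1`, a list of such objects.
#' @export
simulate.aldh_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- if (is.null(seed)) object$seed else as.integer(seed)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  panel <- default_panel(marker_name = "CLL-1")
  one <- function(k) {
    native <- draw_aliquot(object, inhibit = FALSE)
    deab <- draw_aliquot(object, inhibit = TRUE)
    id <- sprintf("%s_sim%d", object$preset,
                  if (is.null(seed)) k else seed + k - 1L)
    pair <- sample_pair(
      event_table(native$values, panel, source_id = id,
                  treatment = "native"),
      event_table(deab$values, panel, source_id = id, treatment = "DEAB")
    )
    structure(list(pair = pair, truth = native$truth, scenario = object),
              class = "aldh_simulation")
  }
  if (nsim == 1L) one(1L) else lapply(seq_len(nsim), one)
}

default_panel <- function(marker_name = "MARKER") {
  flow_panel(stats::setNames(panel_roles(), panel_roles()),
             marker_name = marker_name)
}

#' @export
print.aldh_simulation <- function(x, ...) {
  cat(sprintf("Simulated %s sample pair (%d native events)\n",
              x$scenario$preset, x$pair$native$n_events))
  print(table(truth = x$truth))
  invisible(x)
}

#' Write a simulated sample pair to disk
#'
#' Writes `native.csv`, `deab.csv` (event tables), `truth.csv` (per native
#' event ground-truth label) and `panel.txt` into a directory.
#'
#' @param sim An `aldh_simulation` from [simulate.aldh_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "aldh_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(sim$pair$native, file.path(dir, "native.csv"))
  write_events(sim$pair$deab, file.path(dir, "deab.csv"))
  utils::write.csv(data.frame(truth = as.character(sim$truth)),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  write_panel_config(sim$pair$native$panel, file.path(dir, "panel.txt"))
  invisible(dir)
}
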