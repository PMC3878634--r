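# Food-supply perturbation scenarios and the end-to-end per-group analysis.

#' Across-the-board sodium reduction of the food supply
#'
#' Scales the sodium content (per 100 g) of every category by `multiplier`,
#' leaving every other nutrient untouched. The headline scenario is a 10%
#' cut (`multiplier = 0.9`). A uniform scaling maps the feasibility region
#' exactly via (Na, K) -> (multiplier * Na, K): any pattern supplying s mg
#' sodium before the cut supplies multiplier * s after it, with all other
#' totals unchanged.
#'
#' @param categories category (or foods) table with a `sodium_mg` column.
#' @param multiplier in (0, 1].
#' @return the table with scaled sodium.
#' @export
reduce_sodium <- function(categories, multiplier = 0.9) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 ||
      multiplier <= 0 || multiplier > 1) {
    stop("sodium multiplier must be in (0, 1]")
  }
  categories$sodium_mg <- categories$sodium_mg * multiplier
  categories
}

#' Observed vs modeled MyPyramid pattern table
#'
#' The comparison table of a group's observed diet against an optimized
#' pattern: energy (kcal/d), total weight (kg/d), MyPyramid food-group rows
#' (fruit and vegetable cup-eq/d; total, whole and refined grain oz-eq/d;
#' meat-and-beans oz-eq/d; milk cup-eq/d; oils g/d) and calories from solid
#' fats and added sugars (SoFAS, kcal/d).
#'
#' @param observed an `observed_pattern`.
#' @param modeled an `lp_solution` for the same group.
#' @return object of class `pattern_comparison` (a tibble with attributes).
#' @export
compare_patterns <- function(observed, modeled) {
  if (!identical(observed$group, modeled$group)) {
    stop("observed and modeled patterns are for different groups (",
         observed$group, " vs ", modeled$group, ")")
  }
  if (!identical(modeled$status, "optimal")) {
    stop("modeled pattern has status ", modeled$status)
  }
  spec <- tibble::tribble(
    ~row,                 ~key,                   ~unit,     ~scale,
    "Energy",             "energy_kcal",          "kcal/d",  1,
    "Total weight",       "total_weight_g",       "kg/d",    1e-3,
    "Sodium",             "sodium_mg",            "mg/d",    1,
    "Potassium",          "potassium_mg",         "mg/d",    1,
    "Fruits",             "pyr_fruit_cup",        "cup-eq/d", 1,
    "Vegetables",         "pyr_veg_cup",          "cup-eq/d", 1,
    "Total grains",       "pyr_grain_total_oz",   "oz-eq/d", 1,
    "Whole grains",       "pyr_grain_whole_oz",   "oz-eq/d", 1,
    "Refined grains",     "pyr_grain_refined_oz", "oz-eq/d", 1,
    "Meat and beans",     "pyr_meat_oz",          "oz-eq/d", 1,
    "Milk",               "pyr_milk_cup",         "cup-eq/d", 1,
    "Oils",               "pyr_oils_g",           "g/d",     1,
    "SoFAS",              "pyr_sofas_kcal",       "kcal/d",  1)
  spec <- spec[spec$key %in% names(observed$totals), , drop = FALSE]
  out <- tibble::tibble(
    row = spec$row, unit = spec$unit,
    observed = unname(observed$totals[spec$key]) * spec$scale,
    modeled = unname(modeled$totals[spec$key]) * spec$scale)
  structure(out, group = observed$group, class = c("pattern_comparison",
                                                   class(out)))
}

#' Run the full per-group, per-scenario analysis
#'
#' Orchestrates the whole pipeline for every requested sex-age group and
#' sodium-supply scenario: filters, aggregation, constraint building, the
#' potassium-maximal point on the Na:K ratio line, the fixed-sodium sweep
#' started from that point, the min-deviation pattern at the ratio, and
#' guideline verdicts at the general and strict sodium limits. Artifacts are
#' optionally written (CSV/JSON) with a manifest echoing the configuration.
#'
#' @param config list with entries `foods`, `intakes`, `profiles` (or
#'   `data_dir` to [read_survey()] them), optional `groups` (default all 6),
#'   `scenarios` (named sodium multipliers, default
#'   `c(baseline = 1, sodium_minus_10 = 0.9)`), `ratio`, `guidelines`,
#'   `step_mg`, `constraint_options`, `use_bounds` (set FALSE to skip the
#'   percentile food-group bounds, e.g. for single-individual fixtures whose
#'   percentiles would pin the diet to the observed point), `out_dir`.
#' @return list of per-(group, scenario) results plus a `manifest`.
#' @export
run_full_analysis <- function(config) {
  if (!is.null(config$data_dir)) {
    if (!dir.exists(config$data_dir)) {
      stop("missing input: ", config$data_dir)
    }
    sv <- read_survey(config$data_dir)
    config$foods <- sv$foods; config$intakes <- sv$intakes
    config$profiles <- sv$profiles
  }
  for (need in c("foods", "intakes", "profiles")) {
    if (is.null(config[[need]])) stop("missing input: ", need)
  }
  groups <- config$groups %||% intersect(.dietlp_groups,
                                         unique(config$intakes$sex_age_group))
  use_bounds <- config$use_bounds %||% TRUE
  scenarios <- config$scenarios %||% c(baseline = 1, sodium_minus_10 = 0.9)
  gl <- config$guidelines %||% default_guidelines()
  ratio <- config$ratio %||% gl$ratio
  step_mg <- config$step_mg %||% 100
  copts <- config$constraint_options %||% list()

  foods <- filter_foods(config$foods)
  intakes <- filter_individuals(config$intakes, config$foods)

  results <- list()
  for (g in groups) {
    cats0 <- aggregate_categories(intakes, foods, g)
    bounds <- if (use_bounds) consumption_percentiles(intakes, foods, g)
    observed <- observed_pattern(intakes, cats0, g)
    cs <- build_constraint_set(config$profiles[[g]], bounds, copts)
    for (sc in names(scenarios)) {
      m <- scenarios[[sc]]
      cats <- reduce_sodium(cats0, m)
      anchor <- max_k_at_ratio(cats, cs, ratio)
      if (anchor$status == "optimal") {
        region <- sweep_sodium(cats, cs, start_mg = anchor$sodium_mg,
                               step_mg = if (sc == "baseline") step_mg else
                                 step_mg * m,
                               scenario = sc)
        mindev <- solve_min_deviation(cats, apply_ratio_constraint(cs, ratio),
                                      observed)
        verdicts <- list(
          general = check_guideline_compatibility(region, gl$na_limit,
                                                  gl$k_goal),
          strict = check_guideline_compatibility(region, gl$na_limit_strict,
                                                 gl$k_goal))
        comparison <- if (mindev$status == "optimal") {
          compare_patterns(observed, mindev)
        }
      } else {
        region <- NULL; mindev <- NULL; verdicts <- NULL; comparison <- NULL
      }
      results[[paste(g, sc, sep = "/")]] <- list(
        group = g, scenario = sc, sodium_multiplier = m,
        anchor = anchor, region = region, min_deviation = mindev,
        verdicts = verdicts, comparison = comparison,
        observed = observed)
    }
  }
  manifest <- list(
    groups = groups, scenarios = as.list(scenarios), ratio = ratio,
    guidelines = gl[c("na_limit", "na_limit_strict", "k_goal")],
    step_mg = step_mg, n_results = length(results))
  bundle <- list(results = results, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(results)) {
      r <- results[[key]]
      tag <- gsub("[^A-Za-z0-9]+", "_", key)
      if (!is.null(r$region)) {
        write_region(r$region,
                     csv_file = file.path(config$out_dir,
                                          paste0("region_", tag, ".csv")),
                     json_file = file.path(config$out_dir,
                                           paste0("region_", tag, ".json")))
      }
      if (!is.null(r$comparison)) {
        write.csv(r$comparison,
                  file.path(config$out_dir, paste0("pattern_", tag, ".csv")),
                  row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(manifest, file.path(config$out_dir, "config.yaml"))
  }
  bundle
}
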