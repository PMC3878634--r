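# Exclusion filters and collapse of individual foods into per-group food
# categories with consumption-weighted nutrient profiles.

#' Drop excluded foods
#'
#' Removes baby foods, alcohol, supplements/medical foods, chewing gum and
#' foods with an energy density below 10 kcal/100 g (all carried in the
#' `excluded_class` flag). Idempotent.
#'
#' @param foods foods table.
#' @return filtered foods table.
#' @export
filter_foods <- function(foods) {
  foods[as.character(foods$excluded_class) == "none", , drop = FALSE]
}

#' Drop pregnant individuals and implausibly low energy reporters
#'
#' Excludes pregnant individuals and those whose daily energy intake —
#' computed over foods that pass [filter_foods()], so that the two filters
#' commute — is below 600 kcal/d. Intakes that reference a food code absent
#' from `foods` are a referential-integrity error.
#'
#' @param intakes intake table.
#' @param foods foods table (used for energy densities and exclusion flags).
#' @return filtered intake table; attribute `"dropped"` counts individuals
#'   removed per reason.
#' @export
filter_individuals <- function(intakes, foods) {
  bad <- setdiff(intakes$food_code, foods$food_code)
  if (length(bad)) {
    stop("intake rows reference unknown food codes: ",
         paste(head(bad, 5), collapse = ", "))
  }
  kept_foods <- filter_foods(foods)
  e_per_g <- setNames(kept_foods$energy_kcal / 100, kept_foods$food_code)
  ei <- intakes |>
    dplyr::mutate(e = .data$grams_per_day *
                    dplyr::coalesce(e_per_g[.data$food_code], 0)) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(energy = sum(.data$e), pregnant = any(.data$pregnant))
  drop_preg <- ei$individual_id[ei$pregnant]
  drop_low <- ei$individual_id[ei$energy < 600]
  out <- intakes[!intakes$individual_id %in% union(drop_preg, drop_low), ,
                 drop = FALSE]
  attr(out, "dropped") <- c(pregnant = length(drop_preg),
                            low_energy = length(setdiff(drop_low, drop_preg)))
  out
}

#' Collapse foods into per-group food categories
#'
#' The LP variables of one sex-age group. Each category's per-100 g profile
#' is the consumption-weighted mean of its member foods' profiles, with
#' weights equal to total grams of each food consumed within the group (the
#' weighting that conserves nutrient mass). Categories never consumed by the
#' group are omitted, so the variable list is group-specific. Consumption
#' statistics (p10/p75/p90/mean over consumers, mean over all individuals)
#' are attached per category.
#'
#' @param intakes intake table, already individual- and food-filtered.
#' @param foods foods table (excluded foods are dropped here too, so passing
#'   an unfiltered table is safe).
#' @param group sex-age group label.
#' @return tibble of food categories, one row per category consumed by the
#'   group.
#' @export
aggregate_categories <- function(intakes, foods, group) {
  foods <- filter_foods(foods)
  gi <- intakes[intakes$sex_age_group == group &
                  intakes$food_code %in% foods$food_code, , drop = FALSE]
  if (nrow(gi) == 0) stop("no retained intake rows for group ", group)
  n_indiv <- dplyr::n_distinct(gi$individual_id)

  pcols <- profile_cols(foods)
  joined <- dplyr::inner_join(gi, foods, by = "food_code")

  # weighted per-100 g profile: weights = total grams per food in the group
  per_food <- joined |>
    dplyr::group_by(.data$category_id, .data$subgroup_id,
                    .data$major_group_id, .data$food_code) |>
    dplyr::summarise(w = sum(.data$grams_per_day),
                     dplyr::across(dplyr::all_of(pcols), dplyr::first),
                     .groups = "drop")
  prof <- per_food |>
    dplyr::group_by(.data$category_id, .data$subgroup_id,
                    .data$major_group_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pcols),
                                   ~ sum(.x * w) / sum(w)),
                     .groups = "drop")

  # per-individual daily grams per category -> consumption stats
  per_ind <- joined |>
    dplyr::group_by(.data$category_id, .data$individual_id) |>
    dplyr::summarise(g = sum(.data$grams_per_day), .groups = "drop")
  stats <- per_ind |>
    dplyr::filter(.data$g > 0) |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(
      obs_p10 = quantile(.data$g, 0.10, names = FALSE),
      obs_p75 = quantile(.data$g, 0.75, names = FALSE),
      obs_p90 = quantile(.data$g, 0.90, names = FALSE),
      obs_mean = mean(.data$g),
      obs_n_consumers = dplyr::n(),
      obs_total = sum(.data$g))
  stats$obs_mean_all <- stats$obs_total / n_indiv
  stats$obs_total <- NULL

  out <- dplyr::inner_join(prof, stats, by = "category_id")
  out$group <- group
  out <- out[order(out$category_id), , drop = FALSE]
  attr(out, "n_individuals") <- n_indiv
  out
}

#' Consumption percentile bounds per taxonomy node
#'
#' Computes the bounds the LP food-group constraints use: 10th and 90th
#' percentiles of daily consumption per major food group, and the 75th
#' percentile per subgroup and per category. Major-group percentiles include
#' non-consumers as zeros (a population-level bound); subgroup and category
#' percentiles are over consumers only, since they bound observed
#' consumption. Both choices are switchable. Percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param intakes filtered intake table.
#' @param foods foods table (supplies the taxonomy).
#' @param group sex-age group label.
#' @param major_include_zeros,sub_include_zeros include non-consumers as
#'   zeros at the respective tiers.
#' @return tibble with `node_id`, `tier` (major/subgroup/category), `p10`,
#'   `p75`, `p90` (NA where not used by that tier).
#' @export
consumption_percentiles <- function(intakes, foods, group,
                                    major_include_zeros = TRUE,
                                    sub_include_zeros = FALSE) {
  foods <- filter_foods(foods)
  gi <- intakes[intakes$sex_age_group == group &
                  intakes$food_code %in% foods$food_code, , drop = FALSE]
  if (nrow(gi) == 0) stop("no retained intake rows for group ", group)
  ids <- unique(gi$individual_id)
  joined <- dplyr::inner_join(gi, foods, by = "food_code")

  node_q <- function(node_col, probs, include_zeros) {
    per_ind <- joined |>
      dplyr::group_by(node_id = .data[[node_col]], .data$individual_id) |>
      dplyr::summarise(g = sum(.data$grams_per_day), .groups = "drop") |>
      dplyr::filter(.data$g > 0)   # consumers; zeros re-enter below if asked
    per_ind |>
      dplyr::group_by(.data$node_id) |>
      dplyr::summarise(q = {
        x <- .data$g
        if (include_zeros) x <- c(x, rep(0, length(ids) - length(x)))
        list(quantile(x, probs, names = FALSE))
      }) |>
      tidyr_unpack(probs)
  }
  # minimal unnest: expand the list column into p-columns
  tidyr_unpack <- function(df, probs) {
    m <- do.call(rbind, df$q)
    colnames(m) <- paste0("p", probs * 100)
    dplyr::bind_cols(df[, "node_id", drop = FALSE], tibble::as_tibble(m))
  }

  major <- node_q("major_group_id", c(0.10, 0.90), major_include_zeros)
  major <- tibble::tibble(node_id = major$node_id, tier = "major",
                          p10 = major$p10, p75 = NA_real_, p90 = major$p90)
  sub <- node_q("subgroup_id", 0.75, sub_include_zeros)
  sub <- tibble::tibble(node_id = sub$node_id, tier = "subgroup",
                        p10 = NA_real_, p75 = sub$p75, p90 = NA_real_)
  cat <- node_q("category_id", 0.75, sub_include_zeros)
  cat <- tibble::tibble(node_id = cat$node_id, tier = "category",
                        p10 = NA_real_, p75 = cat$p75, p90 = NA_real_)
  dplyr::bind_rows(major, sub, cat)
}

#' Group-mean observed food pattern
#'
#' The observed diet of a sex-age group: per-category mean daily grams over
#' all retained individuals (non-consumers as zeros), with energy, sodium,
#' potassium, nutrient and MyPyramid totals computed from the category
#' profiles.
#'
#' @param intakes filtered intake table.
#' @param categories category table from [aggregate_categories()].
#' @param group sex-age group label.
#' @return object of class `observed_pattern`: list with `group`, `amounts`
#'   (named g/d) and `totals` (named vector).
#' @export
observed_pattern <- function(intakes, categories, group) {
  if (is.null(categories) || nrow(categories) == 0) {
    stop("empty category list")
  }
  amounts <- setNames(categories$obs_mean_all, categories$category_id)
  totals <- pattern_totals(categories, amounts)
  structure(list(group = group, amounts = amounts, totals = totals),
            class = "observed_pattern")
}

#' Totals of a diet pattern
#'
#' Dot product of category amounts (g/d) with per-100 g profiles.
#'
#' @param categories category table.
#' @param amounts named vector of g/d, names = category ids.
#' @return named numeric vector of daily totals (energy, Na, K, nutrients,
#'   MyPyramid equivalents) plus `total_weight_g`.
#' @export
pattern_totals <- function(categories, amounts) {
  x <- amounts[categories$category_id]
  x[is.na(x)] <- 0
  pcols <- profile_cols(categories)
  tot <- vapply(pcols, function(cc) sum(x * categories[[cc]] / 100),
                numeric(1))
  c(tot, total_weight_g = sum(x))
}

#' @export
print.observed_pattern <- function(x, ...) {
  cat("<observed_pattern> ", x$group, ": ", length(x$amounts),
      " categories, energy ", round(x$totals[["energy_kcal"]]), " kcal/d, Na ",
      round(x$totals[["sodium_mg"]]), " mg/d, K ",
      round(x$totals[["potassium_mg"]]), " mg/d\n", sep = "")
  invisible(x)
}
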