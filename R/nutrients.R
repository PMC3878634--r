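# Nutrient panel registry shared by the generator, the aggregator and the
# constraint builder. Column names double as nutrient identifiers; units are
# embedded in the names (g, mg, ug per 100 g edible portion or per day).

.dietlp_core_cols <- c("energy_kcal", "sodium_mg", "potassium_mg")

.dietlp_dri_nutrients <- c(
  "protein_g", "carbohydrate_g", "fat_g", "satfat_g", "linoleic_g",
  "linolenic_g", "cholesterol_mg", "added_sugar_g", "fiber_g",
  "vitamin_a_ug", "vitamin_c_mg", "vitamin_e_mg", "thiamin_mg",
  "riboflavin_mg", "niacin_mg", "vitamin_b6_mg", "folate_ug",
  "vitamin_b12_ug", "calcium_mg", "copper_mg", "iron_mg", "magnesium_mg",
  "phosphorus_mg", "selenium_ug", "zinc_mg")

.dietlp_pyramid_cols <- c(
  "pyr_fruit_cup", "pyr_veg_cup", "pyr_grain_total_oz", "pyr_grain_whole_oz",
  "pyr_grain_refined_oz", "pyr_meat_oz", "pyr_milk_cup", "pyr_oils_g",
  "pyr_sofas_kcal")

.dietlp_extra_cols <- c("solid_fat_g")

# every per-100 g column a food or category may carry
.dietlp_profile_cols <- function() {
  c(.dietlp_core_cols, .dietlp_dri_nutrients, .dietlp_extra_cols,
    .dietlp_pyramid_cols)
}

#' Columns of a food or category table that hold per-100 g profile values
#'
#' @param x a foods or categories data frame.
#' @return character vector of column names, in canonical order.
#' @export
profile_cols <- function(x) {
  intersect(.dietlp_profile_cols(), names(x))
}

#' Default synthetic Dietary Reference Intake table
#'
#' A documented synthetic stand-in for the DRI panel used to build nutrient
#' adequacy constraints: one row per nutrient with an optional daily minimum
#' and maximum in the unit embedded in the nutrient name. Only three values
#' are fixed by the guideline context the package models (the vitamin E
#' override level of 13 mg/d is applied elsewhere; sodium 2300/1500 mg/d and
#' potassium 4700 mg/d live in [default_guidelines()]); all other bounds are
#' configuration entries of the synthetic world, not claims about real DRIs.
#'
#' @return tibble with columns `nutrient`, `unit`, `min`, `max`.
#' @export
default_dri_table <- function() {
  tibble::tribble(
    ~nutrient,         ~unit, ~min,  ~max,
    "protein_g",        "g",    56,    NA,
    "carbohydrate_g",   "g",   130,    NA,
    "fat_g",            "g",    NA,    95,
    "satfat_g",         "g",    NA,    28,
    "linoleic_g",       "g",    11,    NA,
    "linolenic_g",      "g",   1.3,    NA,
    "cholesterol_mg",   "mg",   NA,   320,
    "added_sugar_g",    "g",    NA,    85,
    "fiber_g",          "g",    25,    NA,
    "vitamin_a_ug",     "ug",  800,    NA,
    "vitamin_c_mg",     "mg",   80,    NA,
    "vitamin_e_mg",     "mg",   15,    NA,
    "thiamin_mg",       "mg",  1.1,    NA,
    "riboflavin_mg",    "mg",  1.2,    NA,
    "niacin_mg",        "mg",   15,    NA,
    "vitamin_b6_mg",    "mg",  1.4,    NA,
    "folate_ug",        "ug",  400,    NA,
    "vitamin_b12_ug",   "ug",  2.4,    NA,
    "calcium_mg",       "mg", 1000,    NA,
    "copper_mg",        "mg",  0.9,    NA,
    "iron_mg",          "mg",   12,    NA,
    "magnesium_mg",     "mg",  360,    NA,
    "phosphorus_mg",    "mg",  700,    NA,
    "selenium_ug",      "ug",   55,    NA,
    "zinc_mg",          "mg",   10,    NA)
}

#' Guideline levels for sodium and potassium
#'
#' The 2010 Dietary Guidelines context the package models: a general sodium
#' limit of 2300 mg/d, a stricter 1500 mg/d limit for at-risk groups, a
#' potassium goal of 4700 mg/d, and the implied Na:K mass ratio, computed as
#' `round(na_limit / k_goal, 2)`.
#'
#' @return list with `na_limit`, `na_limit_strict`, `k_goal`, `ratio`.
#' @export
default_guidelines <- function() {
  na_limit <- 2300
  k_goal <- 4700
  list(na_limit = na_limit, na_limit_strict = 1500, k_goal = k_goal,
       ratio = round(na_limit / k_goal, 2))
}
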