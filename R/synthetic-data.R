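# Seeded synthetic food-composition and intake-survey generator.
#
# The generator emulates the structural features the LP pipeline relies on:
# a 3-tier food taxonomy (categories nested in subgroups nested in 9 major
# groups), per-100 g nutrient profiles that are log-normal within each major
# group (positive and right-skewed, like real composition data), sodium
# concentrated in grain/mixed/prepared foods and potassium in
# fruits/vegetables/dairy, right-skewed consumption amounts, and a small
# configurable fraction of records that exercise each exclusion filter.

.dietlp_groups <- c("M20-30", "M31-50", "M51+", "F20-30", "F31-50", "F51+")

.dietlp_default_eer <- c("M20-30" = 2700, "M31-50" = 2400, "M51+" = 2000,
                         "F20-30" = 2100, "F31-50" = 1900, "F51+" = 1600)

#' Sex-age groups modeled by the package
#' @return character vector of the 6 group labels.
#' @export
sex_age_groups <- function() .dietlp_groups

# per-100 g medians by major food group: energy (kcal), sodium (mg),
# potassium (mg); sigma = log-sd of the lognormal draws
.major_templates <- function() {
  tibble::tribble(
    ~major_group_id, ~major_name,      ~energy, ~sodium, ~potassium,
    "G1", "grains",                       270,    450,       120,
    "G2", "vegetables",                    35,     45,       290,
    "G3", "fruits",                        55,      8,       200,
    "G4", "milk_dairy",                    85,     90,       150,
    "G5", "meat_beans",                   200,    380,       300,
    "G6", "fats_oils",                    550,    420,        60,
    "G7", "sweets_sugars",                380,    160,        90,
    "G8", "beverages",                     35,     12,        70,
    "G9", "mixed_dishes",                 170,    430,       180)
}

# subgroup counts per major group (sums to 39)
.subgroup_counts <- c(G1 = 6, G2 = 7, G3 = 4, G4 = 4, G5 = 7, G6 = 3,
                      G7 = 3, G8 = 3, G9 = 2)

# relative nutrient concentration (per kcal) by major group; rows follow
# .major_templates order. Values are stated once as the synthetic world's
# food-composition pattern: fiber/vitC sit in plants, calcium in dairy,
# B12/zinc/selenium in meat, vitamin E and the essential fatty acids in oils.
.nutrient_multipliers <- function() {
  m <- rbind(
    #          G1   G2   G3   G4   G5   G6   G7   G8   G9
    protein_g        = c(0.8, 0.8, 0.2, 1.5, 2.2, 0.2, 0.3, 0.3, 1.3),
    carbohydrate_g   = c(1.5, 1.2, 1.8, 0.9, 0.2, 0.1, 1.7, 1.5, 1.0),
    fat_g            = c(0.5, 0.3, 0.1, 1.2, 1.8, 3.0, 1.2, 0.1, 1.3),
    satfat_g         = c(0.4, 0.2, 0.1, 1.6, 1.7, 2.2, 1.5, 0.1, 1.3),
    linoleic_g       = c(0.8, 0.6, 0.2, 0.4, 1.2, 4.0, 0.6, 0.1, 1.1),
    linolenic_g      = c(0.7, 0.9, 0.3, 0.5, 1.1, 4.0, 0.5, 0.1, 1.0),
    cholesterol_mg   = c(0.05, 0.02, 0.02, 1.2, 2.5, 0.6, 0.5, 0.05, 1.5),
    fiber_g          = c(1.6, 2.5, 2.2, 0.05, 0.5, 0.1, 0.3, 0.2, 0.8),
    vitamin_a_ug     = c(0.3, 3.0, 1.2, 1.5, 0.8, 0.5, 0.2, 0.1, 0.8),
    vitamin_c_mg     = c(0.1, 2.5, 3.5, 0.3, 0.2, 0.05, 0.2, 1.0, 0.5),
    vitamin_e_mg     = c(0.6, 1.2, 0.8, 0.3, 0.8, 4.5, 0.4, 0.1, 0.9),
    thiamin_mg       = c(2.0, 1.0, 0.6, 0.7, 1.2, 0.1, 0.3, 0.2, 1.0),
    riboflavin_mg    = c(1.5, 0.9, 0.5, 2.0, 1.2, 0.1, 0.4, 0.3, 1.0),
    niacin_mg        = c(1.5, 0.8, 0.4, 0.5, 2.5, 0.1, 0.3, 0.3, 1.2),
    vitamin_b6_mg    = c(1.0, 1.2, 1.0, 0.6, 2.0, 0.1, 0.2, 0.3, 1.0),
    folate_ug        = c(2.2, 1.8, 0.8, 0.4, 0.8, 0.1, 0.3, 0.2, 0.9),
    vitamin_b12_ug   = c(0.8, 0.02, 0.02, 2.0, 3.0, 0.1, 0.3, 0.2, 1.3),
    calcium_mg       = c(0.8, 0.9, 0.4, 4.0, 0.5, 0.2, 0.4, 0.3, 1.0),
    copper_mg        = c(1.2, 1.1, 0.9, 0.3, 1.6, 0.3, 0.7, 0.5, 1.0),
    iron_mg          = c(2.2, 1.0, 0.4, 0.2, 1.8, 0.2, 0.5, 0.2, 1.2),
    magnesium_mg     = c(1.3, 1.5, 0.9, 0.9, 1.1, 0.2, 0.4, 0.6, 1.0),
    phosphorus_mg    = c(1.0, 0.8, 0.4, 2.2, 1.8, 0.3, 0.5, 0.4, 1.2),
    selenium_ug      = c(1.5, 0.4, 0.2, 0.8, 2.8, 0.3, 0.4, 0.2, 1.3),
    zinc_mg          = c(1.1, 0.7, 0.3, 1.4, 2.5, 0.2, 0.4, 0.2, 1.2))
  colnames(m) <- .major_templates()$major_group_id
  m
}

# solid fat / added sugar medians (g per 100 g) by major group
.sofas_templates <- function() {
  g <- .major_templates()$major_group_id
  list(solid_fat = setNames(c(3, 0.3, 0.1, 3.5, 6, 25, 10, 0.2, 6), g),
       added_sugar = setNames(c(4, 0.5, 1.5, 3, 0.5, 1, 40, 7, 3), g))
}

#' Default food taxonomy specification
#'
#' Three tiers: 9 major food groups (USDA-style: grains, vegetables, fruits,
#' milk and dairy, meat/poultry/fish/beans, fats and oils, sweets, beverages,
#' mixed dishes), 39 subgroups nested in them, and `n_categories` food
#' categories distributed over the subgroups.
#'
#' @param n_categories number of food categories (LP variables before
#'   group-specific pruning).
#' @return tibble with one row per category: `category_id`, `subgroup_id`,
#'   `major_group_id`.
#' @export
default_taxonomy <- function(n_categories = 110) {
  stopifnot(n_categories >= 39)
  majors <- rep(names(.subgroup_counts), .subgroup_counts)
  sub_ids <- sprintf("S%02d", seq_along(majors))
  # categories round-robin over subgroups so every subgroup is populated
  sub_of_cat <- sub_ids[(seq_len(n_categories) - 1L) %% length(sub_ids) + 1L]
  tibble::tibble(
    category_id = sprintf("C%03d", seq_len(n_categories)),
    subgroup_id = sub_of_cat,
    major_group_id = majors[match(sub_of_cat, sub_ids)])
}

.excluded_levels <- c("none", "baby_food", "alcohol", "supplement",
                      "chewing_gum", "low_energy_density")

#' Generate a synthetic food-composition database
#'
#' Draws per-100 g profiles from per-major-group log-normal templates in
#' which potassium is dense in fruits, vegetables and dairy and sodium is
#' dense in grain, mixed-dish and prepared foods. DRI-panel nutrients are
#' placed per 100 g with group-specific concentration multipliers (vitamin C
#' in produce, calcium in dairy, B12 in meat, ...), calibrated so ordinary
#' mixed diets land near nutrient adequacy — the property real intake
#' surveys show and the LP stages assume. A configurable fraction of
#' foods carries each exclusion flag; foods below 10 kcal/100 g are always
#' flagged `low_energy_density` (and only those).
#'
#' @param n_foods number of foods; must be at least the category count.
#' @param taxonomy category-level taxonomy, as from [default_taxonomy()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param excluded_rates named rates for `baby_food`, `alcohol`,
#'   `supplement`, `chewing_gum` flags.
#' @param low_energy_rate fraction of beverage-group foods redrawn as
#'   near-zero-energy (water/tea-like), which the 10 kcal rule then flags.
#' @return tibble of foods, one row per `food_code`.
#' @export
generate_food_database <- function(n_foods = 450,
                                   taxonomy = default_taxonomy(),
                                   seed = 1L,
                                   excluded_rates = c(baby_food = 0.02,
                                                      alcohol = 0.03,
                                                      supplement = 0.01,
                                                      chewing_gum = 0.005),
                                   low_energy_rate = 0.30) {
  n_cat <- nrow(taxonomy)
  if (n_foods < n_cat) {
    stop("taxonomy_spec inconsistent: ", n_cat, " categories exceed n_foods = ",
         n_foods)
  }
  set.seed(as.integer(seed))
  tmpl <- .major_templates()

  # every category gets >= 1 food; the rest are spread at random
  cat_of_food <- c(taxonomy$category_id,
                   sample(taxonomy$category_id, n_foods - n_cat, replace = TRUE))
  idx <- match(cat_of_food, taxonomy$category_id)
  major <- taxonomy$major_group_id[idx]
  ti <- match(major, tmpl$major_group_id)

  # draws are mean-preserving log-normals (template value = group mean);
  # sodium's log-sd of 1.0 encodes the large within-group spread of real
  # composition data (raw vs brined/processed items) -- the LP's ability to
  # substitute low-sodium members of each group depends on it
  ln <- function(med, sigma) med * exp(rnorm(n_foods, 0, sigma) - sigma^2 / 2)
  energy <- ln(tmpl$energy[ti], 0.35)
  sodium <- ln(tmpl$sodium[ti], 1.00)
  potassium <- ln(tmpl$potassium[ti], 0.50)

  # some beverages are water/tea-like: energy density ~ U(0, 9) kcal/100 g
  low <- major == "G8" & runif(n_foods) < low_energy_rate
  energy[low] <- runif(sum(low), 0, 9)

  foods <- tibble::tibble(
    food_code = sprintf("F%05d", seq_len(n_foods)),
    name = paste0(tmpl$major_name[ti], "_food_", seq_len(n_foods)),
    category_id = cat_of_food,
    subgroup_id = taxonomy$subgroup_id[idx],
    major_group_id = major,
    popularity = exp(rnorm(n_foods, 0, 1)),
    energy_kcal = energy,
    sodium_mg = sodium,
    potassium_mg = potassium)

  # DRI-panel nutrient densities are per 100 g against a 1500 g/d reference
  # diet, scaled by the group concentration multipliers: micronutrients sit
  # where they sit in real food (vitamin C in produce, calcium in dairy)
  # regardless of energy density. Adequacy factor 1.6 for minimum-type
  # nutrients (ordinary mixed diets overshoot minima), 0.6 of the cap for
  # maximum-type ones. Because intake scales with mass, low-energy groups
  # eat less of everything and sit closer to the adequacy floor.
  dri <- default_dri_table()
  mult <- .nutrient_multipliers()
  for (nut in rownames(mult)) {
    row <- dri[dri$nutrient == nut, ]
    base <- if (!is.na(row$min)) 1.6 * row$min else 0.6 * row$max
    med <- base * mult[nut, ti] / 15
    foods[[nut]] <- med * exp(rnorm(n_foods, 0, 0.35) - 0.35^2 / 2)
  }
  sofas <- .sofas_templates()
  foods$solid_fat_g <- ln(sofas$solid_fat[ti], 0.5)
  foods$added_sugar_g <- ln(sofas$added_sugar[ti], 0.5)

  # MyPyramid equivalents per 100 g
  pz <- function(med, sigma = 0.3) med[ti] * exp(rnorm(n_foods, 0, sigma))
  g <- tmpl$major_group_id
  foods$pyr_fruit_cup <- pz(setNames(c(0, 0, 0.60, 0, 0, 0, 0, 0, 0.08), g))
  foods$pyr_veg_cup <- pz(setNames(c(0, 0.62, 0, 0, 0, 0, 0, 0, 0.15), g))
  grain_tot <- pz(setNames(c(1.1, 0, 0, 0, 0, 0, 0.4, 0, 0.5), g))
  whole_dom <- runif(n_foods) < ifelse(major == "G1", 0.25, 0.10)
  whole_frac <- ifelse(whole_dom, 0.75, 0.05) * runif(n_foods, 0.8, 1.2)
  whole_frac <- pmin(whole_frac, 1)
  foods$pyr_grain_total_oz <- grain_tot
  foods$pyr_grain_whole_oz <- grain_tot * whole_frac
  foods$pyr_grain_refined_oz <- grain_tot * (1 - whole_frac)
  foods$pyr_meat_oz <- pz(setNames(c(0, 0, 0, 0, 2.8, 0, 0, 0, 0.8), g))
  foods$pyr_milk_cup <- pz(setNames(c(0, 0, 0, 0.38, 0, 0, 0.05, 0, 0.08), g))
  foods$pyr_oils_g <- pz(setNames(c(1, 0.2, 0, 0.3, 1, 40, 2, 0, 2), g))
  foods$pyr_sofas_kcal <- 9 * foods$solid_fat_g + 4 * foods$added_sugar_g

  # exclusion flags: explicit classes first, then the energy-density rule
  # overrides so that excluded_class == low_energy_density iff < 10 kcal/100 g
  cls <- rep("none", n_foods)
  u <- runif(n_foods)
  lo <- 0
  for (k in names(excluded_rates)) {
    hi <- lo + excluded_rates[[k]]
    cls[u >= lo & u < hi] <- k
    lo <- hi
  }
  cls[foods$energy_kcal < 10] <- "low_energy_density"
  foods$excluded_class <- factor(cls, levels = .excluded_levels)
  foods
}

#' Generate a synthetic one-day intake survey
#'
#' Each individual samples 20-60 distinct foods (popularity-weighted) with
#' log-normal gram amounts, rescaled so daily energy hits a target drawn
#' around the group's energy requirement (log-normal, CV ~ 25%). A
#' configurable fraction of individuals is pregnant (women only) or reports
#' under 600 kcal/d, to exercise the downstream filters.
#'
#' @param foods foods table from [generate_food_database()].
#' @param group_sizes named counts per sex-age group; defaults to a 4295-
#'   person survey split evenly over the 6 groups.
#' @param seed integer seed.
#' @param eer named energy requirements (kcal/d) per group.
#' @param dri DRI table attached to every group profile.
#' @param pregnant_rate,low_energy_rate rates of the two filter-exercising
#'   conditions.
#' @param foods_per_person integer range of distinct foods per individual.
#' @return list with `intakes` (tibble: individual_id, sex_age_group,
#'   pregnant, food_code, grams_per_day) and `profiles` (list of group
#'   profiles: group, eer_kcal, dri, n_individuals).
#' @export
generate_intake_survey <- function(foods,
                                   group_sizes = NULL,
                                   seed = 1L,
                                   eer = .dietlp_default_eer,
                                   dri = default_dri_table(),
                                   pregnant_rate = 0.02,
                                   low_energy_rate = 0.02,
                                   foods_per_person = c(20L, 60L)) {
  if (is.null(foods) || nrow(foods) == 0) stop("foods table is empty")
  if (is.null(group_sizes)) {
    group_sizes <- setNames(c(716, 716, 716, 716, 716, 715), .dietlp_groups)
  }
  missing_g <- setdiff(.dietlp_groups, names(group_sizes))
  if (length(missing_g)) {
    stop("group_sizes must cover all 6 groups; missing: ",
         paste(missing_g, collapse = ", "))
  }
  set.seed(as.integer(seed))
  per_g_energy <- foods$energy_kcal / 100

  rows <- vector("list", sum(unlist(group_sizes[.dietlp_groups])))
  ridx <- 0L
  iid <- 0L
  for (g in .dietlp_groups) {
    ng <- group_sizes[[g]]
    if (ng == 0) next
    is_female <- startsWith(g, "F")
    for (i in seq_len(ng)) {
      iid <- iid + 1L
      nf <- sample(seq(foods_per_person[1], foods_per_person[2]), 1L)
      nf <- min(nf, nrow(foods))
      pick <- sample.int(nrow(foods), nf, prob = foods$popularity)
      grams <- rlnorm(nf, log(60), 0.8)
      target <- eer[[g]] * exp(rnorm(1, 0, 0.25) - 0.25^2 / 2)
      if (runif(1) < low_energy_rate) target <- runif(1, 300, 590)
      e_raw <- sum(grams * per_g_energy[pick])
      if (e_raw > 0) grams <- grams * target / e_raw
      ridx <- ridx + 1L
      rows[[ridx]] <- tibble::tibble(
        individual_id = sprintf("I%05d", iid),
        sex_age_group = g,
        pregnant = is_female && runif(1) < pregnant_rate,
        food_code = foods$food_code[pick],
        grams_per_day = grams)
    }
  }
  intakes <- if (ridx > 0) dplyr::bind_rows(rows[seq_len(ridx)]) else
    tibble::tibble(individual_id = character(), sex_age_group = character(),
                   pregnant = logical(), food_code = character(),
                   grams_per_day = numeric())

  profiles <- lapply(.dietlp_groups, function(g) {
    new_group_profile(g, eer[[g]], dri, n_individuals = group_sizes[[g]])
  })
  names(profiles) <- .dietlp_groups
  list(intakes = intakes, profiles = profiles)
}

#' Construct a group profile
#'
#' @param group sex-age group label.
#' @param eer_kcal daily energy requirement (kcal), the LP energy equality.
#' @param dri DRI table (`nutrient`, `unit`, `min`, `max`).
#' @param n_individuals surveyed individuals in the group.
#' @return object of class `group_profile`.
#' @export
new_group_profile <- function(group, eer_kcal, dri = default_dri_table(),
                              n_individuals = 0L) {
  stopifnot(eer_kcal > 0)
  if (nrow(dri) && any(!is.na(dri$min) & !is.na(dri$max) & dri$min > dri$max)) {
    stop("DRI table has min > max")
  }
  structure(list(group = group, eer_kcal = eer_kcal, dri = dri,
                 n_individuals = n_individuals),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat("<group_profile> ", x$group, ": EER ", x$eer_kcal, " kcal/d, ",
      nrow(x$dri), " DRI rows, n = ", x$n_individuals, "\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic survey as plain CSV + YAML
#'
#' `foods.csv`, `intakes.csv`, `profiles.csv`, `dri.csv` and a `config.yaml`
#' echo of the generator arguments.
#'
#' @param survey list with `foods`, `intakes`, `profiles` (and optionally the
#'   generator `config`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (for `write_survey`); the survey list (for
#'   `read_survey`).
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(survey$foods, file.path(dir, "foods.csv"), row.names = FALSE)
  write.csv(survey$intakes, file.path(dir, "intakes.csv"), row.names = FALSE)
  prof <- dplyr::bind_rows(lapply(survey$profiles, function(p) {
    tibble::tibble(group = p$group, eer_kcal = p$eer_kcal,
                   n_individuals = p$n_individuals)
  }))
  write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  write.csv(survey$profiles[[1]]$dri, file.path(dir, "dri.csv"),
            row.names = FALSE)
  if (!is.null(survey$config)) {
    yaml::write_yaml(survey$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  foods <- tibble::as_tibble(read.csv(file.path(dir, "foods.csv")))
  foods$excluded_class <- factor(foods$excluded_class,
                                 levels = .excluded_levels)
  intakes <- tibble::as_tibble(read.csv(file.path(dir, "intakes.csv")))
  prof <- read.csv(file.path(dir, "profiles.csv"))
  dri <- tibble::as_tibble(read.csv(file.path(dir, "dri.csv")))
  profiles <- lapply(seq_len(nrow(prof)), function(i) {
    new_group_profile(prof$group[i], prof$eer_kcal[i], dri,
                      prof$n_individuals[i])
  })
  names(profiles) <- prof$group
  list(foods = foods, intakes = intakes, profiles = profiles)
}
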