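# Hand-solvable fixtures. All numbers are part of the fixture registry and
# are relied on by closed-form tests:
#
# toy2 — two categories, energy equality 2000 kcal/d, no nutrient rows.
#   F1 per 100 g: 50 kcal,  20 mg Na, 300 mg K
#   F2 per 100 g: 250 kcal, 500 mg Na, 100 mg K
#   The feasible set is the segment x1 = 4000 - 5*x2 (g/d), x2 in [0, 800]:
#     Na = 800 + 4*x2            => feasible Na interval [800, 4000] mg/d
#     K  = 12000 - 14*x2         => K = 12000 - 3.5*(Na - 800)
#   Observed diet: one individual eating F1 2000 g/d + F2 400 g/d
#   (energy exactly 2000 kcal; Na 2400 mg, K 6400 mg).
#
# toy3 — toy2 plus F3 (150 kcal, 150 mg Na, 500 mg K, 4 g fiber per 100 g)
#   and a fiber >= 30 g/d DRI row (F1 fiber 1, F2 fiber 0.5 g/100 g).
#   Observed diet: F1 1000 g + F2 300 g + F3 500 g (energy 2000 kcal,
#   fiber 31.5 g — feasible).

.toy_registry <- c("toy2", "toy3")

#' Tiny hand-solvable fixtures
#'
#' Returns a fully assembled micro-world: a foods table, a one-person intake
#' table, a group profile (EER 2000 kcal/d), the aggregated category table
#' and the observed pattern. Every number is documented in the fixture
#' registry (see the source of this file) so closed-form expectations can be
#' derived by hand.
#'
#' @param name fixture id, one of `"toy2"`, `"toy3"`.
#' @return list with `foods`, `intakes`, `profile`, `categories`, `observed`.
#' @export
make_toy_fixture <- function(name) {
  if (!name %in% .toy_registry) {
    stop("unknown fixture '", name, "'; known fixtures: ",
         paste(.toy_registry, collapse = ", "))
  }
  base <- tibble::tibble(
    food_code = c("F1", "F2"),
    name = c("lean_staple", "dense_salty"),
    category_id = c("C001", "C002"),
    subgroup_id = c("S01", "S02"),
    major_group_id = c("G2", "G1"),
    popularity = 1,
    energy_kcal = c(50, 250),
    sodium_mg = c(20, 500),
    potassium_mg = c(300, 100),
    excluded_class = factor("none", levels = .excluded_levels))
  if (name == "toy2") {
    foods <- base
    foods$fiber_g <- 0
    dri <- default_dri_table()[0, ]
    grams <- c(F1 = 2000, F2 = 400)
  } else {
    foods <- dplyr::bind_rows(base, tibble::tibble(
      food_code = "F3", name = "fibrous_mixed", category_id = "C003",
      subgroup_id = "S03", major_group_id = "G9", popularity = 1,
      energy_kcal = 150, sodium_mg = 150, potassium_mg = 500,
      excluded_class = factor("none", levels = .excluded_levels)))
    foods$fiber_g <- c(1, 0.5, 4)
    dri <- tibble::tibble(nutrient = "fiber_g", unit = "g", min = 30,
                          max = NA_real_)
    grams <- c(F1 = 1000, F2 = 300, F3 = 500)
  }
  profile <- new_group_profile("M51+", eer_kcal = 2000, dri = dri,
                               n_individuals = 1L)
  intakes <- tibble::tibble(
    individual_id = "I1",
    sex_age_group = profile$group,
    pregnant = FALSE,
    food_code = names(grams),
    grams_per_day = unname(grams))
  categories <- aggregate_categories(intakes, foods, profile$group)
  observed <- observed_pattern(intakes, categories, profile$group)
  list(foods = foods, intakes = intakes, profile = profile,
       categories = categories, observed = observed)
}
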