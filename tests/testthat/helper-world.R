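# Shared synthetic world for the suite: 120-category taxonomy, 450 foods,
# 150 individuals per group, seed 3. Built once per test run.

.world_cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.world_cache$world)) {
    foods <- generate_food_database(n_foods = 450,
                                    taxonomy = default_taxonomy(120),
                                    seed = 3)
    sizes <- setNames(rep(150L, 6), sex_age_groups())
    sv <- generate_intake_survey(foods, group_sizes = sizes, seed = 3)
    intakes <- filter_individuals(sv$intakes, foods)
    .world_cache$world <- list(foods = foods, survey = sv, intakes = intakes)
  }
  .world_cache$world
}

# aggregated pieces for one group, memoized
test_group <- function(g) {
  key <- paste0("grp_", g)
  if (is.null(.world_cache[[key]])) {
    w <- test_world()
    cats <- aggregate_categories(w$intakes, w$foods, g)
    bounds <- consumption_percentiles(w$intakes, w$foods, g)
    obs <- observed_pattern(w$intakes, cats, g)
    cs <- build_constraint_set(w$survey$profiles[[g]], bounds)
    .world_cache[[key]] <- list(categories = cats, bounds = bounds,
                                observed = obs, cs = cs,
                                profile = w$survey$profiles[[g]])
  }
  .world_cache[[key]]
}
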