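# The two objectives against closed forms and the brute-force grid oracle.

test_that("toy2 max-K solutions match closed forms", {
  fx <- make_toy_fixture("toy2")
  cs <- build_constraint_set(fx$profile)
  # energy equality only: K* = 12000 at x = (4000, 0)
  sol <- solve_max_potassium(fx$categories, cs)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 12000, tolerance = 1e-9)
  expect_equal(unname(sol$amounts), c(4000, 0), tolerance = 1e-8)
  # with ratio 0.49 the feasible set shrinks to one point: from
  # Na = 800 + 4 x2 and K = 12000 - 14 x2 (x2 in g/d), Na = 0.49 K gives
  # x2 = 5080/10.86 g -> K* ~ 5451.2, Na* ~ 2671.1
  sol49 <- solve_max_potassium(fx$categories,
                               apply_ratio_constraint(cs, 0.49))
  expect_equal(sol49$totals[["potassium_mg"]], 12000 - 14 * 5080 / 10.86,
               tolerance = 1e-6)
  expect_equal(sol49$totals[["sodium_mg"]],
               0.49 * sol49$totals[["potassium_mg"]], tolerance = 1e-6)
})

test_that("single-category energy equality forces the full solution", {
  fx <- make_toy_fixture("toy2")
  one <- fx$categories[1, ]
  cs <- build_constraint_set(fx$profile)
  sol <- solve_max_potassium(one, cs)
  expect_equal(unname(sol$amounts), 4000)      # 2000 kcal / 0.5 kcal/g
  expect_equal(sol$totals[["potassium_mg"]], 12000)
})

test_that("a zero-energy potassium source makes max-K unbounded", {
  fx <- make_toy_fixture("toy2")
  cats <- dplyr::bind_rows(fx$categories,
                           dplyr::mutate(fx$categories[1, ],
                                         category_id = "C999",
                                         energy_kcal = 0, sodium_mg = 0))
  sol <- solve_max_potassium(cats, build_constraint_set(fx$profile))
  expect_identical(sol$status, "unbounded")
})

test_that("min-deviation returns the observed pattern when it is feasible", {
  fx <- make_toy_fixture("toy3")
  cs <- build_constraint_set(fx$profile)
  sol <- solve_min_deviation(fx$categories, cs, fx$observed)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$deviation_score, 0, tolerance = 1e-9)
  expect_equal(sol$amounts[names(fx$observed$amounts)], fx$observed$amounts,
               tolerance = 1e-9)
})

test_that("min-deviation projects onto the ratio line (vs grid oracle)", {
  fx <- make_toy_fixture("toy2")
  cs <- apply_ratio_constraint(build_constraint_set(fx$profile), 0.49)
  sol <- solve_min_deviation(fx$categories, cs, fx$observed)
  expect_identical(sol$status, "optimal")
  expect_gt(sol$deviation_score, 0)  # observed has ratio 2400/6400 = 0.375
  oracle <- brute_force_optimum(fx$categories, cs, "min_deviation",
                                grid_step = 0.01, observed = fx$observed)
  expect_equal(sol$deviation_score, oracle$value,
               tolerance = 0.01 * max(1, oracle$value))
  # deviation equals sum of weighted absolute shifts from observed
  obs <- fx$observed$amounts[names(sol$amounts)]
  wts <- 1 / obs
  expect_equal(sol$deviation_score, sum(wts * abs(sol$amounts - obs)),
               tolerance = 1e-9)
})

test_that("min-deviation faithfully reports infeasibility", {
  fx <- make_toy_fixture("toy2")
  cats <- fx$categories
  cats$energy_kcal <- 0
  sol <- solve_min_deviation(cats, build_constraint_set(fx$profile),
                             fx$observed)
  expect_identical(sol$status, "infeasible")
  expect_null(sol$amounts)
})

test_that("brute-force oracle agrees with the simplex on both fixtures", {
  for (nm in c("toy2", "toy3")) {
    fx <- make_toy_fixture(nm)
    cs <- build_constraint_set(fx$profile)
    lp <- solve_max_potassium(fx$categories, cs)
    bf <- brute_force_optimum(fx$categories, cs, "max_potassium",
                              grid_step = 0.01)
    expect_identical(bf$status, "optimal")
    expect_lte(bf$value, lp$objective_value + 1e-6)
    expect_equal(bf$value, lp$objective_value,
                 tolerance = 0.01 * lp$objective_value)
  }
})

test_that("brute-force oracle honors its guard rails", {
  grp <- test_group("M51+")
  expect_error(brute_force_optimum(grp$categories, grp$cs, "max_potassium"),
               "at most 3")
  fx <- make_toy_fixture("toy2")
  inf <- brute_force_optimum(fx$categories,
                             fix_sodium(build_constraint_set(fx$profile), 0),
                             "max_potassium", grid_step = 0.05)
  expect_identical(inf$status, "infeasible")
  # constant objective: all-zero potassium -> any feasible point, value 0
  cats0 <- fx$categories
  cats0$potassium_mg <- 0
  const <- brute_force_optimum(cats0, build_constraint_set(fx$profile),
                               "max_potassium", grid_step = 0.05)
  expect_identical(const$status, "optimal")
  expect_equal(const$value, 0)
})

test_that("objective values are invariant to profile/amount rescaling", {
  # multiply per-100 g vectors by c, divide amounts by c: totals unchanged
  fx <- make_toy_fixture("toy2")
  cs <- build_constraint_set(fx$profile)
  base <- solve_max_potassium(fx$categories, cs)
  cc <- 4
  scaled <- fx$categories
  for (col in profile_cols(scaled)) scaled[[col]] <- scaled[[col]] * cc
  sol <- solve_max_potassium(scaled, cs)
  expect_equal(sol$objective_value, base$objective_value, tolerance = 1e-9)
  expect_equal(unname(sol$amounts), unname(base$amounts) / cc,
               tolerance = 1e-8)
})

test_that("deviation score is zero iff the observed pattern is feasible", {
  grp <- test_group("F20-30")
  obs <- grp$observed
  # direction 1: loose constraints containing the observed point -> zero
  p <- grp$profile
  p$dri <- p$dri[0, ]
  cs_loose <- build_constraint_set(p, NULL)
  cs_loose$energy_kcal <- unname(obs$totals[["energy_kcal"]])
  sol <- solve_min_deviation(grp$categories, cs_loose, obs)
  expect_equal(sol$deviation_score, 0, tolerance = 1e-8)
  # direction 2: observed violates the EER equality -> strictly positive
  sol2 <- solve_min_deviation(grp$categories, grp$cs, obs)
  mat <- as_lp_matrices(grp$cs, grp$categories)
  obs_feasible <- lp_point_feasible(unname(obs$amounts[mat$vars]),
                                    mat$A_ub, mat$b_ub, mat$A_eq, mat$b_eq)
  expect_false(obs_feasible)
  expect_gt(sol2$deviation_score, 1e-6)
})
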