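# Constraint-set construction, the ratio and fixed-sodium devices, and the
# lossless lowering to matrix form.

test_that("constraint set carries energy, DRI rows and percentile bounds", {
  grp <- test_group("M20-30")
  cs <- grp$cs
  expect_equal(cs$energy_kcal, 2700)
  # one row per non-NA DRI bound
  dri <- grp$profile$dri
  expect_identical(nrow(cs$nutrient_rows),
                   sum(!is.na(dri$min)) + sum(!is.na(dri$max)))
  # majors: [p10, p90]; subgroups/categories: [0, p75]
  mj <- cs$group_bounds[cs$group_bounds$tier == "major", ]
  b <- grp$bounds[grp$bounds$tier == "major", ]
  expect_equal(mj$lower, b$p10)
  expect_equal(mj$upper, b$p90)
  sg <- cs$group_bounds[cs$group_bounds$tier == "subgroup", ]
  expect_true(all(sg$lower == 0))

  # vitamin E override resets the minimum to 13 mg/d
  cs13 <- build_constraint_set(grp$profile, grp$bounds,
                               options = list(vitamin_e_min = 13))
  row <- cs13$nutrient_rows[cs13$nutrient_rows$nutrient == "vitamin_e_mg" &
                              cs13$nutrient_rows$sense == ">=", ]
  expect_equal(row$bound, 13)

  # empty DRI table: only energy + group bounds
  p0 <- grp$profile
  p0$dri <- p0$dri[0, ]
  cs0 <- build_constraint_set(p0, grp$bounds)
  expect_identical(nrow(cs0$nutrient_rows), 0L)

  # toy2: exactly one equality row (energy), zero nutrient rows
  fx <- make_toy_fixture("toy2")
  cst <- build_constraint_set(fx$profile)
  mat <- as_lp_matrices(cst, fx$categories)
  expect_identical(nrow(mat$A_eq), 1L)
  expect_identical(nrow(cst$nutrient_rows), 0L)

  # malformed DRI rejected
  pbad <- grp$profile
  pbad$dri$min[3] <- 1e6
  pbad$dri$max[3] <- 1
  expect_error(build_constraint_set(pbad, grp$bounds), "min > max")
})

test_that("ratio constraint is the equality Na - r K = 0", {
  fx <- make_toy_fixture("toy2")
  cs <- apply_ratio_constraint(build_constraint_set(fx$profile), 2300 / 4700)
  # a pattern with exactly Na 2300 / K 4700 satisfies the row exactly
  mat <- as_lp_matrices(cs, fx$categories)
  ratio_row <- mat$A_eq[2, ]
  # solve for the pattern with those totals: 0.2x1+5x2=2300, 3x1+x2=4700
  x <- solve(rbind(c(0.2, 5), c(3, 1)), c(2300, 4700))
  expect_equal(sum(ratio_row * x), 0, tolerance = 1e-9)
  # r = 1 satisfied by Na == K patterns
  cs1 <- apply_ratio_constraint(build_constraint_set(fx$profile), 1)
  m1 <- as_lp_matrices(cs1, fx$categories)
  xeq <- solve(rbind(c(0.2, 5), c(3, 1)), c(3000, 3000))
  expect_equal(sum(m1$A_eq[2, ] * xeq), 0, tolerance = 1e-9)
  expect_error(apply_ratio_constraint(build_constraint_set(fx$profile), -1),
               "positive")
  # solver output substituted into the raw bilinear check
  sol <- solve_max_potassium(fx$categories,
                             apply_ratio_constraint(build_constraint_set(fx$profile),
                                                    0.49))
  a <- unname(sol$amounts)
  na_tot <- 0.2 * a[1] + 5 * a[2]
  k_tot <- 3 * a[1] + 1 * a[2]
  expect_equal(na_tot, 0.49 * k_tot, tolerance = 1e-6)
})

test_that("fixing sodium pins the level, rejects negatives, is idempotent", {
  fx <- make_toy_fixture("toy2")
  cs <- build_constraint_set(fx$profile)
  sol <- solve_max_potassium(fx$categories, fix_sodium(cs, 800))
  # closed form: x2 = 0, x1 = 4000 g/d, K = 12000 mg
  expect_equal(unname(sol$amounts), c(4000, 0), tolerance = 1e-8)
  expect_equal(sol$totals[["potassium_mg"]], 12000, tolerance = 1e-8)

  s0 <- solve_max_potassium(fx$categories, fix_sodium(cs, 0))
  expect_identical(s0$status, "infeasible")  # both foods carry sodium

  once <- fix_sodium(cs, 1234)
  twice <- fix_sodium(once, 1234)
  expect_identical(as_lp_matrices(once, fx$categories),
                   as_lp_matrices(twice, fx$categories))
  expect_error(fix_sodium(cs, -5), ">= 0")
})

test_that("matrix lowering round-trips through row provenance", {
  grp <- test_group("F51+")
  cs <- fix_sodium(apply_ratio_constraint(grp$cs, 0.49), 1500)
  mat <- as_lp_matrices(cs, grp$categories)
  back <- constraint_set_from_matrices(mat)
  expect_equal(back$energy_kcal, cs$energy_kcal)
  expect_equal(back$ratio, cs$ratio)
  expect_equal(back$fixed_sodium_mg, cs$fixed_sodium_mg)
  expect_equal(dplyr::arrange(back$nutrient_rows, .data$nutrient, .data$sense),
               dplyr::arrange(cs$nutrient_rows, .data$nutrient, .data$sense))
  gb0 <- dplyr::arrange(cs$group_bounds, .data$node_id)
  gb1 <- dplyr::arrange(back$group_bounds, .data$node_id)
  # nodes without members among this group's categories drop out in matrix
  # form; compare on the shared nodes
  shared <- intersect(gb0$node_id, gb1$node_id)
  expect_equal(gb1[gb1$node_id %in% shared, c("node_id", "tier", "upper")],
               gb0[gb0$node_id %in% shared, c("node_id", "tier", "upper")])
  # rebuilt matrices are identical
  mat2 <- as_lp_matrices(back, grp$categories)
  expect_equal(mat2$A_eq, mat$A_eq)
  expect_equal(mat2$b_eq, mat$b_eq)
  expect_equal(sort(mat2$b_ub), sort(mat$b_ub))
})

test_that("constraint sets survive a YAML round-trip", {
  grp <- test_group("M51+")
  cs <- apply_ratio_constraint(grp$cs, 0.49)
  f <- withr::local_tempfile(fileext = ".yaml")
  constraint_set_to_yaml(cs, f)
  back <- constraint_set_from_yaml(f)
  expect_equal(back$energy_kcal, cs$energy_kcal)
  expect_equal(back$ratio, cs$ratio)
  expect_equal(as.data.frame(back$nutrient_rows),
               as.data.frame(cs$nutrient_rows))
  expect_equal(as.data.frame(back$group_bounds),
               as.data.frame(cs$group_bounds))
})

test_that("adding a constraint never enlarges the feasible set", {
  fx <- make_toy_fixture("toy2")
  cs <- build_constraint_set(fx$profile)
  # grid sample of the energy plane
  x2 <- seq(0, 800, by = 8)
  pts <- cbind(4000 - 5 * x2, x2)
  feas <- function(cs) {
    mat <- as_lp_matrices(cs, fx$categories)
    apply(pts, 1, function(x) {
      lp_point_feasible(x, mat$A_ub, mat$b_ub, mat$A_eq, mat$b_eq,
                        tol = 1e-9)
    })
  }
  base <- feas(cs)
  for (tighter in list(fix_sodium(cs, 2300),
                       apply_ratio_constraint(cs, 0.49))) {
    after <- feas(tighter)
    expect_true(all(!after | base))  # after => base
  }
})

test_that("MPS export writes a parseable deck", {
  fx <- make_toy_fixture("toy2")
  mat <- as_lp_matrices(build_constraint_set(fx$profile), fx$categories)
  f <- withr::local_tempfile(fileext = ".mps")
  write_mps(mat, setNames(fx$categories$potassium_mg / 100,
                          fx$categories$category_id), f)
  txt <- readLines(f)
  expect_identical(txt[1], "NAME          DIETLP")
  expect_true(any(grepl("^RHS", txt)))
  expect_identical(txt[length(txt)], "ENDATA")
})
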