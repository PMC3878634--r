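# Mapping the feasible (sodium, potassium) region of a group by sweeping a
# fixed daily sodium level, and guideline-compatibility queries against it.

#' Potassium-maximal pattern on the Na:K ratio line
#'
#' Adds the ratio equality to the constraint set and maximizes potassium:
#' the anchor point of the feasibility analysis, and the sweep's default
#' starting sodium level.
#'
#' @param categories category table.
#' @param cs a `constraint_set` without a fixed-sodium equality.
#' @param r Na:K mass ratio.
#' @return list with `status`, and when optimal `sodium_mg`, `potassium_mg`
#'   and the full `solution`.
#' @export
max_k_at_ratio <- function(categories, cs, r = default_guidelines()$ratio) {
  if (!is.null(cs$fixed_sodium_mg)) {
    stop("constraint set already fixes sodium; remove it before the ratio run")
  }
  sol <- solve_max_potassium(categories, apply_ratio_constraint(cs, r))
  if (sol$status != "optimal") {
    return(list(status = sol$status))
  }
  list(status = "optimal",
       sodium_mg = sol$totals[["sodium_mg"]],
       potassium_mg = sol$totals[["potassium_mg"]],
       solution = sol)
}

#' Sweep fixed sodium to map the feasible (Na, K) region
#'
#' With the ratio constraint removed, fixes daily sodium and solves a max-K
#' and a min-K LP at each level: downward from `start_mg` in `step_mg`
#' decrements until the model first turns infeasible, and upward likewise,
#' so both boundaries of the sodium interval are located. The min-K solve
#' closes the lower edge of the plotted region; the projection of the LP
#' polytope onto (Na, K) is convex, so the feasible grid points form a
#' contiguous interval and `k_min <= k_max` everywhere. If `start_mg` itself
#' is infeasible the sweep first relocates to the highest feasible grid
#' level (an LP maximizing sodium finds it), or returns an empty region.
#'
#' @param categories category table.
#' @param cs a `constraint_set`; any ratio constraint is dropped, as the
#'   sweep replaces it.
#' @param start_mg starting sodium level, mg/d.
#' @param step_mg grid step, mg (default 100 = 0.1 g).
#' @param scenario tag stored on the region.
#' @return object of class `feasibility_region`.
#' @export
sweep_sodium <- function(categories, cs, start_mg, step_mg = 100,
                         scenario = "baseline") {
  stopifnot(start_mg >= 0, step_mg > 0)
  cs$ratio <- NULL
  cs$ratio_sense <- NULL
  cs$fixed_sodium_mg <- NULL

  # lower once; only the fixed-sodium right-hand side changes along the grid
  mat <- as_lp_matrices(cs, categories)
  na_obj <- categories$sodium_mg / 100
  k_obj <- categories$potassium_mg / 100
  A_eq_s <- rbind(mat$A_eq, na_obj)

  solve_at <- function(s) {
    b_eq_s <- c(mat$b_eq, s)
    kmax <- solve_lp(k_obj, A_ub = mat$A_ub, b_ub = mat$b_ub,
                     A_eq = A_eq_s, b_eq = b_eq_s, maximize = TRUE)
    if (kmax$status != "optimal") return(NULL)
    kmin <- solve_lp(k_obj, A_ub = mat$A_ub, b_ub = mat$b_ub,
                     A_eq = A_eq_s, b_eq = b_eq_s, maximize = FALSE)
    c(k_min = kmin$value, k_max = kmax$value)
  }

  first <- solve_at(start_mg)
  if (is.null(first)) {
    # relocate: highest feasible grid level at or below max attainable Na
    hi <- solve_lp(na_obj, A_ub = mat$A_ub, b_ub = mat$b_ub,
                   A_eq = mat$A_eq, b_eq = mat$b_eq, maximize = TRUE)
    if (hi$status != "optimal") {
      return(.new_region(cs$group, scenario, step_mg, NULL))
    }
    k <- floor((hi$value - start_mg) / step_mg)
    start2 <- start_mg + k * step_mg
    found <- NULL
    while (start2 >= 0) {
      found <- solve_at(start2)
      if (!is.null(found)) break
      start2 <- start2 - step_mg
    }
    if (is.null(found)) {
      return(.new_region(cs$group, scenario, step_mg, NULL))
    }
    start_mg <- start2
    first <- found
  }

  rows <- list(tibble::tibble(sodium_mg = start_mg, k_min = first[["k_min"]],
                              k_max = first[["k_max"]], feasible = TRUE))
  s <- start_mg - step_mg
  while (s >= 0) {
    r <- solve_at(s)
    if (is.null(r)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sodium_mg = s, k_min = NA_real_, k_max = NA_real_, feasible = FALSE)
      break
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sodium_mg = s, k_min = r[["k_min"]], k_max = r[["k_max"]],
      feasible = TRUE)
    s <- s - step_mg
  }
  s <- start_mg + step_mg
  repeat {
    r <- solve_at(s)
    if (is.null(r)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sodium_mg = s, k_min = NA_real_, k_max = NA_real_, feasible = FALSE)
      break
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sodium_mg = s, k_min = r[["k_min"]], k_max = r[["k_max"]],
      feasible = TRUE)
    s <- s + step_mg
  }
  grid <- dplyr::arrange(dplyr::bind_rows(rows), .data$sodium_mg)
  .new_region(cs$group, scenario, step_mg, grid)
}

.new_region <- function(group, scenario, step, grid) {
  if (is.null(grid)) {
    grid <- tibble::tibble(sodium_mg = numeric(), k_min = numeric(),
                           k_max = numeric(), feasible = logical())
  }
  feas <- grid$sodium_mg[grid$feasible]
  na_interval <- if (length(feas)) range(feas) else c(NA_real_, NA_real_)
  structure(list(group = group, scenario = scenario, step = step,
                 grid = grid, na_interval = na_interval),
            class = "feasibility_region")
}

#' @export
print.feasibility_region <- function(x, ...) {
  nf <- sum(x$grid$feasible)
  cat("<feasibility_region> ", x$group, " [", x$scenario, "]: ", sep = "")
  if (nf == 0) {
    cat("empty\n")
  } else {
    cat(nf, " feasible grid points, Na in [", x$na_interval[1], ", ",
        x$na_interval[2], "] mg/d (step ", x$step, " mg)\n", sep = "")
  }
  invisible(x)
}

#' Is a (sodium, potassium) point inside a feasibility region?
#'
#' Linear interpolation of the grid's `k_min`/`k_max` envelopes between
#' feasible grid points.
#'
#' @param region a `feasibility_region`.
#' @param na_mg,k_mg the query point, mg/d.
#' @param tol relative tolerance on the envelope comparison.
#' @return logical.
#' @export
region_contains <- function(region, na_mg, k_mg, tol = .dietlp_tol) {
  g <- region$grid[region$grid$feasible, , drop = FALSE]
  if (nrow(g) == 0) return(FALSE)
  if (na_mg < region$na_interval[1] - tol * max(1, region$na_interval[1]) ||
      na_mg > region$na_interval[2] + tol * max(1, region$na_interval[2])) {
    return(FALSE)
  }
  if (nrow(g) == 1) {
    kl <- g$k_min[1]; ku <- g$k_max[1]
  } else {
    kl <- stats::approx(g$sodium_mg, g$k_min, xout = na_mg, rule = 2)$y
    ku <- stats::approx(g$sodium_mg, g$k_max, xout = na_mg, rule = 2)$y
  }
  k_mg >= kl - tol * max(1, abs(kl)) && k_mg <= ku + tol * max(1, abs(ku))
}

#' Can a region meet a sodium limit and a potassium goal simultaneously?
#'
#' TRUE when some feasible grid level has sodium at or below `na_limit` and
#' a potassium ceiling (`k_max`) at or above `k_goal`. The witness returned
#' is the qualifying grid point with the highest sodium — the pattern that
#' meets the potassium goal while staying just inside the sodium limit.
#'
#' @param region a `feasibility_region`.
#' @param na_limit sodium limit, mg/d.
#' @param k_goal potassium goal, mg/d.
#' @return list with `compatible` and, when TRUE, `witness` = c(sodium_mg,
#'   potassium_mg).
#' @export
check_guideline_compatibility <- function(region,
                                          na_limit = default_guidelines()$na_limit,
                                          k_goal = default_guidelines()$k_goal) {
  g <- region$grid[region$grid$feasible, , drop = FALSE]
  ok <- g$sodium_mg <= na_limit & g$k_max >= k_goal
  if (!any(ok)) return(list(compatible = FALSE, witness = NULL))
  i <- which(ok)[which.max(g$sodium_mg[which(ok)])]
  list(compatible = TRUE,
       witness = c(sodium_mg = g$sodium_mg[i], potassium_mg = g$k_max[i]))
}

#' LP feasibility re-check of a (sodium, potassium) point
#'
#' Solves a zero-objective LP with both sodium and potassium pinned to the
#' query point on top of the constraint set — the exact counterpart of the
#' interpolated [region_contains()] answer, used to validate region
#' membership and convexity midpoints.
#'
#' @param categories category table.
#' @param cs a `constraint_set` (ratio/fixed-sodium entries are replaced).
#' @param na_mg,k_mg the query point, mg/d.
#' @return logical: is some diet with exactly these totals feasible?
#' @export
point_feasible_lp <- function(categories, cs, na_mg, k_mg) {
  cs$ratio <- NULL
  cs$ratio_sense <- NULL
  cs <- fix_sodium(cs, na_mg)
  mat <- as_lp_matrices(cs, categories)
  A_eq <- rbind(mat$A_eq, categories$potassium_mg / 100)
  b_eq <- c(mat$b_eq, k_mg)
  res <- solve_lp(rep(0, length(mat$vars)), A_ub = mat$A_ub, b_ub = mat$b_ub,
                  A_eq = A_eq, b_eq = b_eq)
  identical(res$status, "optimal")
}

#' Export a region's grid as CSV and metadata as JSON
#'
#' @param region a `feasibility_region`.
#' @param csv_file,json_file output paths (either may be NULL to skip).
#' @return invisibly, the region.
#' @export
write_region <- function(region, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file)) {
    write.csv(region$grid, csv_file, row.names = FALSE)
  }
  if (!is.null(json_file)) {
    meta <- list(group = region$group, scenario = region$scenario,
                 step_mg = region$step,
                 na_interval = as.numeric(region$na_interval),
                 n_feasible = sum(region$grid$feasible))
    jsonlite::write_json(meta, json_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(region)
}

#' Plot a feasibility region
#'
#' Fig.-style panel: the band between the minimal and maximal attainable
#' potassium at each permitted sodium level, with guideline reference lines.
#' Requires ggplot2.
#'
#' @param region a `feasibility_region` (or list of them for overlays).
#' @param guidelines list as [default_guidelines()].
#' @return a ggplot object.
#' @export
plot_region <- function(region, guidelines = default_guidelines()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_region requires ggplot2")
  }
  regions <- if (inherits(region, "feasibility_region")) list(region) else region
  df <- dplyr::bind_rows(lapply(regions, function(r) {
    g <- r$grid[r$grid$feasible, , drop = FALSE]
    g$scenario <- r$scenario
    g$group <- r$group
    g
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sodium_mg / 1000)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$k_min / 1000,
                                      ymax = .data$k_max / 1000,
                                      fill = .data$scenario), alpha = 0.4) +
    ggplot2::geom_hline(yintercept = guidelines$k_goal / 1000,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(guidelines$na_limit,
                                       guidelines$na_limit_strict) / 1000,
                        linetype = "dotted") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Sodium (g/d)", y = "Potassium (g/d)",
                  fill = "Scenario")
}
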