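# The two optimization problems of the pipeline — maximize potassium, and
# minimize weighted-L1 deviation from the observed pattern — plus an
# exhaustive grid oracle for small instances.

.new_lp_solution <- function(status, categories = NULL, x = NULL,
                             objective_value = NA_real_, group = NULL,
                             deviation_score = NULL) {
  sol <- list(status = status, amounts = NULL, objective_value = objective_value,
              totals = NULL, group = group, deviation_score = deviation_score)
  if (identical(status, "optimal")) {
    amounts <- setNames(pmax(x, 0), categories$category_id)
    sol$amounts <- amounts
    sol$totals <- pattern_totals(categories, amounts)
  }
  structure(sol, class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("<lp_solution> status: ", x$status, sep = "")
  if (identical(x$status, "optimal")) {
    cat(", energy ", round(x$totals[["energy_kcal"]]), " kcal/d, Na ",
        round(x$totals[["sodium_mg"]]), " mg/d, K ",
        round(x$totals[["potassium_mg"]]), " mg/d", sep = "")
    if (!is.null(x$deviation_score)) {
      cat(", deviation ", signif(x$deviation_score, 4), sep = "")
    }
  }
  cat("\n")
  invisible(x)
}

#' Maximize (or minimize) daily potassium subject to a constraint set
#'
#' Solves max (or min) of the pattern's potassium over nonnegative category
#' amounts under the lowered constraint set. An unbounded model (possible
#' only without an effective energy equality) is reported as a modeling
#' error via `status = "unbounded"`.
#'
#' @param categories category table (LP variables).
#' @param cs a `constraint_set` referencing only present categories.
#' @param sense `"max"` (default) or `"min"` — the min-K problem closes the
#'   lower boundary of the feasibility region.
#' @return an `lp_solution`.
#' @export
solve_max_potassium <- function(categories, cs, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(nrow(categories) >= 1)
  mat <- as_lp_matrices(cs, categories)
  obj <- categories$potassium_mg / 100
  res <- solve_lp(obj, A_ub = mat$A_ub, b_ub = mat$b_ub,
                  A_eq = mat$A_eq, b_eq = mat$b_eq,
                  maximize = sense == "max")
  if (res$status != "optimal") {
    return(.new_lp_solution(res$status, group = cs$group))
  }
  .new_lp_solution("optimal", categories, res$x, res$value, cs$group)
}

# deviation weights: 1/observed-mean-over-all for consumed categories, else
# 1/(mean positive observed mean) — keeps never-consumed variables on a
# comparable scale
.deviation_weights <- function(categories, observed, scheme) {
  obs <- observed$amounts[categories$category_id]
  obs[is.na(obs)] <- 0
  if (scheme == "l1") return(setNames(rep(1, nrow(categories)),
                                      categories$category_id))
  fallback <- mean(obs[obs > 0])
  if (!is.finite(fallback) || fallback <= 0) fallback <- 1
  w <- ifelse(obs > 0, 1 / obs, 1 / fallback)
  setNames(w, categories$category_id)
}

#' Minimize deviation from the observed pattern
#'
#' Finds the feasible pattern closest to the group's observed diet under a
#' weighted L1 distance, linearized with split variables:
#' \eqn{x_i - obs_i = d^+_i - d^-_i}, \eqn{d^\pm \ge 0}, objective
#' \eqn{\sum_i w_i (d^+_i + d^-_i)}. Default weights are 1/observed mean
#' (`scheme = "inverse_mean"`), so the score is a sum of relative
#' deviations; `scheme = "l1"` gives plain grams.
#'
#' @param categories category table.
#' @param cs a `constraint_set`.
#' @param observed an `observed_pattern` covering the category list.
#' @param scheme deviation weighting, `"inverse_mean"` or `"l1"`.
#' @return an `lp_solution` with `deviation_score` set.
#' @export
solve_min_deviation <- function(categories, cs, observed,
                                scheme = c("inverse_mean", "l1")) {
  scheme <- match.arg(scheme)
  n <- nrow(categories)
  mat <- as_lp_matrices(cs, categories)
  obs <- observed$amounts[categories$category_id]
  obs[is.na(obs)] <- 0
  w <- .deviation_weights(categories, observed, scheme)

  zero <- matrix(0, nrow(mat$A_eq), n)
  A_eq <- rbind(cbind(mat$A_eq, zero, zero),
                cbind(diag(n), -diag(n), diag(n)))
  b_eq <- c(mat$b_eq, unname(obs))
  A_ub <- if (nrow(mat$A_ub)) cbind(mat$A_ub, matrix(0, nrow(mat$A_ub), 2 * n))
          else NULL
  obj <- c(rep(0, n), w, w)
  res <- solve_lp(obj, A_ub = A_ub, b_ub = mat$b_ub,
                  A_eq = A_eq, b_eq = b_eq, maximize = FALSE)
  if (res$status != "optimal") {
    return(.new_lp_solution(res$status, group = cs$group))
  }
  sol <- .new_lp_solution("optimal", categories, res$x[seq_len(n)],
                          res$value, cs$group, deviation_score = res$value)
  sol
}

#' Brute-force grid oracle for tiny LP instances
#'
#' Independent check of the solvers on at most 3 categories: solves the
#' equality rows (energy, and any ratio / fixed-sodium rows) exactly for a
#' set of dependent variables, scans the remaining free variables on a
#' regular grid in 100-g portion units, keeps grid points whose implied
#' full solution is nonnegative and satisfies every inequality, and returns
#' the best objective value. Because equalities hold exactly at every
#' candidate, the oracle cannot leak optimality through constraint slack;
#' its only error is the grid spacing, so it converges to the LP optimum as
#' `grid_step` shrinks. It shares no code with the simplex path.
#'
#' @param categories category table with <= 3 rows.
#' @param cs a `constraint_set`.
#' @param objective `"max_potassium"`, `"min_potassium"` or
#'   `"min_deviation"`.
#' @param grid_step grid resolution in 100-g portions (0.01 = 1 g).
#' @param observed an `observed_pattern`; required for `"min_deviation"`.
#' @param scheme deviation weighting, as in [solve_min_deviation()].
#' @return list with `status`, `value`, `x` (g/d at the best grid point).
#' @export
brute_force_optimum <- function(categories, cs,
                                objective = c("max_potassium", "min_potassium",
                                              "min_deviation"),
                                grid_step = 0.01, observed = NULL,
                                scheme = "inverse_mean") {
  objective <- match.arg(objective)
  n <- nrow(categories)
  if (n > 3) stop("brute-force oracle supports at most 3 categories")
  mat <- as_lp_matrices(cs, categories)
  E <- cs$energy_kcal
  e_per_g <- categories$energy_kcal / 100
  if (any(e_per_g <= 0)) stop("oracle requires strictly positive energy densities")

  step_g <- grid_step * 100
  A_eq <- mat$A_eq
  qa <- qr(t(A_eq))                       # column pivoting on rows
  indep <- sort(qa$pivot[seq_len(qa$rank)])
  if (length(indep) < nrow(A_eq)) {
    # consistency of dropped (dependent) rows is re-checked on candidates
    dep_rows <- setdiff(seq_len(nrow(A_eq)), indep)
  } else {
    dep_rows <- integer(0)
  }
  Ar <- A_eq[indep, , drop = FALSE]
  br <- mat$b_eq[indep]
  m_eq <- nrow(Ar)
  if (m_eq > n) return(list(status = "infeasible", value = NA_real_))

  # choose dependent variables so the square block is invertible
  qv <- qr(Ar)
  dep <- sort(qv$pivot[seq_len(m_eq)])
  free <- setdiff(seq_len(n), dep)
  Adep <- Ar[, dep, drop = FALSE]

  if (length(free) == 0) {
    xs <- matrix(solve(Adep, br), 1, byrow = TRUE)
    G0 <- matrix(numeric(0), 1, 0)
  } else {
    ranges <- lapply(free, function(j) seq(0, E / e_per_g[j], by = step_g))
    G0 <- as.matrix(expand.grid(ranges))
    rhs <- matrix(br, nrow(G0), m_eq, byrow = TRUE) -
      G0 %*% t(Ar[, free, drop = FALSE])
    xs <- rhs %*% t(solve(Adep))
  }
  grid <- matrix(0, nrow(G0), n)
  if (length(free)) grid[, free] <- G0
  grid[, dep] <- xs

  # equalities hold exactly by construction; check sign, redundant equality
  # rows, and the inequalities at a tight tolerance
  feas <- rowSums(grid < -1e-9 * max(1, E)) == 0
  for (i in dep_rows) {
    lhs <- drop(grid %*% A_eq[i, ])
    feas <- feas & abs(lhs - mat$b_eq[i]) <= 1e-7 * max(1, abs(mat$b_eq[i]))
  }
  if (nrow(mat$A_ub)) {
    for (i in seq_along(mat$b_ub)) {
      lhs <- drop(grid %*% mat$A_ub[i, ])
      feas <- feas & lhs <= mat$b_ub[i] + 1e-9 * max(1, abs(mat$b_ub[i]))
    }
  }
  if (!any(feas)) return(list(status = "infeasible", value = NA_real_))
  G <- grid[feas, , drop = FALSE]
  G[G < 0] <- 0

  val <- switch(objective,
    max_potassium = ,
    min_potassium = drop(G %*% (categories$potassium_mg / 100)),
    min_deviation = {
      if (is.null(observed)) stop("min_deviation oracle needs `observed`")
      obs <- observed$amounts[categories$category_id]
      obs[is.na(obs)] <- 0
      w <- .deviation_weights(categories, observed, scheme)
      drop(abs(sweep(G, 2, obs)) %*% w)
    })
  best <- if (objective == "max_potassium") which.max(val) else which.min(val)
  list(status = "optimal", value = val[best],
       x = setNames(G[best, ], categories$category_id))
}
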