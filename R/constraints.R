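# Linear constraint system: energy equality at the group's requirement, DRI
# nutrient rows, percentile-based food-group bounds, and the optional Na:K
# ratio and fixed-sodium equalities.

#' Build the constraint set for one sex-age group
#'
#' Assembles: the energy equality at the group's energy requirement; one
#' inequality row per DRI entry (min and/or max); major-group amounts bounded
#' by the observed 10th and 90th percentiles; subgroup and category amounts
#' bounded above by the observed 75th percentile (lower bound 0). The
#' vitamin E override (`options$vitamin_e_min`, conventionally 13 mg/d)
#' replaces the vitamin E minimum, for groups whose reported diets carry no
#' vegetable oils. Guideline rows for sodium/potassium are NOT part of the
#' DRI panel here; toggle them with `options$na_max` / `options$k_min`
#' because the sodium sweep and the ratio analyses replace them.
#'
#' @param profile a `group_profile`.
#' @param bounds percentile table from [consumption_percentiles()], or NULL
#'   for no food-group bounds (toy fixtures).
#' @param options list: `vitamin_e_min`, `na_max`, `k_min`.
#' @return object of class `constraint_set`.
#' @export
build_constraint_set <- function(profile, bounds = NULL, options = list()) {
  dri <- profile$dri
  if (nrow(dri) && any(!is.na(dri$min) & !is.na(dri$max) & dri$min > dri$max)) {
    stop("DRI row with min > max")
  }
  rows <- list()
  if (nrow(dri)) {
    for (i in seq_len(nrow(dri))) {
      if (!is.na(dri$min[i])) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          nutrient = dri$nutrient[i], sense = ">=", bound = dri$min[i],
          units = dri$unit[i])
      }
      if (!is.na(dri$max[i])) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          nutrient = dri$nutrient[i], sense = "<=", bound = dri$max[i],
          units = dri$unit[i])
      }
    }
  }
  nutrient_rows <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(nutrient = character(), sense = character(),
                   bound = numeric(), units = character())

  if (!is.null(options$vitamin_e_min)) {
    hit <- nutrient_rows$nutrient == "vitamin_e_mg" & nutrient_rows$sense == ">="
    if (any(hit)) {
      nutrient_rows$bound[hit] <- options$vitamin_e_min
    } else {
      nutrient_rows <- dplyr::bind_rows(nutrient_rows, tibble::tibble(
        nutrient = "vitamin_e_mg", sense = ">=",
        bound = options$vitamin_e_min, units = "mg"))
    }
  }
  if (!is.null(options$na_max)) {
    nutrient_rows <- dplyr::bind_rows(nutrient_rows, tibble::tibble(
      nutrient = "sodium_mg", sense = "<=", bound = options$na_max,
      units = "mg"))
  }
  if (!is.null(options$k_min)) {
    nutrient_rows <- dplyr::bind_rows(nutrient_rows, tibble::tibble(
      nutrient = "potassium_mg", sense = ">=", bound = options$k_min,
      units = "mg"))
  }
  if (anyDuplicated(nutrient_rows[, c("nutrient", "sense")])) {
    stop("duplicate nutrient/sense pairs in constraint set")
  }

  group_bounds <- if (is.null(bounds) || nrow(bounds) == 0) {
    tibble::tibble(node_id = character(), tier = character(),
                   lower = numeric(), upper = numeric())
  } else {
    tibble::tibble(
      node_id = bounds$node_id,
      tier = bounds$tier,
      lower = ifelse(bounds$tier == "major", bounds$p10, 0),
      upper = ifelse(bounds$tier == "major", bounds$p90, bounds$p75))
  }

  structure(list(group = profile$group,
                 energy_kcal = profile$eer_kcal,
                 nutrient_rows = nutrient_rows,
                 group_bounds = group_bounds,
                 ratio = NULL,
                 fixed_sodium_mg = NULL),
            class = "constraint_set")
}

#' Hold the Na:K mass ratio constant
#'
#' Adds the linear equality (sodium mg/d) - r * (potassium mg/d) = 0. The
#' guideline-implied default is r = 2300/4700, rounded to 0.49. An
#' inequality mode (`sense = "<="`, sodium at most r times potassium) is
#' available since the ratio is also discussed as a guideline ceiling.
#'
#' @param cs a `constraint_set`.
#' @param r Na:K mass ratio, > 0.
#' @param sense `"="` (default) or `"<="`.
#' @return the updated `constraint_set`.
#' @export
apply_ratio_constraint <- function(cs, r = default_guidelines()$ratio,
                                   sense = c("=", "<=")) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    stop("ratio r must be a single positive number")
  }
  cs$ratio <- r
  cs$ratio_sense <- match.arg(sense)
  cs
}

#' Fix the daily sodium amount
#'
#' Adds the equality (sodium mg/d) = s, the device the sodium sweep uses.
#' Idempotent for a given `s`. With `exclusive = TRUE` any Na:K ratio
#' constraint is removed first.
#'
#' @param cs a `constraint_set`.
#' @param s sodium level mg/d, >= 0.
#' @param exclusive drop an existing ratio constraint.
#' @return the updated `constraint_set`.
#' @export
fix_sodium <- function(cs, s, exclusive = FALSE) {
  if (!is.numeric(s) || length(s) != 1 || s < 0) {
    stop("fixed sodium level must be a single number >= 0")
  }
  if (exclusive) {
    cs$ratio <- NULL
    cs$ratio_sense <- NULL
  }
  cs$fixed_sodium_mg <- s
  cs
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> ", x$group, ": energy = ", x$energy_kcal,
      " kcal/d, ", nrow(x$nutrient_rows), " nutrient rows, ",
      nrow(x$group_bounds), " food-group bounds", sep = "")
  if (!is.null(x$ratio)) cat(", Na:K ", x$ratio_sense %||% "=", " ", x$ratio,
                             sep = "")
  if (!is.null(x$fixed_sodium_mg)) cat(", Na = ", x$fixed_sodium_mg, " mg/d",
                                       sep = "")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lower a constraint set and category table to LP matrices
#'
#' Dense rows over the group's category variables (amounts in g/d, lower
#' bound 0 implicit in the solver). Every matrix row carries provenance in
#' `row_info`, and [constraint_set_from_matrices()] inverts the lowering.
#'
#' @param cs a `constraint_set`.
#' @param categories category table for the same group.
#' @return list: `vars`, `A_eq`, `b_eq`, `A_ub`, `b_ub`, `row_info`
#'   (tibble with kind/ref/sense/bound per row, eq rows first).
#' @export
as_lp_matrices <- function(cs, categories) {
  vars <- categories$category_id
  n <- length(vars)
  per_g <- function(col) {
    if (col %in% names(categories)) categories[[col]] / 100 else rep(0, n)
  }
  eq <- list(); eqb <- numeric()
  ub <- list(); ubb <- numeric()
  info_kind <- character(); info_ref <- character()
  info_sense <- character(); info_bound <- numeric(); info_side <- character()
  note <- function(kind, ref, sense, bound, side) {
    info_kind[length(info_kind) + 1L] <<- kind
    info_ref[length(info_ref) + 1L] <<- ref
    info_sense[length(info_sense) + 1L] <<- sense
    info_bound[length(info_bound) + 1L] <<- bound
    info_side[length(info_side) + 1L] <<- side
  }
  add_eq <- function(a, b, kind, ref, bound) {
    eq[[length(eq) + 1L]] <<- a; eqb[length(eqb) + 1L] <<- b
    note(kind, ref, "=", bound, "eq")
  }
  add_ub <- function(a, b, kind, ref, sense, bound) {
    ub[[length(ub) + 1L]] <<- a; ubb[length(ubb) + 1L] <<- b
    note(kind, ref, sense, bound, "ub")
  }

  add_eq(per_g("energy_kcal"), cs$energy_kcal, "energy", "energy_kcal",
         cs$energy_kcal)
  if (!is.null(cs$ratio)) {
    a <- per_g("sodium_mg") - cs$ratio * per_g("potassium_mg")
    if (identical(cs$ratio_sense %||% "=", "=")) {
      add_eq(a, 0, "ratio", as.character(cs$ratio), cs$ratio)
    } else {
      add_ub(a, 0, "ratio", as.character(cs$ratio), "<=", cs$ratio)
    }
  }
  if (!is.null(cs$fixed_sodium_mg)) {
    add_eq(per_g("sodium_mg"), cs$fixed_sodium_mg, "sodium_fixed",
           "sodium_mg", cs$fixed_sodium_mg)
  }
  nr <- cs$nutrient_rows
  for (i in seq_len(nrow(nr))) {
    a <- per_g(nr$nutrient[i])
    if (nr$sense[i] == ">=") {
      add_ub(-a, -nr$bound[i], "nutrient", nr$nutrient[i], ">=", nr$bound[i])
    } else {
      add_ub(a, nr$bound[i], "nutrient", nr$nutrient[i], "<=", nr$bound[i])
    }
  }
  gb <- cs$group_bounds
  for (i in seq_len(nrow(gb))) {
    node_col <- switch(gb$tier[i], major = "major_group_id",
                       subgroup = "subgroup_id", category = "category_id")
    memb <- as.numeric(categories[[node_col]] == gb$node_id[i])
    if (!any(memb > 0)) next
    if (!is.na(gb$lower[i]) && gb$lower[i] > 0) {
      add_ub(-memb, -gb$lower[i], paste0("bound_", gb$tier[i]),
             gb$node_id[i], ">=", gb$lower[i])
    }
    if (!is.na(gb$upper[i])) {
      add_ub(memb, gb$upper[i], paste0("bound_", gb$tier[i]),
             gb$node_id[i], "<=", gb$upper[i])
    }
  }

  A_eq <- do.call(rbind, eq)
  A_ub <- if (length(ub)) do.call(rbind, ub) else matrix(0, 0, n)
  colnames(A_eq) <- vars
  if (nrow(A_ub)) colnames(A_ub) <- vars
  ord <- order(info_side != "eq")  # eq rows first, stable
  row_info <- tibble::tibble(kind = info_kind, ref = info_ref,
                             sense = info_sense,
                             bound = info_bound)[ord, , drop = FALSE]
  list(vars = vars, A_eq = A_eq, b_eq = eqb, A_ub = A_ub, b_ub = ubb,
       row_info = row_info, group = cs$group, energy_kcal = cs$energy_kcal)
}

#' Rebuild a constraint set from lowered matrices
#'
#' Inverse of [as_lp_matrices()] via the row-provenance table; used to check
#' that lowering loses no information.
#'
#' @param mat output of [as_lp_matrices()].
#' @return a `constraint_set`.
#' @export
constraint_set_from_matrices <- function(mat) {
  ri <- mat$row_info
  nutr <- ri[ri$kind == "nutrient", ]
  gb <- ri[ri$kind %in% c("bound_major", "bound_subgroup", "bound_category"), ]
  gb_nodes <- unique(gb[, c("kind", "ref")])
  group_bounds <- tibble::tibble(
    node_id = gb_nodes$ref,
    tier = sub("^bound_", "", gb_nodes$kind),
    lower = vapply(seq_len(nrow(gb_nodes)), function(i) {
      h <- gb$ref == gb_nodes$ref[i] & gb$kind == gb_nodes$kind[i] &
        gb$sense == ">="
      if (any(h)) gb$bound[h][1] else 0
    }, numeric(1)),
    upper = vapply(seq_len(nrow(gb_nodes)), function(i) {
      h <- gb$ref == gb_nodes$ref[i] & gb$kind == gb_nodes$kind[i] &
        gb$sense == "<="
      if (any(h)) gb$bound[h][1] else NA_real_
    }, numeric(1)))
  cs <- structure(list(
    group = mat$group,
    energy_kcal = ri$bound[ri$kind == "energy"][1],
    nutrient_rows = tibble::tibble(nutrient = nutr$ref, sense = nutr$sense,
                                   bound = nutr$bound,
                                   units = sub(".*_", "", nutr$ref)),
    group_bounds = group_bounds,
    ratio = NULL, fixed_sodium_mg = NULL), class = "constraint_set")
  if (any(ri$kind == "ratio")) {
    cs$ratio <- ri$bound[ri$kind == "ratio"][1]
    cs$ratio_sense <- ri$sense[ri$kind == "ratio"][1]
    if (cs$ratio_sense == "=") cs$ratio_sense <- "="
  }
  if (any(ri$kind == "sodium_fixed")) {
    cs$fixed_sodium_mg <- ri$bound[ri$kind == "sodium_fixed"][1]
  }
  cs
}

#' Serialize a constraint set to / from YAML
#'
#' @param cs a `constraint_set`.
#' @param file path to write to / read from.
#' @return `file` invisibly; `constraint_set_from_yaml()` returns the set.
#' @export
constraint_set_to_yaml <- function(cs, file) {
  obj <- list(group = cs$group, energy_kcal = cs$energy_kcal,
              nutrient_rows = lapply(seq_len(nrow(cs$nutrient_rows)),
                                     function(i) as.list(cs$nutrient_rows[i, ])),
              group_bounds = lapply(seq_len(nrow(cs$group_bounds)),
                                    function(i) {
                                      r <- as.list(cs$group_bounds[i, ])
                                      r$upper <- if (is.na(r$upper)) NULL else r$upper
                                      r
                                    }),
              ratio = cs$ratio, ratio_sense = cs$ratio_sense,
              fixed_sodium_mg = cs$fixed_sodium_mg)
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname constraint_set_to_yaml
#' @export
constraint_set_from_yaml <- function(file) {
  obj <- yaml::read_yaml(file)
  nr <- if (length(obj$nutrient_rows)) dplyr::bind_rows(obj$nutrient_rows) else
    tibble::tibble(nutrient = character(), sense = character(),
                   bound = numeric(), units = character())
  gb <- if (length(obj$group_bounds)) {
    dplyr::bind_rows(lapply(obj$group_bounds, function(r) {
      tibble::tibble(node_id = r$node_id, tier = r$tier, lower = r$lower,
                     upper = r$upper %||% NA_real_)
    }))
  } else {
    tibble::tibble(node_id = character(), tier = character(),
                   lower = numeric(), upper = numeric())
  }
  structure(list(group = obj$group, energy_kcal = obj$energy_kcal,
                 nutrient_rows = nr, group_bounds = gb,
                 ratio = obj$ratio, ratio_sense = obj$ratio_sense,
                 fixed_sodium_mg = obj$fixed_sodium_mg),
            class = "constraint_set")
}

#' Export lowered matrices in MPS format
#'
#' Minimal fixed-format MPS writer for cross-checking models in external
#' solvers.
#'
#' @param mat output of [as_lp_matrices()].
#' @param objective named objective coefficients (names = variable ids).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mps <- function(mat, objective, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("NAME          DIETLP")
  w("ROWS")
  w(" N  COST")
  nm_eq <- sprintf("E%04d", seq_along(mat$b_eq))
  nm_ub <- sprintf("L%04d", seq_along(mat$b_ub))
  for (r in nm_eq) w(" E  ", r)
  for (r in nm_ub) w(" L  ", r)
  w("COLUMNS")
  for (j in seq_along(mat$vars)) {
    v <- mat$vars[j]
    cj <- if (v %in% names(objective)) objective[[v]] else 0
    if (cj != 0) w("    ", v, "  COST  ", format(cj, digits = 12))
    for (i in seq_along(mat$b_eq)) {
      if (mat$A_eq[i, j] != 0) {
        w("    ", v, "  ", nm_eq[i], "  ", format(mat$A_eq[i, j], digits = 12))
      }
    }
    for (i in seq_along(mat$b_ub)) {
      if (mat$A_ub[i, j] != 0) {
        w("    ", v, "  ", nm_ub[i], "  ", format(mat$A_ub[i, j], digits = 12))
      }
    }
  }
  w("RHS")
  for (i in seq_along(mat$b_eq)) {
    w("    RHS  ", nm_eq[i], "  ", format(mat$b_eq[i], digits = 12))
  }
  for (i in seq_along(mat$b_ub)) {
    w("    RHS  ", nm_ub[i], "  ", format(mat$b_ub[i], digits = 12))
  }
  w("BOUNDS")
  w("ENDATA")
  invisible(file)
}
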