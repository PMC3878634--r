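#' Solve a linear program
#'
#' Thin interface over the package's dense two-phase simplex. Solves
#' \deqn{\min / \max\; c^\top x \quad \mathrm{s.t.}\; A_{ub} x \le b_{ub},\;
#'   A_{eq} x = b_{eq},\; x \ge 0.}
#' Pivoting is deterministic (Dantzig rule with lowest-index tie-breaks and a
#' Bland anti-cycling fallback), so repeated solves of the same problem give
#' bit-identical answers — a property the sweep and tie-break guarantees of
#' the region mapper rely on.
#'
#' @param objective numeric objective coefficients, one per variable.
#' @param A_ub,b_ub inequality rows \eqn{A_{ub} x \le b_{ub}} (may be NULL).
#' @param A_eq,b_eq equality rows \eqn{A_{eq} x = b_{eq}} (may be NULL).
#' @param maximize logical; maximize instead of minimize.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`), and for optimal solves `x` and `value`.
#' @examples
#' # max x1 + x2 s.t. x1 + 2 x2 <= 4, x1 <= 3
#' solve_lp(c(1, 1), A_ub = rbind(c(1, 2), c(1, 0)), b_ub = c(4, 3),
#'          maximize = TRUE)
#' @export
solve_lp <- function(objective, A_ub = NULL, b_ub = NULL,
                     A_eq = NULL, b_eq = NULL, maximize = FALSE) {
  n <- length(objective)
  stopifnot(n >= 1L)
  if (is.null(A_ub)) {
    A_ub <- matrix(0, 0L, n); b_ub <- numeric(0)
  }
  if (is.null(A_eq)) {
    A_eq <- matrix(0, 0L, n); b_eq <- numeric(0)
  }
  A_ub <- as.matrix(A_ub); A_eq <- as.matrix(A_eq)
  stopifnot(ncol(A_ub) == n, ncol(A_eq) == n,
            nrow(A_ub) == length(b_ub), nrow(A_eq) == length(b_eq))
  res <- .simplex_cpp(as.numeric(objective),
                      A_ub, as.numeric(b_ub),
                      A_eq, as.numeric(b_eq),
                      isTRUE(maximize))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "2" = "unbounded",
                   "3" = "maxiter")
  if (identical(status, "maxiter")) {
    stop("simplex iteration limit reached; the model is numerically degenerate")
  }
  if (status != "optimal") {
    return(list(status = status, x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = as.numeric(res$x), value = res$value)
}

# Shared feasibility tolerance (relative): used by the solver wrapper, the
# region mapper and the brute-force oracle when re-checking constraints.
.dietlp_tol <- 1e-6

#' Check whether a point satisfies an LP's constraints
#'
#' Relative feasibility check at the package-wide tolerance (1e-6), used by
#' the brute-force oracle and the region midpoint re-checks.
#'
#' @inheritParams solve_lp
#' @param x candidate point.
#' @param tol relative tolerance.
#' @return logical.
#' @export
lp_point_feasible <- function(x, A_ub = NULL, b_ub = NULL,
                              A_eq = NULL, b_eq = NULL, tol = .dietlp_tol) {
  if (any(x < -tol)) return(FALSE)
  ok <- TRUE
  if (!is.null(A_ub) && nrow(A_ub <- as.matrix(A_ub)) > 0) {
    lhs <- drop(A_ub %*% x)
    ok <- ok && all(lhs <= b_ub + tol * pmax(1, abs(b_ub)))
  }
  if (!is.null(A_eq) && nrow(A_eq <- as.matrix(A_eq)) > 0) {
    lhs <- drop(A_eq %*% x)
    ok <- ok && all(abs(lhs - b_eq) <= tol * pmax(1, abs(b_eq)))
  }
  ok
}
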