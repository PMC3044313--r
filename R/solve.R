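#' Solve a CSWO instance
#'
#' Front end over the three exact solvers: the bounded-search-tree
#' `"branching"` solver (fixed-parameter in `d` and `k`; the default), the
#' exhaustive `"enumerate"` center-enumeration solver, and the `"ilp"`
#' subset-enumeration solver built on the closest-string 0/1 program.  All
#' three are exact, so their feasibility verdicts agree; they differ in
#' which instances they handle comfortably and in which witness solution
#' they return.
#'
#' With `minimize = "d"` (resp. `"k"`) the other parameter is held fixed
#' and the smallest feasible radius (resp. outlier budget) is found by an
#' ascending scan, exact by monotonicity of feasibility.
#'
#' @param inst a [cswo_instance].
#' @param d,k override the instance's radius / outlier budget.  The one
#'   being minimized is ignored.
#' @param method `"branching"`, `"enumerate"` or `"ilp"`.
#' @param minimize `NULL` for the decision problem, or `"d"` / `"k"`.
#' @param max_centers,max_subsets search-space caps for the baseline
#'   solvers.
#' @return A [cswo_solution].  When minimizing, the optimum is attached as
#'   field `minimized` (a list with `parameter` and `value`).
#' @examples
#' inst <- cswo_instance(c("AAAA", "AAAT", "TTTT"), k = 1)
#' sol <- cswo_solve(inst, minimize = "d")
#' sol$minimized$value  # 1
#' @export
cswo_solve <- function(inst, d = NULL, k = NULL,
                       method = c("branching", "enumerate", "ilp"),
                       minimize = NULL,
                       max_centers = 2e6, max_subsets = 1e5) {
  stopifnot(is_cswo_instance(inst))
  method <- match.arg(method)
  solver <- switch(method,
    branching = solve_branching,
    enumerate = function(inst, d, k)
      enumerate_centers(inst, d, k, max_centers = max_centers),
    ilp = function(inst, d, k)
      solve_subset_ilp(inst, d, k, max_subsets = max_subsets))
  if (is.null(minimize))
    return(solver(inst, need_d(inst, d), need_k(inst, k)))
  minimize <- match.arg(minimize, c("d", "k"))
  if (minimize == "d") {
    res <- minimize_d(inst, k = need_k(inst, k), solver = solver)
    sol <- res$solution
    sol$minimized <- list(parameter = "d", value = res$d)
  } else {
    res <- minimize_k(inst, d = need_d(inst, d), solver = solver)
    sol <- res$solution
    sol$minimized <- list(parameter = "k", value = res$k)
  }
  sol
}
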