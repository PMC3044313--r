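#' Fixed-parameter bounded search tree solver for CSWO
#'
#' Decision solver for CLOSEST STRING WITH OUTLIERS parameterized by the
#' radius `d` and the outlier budget `k`.  The recursion keeps a candidate
#' center `x` and two budgets: `delta_d`, the number of candidate positions
#' that may still be changed, and `k_rem`, the number of strings that may
#' still be declared outliers.  At each node it picks the lowest-id active
#' string `s_i` with `hamming_dist(x, s_i) > d` (if none exists, `x` is a
#' valid center for the active set and the node succeeds) and branches:
#' first declare `s_i` an outlier (drop it, `k_rem - 1`); if that fails, for
#' each of the first `d + 1` mismatch positions `p` (in increasing order) set
#' `x[p] <- s_i[p]` and recurse with `delta_d - 1`.  Each position branch
#' starts from the candidate as it was on entry to the node, so exactly one
#' position changes per `delta_d` decrement.
#'
#' A single start from `s_1` is incomplete: with strings
#' `{"AAAA...", "TTTT...", "TTTT..."}`, `d = 0`, `k = 1`, the only feasible
#' center is the repeated string, yet `s_1` lies farther than the `delta_d`
#' budget allows from it.  In any feasible solution at most `k` strings are
#' outliers, so among the first `min(k + 1, n)` strings at least one is an
#' inlier of some feasible solution and lies within `d` of its center — which
#' is what the bounded-search-tree argument needs of the start.  The solver
#' therefore restarts the recursion from each of the first `min(k + 1, n)`
#' strings and returns the first success, making it complete at a cost of at
#' most a factor `k + 1` on the per-start search-tree bound
#' `2^(k+d) * (d+1)^d + 1` nodes.
#'
#' @param inst a [cswo_instance].
#' @param d,k override the instance's radius / outlier budget.
#' @return A [cswo_solution]; `feasible` is `FALSE` when no center exists at
#'   `(d, k)`.  The `stats` field holds `nodes_per_start` (nodes visited in
#'   each restart), `outlier_branches` and `position_branches`.
#' @examples
#' inst <- cswo_instance(c("ACGT", "ACGA", "TTTT"), d = 1, k = 1)
#' solve_branching(inst)
#' @seealso [enumerate_centers()], [solve_subset_ilp()] for the exact
#'   baselines, [minimize_d()] and [minimize_k()] for the optimization
#'   wrappers.
#' @export
solve_branching <- function(inst, d = NULL, k = NULL) {
  stopifnot(is_cswo_instance(inst))
  d <- need_d(inst, d); k <- need_k(inst, k)
  mat <- inst$tokens
  n <- nrow(mat); ell <- ncol(mat)

  stats <- new.env(parent = emptyenv())
  stats$nodes <- integer(0)
  stats$outlier_branches <- 0L
  stats$position_branches <- 0L
  done <- function(center, inliers, feasible = TRUE) {
    cswo_solution(
      center = center, inliers = inliers,
      outliers = setdiff(seq_len(n), inliers),
      feasible = feasible, method = "branching",
      stats = list(nodes_per_start = stats$nodes,
                   outlier_branches = stats$outlier_branches,
                   position_branches = stats$position_branches))
  }

  ## degenerate budgets: nothing need be covered (k >= n; the strings s_1
  ## happens to cover stay inliers so the solution invariants hold), or the
  ## radius covers everything.  Counts as one visited node so stats always
  ## reflect a completed solve.
  if (n - k <= 0L) {
    stats$nodes <- 1L
    return(done(mat[1L, ], coverage(inst, mat[1L, ], d = d)))
  }
  if (d >= ell) {
    stats$nodes <- 1L
    return(done(mat[1L, ], seq_len(n)))
  }

  recurse <- function(active, cand, delta_d, k_rem) {
    if (delta_d < 0L || k_rem < 0L) return(NULL)
    ## count only iterations that pass the budget guard: exhausted-budget
    ## calls are their parent's failed guess, not search-tree nodes
    stats$nodes[length(stats$nodes)] <- stats$nodes[length(stats$nodes)] + 1L
    viol <- 0L
    for (i in active) {
      if (sum(cand != mat[i, ]) > d) { viol <- i; break }
    }
    if (viol == 0L)
      return(list(center = cand, inliers = active))
    ## branch 1: s_viol is an outlier
    stats$outlier_branches <- stats$outlier_branches + 1L
    res <- recurse(active[active != viol], cand, delta_d, k_rem - 1L)
    if (!is.null(res)) return(res)
    ## branch 2: move the candidate toward s_viol at one of the first
    ## d + 1 mismatch positions (|P| >= d + 1 since hamming > d)
    p_all <- which(cand != mat[viol, ])
    p_sel <- p_all[seq_len(d + 1L)]
    for (p in p_sel) {
      stats$position_branches <- stats$position_branches + 1L
      cand2 <- cand
      cand2[p] <- mat[viol, p]
      res <- recurse(active, cand2, delta_d - 1L, k_rem)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  for (start in seq_len(min(k + 1L, n))) {
    stats$nodes <- c(stats$nodes, 0L)
    res <- recurse(seq_len(n), mat[start, ], d, k)
    if (!is.null(res))
      return(done(res$center, res$inliers))
  }
  done(NULL, integer(0), feasible = FALSE)
}

#' Smallest feasible radius for a fixed outlier budget
#'
#' Scans `d = 0, 1, ..., l` in order and returns the first value at which
#' [solve_branching()] finds a solution; `d = l` is always feasible.
#' Feasibility is monotone in `d`, so the linear scan is exact and keeps a
#' witness solution for the optimum.
#'
#' @param inst a [cswo_instance].
#' @param k outlier budget (defaults to the instance's `k`).
#' @param solver decision solver to use, called as `solver(inst, d, k)`.
#' @return A list with `d` (the minimum radius) and `solution` (a feasible
#'   [cswo_solution] at that radius).
#' @export
minimize_d <- function(inst, k = NULL, solver = solve_branching) {
  stopifnot(is_cswo_instance(inst))
  k <- need_k(inst, k)
  for (d in 0:string_length(inst)) {
    sol <- solver(inst, d = d, k = k)
    if (sol$feasible) return(list(d = d, solution = sol))
  }
  stop("internal error: d = l must be feasible")  # nocov
}

#' Smallest feasible outlier budget for a fixed radius
#'
#' Scans `k = 0, 1, ..., n`; `k = n` is always feasible (no string need be
#' covered).  Monotone feasibility makes the linear scan exact.
#'
#' @param inst a [cswo_instance].
#' @param d Hamming radius (defaults to the instance's `d`).
#' @param solver decision solver to use, called as `solver(inst, d, k)`.
#' @return A list with `k` (the minimum budget) and `solution`.
#' @export
minimize_k <- function(inst, d = NULL, solver = solve_branching) {
  stopifnot(is_cswo_instance(inst))
  d <- need_d(inst, d)
  for (k in 0:n_strings(inst)) {
    sol <- solver(inst, d = d, k = k)
    if (sol$feasible) return(list(k = k, solution = sol))
  }
  stop("internal error: k = n must be feasible")  # nocov
}
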