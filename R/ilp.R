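#' Exact closest string via a 0/1 integer program
#'
#' Solves the classic CLOSEST STRING decision problem (no outliers) for a set
#' of equal-length strings through its direct position-symbol 0/1
#' formulation: indicator variables `x[p, a]` for each position `p` and each
#' symbol `a` occurring in column `p`, with `sum_a x[p, a] = 1` per column
#' and, for every string `s_i`, `sum_p (1 - x[p, s_i[p]]) <= d`.  The
#' program is solved exactly by depth-first branch and bound over the
#' columns: each level assigns one column's symbol and any partial assignment
#' in which some string already exceeds `d` mismatches is pruned.  Restricting
#' column `p` to its occurring symbols is lossless (a non-occurring symbol
#' matches no string at `p`).
#'
#' @param strings a [cswo_instance], token matrix, character vector, or list
#'   of token vectors (see [cswo_instance()] for the accepted forms).
#' @param d nonnegative Hamming radius.
#' @return The center as a token vector, with attribute `nodes` (search nodes
#'   explored), or `NULL` if no center within `d` of every string exists.
#' @examples
#' closest_string_ilp(c("AA", "TT"), d = 1)  # e.g. "A" "T"
#' closest_string_ilp(c("AA", "TT"), d = 0)  # NULL
#' @export
closest_string_ilp <- function(strings, d) {
  mat <- if (is_cswo_instance(strings)) strings$tokens
         else as_token_matrix(strings)
  d <- check_count(d, "d")
  n <- nrow(mat); ell <- ncol(mat)
  if (n == 0L) stop("'strings' must be non-empty", call. = FALSE)

  ## per column: occurring symbols and, per symbol, the 0/1 mismatch
  ## increment over strings
  columns <- lapply(seq_len(ell), function(j) unique(mat[, j]))
  mism <- lapply(seq_len(ell), function(j)
    lapply(columns[[j]], function(a) as.integer(mat[, j] != a)))

  nodes <- 0L
  choice <- integer(ell)
  found <- FALSE
  dfs <- function(j, counts) {
    nodes <<- nodes + 1L
    if (j > ell) { found <<- TRUE; return(TRUE) }
    for (a in seq_along(columns[[j]])) {
      nc <- counts + mism[[j]][[a]]
      if (all(nc <= d)) {
        choice[j] <<- a
        if (dfs(j + 1L, nc)) return(TRUE)
      }
    }
    FALSE
  }
  dfs(1L, integer(n))
  if (!found) return(NULL)
  center <- vapply(seq_len(ell), function(j) columns[[j]][choice[j]],
                   character(1))
  attr(center, "nodes") <- nodes
  center
}

#' Subset enumeration + integer-program CSWO solver
#'
#' Exact CSWO solver that enumerates all inlier subsets of size
#' `n* = n - k` in lexicographic id order and runs [closest_string_ilp()]
#' on each, returning the first subset that admits a center within radius
#' `d`.  Its feasibility verdict is identical to [enumerate_centers()]'s;
#' the solver is practical when `choose(n, n - k)` is small.
#'
#' @param inst a [cswo_instance].
#' @param d,k override the instance's radius / outlier budget.
#' @param max_subsets refuse to enumerate more than this many subsets
#'   (error of class `cswo_too_large`).
#' @return A [cswo_solution] with extra field `subsets_tried`.
#' @examples
#' inst <- cswo_instance(c("AA", "AA", "TT"), d = 0, k = 1)
#' solve_subset_ilp(inst)
#' @export
solve_subset_ilp <- function(inst, d = NULL, k = NULL, max_subsets = 1e5) {
  stopifnot(is_cswo_instance(inst))
  d <- need_d(inst, d); k <- need_k(inst, k)
  n <- n_strings(inst)
  nstar <- n - k
  if (nstar <= 0L)
    return(cswo_solution(inst$tokens[1L, ], seq_len(n), integer(0),
                         feasible = TRUE, method = "subset_ilp",
                         subsets_tried = 0L))
  n_subsets <- choose(n, nstar)
  if (n_subsets > max_subsets)
    stop(structure(
      class = c("cswo_too_large", "error", "condition"),
      list(message = sprintf(
             "%.0f subsets of size %d, above the cap of %.0f",
             n_subsets, nstar, max_subsets),
           call = sys.call(-1))))
  subsets <- utils::combn(n, nstar)   # columns in lexicographic order
  for (s in seq_len(ncol(subsets))) {
    ids <- subsets[, s]
    center <- closest_string_ilp(inst$tokens[ids, , drop = FALSE], d)
    if (!is.null(center))
      return(cswo_solution(as.vector(center), ids, setdiff(seq_len(n), ids),
                           feasible = TRUE, method = "subset_ilp",
                           subsets_tried = s))
  }
  cswo_solution(NULL, integer(0), integer(0), feasible = FALSE,
                method = "subset_ilp", subsets_tried = ncol(subsets))
}
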