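#' Exhaustive center enumeration solver
#'
#' Enumerates candidate centers over the cross-product of per-column
#' occurring-symbol sets and returns a coverage-maximizing center.  The
#' column restriction is lossless: replacing a center symbol at position `p`
#' by a symbol that occurs at `p` in some input string never decreases
#' coverage, because a non-occurring symbol matches zero strings at `p`.
#' The maximum coverage over the restricted set therefore equals the maximum
#' over all `|alphabet|^l` centers, and the solver is exact.
#'
#' Enumeration order is lexicographic: columns are scanned left to right,
#' with each column's symbols in first-occurrence order (scanning strings by
#' id); ties among equal-coverage centers go to the first in this order.
#' Candidates are processed in vectorized batches.
#'
#' @param inst a [cswo_instance].
#' @param d,k override the instance's radius / outlier budget.
#' @param max_centers refuse to enumerate more than this many candidate
#'   centers (error of class `cswo_too_large`).
#' @param stop_at optional coverage level at which to stop early.  Useful
#'   when only the feasibility verdict matters (pass `n - k`): the verdict is
#'   still exact, but the reported `best_coverage` is then only a lower
#'   bound for the true maximum.
#' @return A [cswo_solution] with extra fields `best_coverage` (the maximum
#'   number of strings any candidate covers) and `n_centers` (candidates
#'   examined).  `feasible` is `TRUE` iff `best_coverage >= n - k`; the
#'   returned center and coverage sets are reported even when infeasible.
#' @examples
#' inst <- cswo_instance(c("AAT", "AAA", "TTT"), d = 1, k = 1)
#' enumerate_centers(inst)
#' @export
enumerate_centers <- function(inst, d = NULL, k = NULL,
                              max_centers = 2e6, stop_at = NULL) {
  stopifnot(is_cswo_instance(inst))
  d <- need_d(inst, d); k <- need_k(inst, k)
  mat <- inst$tokens
  n <- nrow(mat); ell <- ncol(mat)

  ## per-column occurring symbols, first-occurrence order
  columns <- lapply(seq_len(ell), function(j) unique(mat[, j]))
  sizes <- lengths(columns)
  total <- prod(sizes)
  if (total > max_centers)
    stop(structure(
      class = c("cswo_too_large", "error", "condition"),
      list(message = sprintf(
             "center search space has %.0f candidates, above the cap of %.0f",
             total, max_centers),
           call = sys.call(-1))))

  ## integer-encode strings per column for vectorized comparison
  enc <- vapply(seq_len(ell), function(j) match(mat[, j], columns[[j]]),
                integer(n))
  enc <- matrix(enc, nrow = n)  # n x ell even when n == 1

  ## strides for lexicographic order: column 1 most significant
  strides <- rev(cumprod(rev(c(sizes[-1L], 1))))

  best_cov <- -1L
  best_idx <- NA_real_
  examined <- 0
  batch <- 65536L
  idx0 <- 0
  while (idx0 < total) {
    nb <- min(batch, total - idx0)
    idx <- idx0 + seq_len(nb) - 1
    dist <- matrix(0L, nrow = nb, ncol = n)
    for (j in seq_len(ell)) {
      digit <- (idx %/% strides[j]) %% sizes[j] + 1
      dist <- dist + (matrix(digit, nrow = nb, ncol = n) !=
                      matrix(enc[, j], nrow = nb, ncol = n, byrow = TRUE))
    }
    cov <- rowSums(dist <= d)
    m <- max(cov)
    if (m > best_cov) {
      best_cov <- as.integer(m)
      best_idx <- idx[which.max(cov)]
    }
    examined <- examined + nb
    idx0 <- idx0 + nb
    if (!is.null(stop_at) && best_cov >= stop_at) break
  }

  center <- vapply(seq_len(ell), function(j) {
    columns[[j]][(best_idx %/% strides[j]) %% sizes[j] + 1]
  }, character(1))
  covered <- coverage(inst, center, d = d)
  feasible <- best_cov >= n - k
  cswo_solution(
    center = center,
    inliers = if (feasible) covered else integer(0),
    outliers = if (feasible) setdiff(seq_len(n), covered) else integer(0),
    feasible = feasible, method = "enumerate",
    best_coverage = best_cov, n_centers = examined)
}
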