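## Seeded generators.  Each generator is a pure function of its arguments:
## the RNG state is set from `seed` for the duration of the call and the
## caller's state is restored afterwards.  The random stream is consumed in
## a fixed, documented order so generated fixtures are stable.

with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## uniform draw of `size` elements from x, safe for length-1 x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Generate a planted-center CSWO instance with known ground truth
#'
#' Emulates the model's motivating scenario: an unknown center string, a
#' majority of strings sampled within radius `d` of it, and `k` outliers
#' placed strictly outside.  Each of the `n - k` inliers flips a uniform
#' number (0..`d`) of distinct positions of the center to different symbols;
#' each outlier flips exactly `d + outlier_margin` positions, so it sits at
#' exactly that distance and the inlier/outlier boundary is sharp.  Ids are
#' shuffled so the outliers are not last.  The random stream is consumed in
#' a fixed order: center, id shuffle, then strings in id order.
#'
#' @param n number of strings.
#' @param l string length.
#' @param d planted radius, `d + outlier_margin <= l`.
#' @param k number of outliers, `k <= n`.
#' @param alphabet symbols to draw from (at least 2).
#' @param seed integer seed; same seed, same instance.
#' @param outlier_margin how far beyond `d` each outlier sits (>= 1).
#' @return A list with `instance` (a [cswo_instance] carrying `d` and `k`)
#'   and `truth` (class `cswo_planted_truth`: `center`, `inlier_ids`,
#'   `outlier_ids`, `d`, `k`, `outlier_margin`, `seed`).  By construction
#'   `verify_solution(instance, truth-as-solution)` is `TRUE`.
#' @examples
#' gp <- generate_planted(8, 10, d = 2, k = 2, alphabet = c("A","C","G","T"),
#'                        seed = 1)
#' verify_solution(gp$instance, list(center = gp$truth$center,
#'                                   inliers = gp$truth$inlier_ids,
#'                                   outliers = gp$truth$outlier_ids))
#' @export
generate_planted <- function(n, l, d, k, alphabet, seed, outlier_margin = 1) {
  n <- check_count(n, "n"); l <- check_count(l, "l")
  d <- check_count(d, "d"); k <- check_count(k, "k")
  outlier_margin <- check_count(outlier_margin, "outlier_margin")
  alphabet <- unique(as.character(alphabet))
  if (length(alphabet) < 2L)
    stop("'alphabet' must contain at least 2 symbols", call. = FALSE)
  if (outlier_margin < 1L)
    stop("'outlier_margin' must be >= 1", call. = FALSE)
  if (d + outlier_margin > l)
    stop("need d + outlier_margin <= l so outliers fit in the string",
         call. = FALSE)
  if (k > n) stop("need k <= n", call. = FALSE)
  if (n < 1L) stop("need n >= 1", call. = FALSE)

  with_seed(seed, {
    center <- resample(alphabet, l, replace = TRUE)
    outlier_ids <- sort(resample(seq_len(n), k))
    tokens <- matrix(NA_character_, nrow = n, ncol = l)
    for (id in seq_len(n)) {
      flips <- if (id %in% outlier_ids) d + outlier_margin
               else resample(0:d, 1L)
      s <- center
      if (flips > 0L) {
        pos <- resample(seq_len(l), flips)
        for (p in pos) s[p] <- resample(setdiff(alphabet, center[p]), 1L)
      }
      tokens[id, ] <- s
    }
    inst <- cswo_instance(tokens, d = d, k = k, alphabet = alphabet,
                          names = sprintf("str%d", seq_len(n)))
    truth <- structure(
      list(center = center,
           inlier_ids = setdiff(seq_len(n), outlier_ids),
           outlier_ids = outlier_ids,
           d = d, k = k, outlier_margin = outlier_margin, seed = seed),
      class = "cswo_planted_truth")
    list(instance = inst, truth = truth)
  })
}

#' Generate an i.i.d. uniform random instance
#'
#' Every symbol is drawn uniformly and independently from the alphabet;
#' used for oracle-equivalence fuzzing of the solvers.
#'
#' @param n number of strings (>= 1).
#' @param l string length (>= 1).
#' @param alphabet symbols to draw from (>= 1).
#' @param seed integer seed.
#' @param d,k optional radius / budget to stamp on the instance.
#' @return A [cswo_instance].
#' @export
generate_random_instance <- function(n, l, alphabet, seed, d = NA, k = NA) {
  n <- check_count(n, "n"); l <- check_count(l, "l")
  if (n < 1L || l < 1L) stop("need n >= 1 and l >= 1", call. = FALSE)
  alphabet <- unique(as.character(alphabet))
  if (length(alphabet) < 1L)
    stop("'alphabet' must be non-empty", call. = FALSE)
  with_seed(seed, {
    tokens <- matrix(resample(alphabet, n * l, replace = TRUE),
                     nrow = n, ncol = l)
    cswo_instance(tokens, d = d, k = k, alphabet = alphabet,
                  names = sprintf("str%d", seq_len(n)))
  })
}

#' Generate a random graph, optionally with a planted clique
#'
#' Erdős–Rényi G(n, p) edges plus, when requested, all edges of a clique on
#' a uniformly chosen vertex subset.  Stream order: planted subset first,
#' then the pair coin flips in lexicographic pair order.
#'
#' @param n_vertices number of vertices.
#' @param edge_probability probability of each pair being an edge.
#' @param seed integer seed.
#' @param planted_clique_size optional size of a clique to plant.
#' @return A [cswo_graph]; when a clique is planted, the chosen vertices are
#'   attached as attribute `planted_clique`.
#' @export
random_graph <- function(n_vertices, edge_probability, seed,
                         planted_clique_size = NULL) {
  n_vertices <- check_count(n_vertices, "n_vertices")
  if (n_vertices < 1L) stop("'n_vertices' must be positive", call. = FALSE)
  if (!is.numeric(edge_probability) || edge_probability < 0 ||
      edge_probability > 1)
    stop("'edge_probability' must be in [0, 1]", call. = FALSE)
  if (!is.null(planted_clique_size)) {
    planted_clique_size <- check_count(planted_clique_size,
                                       "planted_clique_size")
    if (planted_clique_size > n_vertices)
      stop("'planted_clique_size' must be <= n_vertices", call. = FALSE)
  }
  with_seed(seed, {
    planted <- if (!is.null(planted_clique_size) && planted_clique_size >= 1L)
      sort(resample(seq_len(n_vertices), planted_clique_size))
    else integer(0)
    pairs <- if (n_vertices >= 2L) t(utils::combn(n_vertices, 2L))
             else matrix(integer(0), ncol = 2)
    keep <- stats::runif(nrow(pairs)) < edge_probability
    if (length(planted) >= 2L) {
      pc <- t(utils::combn(planted, 2L))
      keep <- keep | (paste(pairs[, 1L], pairs[, 2L]) %in%
                      paste(pc[, 1L], pc[, 2L]))
    }
    g <- cswo_graph(n_vertices, pairs[keep, , drop = FALSE])
    attr(g, "planted_clique") <- planted
    g
  })
}
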