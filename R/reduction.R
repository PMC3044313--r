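#' Undirected graphs for the CLIQUE reduction
#'
#' A minimal undirected graph: vertices are named `v1..v<n>`, edges are
#' unordered pairs stored with the smaller endpoint first.  Self-loops and
#' duplicate edges are rejected.
#'
#' @param n_vertices positive integer number of vertices.
#' @param edges a two-column matrix (or vector coercible to one, row-wise)
#'   of 1-based vertex pairs.
#' @return An object of class `cswo_graph` with fields `n_vertices` and
#'   `edges` (a matrix with columns `r`, `s`, `r < s`, rows in input order).
#' @examples
#' g <- cswo_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))
#' @export
cswo_graph <- function(n_vertices, edges) {
  n_vertices <- check_count(n_vertices, "n_vertices")
  if (n_vertices < 1L) stop("'n_vertices' must be positive", call. = FALSE)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    if (!is.matrix(edges)) edges <- matrix(as.integer(edges), ncol = 2,
                                           byrow = TRUE)
    storage.mode(edges) <- "integer"
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns", call. = FALSE)
  if (any(edges < 1L) || any(edges > n_vertices))
    stop("edge endpoints must lie in 1..n_vertices", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed", call. = FALSE)
  edges <- cbind(r = pmin(edges[, 1L], edges[, 2L]),
                 s = pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(edges))
    stop("duplicate edges are not allowed", call. = FALSE)
  structure(list(n_vertices = n_vertices, edges = edges),
            class = "cswo_graph")
}

#' @export
print.cswo_graph <- function(x, ...) {
  cat(sprintf("Undirected graph: %d vertices, %d edges\n",
              x$n_vertices, nrow(x$edges)))
  invisible(x)
}

#' Constructive reduction from CLIQUE to CSWO
#'
#' Builds the string-gadget instance whose feasibility encodes the presence
#' of a clique of size `t` in the graph.  Over an unbounded alphabet with
#' one symbol `v<r>` per vertex and one fresh symbol `c_<i>_<j>_<m>` per
#' produced string, the reduction emits, for every position pair
#' `1 <= i < j <= t` and every edge `e_m = (v_r, v_s)` (with `r < s`), the
#' length-`t` string carrying `v_r` at position `i`, `v_s` at position `j`,
#' and the string's own `c` symbol everywhere else.  The instance gets
#' radius `d = t - 2` and outlier budget `k = n_strings - t*(t-1)/2`, i.e.
#' exactly `n* = t*(t-1)/2` strings — one per clique edge — must be covered.
#' A feasible center is then forced to consist of `t` vertex symbols
#' (each `c` symbol appears in only one string, so a center using one could
#' never cover enough strings), and those `t` vertices are pairwise
#' adjacent: the instance is feasible iff the graph has a `t`-clique.
#'
#' Edges are indexed `m = 1, 2, ...` in lexicographic `(r, s)` order.
#'
#' @param g a [cswo_graph] with at least one edge.
#' @param t clique size, `t > 2` (smaller values make the construction
#'   degenerate).
#' @return A list of class `cswo_reduction` with elements `instance` (a
#'   [cswo_instance]) and `map` (a reduction map: `t`, `edge_order` — the
#'   edge matrix in index order —, `string_key` — a data frame of each
#'   string id's `(i, j, m)` triple —, `vertex_symbols`, `c_symbols`).
#' @examples
#' g <- cswo_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))
#' red <- reduce_clique(g, t = 3)
#' n_strings(red$instance)       # 12
#' red$instance$d                # 1
#' @export
reduce_clique <- function(g, t) {
  stopifnot(inherits(g, "cswo_graph"))
  t <- check_count(t, "t")
  if (t <= 2L)
    stop("the reduction requires t > 2 (smaller t is degenerate)",
         call. = FALSE)
  if (nrow(g$edges) == 0L)
    stop("the reduction requires a graph with at least one edge",
         call. = FALSE)

  edge_order <- g$edges[order(g$edges[, 1L], g$edges[, 2L]), , drop = FALSE]
  m_edges <- nrow(edge_order)
  pairs <- which(upper.tri(matrix(0, t, t)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]  # (i, j), i < j

  n_str <- nrow(pairs) * m_edges
  tokens <- matrix(NA_character_, nrow = n_str, ncol = t)
  key <- data.frame(id = seq_len(n_str), i = 0L, j = 0L, m = 0L)
  c_symbols <- character(n_str)
  id <- 0L
  for (pq in seq_len(nrow(pairs))) {
    i <- pairs[pq, 1L]; j <- pairs[pq, 2L]
    for (m in seq_len(m_edges)) {
      id <- id + 1L
      csym <- sprintf("c_%d_%d_%d", i, j, m)
      row <- rep(csym, t)
      row[i] <- sprintf("v%d", edge_order[m, 1L])
      row[j] <- sprintf("v%d", edge_order[m, 2L])
      tokens[id, ] <- row
      key$i[id] <- i; key$j[id] <- j; key$m[id] <- m
      c_symbols[id] <- csym
    }
  }
  rownames(tokens) <- sprintf("s_%d_%d_%d", key$i, key$j, key$m)
  vertex_symbols <- sprintf("v%d", seq_len(g$n_vertices))

  inst <- cswo_instance(tokens, d = t - 2L,
                        k = n_str - t * (t - 1L) %/% 2L,
                        alphabet = c(vertex_symbols, c_symbols))
  map <- structure(
    list(t = t, edge_order = edge_order, string_key = key,
         vertex_symbols = vertex_symbols, c_symbols = c_symbols),
    class = "cswo_reduction_map")
  structure(list(instance = inst, map = map), class = "cswo_reduction")
}

#' @export
print.cswo_reduction <- function(x, ...) {
  cat(sprintf("CLIQUE->CSWO reduction (t = %d):\n", x$map$t))
  print(x$instance)
  invisible(x)
}

#' Decode a CSWO center back to a vertex set
#'
#' A feasible center of a reduced instance contains only vertex symbols;
#' its `t` positions name the clique vertices.  A center containing any
#' per-string `c` symbol is rejected (it cannot be part of a valid clique
#' encoding).
#'
#' @param center the center string (token vector or [cswo_solution]).
#' @param map the `map` component of a [reduce_clique()] result (or the
#'   `cswo_reduction` itself).
#' @return Integer vector of `t` vertex ids in position order, or `NULL`
#'   when the center contains a non-vertex symbol.
#' @examples
#' g <- cswo_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))
#' red <- reduce_clique(g, 3)
#' decode_center(c("v1", "v2", "v3"), red$map)  # 1 2 3
#' @export
decode_center <- function(center, map) {
  if (inherits(map, "cswo_reduction")) map <- map$map
  stopifnot(inherits(map, "cswo_reduction_map"))
  if (inherits(center, "cswo_solution")) center <- center$center
  center <- as_tokens(center)
  if (length(center) != map$t)
    stop("length mismatch: center has ", length(center),
         " symbols, reduction uses t = ", map$t, call. = FALSE)
  ids <- match(center, map$vertex_symbols)
  if (anyNA(ids)) return(NULL)
  as.integer(ids)
}

#' Is a vertex set a clique?
#'
#' @param g a [cswo_graph].
#' @param vertices distinct vertex ids.
#' @return `TRUE` iff every pair of the given vertices is an edge of `g`
#'   (vacuously true for fewer than two vertices).
#' @export
is_clique <- function(g, vertices) {
  stopifnot(inherits(g, "cswo_graph"))
  vertices <- as.integer(vertices)
  if (anyDuplicated(vertices))
    stop("'vertices' must be distinct", call. = FALSE)
  if (any(vertices < 1L) || any(vertices > g$n_vertices))
    stop("'vertices' out of range 1..n_vertices", call. = FALSE)
  if (length(vertices) < 2L) return(TRUE)
  have <- paste(g$edges[, 1L], g$edges[, 2L])
  pr <- utils::combn(sort(vertices), 2L)
  all(paste(pr[1L, ], pr[2L, ]) %in% have)
}
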