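#' Closest String with Outliers (CSWO) problem instances
#'
#' An instance bundles `n` equal-length strings over a common alphabet with a
#' Hamming radius `d` and an outlier budget `k`.  A feasible solution is a
#' center string within Hamming distance `d` of at least `n - k` of the input
#' strings; the remaining (at most `k`) strings are the outliers.
#'
#' Symbols are opaque tokens, so alphabets are not limited to single
#' characters: `"A"` and `"c_1_2_3"` are both legal symbols.  Strings of
#' single-character symbols may be given as plain character scalars
#' (`"ACGT"`), which are split into one token per character.  String identity
#' is positional: duplicated input strings are distinct instance members.
#'
#' @param strings the input strings: a character vector (each element split
#'   into single-character tokens), a list of character vectors (one token per
#'   element), or a character matrix with one row per string and one token per
#'   cell.
#' @param d nonnegative integer Hamming radius, or `NA` if undecided
#'   (required before solving; `d > l` is legal and makes every string an
#'   inlier).
#' @param k nonnegative integer outlier budget, or `NA` if undecided
#'   (`k >= n` makes the instance trivially feasible).
#' @param alphabet optional character vector of symbols; the observed symbols
#'   are always included, so this only adds extra symbols.
#' @param names optional display names for the strings.
#'
#' @return An object of class `cswo_instance`: a list with elements `tokens`
#'   (an `n x l` character matrix), `alphabet`, `d` and `k`.
#' @examples
#' inst <- cswo_instance(c("ACGT", "ACGA", "TCGA"), d = 1, k = 1)
#' inst
#' @export
cswo_instance <- function(strings, d = NA, k = NA, alphabet = NULL,
                          names = NULL) {
  tokens <- as_token_matrix(strings)
  check_tokens(tokens)
  if (!is.null(names)) {
    if (length(names) != nrow(tokens))
      stop("'names' must have one entry per string", call. = FALSE)
    rownames(tokens) <- names
  }
  d <- check_count(d, "d", allow_na = TRUE)
  k <- check_count(k, "k", allow_na = TRUE)
  observed <- unique(as.vector(t(tokens)))
  alphabet <- unique(c(observed, as.character(alphabet %||% character())))
  structure(
    list(tokens = tokens, alphabet = alphabet, d = d, k = k),
    class = "cswo_instance"
  )
}

#' @export
print.cswo_instance <- function(x, ...) {
  n <- nrow(x$tokens)
  cat(sprintf(
    "CSWO instance: %d string%s of length %d over %d symbols (d = %s, k = %s)\n",
    n, if (n == 1) "" else "s", ncol(x$tokens), length(x$alphabet),
    format(x$d), format(x$k)
  ))
  show <- utils::head(seq_len(n), 10L)
  nm <- rownames(x$tokens) %||% paste0("s", show)
  for (i in show)
    cat(sprintf("  %s: %s\n", nm[i], paste(x$tokens[i, ], collapse = " ")))
  if (n > 10) cat(sprintf("  ... and %d more\n", n - 10))
  invisible(x)
}

#' @rdname cswo_instance
#' @param x object to test.
#' @export
is_cswo_instance <- function(x) inherits(x, "cswo_instance")

#' Number of strings and string length of an instance
#'
#' @param inst a [cswo_instance].
#' @return `n_strings()` the number of strings `n`; `string_length()` the
#'   common length `l`.
#' @export
n_strings <- function(inst) nrow(inst$tokens)

#' @rdname n_strings
#' @export
string_length <- function(inst) ncol(inst$tokens)

## ---- token plumbing ---------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert string input to a token vector
#'
#' A character scalar is split into single-character tokens; a character
#' vector of length > 1 is taken as one token per element.
#' @param x character scalar or character vector of tokens.
#' @return character vector of tokens.
#' @export
as_tokens <- function(x) {
  x <- as.character(x)
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  x
}

as_token_matrix <- function(strings) {
  if (is.matrix(strings)) {
    storage.mode(strings) <- "character"
    return(strings)
  }
  if (is.character(strings)) {
    nm <- names(strings)
    strings <- lapply(strings, as_tokens)
    names(strings) <- nm
  }
  if (!is.list(strings))
    stop("'strings' must be a character vector, list of token vectors, ",
         "or character matrix", call. = FALSE)
  if (length(strings) == 0L)
    stop("an instance needs at least one string", call. = FALSE)
  lens <- lengths(strings)
  if (length(unique(lens)) != 1L)
    stop("all strings must share one length; got lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, lapply(strings, as.character))
  rownames(mat) <- names(strings)
  mat
}

check_tokens <- function(mat) {
  if (ncol(mat) < 1L)
    stop("strings must have length >= 1", call. = FALSE)
  bad <- !nzchar(mat) | grepl("[[:space:]>]", mat)
  if (any(bad))
    stop("symbols must be non-empty and contain no whitespace or '>': ",
         paste(utils::head(unique(mat[bad]), 3), collapse = ", "),
         call. = FALSE)
  invisible(mat)
}

check_count <- function(x, what, allow_na = FALSE) {
  if (length(x) != 1L)
    stop("'", what, "' must be a single value", call. = FALSE)
  if (is.na(x)) {
    if (allow_na) return(NA_integer_)
    stop("'", what, "' is required", call. = FALSE)
  }
  if (!is.numeric(x) || x < 0 || x != floor(x))
    stop("'", what, "' must be a nonnegative integer", call. = FALSE)
  as.integer(x)
}

## requires a concrete d (resp. k) either on the instance or supplied
need_d <- function(inst, d) check_count(if (is.null(d)) inst$d else d, "d")
need_k <- function(inst, k) check_count(if (is.null(k)) inst$k else k, "k")

## ---- distances --------------------------------------------------------

#' Hamming distance between two equal-length strings
#'
#' @param x,y strings as character scalars (split per character) or token
#'   vectors; see [as_tokens()].
#' @return The number of positions at which `x` and `y` differ.
#' @examples
#' hamming_dist("AAA", "ATA")   # 1
#' hamming_dist(c("v1", "v2", "v3"), c("c_2_3_4", "v2", "v3"))  # 1
#' @export
hamming_dist <- function(x, y) {
  x <- as_tokens(x); y <- as_tokens(y)
  check_equal_length(x, y)
  sum(x != y)
}

#' Positions at which two equal-length strings differ
#'
#' @inheritParams hamming_dist
#' @return Strictly increasing integer vector of 1-based mismatch positions;
#'   its length equals [hamming_dist()].
#' @export
mismatch_positions <- function(x, y) {
  x <- as_tokens(x); y <- as_tokens(y)
  check_equal_length(x, y)
  which(x != y)
}

check_equal_length <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y), " symbols",
         call. = FALSE)
  invisible(NULL)
}

## ---- solutions --------------------------------------------------------

#' Construct a CSWO solution object
#'
#' Solvers return these; `feasible = FALSE` encodes the "not found" verdict
#' (for decision solvers) while still carrying any best-effort information
#' such as the best coverage seen.
#'
#' @param center token vector (the center string), or `NULL` when infeasible.
#' @param inliers,outliers integer vectors of 1-based string ids partitioning
#'   `1..n` (empty when infeasible).
#' @param feasible logical verdict.
#' @param method solver name.
#' @param ... further fields (e.g. `stats`, `best_coverage`) stored as-is.
#' @return An object of class `cswo_solution`.
#' @export
cswo_solution <- function(center, inliers, outliers, feasible = TRUE,
                          method = NA_character_, ...) {
  structure(
    list(center = if (is.null(center)) NULL else as_tokens(center),
         inliers = as.integer(inliers), outliers = as.integer(outliers),
         feasible = isTRUE(feasible), method = method, ...),
    class = "cswo_solution"
  )
}

#' @export
print.cswo_solution <- function(x, ...) {
  if (!x$feasible) {
    cat("CSWO solution: not found (infeasible at the given d, k)\n")
    if (!is.null(x$best_coverage))
      cat(sprintf("  best coverage seen: %d\n", x$best_coverage))
    return(invisible(x))
  }
  cat("CSWO solution (", x$method, ")\n", sep = "")
  cat("  center:  ", paste(x$center, collapse = " "), "\n", sep = "")
  cat("  inliers: ", length(x$inliers), " string(s): ",
      paste(x$inliers, collapse = ", "), "\n", sep = "")
  cat("  outliers:", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
      else " none", "\n")
  invisible(x)
}

#' @method summary cswo_solution
#' @export
summary.cswo_solution <- function(object, ...) {
  print(object)
  if (!is.null(object$stats)) {
    s <- object$stats
    cat(sprintf(
      "  search: %d node(s) visited (%d outlier, %d position branches)\n",
      sum(s$nodes_per_start), s$outlier_branches, s$position_branches))
  }
  invisible(object)
}

#' Verify a CSWO solution against an instance
#'
#' Checks the full solution contract: `inliers` and `outliers` partition
#' `1..n`, at most `k` outliers, and every inlier is within Hamming distance
#' `d` of the center.
#'
#' @param inst a [cswo_instance] with concrete `d` and `k` (or supply them).
#' @param sol a [cswo_solution] or a list with `center`, `inliers`,
#'   `outliers`.
#' @param d,k override the instance's radius / budget.
#' @return `TRUE` or `FALSE`.  A center of the wrong length is an error, not
#'   `FALSE`.
#' @export
verify_solution <- function(inst, sol, d = NULL, k = NULL) {
  stopifnot(is_cswo_instance(inst))
  d <- need_d(inst, d); k <- need_k(inst, k)
  n <- n_strings(inst)
  center <- as_tokens(sol$center)
  if (length(center) != string_length(inst))
    stop("length mismatch: center has ", length(center),
         " symbols, instance strings have ", string_length(inst),
         call. = FALSE)
  inl <- as.integer(sol$inliers); out <- as.integer(sol$outliers)
  ids <- sort(c(inl, out))
  if (length(ids) != n || any(ids != seq_len(n)) || anyDuplicated(c(inl, out)))
    return(FALSE)
  if (length(out) > k) return(FALSE)
  for (i in inl)
    if (sum(center != inst$tokens[i, ]) > d) return(FALSE)
  TRUE
}

#' String ids covered by a center
#'
#' @param inst a [cswo_instance].
#' @param center a center string (character scalar or token vector).
#' @param d override the instance radius.
#' @return Increasing integer vector of the ids `i` with
#'   `hamming_dist(center, strings[i]) <= d`.
#' @export
coverage <- function(inst, center, d = NULL) {
  stopifnot(is_cswo_instance(inst))
  d <- need_d(inst, d)
  center <- as_tokens(center)
  if (length(center) != string_length(inst))
    stop("length mismatch: center has ", length(center),
         " symbols, instance strings have ", string_length(inst),
         call. = FALSE)
  dists <- rowSums(inst$tokens != matrix(center, nrow = n_strings(inst),
                                         ncol = string_length(inst),
                                         byrow = TRUE))
  unname(which(dists <= d))
}

#' Per-string Hamming distances from a center
#'
#' @inheritParams coverage
#' @return Integer vector of length `n`.
#' @export
center_distances <- function(inst, center) {
  stopifnot(is_cswo_instance(inst))
  center <- as_tokens(center)
  if (length(center) != string_length(inst))
    stop("length mismatch: center has ", length(center),
         " symbols, instance strings have ", string_length(inst),
         call. = FALSE)
  as.integer(rowSums(inst$tokens != matrix(center, nrow = n_strings(inst),
                                           ncol = string_length(inst),
                                           byrow = TRUE)))
}
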