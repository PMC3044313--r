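## Instance, graph and config file formats.
##
## Two instance formats are supported.  FASTA covers the biological case
## where every symbol is a single character.  The "tokens" dialect covers
## arbitrary token alphabets (as produced by the CLIQUE reduction):
##   # comment lines start with '#'
##   @d 1            optional radius directive
##   @k 9            optional outlier-budget directive
##   @alphabet x y   optional extra symbols beyond the observed ones
##   v1 v2 c_1_2_1   every other non-empty line is one string,
##                   whitespace-separated tokens
## Graphs are plain edge lists: an optional header "p <n_vertices>", then
## one 1-based edge "u v" per line.

format_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, if (is.na(line)) "?" else line, msg),
       call. = FALSE)
}

#' Read a CSWO instance from FASTA or tokens format
#'
#' @param path file to read.
#' @param format `"fasta"`, `"tokens"`, or `"auto"` (FASTA when the file
#'   extension is `.fa/.fasta/.fna/.ffn/.faa` or the first non-blank
#'   character is `>`).
#' @return A [cswo_instance]; `d` and `k` come from `@d` / `@k` directives
#'   when present (tokens format), otherwise `NA`.
#' @export
read_strings <- function(path, format = c("auto", "fasta", "tokens")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    if (grepl("\\.(fa|fasta|fna|ffn|faa)$", path, ignore.case = TRUE)) {
      format <- "fasta"
    } else {
      first <- readLines(path, n = 50L, warn = FALSE)
      first <- first[nzchar(trimws(first))]
      format <- if (length(first) && startsWith(trimws(first[1L]), ">"))
        "fasta" else "tokens"
    }
  }
  if (format == "fasta") read_strings_fasta(path) else read_strings_tokens(path)
}

read_strings_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) format_error(path, NA, "empty FASTA file")
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L)
    format_error(path, NA, paste0(
      "all records must share one length; got lengths ",
      paste(unique(lens), collapse = ", ")))
  cswo_instance(as.character(set), names = names(set))
}

read_strings_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  d <- NA; k <- NA; extra <- character(0)
  strs <- list(); lineno <- integer(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- strsplit(line, "[[:space:]]+")[[1L]]
    if (startsWith(line, "@")) {
      key <- toks[1L]
      if (key == "@d" || key == "@k") {
        val <- suppressWarnings(as.integer(toks[2L]))
        if (length(toks) != 2L || is.na(val) || val < 0L)
          format_error(path, i, paste0("'", key,
                       "' needs one nonnegative integer"))
        if (key == "@d") d <- val else k <- val
      } else if (key == "@alphabet") {
        extra <- c(extra, toks[-1L])
      } else {
        format_error(path, i, paste0("unknown directive '", key, "'"))
      }
      next
    }
    strs[[length(strs) + 1L]] <- toks
    lineno <- c(lineno, i)
  }
  if (length(strs) == 0L) format_error(path, NA, "no strings in file")
  lens <- lengths(strs)
  if (length(unique(lens)) != 1L) {
    bad <- lineno[lens != lens[1L]]
    format_error(path, bad[1L], sprintf(
      "string has %d tokens, expected %d (as on line %d)",
      lens[lens != lens[1L]][1L], lens[1L], lineno[1L]))
  }
  cswo_instance(strs, d = d, k = k, alphabet = extra)
}

#' Write a CSWO instance to FASTA or tokens format
#'
#' The tokens writer emits a canonical form (directives first, then one
#' string per line) that round-trips bit-exactly through [read_strings()].
#' FASTA is only available when every symbol is a single character.
#'
#' @param inst a [cswo_instance].
#' @param path output file.
#' @param format `"tokens"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_strings <- function(inst, path, format = c("tokens", "fasta")) {
  stopifnot(is_cswo_instance(inst))
  format <- match.arg(format)
  if (format == "fasta") {
    if (any(nchar(inst$tokens) != 1L))
      stop("FASTA needs single-character symbols; ",
           "use the tokens format for this instance", call. = FALSE)
    seqs <- apply(inst$tokens, 1L, paste, collapse = "")
    names(seqs) <- rownames(inst$tokens) %||%
      sprintf("str%d", seq_len(n_strings(inst)))
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
    return(invisible(path))
  }
  lines <- character(0)
  if (!is.na(inst$d)) lines <- c(lines, paste("@d", inst$d))
  if (!is.na(inst$k)) lines <- c(lines, paste("@k", inst$k))
  observed <- unique(as.vector(t(inst$tokens)))
  extra <- setdiff(inst$alphabet, observed)
  if (length(extra))
    lines <- c(lines, paste("@alphabet", paste(extra, collapse = " ")))
  lines <- c(lines, apply(inst$tokens, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected graph from an edge-list file
#'
#' Format: optional comments (`#`), an optional header `p <n_vertices>`,
#' then one edge `u v` per line (1-based; order within a line does not
#' matter).  Without a header the vertex count is the largest endpoint.
#'
#' @param path file to read.
#' @return A [cswo_graph].
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nv <- NA_integer_
  edges <- matrix(integer(0), ncol = 2)
  seen <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- strsplit(line, "[[:space:]]+")[[1L]]
    if (toks[1L] == "p") {
      val <- suppressWarnings(as.integer(toks[2L]))
      if (length(toks) != 2L || is.na(val) || val < 1L)
        format_error(path, i, "'p' header needs one positive integer")
      nv <- val
      next
    }
    uv <- suppressWarnings(as.integer(toks))
    if (length(uv) != 2L || anyNA(uv))
      format_error(path, i, "expected an edge 'u v'")
    if (uv[1L] == uv[2L]) format_error(path, i, "self-loop")
    if (!is.na(nv) && any(uv < 1L | uv > nv))
      format_error(path, i,
                   sprintf("endpoint out of range 1..%d", nv))
    if (any(uv < 1L)) format_error(path, i, "endpoints must be >= 1")
    key <- paste(min(uv), max(uv))
    if (key %in% seen) format_error(path, i, paste("duplicate edge", key))
    seen <- c(seen, key)
    edges <- rbind(edges, c(min(uv), max(uv)))
  }
  if (is.na(nv)) nv <- if (nrow(edges)) max(edges) else 1L
  cswo_graph(nv, edges)
}

#' Write a graph as an edge list
#'
#' @param g a [cswo_graph].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "cswo_graph"))
  writeLines(c(paste("p", g$n_vertices),
               apply(g$edges, 1L, paste, collapse = " ")),
             path)
  invisible(path)
}

#' Write planted ground truth as a key-value sidecar file
#'
#' @param truth the `truth` component of [generate_planted()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cswo_planted_truth"))
  writeLines(c(
    paste("center:", paste(truth$center, collapse = " ")),
    paste("inliers:", paste(truth$inlier_ids, collapse = " ")),
    paste("outliers:", paste(truth$outlier_ids, collapse = " ")),
    paste("d:", truth$d), paste("k:", truth$k),
    paste("outlier_margin:", truth$outlier_margin),
    paste("seed:", truth$seed)), path)
  invisible(path)
}

## key = value config (ilp.backend, enumerate.max_centers,
## subset.max_subsets); unknown keys rejected so typos surface
read_cswo_config <- function(path) {
  defaults <- list(ilp.backend = "branchbound",
                   enumerate.max_centers = 2e6,
                   subset.max_subsets = 1e5)
  if (is.null(path) || !file.exists(path)) return(defaults)
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) format_error(path, i, "expected 'key = value'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(defaults))
      format_error(path, i, paste0("unknown config key '", key, "'"))
    if (key == "ilp.backend") {
      if (val != "branchbound")
        format_error(path, i, paste0("unsupported ilp.backend '", val,
                     "' (available: branchbound)"))
      defaults[[key]] <- val
    } else {
      defaults[[key]] <- as.numeric(val)
    }
  }
  defaults
}
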