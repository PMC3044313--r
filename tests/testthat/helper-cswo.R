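# Shared fixtures and the independent brute-force oracle used to check the
# solvers.  The oracle enumerates the FULL |alphabet|^l center space with
# plain loops -- deliberately sharing no code with the package's
# column-restricted, batched enumeration.

fig1_graph <- function() {
  cswo_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))
}

fig1_reduction <- function() reduce_clique(fig1_graph(), t = 3)

oracle_best_coverage <- function(inst, d = inst$d) {
  ell <- string_length(inst)
  cand <- as.matrix(expand.grid(rep(list(inst$alphabet), ell),
                                stringsAsFactors = FALSE))
  best <- 0L
  for (r in seq_len(nrow(cand))) {
    cov <- 0L
    for (i in seq_len(n_strings(inst)))
      if (sum(cand[r, ] != inst$tokens[i, ]) <= d) cov <- cov + 1L
    if (cov > best) best <- cov
  }
  best
}

oracle_feasible <- function(inst, d = inst$d, k = inst$k) {
  oracle_best_coverage(inst, d) >= n_strings(inst) - k
}

# all n-tuples over a binary alphabet of length l, as instances
all_binary_instances <- function(n, l, alphabet = c("A", "B")) {
  per <- length(alphabet)^l
  word <- function(idx) {  # idx in 0..per-1 -> token vector
    vapply(seq_len(l), function(p)
      alphabet[(idx %/% length(alphabet)^(p - 1L)) %% length(alphabet) + 1L],
      character(1))
  }
  words <- lapply(0:(per - 1L), word)
  tuples <- expand.grid(rep(list(seq_len(per)), n))
  lapply(seq_len(nrow(tuples)), function(r)
    cswo_instance(do.call(rbind, words[as.integer(tuples[r, ])]),
                  alphabet = alphabet))
}

random_token_pair <- function(ell, alphabet) {
  list(x = sample(alphabet, ell, replace = TRUE),
       y = sample(alphabet, ell, replace = TRUE))
}
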