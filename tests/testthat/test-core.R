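test_that("hamming distance counts differing positions", {
  expect_identical(hamming_dist("AAA", "AAA"), 0L)
  expect_identical(hamming_dist("AAA", "ATA"), 1L)
  # token alphabets: gadget string vs the clique center differ only in the
  # padding position
  expect_identical(
    hamming_dist(c("v1", "v2", "v3"), c("c_2_3_4", "v2", "v3")), 1L)
  expect_error(hamming_dist("AA", "AAA"), "length mismatch")
})

test_that("hamming distance is a metric on equal-length strings", {
  set.seed(7)
  for (rep in 1:50) {
    ell <- sample(1:8, 1)
    ab <- c("A", "C", "G", "T")
    x <- sample(ab, ell, replace = TRUE)
    y <- sample(ab, ell, replace = TRUE)
    z <- sample(ab, ell, replace = TRUE)
    expect_gte(hamming_dist(x, y), 0L)
    expect_identical(hamming_dist(x, y) == 0L, identical(x, y))
    expect_identical(hamming_dist(x, y), hamming_dist(y, x))
    expect_lte(hamming_dist(x, z),
               hamming_dist(x, y) + hamming_dist(y, z))
  }
})

test_that("mismatch_positions lists the differing positions in order", {
  expect_identical(mismatch_positions("AAA", "AAA"), integer(0))
  expect_identical(mismatch_positions("ACGT", "AGGA"), c(2L, 4L))
  expect_error(mismatch_positions("A", "AA"), "length mismatch")
  set.seed(11)
  for (rep in 1:40) {
    p <- random_token_pair(sample(2:10, 1), c("A", "B", "C"))
    pos <- mismatch_positions(p$x, p$y)
    expect_identical(length(pos), as.integer(hamming_dist(p$x, p$y)))
    expect_true(all(diff(pos) > 0))
    expect_true(all(p$x[pos] != p$y[pos]))
  }
})

test_that("instances validate their strings and derive the alphabet", {
  inst <- cswo_instance(c("ACG", "ACT"), d = 1, k = 0)
  expect_identical(n_strings(inst), 2L)
  expect_identical(string_length(inst), 3L)
  expect_setequal(inst$alphabet, c("A", "C", "G", "T"))
  expect_error(cswo_instance(c("AC", "ACT")), "share one length")
  expect_error(cswo_instance(list(c("a b", "c"))), "whitespace")
  expect_error(cswo_instance(c("AC", "AC"), d = -1), "nonnegative")
  # duplicates are distinct members
  inst2 <- cswo_instance(c("AA", "AA"), d = 0, k = 0)
  expect_identical(n_strings(inst2), 2L)
})

test_that("verify_solution enforces the full solution contract", {
  red <- fig1_reduction()
  inst <- red$instance
  sol <- list(center = c("v1", "v2", "v3"),
              inliers = c(1L, 6L, 12L),
              outliers = setdiff(1:12, c(1L, 6L, 12L)))
  expect_true(verify_solution(inst, sol))

  ident <- cswo_instance(c("AAA", "AAA"), d = 0, k = 0)
  expect_true(verify_solution(
    ident, list(center = "AAA", inliers = 1:2, outliers = integer(0))))
  expect_false(verify_solution(
    ident, list(center = "ATA", inliers = 1:2, outliers = integer(0))))
  # malformed partitions fail, wrong-length centers error
  expect_false(verify_solution(
    ident, list(center = "AAA", inliers = 1L, outliers = integer(0))))
  expect_false(verify_solution(
    ident, list(center = "AAA", inliers = 1:2, outliers = 2L)))
  expect_error(verify_solution(
    ident, list(center = "AA", inliers = 1:2, outliers = integer(0))),
    "length mismatch")
})

test_that("verify_solution is monotone in d and k", {
  set.seed(23)
  for (rep in 1:20) {
    inst <- generate_random_instance(4, 4, c("A", "C"), seed = rep)
    center <- sample(c("A", "C"), 4, replace = TRUE)
    d <- sample(0:3, 1); k <- sample(0:3, 1)
    cov <- coverage(inst, center, d = d)
    sol <- list(center = center, inliers = cov,
                outliers = setdiff(1:4, cov))
    if (verify_solution(inst, sol, d = d, k = k)) {
      expect_true(verify_solution(inst, sol, d = d + 1, k = k))
      expect_true(verify_solution(inst, sol, d = d, k = k + 1))
    }
  }
})

test_that("coverage returns exactly the ids within radius", {
  red <- fig1_reduction()
  expect_identical(length(coverage(red$instance, c("v1", "v2", "v3"))), 3L)
  inst <- cswo_instance(c("ACGT", "TTTT", "ACGA"))
  # d = l covers everything
  expect_identical(coverage(inst, "GGGG", d = 4), 1:3)
  set.seed(31)
  for (rep in 1:20) {
    inst <- generate_random_instance(6, 5, c("A", "C", "G"), seed = 100 + rep)
    center <- sample(c("A", "C", "G"), 5, replace = TRUE)
    d <- sample(0:5, 1)
    brute <- which(vapply(seq_len(6), function(i)
      hamming_dist(center, inst$tokens[i, ]) <= d, logical(1)))
    expect_identical(coverage(inst, center, d = d), brute)
    # monotone nondecreasing in d
    expect_true(all(coverage(inst, center, d = d) %in%
                    coverage(inst, center, d = d + 1)))
  }
})
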