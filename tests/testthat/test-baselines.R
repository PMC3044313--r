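test_that("enumerate_centers is exact and the column restriction is lossless", {
  ident <- cswo_instance(c("ACG", "ACG"), d = 0, k = 0)
  sol <- enumerate_centers(ident)
  expect_true(sol$feasible)
  expect_identical(sol$center, c("A", "C", "G"))
  expect_identical(sol$best_coverage, 2L)

  red <- fig1_reduction()
  gsol <- enumerate_centers(red$instance)
  expect_identical(gsol$best_coverage, 3L)
  expect_identical(gsol$center, c("v1", "v2", "v3"))

  # against the unrestricted full-alphabet brute force
  set.seed(53)
  for (rep in 1:30) {
    inst <- generate_random_instance(sample(2:5, 1), sample(1:4, 1),
                                     c("A", "B"), seed = 4000 + rep)
    d <- sample(0:2, 1)
    sol <- enumerate_centers(inst, d = d, k = 0)
    expect_identical(sol$best_coverage, oracle_best_coverage(inst, d))
  }
})

test_that("enumerate_centers best coverage is monotone in d", {
  set.seed(59)
  inst <- generate_random_instance(6, 5, c("A", "C", "G", "T"), seed = 99)
  covs <- vapply(0:5, function(d)
    enumerate_centers(inst, d = d, k = 0)$best_coverage, integer(1))
  expect_true(all(diff(covs) >= 0))
  expect_identical(covs[6], 6L)   # d = l covers all
})

test_that("enumerate_centers refuses oversized search spaces by name", {
  inst <- generate_random_instance(8, 10, c("A", "C", "G", "T"), seed = 5)
  err <- tryCatch(enumerate_centers(inst, d = 1, k = 0, max_centers = 100),
                  error = identity)
  expect_s3_class(err, "cswo_too_large")
  expect_match(conditionMessage(err), "candidates, above the cap")
})

test_that("closest_string_ilp solves the 0/1 program exactly", {
  expect_identical(as.vector(closest_string_ilp(c("AC", "AC"), d = 0)),
                   c("A", "C"))
  center <- closest_string_ilp(c("AA", "TT"), d = 1)
  expect_false(is.null(center))
  expect_lte(hamming_dist(center, "AA"), 1)
  expect_lte(hamming_dist(center, "TT"), 1)
  expect_null(closest_string_ilp(c("AA", "TT"), d = 0))

  # feasibility agrees with enumeration at k = 0
  set.seed(61)
  for (rep in 1:30) {
    inst <- generate_random_instance(sample(2:5, 1), sample(1:5, 1),
                                     c("A", "C", "G"), seed = 5000 + rep)
    d <- sample(0:3, 1)
    center <- closest_string_ilp(inst$tokens, d)
    enum <- enumerate_centers(inst, d = d, k = 0)
    expect_identical(!is.null(center), enum$feasible)
    if (!is.null(center))
      expect_true(all(center_distances(inst, as.vector(center)) <= d))
  }
})

test_that("solve_subset_ilp scans inlier subsets in lexicographic order", {
  # k = 0 reduces to a single closest-string call
  inst0 <- cswo_instance(c("ACA", "ACT"), d = 1, k = 0)
  sol0 <- solve_subset_ilp(inst0)
  expect_true(sol0$feasible)
  expect_identical(sol0$inliers, 1:2)
  expect_identical(sol0$subsets_tried, 1L)

  inst <- cswo_instance(c("AA", "AA", "TT"), d = 0, k = 1)
  sol <- solve_subset_ilp(inst)
  expect_true(sol$feasible)
  expect_identical(sol$inliers, c(1L, 2L))   # first feasible subset
  expect_identical(sol$outliers, 3L)

  red <- fig1_reduction()
  gsol <- solve_subset_ilp(red$instance)
  expect_true(gsol$feasible)
  expect_identical(rownames(red$instance$tokens)[gsol$inliers],
                   c("s_1_2_1", "s_1_3_2", "s_2_3_4"))

  err <- tryCatch(solve_subset_ilp(inst, max_subsets = 2), error = identity)
  expect_s3_class(err, "cswo_too_large")
})

test_that("the three exact solvers agree on feasibility", {
  set.seed(67)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    inst <- generate_random_instance(n, sample(2:5, 1),
                                     c("A", "C", "G", "T"),
                                     seed = 6000 + rep)
    d <- sample(0:2, 1); k <- sample(0:2, 1)
    vb <- solve_branching(inst, d, k)$feasible
    ve <- enumerate_centers(inst, d, k)$feasible
    vi <- solve_subset_ilp(inst, d, k)$feasible
    expect_identical(vb, ve)
    expect_identical(ve, vi)
  }
})
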