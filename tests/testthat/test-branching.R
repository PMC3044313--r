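test_that("branching solver handles immediate and infeasible cases", {
  ident <- cswo_instance(c("AAA", "AAA"), d = 0, k = 0)
  sol <- solve_branching(ident)
  expect_true(sol$feasible)
  expect_identical(sol$center, c("A", "A", "A"))
  expect_identical(sol$inliers, 1:2)

  far <- cswo_instance(c("AAA", "TTT"), d = 0, k = 0)
  expect_false(solve_branching(far)$feasible)

  # degenerate budgets
  expect_true(solve_branching(far, d = 0, k = 2)$feasible)   # n - k <= 0
  expect_true(solve_branching(far, d = 3, k = 0)$feasible)   # d >= l
})

test_that("multi-start repair finds solutions the s_1 start would miss", {
  # s_1 must be the outlier, and it is 10 changes away from the only
  # feasible center -- far beyond the delta_d = 0 budget
  inst <- cswo_instance(c(strrep("A", 10), strrep("T", 10), strrep("T", 10)),
                        d = 0, k = 1)
  expect_true(oracle_feasible(inst))      # independent confirmation
  sol <- solve_branching(inst)
  expect_true(sol$feasible)
  expect_identical(sol$center, rep("T", 10))
  expect_identical(sol$outliers, 1L)
  expect_true(verify_solution(inst, sol))
})

test_that("branching recovers the clique strings of the gadget instance", {
  red <- fig1_reduction()
  sol <- solve_branching(red$instance)
  expect_true(sol$feasible)
  expect_identical(length(sol$inliers), 3L)
  expect_true(verify_solution(red$instance, sol))
  # the only size-3 coverable subset is the clique's edge strings
  expect_identical(rownames(red$instance$tokens)[sol$inliers],
                   c("s_1_2_1", "s_1_3_2", "s_2_3_4"))
})

test_that("feasibility verdict matches the brute-force oracle on binary fuzz", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(2:5, 1); ell <- sample(1:4, 1)
    inst <- generate_random_instance(n, ell, c("A", "B"), seed = 1000 + rep)
    d <- sample(0:2, 1); k <- sample(0:2, 1)
    sol <- solve_branching(inst, d = d, k = k)
    expect_identical(sol$feasible, oracle_feasible(inst, d, k),
                     info = sprintf("rep=%d n=%d l=%d d=%d k=%d",
                                    rep, n, ell, d, k))
    if (sol$feasible) expect_true(verify_solution(inst, sol, d = d, k = k))
  }
})

test_that("feasibility is monotone in the budgets", {
  set.seed(43)
  for (rep in 1:25) {
    inst <- generate_random_instance(sample(2:6, 1), sample(2:5, 1),
                                     c("A", "C", "G", "T"),
                                     seed = 2000 + rep)
    d <- sample(0:2, 1); k <- sample(0:2, 1)
    if (solve_branching(inst, d = d, k = k)$feasible) {
      expect_true(solve_branching(inst, d = d + 1, k = k)$feasible)
      expect_true(solve_branching(inst, d = d, k = k + 1)$feasible)
    }
  }
})

test_that("minimize_d finds the smallest feasible radius with a witness", {
  ident <- cswo_instance(c("AAAA", "AAAA"))
  expect_identical(minimize_d(ident, k = 0)$d, 0L)

  inst <- cswo_instance(c("AAAA", "AAAT", "TTTT"))
  res <- minimize_d(inst, k = 1)
  expect_identical(res$d, 1L)
  expect_identical(res$solution$outliers, 3L)   # the TTTT string
  expect_true(verify_solution(inst, res$solution, d = 1, k = 1))
  # oracle agreement: infeasible at d - 1, feasible at d
  expect_false(oracle_feasible(inst, d = 0, k = 1))
  expect_true(oracle_feasible(inst, d = 1, k = 1))

  red <- fig1_reduction()
  expect_identical(minimize_d(red$instance, k = 9)$d, 1L)
})

test_that("minimize_k finds the smallest feasible outlier budget", {
  ident <- cswo_instance(c("AA", "AA"))
  expect_identical(minimize_k(ident, d = 0)$k, 0L)
  inst <- cswo_instance(c("AA", "AA", "TT"))
  expect_identical(minimize_k(inst, d = 0)$k, 1L)
  set.seed(47)
  for (rep in 1:15) {
    rinst <- generate_random_instance(sample(2:4, 1), sample(1:3, 1),
                                      c("A", "B"), seed = 3000 + rep)
    d <- sample(0:2, 1)
    res <- minimize_k(rinst, d = d)
    expect_true(oracle_feasible(rinst, d = d, k = res$k))
    if (res$k > 0)
      expect_false(oracle_feasible(rinst, d = d, k = res$k - 1L))
  }
})

test_that("cswo_solve front end dispatches and minimizes", {
  inst <- cswo_instance(c("AAAA", "AAAT", "TTTT"), k = 1)
  sol <- cswo_solve(inst, minimize = "d")
  expect_identical(sol$minimized, list(parameter = "d", value = 1L))
  for (m in c("branching", "enumerate", "ilp")) {
    s <- cswo_solve(inst, d = 1, k = 1, method = m)
    expect_true(s$feasible)
    expect_true(verify_solution(inst, s, d = 1, k = 1))
  }
  expect_error(cswo_solve(inst, method = "branching"), "'d' is required")
})
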