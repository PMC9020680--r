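test_that("counts reconstruct from published rate and group size", {
  expect_identical(reconstruct_count(2.37, 1011), 24L)
  expect_identical(reconstruct_count(3.61, 83), 3L)
  expect_identical(reconstruct_count(0.76, 1316), 10L)
  # the two laparoscopy-without-infection cells sum to the printed total
  expect_identical(reconstruct_count(3.61, 83) +
                     reconstruct_count(0.76, 1316),
                   reconstruct_count(0.93, 1399))
  expect_identical(reconstruct_count(0, 500), 0L)
  expect_warning(reconstruct_count(1.5, 100), "ambiguous")
})

test_that("observed difference is the signed difference in proportions", {
  t <- two_by_two(3, 83, 10, 1316)
  expect_equal(observed_diff(t), 3 / 83 - 10 / 1316)
  expect_equal(round(observed_diff(t), 5), 0.02855)
  expect_equal(observed_diff(two_by_two(4, 20, 4, 20)), 0)
  expect_equal(observed_diff(two_by_two(0, 15, 0, 7)), 0)
  expect_error(two_by_two(5, 4, 0, 3))
})

test_that("exact tail equals brute-force enumeration of label
           assignments on small tables", {
  # every table with n1 + n2 <= 12: compare against full enumeration of
  # all choose(N, n1) group-1 label subsets
  for (n1 in 1:6) for (n2 in 1:6) {
    for (x1 in 0:n1) for (x2 in 0:n2) {
      p_pkg <- exact_p(two_by_two(x1, n1, x2, n2))
      p_ref <- enumerate_p(x1, n1, x2, n2)
      expect_equal(p_pkg, p_ref, tolerance = 1e-10,
                   label = sprintf("exact_p(%d,%d,%d,%d)", x1, n1, x2, n2))
    }
  }
})

test_that("exact tail satisfies degeneracy, monotonicity and tie
           accounting", {
  # degenerate tables: no complications, or all complications
  expect_equal(exact_p(two_by_two(0, 40, 0, 25)), 1)
  expect_equal(exact_p(two_by_two(40, 40, 25, 25)), 1)
  # upper-tail monotonicity: raising x1 at fixed margins shrinks the tail
  for (n1 in c(5, 20)) for (n2 in c(7, 30)) {
    for (K in 1:min(n1 + n2, 10)) {
      xs <- max(0, K - n2):min(K, n1)
      p <- vapply(xs, function(x)
        exact_p(two_by_two(x, n1, K - x, n2)), numeric(1))
      expect_true(all(diff(p) <= 1e-12))
    }
  }
  # swapping the groups accounts for the tied mass exactly once
  for (n1 in 2:5) for (n2 in 2:5) for (x1 in 0:n1) for (x2 in 0:n2) {
    t <- two_by_two(x1, n1, x2, n2)
    r <- two_by_two(x2, n2, x1, n1)
    tie <- dhyper(x1, x1 + x2, n1 + n2 - x1 - x2, n1)
    expect_equal(exact_p(t) + exact_p(r), 1 + tie, tolerance = 1e-10)
  }
})

test_that("randomization test is seed-reproducible and leaves the RNG
           untouched", {
  t <- two_by_two(3, 83, 10, 1316)
  set.seed(99)
  before <- .Random.seed
  a <- randomization_test(t, B = 5000, seed = 7)
  expect_identical(.Random.seed, before)
  b <- randomization_test(t, B = 5000, seed = 7)
  expect_identical(a$p_mc, b$p_mc)
  expect_equal(a$seed, 7L)
  expect_equal(a$mc_se, sqrt(a$p_mc * (1 - a$p_mc) / 5000))
  c <- randomization_test(t, B = 5000, seed = 8)
  expect_false(identical(a$p_mc, c$p_mc))
  expect_error(randomization_test(t, B = 0), "positive")
})

test_that("degenerate tables give Monte-Carlo p of exactly one", {
  # all permuted differences equal the observed difference of zero, and
  # ties count in the upper tail
  r <- randomization_test(two_by_two(0, 30, 0, 50), B = 500, seed = 1)
  expect_equal(r$p_mc, 1)
  expect_equal(r$p_exact, 1)
  # an identical-count table has d_obs = 0 but a non-degenerate null:
  # ties at the observed zero keep p above one half, and the tie mass is
  # exactly the symmetric hypergeometric identity
  r2 <- randomization_test(two_by_two(4, 10, 4, 10), B = 2000, seed = 1)
  expect_equal(observed_diff(r2$table), 0)
  expect_gt(r2$p_mc, 0.5)
  tie <- dhyper(4, 8, 12, 10)
  expect_equal(r2$p_exact, (1 + tie) / 2, tolerance = 1e-10)
})

test_that("count sampling and literal label shuffling agree within
           Monte-Carlo error", {
  t <- two_by_two(4, 30, 3, 45)
  pe <- exact_p(t)
  a <- randomization_test(t, B = 4000, seed = 5, method = "count")
  b <- randomization_test(t, B = 4000, seed = 5, method = "shuffle")
  bound <- 4 * sqrt(pe * (1 - pe) / 4000)
  expect_lt(abs(a$p_mc - pe), bound)
  expect_lt(abs(b$p_mc - pe), bound)
})

test_that("Monte-Carlo p converges to the exact tail across seeds", {
  tables <- list(two_by_two(2, 39, 2, 822), two_by_two(3, 20, 4, 35))
  B <- 1000
  for (t in tables) {
    pe <- exact_p(t)
    bound <- 4 * sqrt(pe * (1 - pe) / B)
    ok <- vapply(1:110, function(s)
      abs(randomization_test(t, B = B, seed = s)$p_mc - pe) <= bound,
      logical(1))
    expect_gte(mean(ok), 0.99)
  }
})

test_that("add-one estimator relates to the raw proportion exactly", {
  t <- two_by_two(5, 40, 2, 60)
  raw <- randomization_test(t, B = 2000, seed = 3, estimator = "raw")
  add1 <- randomization_test(t, B = 2000, seed = 3,
                             estimator = "add_one")
  expect_equal(add1$p_mc, (2000 * raw$p_mc + 1) / 2001)
  expect_gt(add1$p_mc, 0)
})

test_that("fitted test exposes coefficients, summaries and null draws", {
  t <- two_by_two(3, 83, 10, 1316, c("prophylaxis", "none"))
  r <- randomization_test(t, B = 2000, seed = 2, keep_null = TRUE)
  expect_s3_class(r, "rand_test")
  expect_equal(unname(coef(r)), c(3 / 83, 10 / 1316, observed_diff(t)))
  s <- summary(r)
  expect_equal(s$p_mc, r$p_mc)
  expect_true(s$significant == (r$p_mc < 0.05))
  expect_length(r$null_dist, 2000)
  draws <- simulate(r, nsim = 500, seed = 4)
  expect_length(draws, 500)
  # null draws live on the lattice of achievable differences
  K <- 13
  lattice <- (0:K) / 83 - (K - (0:K)) / 1316
  expect_true(all(draws %in% lattice))
  expect_output(print(r), "p = ")
})

test_that("comparison plans resolve strata and annotate significance", {
  sp <- small_spec(n = 300L, rate1 = 0.15, rate2 = 0.01)
  b <- generate_cohort(sp, seed = 21)
  calls <- call_complications(b$procedures, b$events,
                              overrides = b$overrides)
  tally <- tally_complications(calls, b$procedures,
                               by = c("procedure_type", "prophylaxis"))
  res <- run_comparisons(tally, small_plan()$treatment, B = 2000,
                         seed = 1)
  df <- as.data.frame(res)
  expect_equal(nrow(df), 1)
  expect_true(df$significant)  # planted 15% vs 1% must be detected
  expect_equal(df$x1 + df$x2, sum(tally$complications))

  bad_plan <- list(list(name = "bad",
                        stratum_a = list(procedure_type = "MRI"),
                        stratum_b = list(procedure_type = "PLN")))
  expect_error(run_comparisons(tally, bad_plan, B = 10, seed = 1),
               "matches 0 tally rows")
  # a stratum compared with itself: zero observed difference, and the
  # tie-inclusive upper tail keeps p above one half
  self <- two_by_two(tally$complications[1], tally$procedures[1],
                     tally$complications[1], tally$procedures[1])
  rs <- randomization_test(self, B = 500, seed = 1)
  expect_equal(rs$d_obs, 0)
  expect_gt(rs$p_mc, 0.5)
  expect_false(rs$p_mc < 0.05)
})
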