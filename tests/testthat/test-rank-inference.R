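test_that("within-problem ranking follows best-is-1 with average-rank ties", {
  m <- rbind(c(0.9, 0.8, 0.7))
  expect_equal(unname(rank_problems(m)$ranks[1, ]), c(1, 2, 3))
  m <- rbind(c(0.8, 0.8, 0.7))
  expect_equal(unname(rank_problems(m)$ranks[1, ]), c(1.5, 1.5, 3))
  m <- rbind(c(0.5, 0.5, 0.5))
  expect_equal(unname(rank_problems(m)$ranks[1, ]), rep(2, 3))
  expect_error(rank_problems(rbind(c(1, NA))), "no missing")
})

test_that("rank sums are conserved on random results tables", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    k <- sample(2:8, 1)
    m <- matrix(runif(n * k), n, k)
    m[sample(length(m), n)] <- 0.5  # inject ties
    rs <- rank_problems(m)
    expect_equal(sum(rs$rank_sums), n * k * (k + 1) / 2)
  }
})

test_that("published seven-classifier average ranks reconstruct exact rank sums", {
  rs <- reconstruct_rank_sums(ref_classifier_ranks(), 42)
  expect_equal(rs$rank_sums, c(100, 119, 123, 142.5, 171, 249.5, 271))
  expect_equal(sum(rs$rank_sums), 1176)  # 42 * 7 * 8 / 2
  expect_error(rank_summary(c(1, 2, 3), 5), "rank sums total")
})

test_that("Friedman and Iman-Davenport statistics match their formulas", {
  # identical treatments on every problem
  rs <- rank_problems(matrix(0.5, 6, 3))
  fr <- friedman_test_ranks(rs)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p.value, 1)

  # seven classifiers over 42 problems (reconstructed rank sums)
  fr <- friedman_test_ranks(reconstruct_rank_sums(ref_classifier_ranks(),
                                                  42))
  expect_equal(fr$statistic, 137.554, tolerance = 1e-4)
  expect_equal(fr$iman_davenport, 49.278, tolerance = 1e-4)
  expect_equal(fr$df1, 6)
  expect_equal(fr$df2, 246)
  expect_lt(fr$p.value, 1e-15)

  # degenerate: every problem yields the identical ranking
  rs <- rank_problems(matrix(rep(c(0.9, 0.6, 0.3), each = 5), 5, 3))
  fr <- friedman_test_ranks(rs)
  expect_true(fr$degenerate)
  expect_equal(fr$p.value, 0)
})

test_that("the Friedman chi-square agrees with stats::friedman.test", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    k <- sample(3:6, 1)
    m <- matrix(runif(n * k), n, k)
    ours <- friedman_test_ranks(rank_problems(m))
    ref <- friedman.test(m)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.chisq, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the omnibus p depends on the values only through their ranks", {
  set.seed(44)
  m <- matrix(runif(36), 12, 3)
  p1 <- friedman_test_ranks(rank_problems(m))$p.value
  p2 <- friedman_test_ranks(rank_problems(qlogis(m / 2)))$p.value
  expect_equal(p1, p2)
})

test_that("pairwise z follows its closed form and is antisymmetric", {
  rs <- reconstruct_rank_sums(ref_classifier_ranks(), 42)
  # KNN vs LVQ: rank-sum difference 100 over n = 42, se = sqrt(2/9)
  pz <- pairwise_z(rs, "LVQ", "KNN")
  expect_equal(pz$z, (100 / 42) / sqrt(7 * 8 / (6 * 42)), tolerance = 1e-10)
  expect_equal(pz$z, 5.0508, tolerance = 1e-4)
  rev <- pairwise_z(rs, "KNN", "LVQ")
  expect_equal(rev$z, -pz$z)
  expect_equal(rev$p.value, pz$p.value)
  # equal average ranks
  rs2 <- rank_summary(c(A = 9, B = 9, C = 18), 6)
  expect_equal(pairwise_z(rs2, "A", "B")$z, 0)
  expect_equal(pairwise_z(rs2, "A", "B")$p.value, 1)
})

test_that("achievable true-hypothesis counts match set-partition enumeration", {
  expect_equal(shaffer_true_counts(3), c(0, 1, 3))
  expect_equal(shaffer_true_counts(4), c(0, 1, 2, 3, 6))
  expect_equal(shaffer_true_counts(7),
               c(0, 1, 2, 3, 4, 5, 6, 7, 9, 10, 11, 15, 21))
  for (k in 2:8) {
    oracle <- sort(unique(vapply(
      enumerate_partitions(k),
      function(p) sum(choose(p, 2)), 0)))
    expect_equal(shaffer_true_counts(k), as.integer(oracle))
  }
})

test_that("the step-down multiplier schedule is monotone with known endpoints", {
  t7 <- shaffer_multipliers(7)
  expect_equal(t7[1:2], c(21L, 15L))
  expect_equal(t7[20:21], c(2L, 1L))
  for (k in 3:8) {
    tk <- shaffer_multipliers(k)
    expect_equal(tk[1], k * (k - 1) / 2)
    expect_true(all(diff(tk) <= 0))
  }
})

test_that("Shaffer adjustment applies the step-down rule with monotonicity", {
  # k = 3: multipliers (3, 1, 1)
  raw <- c(1e-6, 0.02, 0.5)
  expect_equal(shaffer_adjust(raw), c(3e-6, 0.02, 0.5))
  # order-independence: shuffled input maps back correctly
  expect_equal(shaffer_adjust(raw[c(3, 1, 2)]), c(0.5, 3e-6, 0.02))
  expect_equal(shaffer_adjust(rep(1, 6)), rep(1, 6))
  # adjusted never below raw, monotone along the sorted family
  set.seed(45)
  for (k in c(3, 5, 7)) {
    p <- runif(k * (k - 1) / 2)^3
    adj <- shaffer_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # Shaffer is never more conservative than Nemenyi
    expect_true(all(adj <= nemenyi_adjust(p) + 1e-15))
  }
  expect_error(shaffer_adjust(runif(5)), "complete all-pairs family")
})

test_that("Nemenyi adjustment multiplies by m and caps at 1", {
  p <- c(1e-3, rep(0.5, 20))
  adj <- nemenyi_adjust(p)
  expect_equal(adj[1], 0.021)
  expect_true(all(adj[-1] == 1))
})

test_that("critical-distance grouping splits the published classifier family", {
  rs <- reconstruct_rank_sums(ref_classifier_ranks(), 42)
  gr <- cd_groups(rs, alpha = 0.001)
  expect_equal(gr$order, c("RBF", "Lin", "MLP", "RF", "KNN", "DT", "LVQ"))
  expect_length(gr$groups, 2L)
  expect_setequal(gr$groups[[1]], c("RBF", "Lin", "MLP", "RF", "KNN"))
  expect_setequal(gr$groups[[2]], c("DT", "LVQ"))
  # all null results -> one group; all rejected -> singletons
  pw <- posthoc_pairwise(rs)
  pw$p_shaffer <- 1
  expect_length(cd_groups(rs, pw, alpha = 0.001)$groups, 1L)
  pw$p_shaffer <- 0
  expect_length(cd_groups(rs, pw, alpha = 0.001)$groups, 7L)
})

test_that("adjusted p-values are invariant under treatment relabeling", {
  set.seed(46)
  m <- matrix(runif(60), 12, 5,
              dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  pw1 <- posthoc_pairwise(rank_problems(m))
  perm <- c(3, 1, 5, 2, 4)
  pw2 <- posthoc_pairwise(rank_problems(m[, perm]))
  key <- function(pw) paste(pmin(pw$better, pw$worse),
                            pmax(pw$better, pw$worse))
  expect_equal(pw1$p_shaffer[order(key(pw1))],
               pw2$p_shaffer[order(key(pw2))])
})

test_that("compare_treatments runs the chain on a results table", {
  set.seed(47)
  grid <- expand.grid(dataset = c("d1", "d2", "d3"),
                      threshold = c(1e-3, 1e-4),
                      algorithm = c("SVM-linear", "RF"),
                      encoding = c("additive", "recdom", "genotypic"),
                      stringsAsFactors = FALSE)
  bump <- ifelse(grid$encoding == "additive", 0.05, 0)
  grid$mean_auc <- 0.6 + bump + rnorm(nrow(grid), sd = 0.01)
  cmp <- compare_treatments(grid, treatment = "encoding")
  expect_equal(cmp$summary$n, 12)
  expect_equal(cmp$summary$k, 3)
  best <- cmp$summary$treatments[which.min(cmp$summary$avg_ranks)]
  expect_equal(best, "additive")
  expect_lt(cmp$friedman$p.value, 0.01)
  expect_output(print(cmp), "average ranks")
})
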