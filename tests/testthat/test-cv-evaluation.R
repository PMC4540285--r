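test_that("5x2 splits partition the samples, stratified and reproducible", {
  status <- rep(c(1L, 0L), c(24, 18))
  sp <- split_5x2(status, seed = 3)
  expect_length(sp, 10L)
  for (f in sp) {
    expect_setequal(c(f$train, f$test), seq_along(status))
    expect_length(intersect(f$train, f$test), 0L)
    # class balance differs by at most one per half
    expect_lte(abs(sum(status[f$train] == 1L) - 12), 1)
    expect_lte(abs(sum(status[f$train] == 0L) - 9), 1)
  }
  # each repetition uses the same partition both ways
  expect_setequal(sp[[1]]$train, sp[[2]]$test)
  expect_identical(split_5x2(status, seed = 3), sp)
  expect_false(identical(split_5x2(status, seed = 4), sp))
})

test_that("a 4-sample toy set splits one case and one control per half", {
  status4 <- c(1L, 1L, 0L, 0L)
  sp <- split_5x2(status4, seed = 1)
  for (f in sp) {
    expect_length(f$train, 2L)
    expect_setequal(status4[f$train], c(0L, 1L))
    expect_setequal(status4[f$test], c(0L, 1L))
  }
})

test_that("AUC equals brute-force pair counting and behaves at the extremes", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(17)
  for (i in 1:20) {
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
    expect_equal(auc(scores, labels), auc_brute_force(scores, labels))
    # inverting the scores reflects the AUC
    expect_equal(auc(-scores, labels), 1 - auc(scores, labels))
  }
})

test_that("inner grid search returns single grids unchanged and dedups", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0L, 1L), 10)
  spec1 <- classifier_spec("SVM-linear", data.frame(cost = 1))
  got <- inner_grid_search(x, y, spec1, seed = 5)
  expect_equal(got$params$cost, 1)
  specd <- classifier_spec("kNN", data.frame(k = c(3L, 3L, 5L),
                                             weight = "constant",
                                             stringsAsFactors = FALSE))
  specu <- classifier_spec("kNN", data.frame(k = c(3L, 5L),
                                             weight = "constant",
                                             stringsAsFactors = FALSE))
  expect_equal(inner_grid_search(x, y, specd, seed = 7)$params,
               inner_grid_search(x, y, specu, seed = 7)$params)
})

test_that("grid search picks the argmax of an exhaustive re-evaluation", {
  set.seed(23)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = rnorm(n, mean = y * 1.6), f2 = rnorm(n))
  spec <- classifier_spec("kNN", expand.grid(k = c(1L, 5L, 15L),
                                             weight = "constant",
                                             stringsAsFactors = FALSE))
  got <- inner_grid_search(x, y, spec, seed = 11)
  expect_equal(got$auc, max(got$table$mean_auc))
  best_row <- which(got$table$mean_auc == got$auc)[1]
  expect_equal(got$params$k, got$table$k[best_row])
})

test_that("every classifier family fits and returns ranking scores", {
  set.seed(29)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(matrix(rnorm(n * 2, mean = rep(y, 2)), n, 2),
             matrix(rnorm(n * 2), n, 2))
  colnames(x) <- paste0("f", 1:4)
  small_grids <- list(
    "DT" = data.frame(cp = 0.01),
    "RF" = data.frame(num_trees = 50L),
    "SVM-linear" = data.frame(cost = 1),
    "SVM-RBF" = data.frame(cost = 1, gamma = 0.1),
    "kNN" = data.frame(k = 5L, weight = "inverse",
                       stringsAsFactors = FALSE),
    "MLP" = data.frame(size = 4L, decay = 0.1),
    "LVQ" = data.frame(codebook = 3L)
  )
  for (nm in names(small_grids)) {
    spec <- classifier_spec(nm, small_grids[[nm]])
    m <- fit_classifier(spec, spec$grid[1, , drop = FALSE], x, y, seed = 2)
    s <- score_classifier(m, x)
    expect_length(s, n)
    expect_true(is.numeric(s))
    # with a strong linear signal, every family must beat chance in-sample
    expect_gt(auc(s, y), 0.6)
  }
})

test_that("null data yields chance-level AUC and strong signal beats it", {
  spec <- classifier_spec("SVM-linear", data.frame(cost = c(0.1, 1)))
  null_d <- make_null_dataset(60, 60, 60, seed = 303)
  sp <- split_5x2(null_d, seed = 1)
  rec0 <- run_setting(null_d, 0.05, "additive", spec, sp, seed = 5)
  expect_lt(abs(rec0$mean_auc - 0.5), 0.12)

  arch <- architecture_spec(40, maf = 0.3, causal = list(
    list(snp = 7, model = "additive", effect = 3.0)))
  d <- simulate_cohort(arch, cohort_spec(150, 150), seed = 31)
  sp <- split_5x2(d, seed = 2)
  rec <- run_setting(d, 0.01, "additive", spec, sp, seed = 6)
  # analytic AUC of the single-SNP score from the two genotype mixtures
  q <- 0.3
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  pd <- plogis(qlogis(0.1) + log(3) * 0:2)
  p_case <- pg * pd / sum(pg * pd)
  p_ctrl <- pg * (1 - pd) / sum(pg * (1 - pd))
  analytic <- sum(outer(p_case, p_ctrl, function(a, b) a * b) *
                    outer(0:2, 0:2, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_gt(rec$mean_auc, 0.55)
  expect_lt(abs(rec$mean_auc - analytic), 0.07)
})

test_that("a fold retaining zero SNPs is flagged at AUC 0.5", {
  null_d <- make_null_dataset(30, 40, 40, seed = 7)
  spec <- classifier_spec("SVM-linear", data.frame(cost = 1))
  sp <- split_5x2(null_d, seed = 1)
  rec <- run_setting(null_d, 1e-8, "additive", spec, sp, seed = 9)
  expect_true(all(rec$degenerate))
  expect_equal(rec$mean_auc, 0.5)
})

test_that("identical seeds reproduce the AUC record exactly", {
  arch <- architecture_spec(30, maf = 0.3, causal = list(
    list(snp = 1, model = "additive", effect = 2)))
  d <- simulate_cohort(arch, cohort_spec(80, 80), seed = 15)
  sp <- split_5x2(d, seed = 4)
  spec <- classifier_spec("RF", data.frame(num_trees = c(30L, 60L)))
  r1 <- run_setting(d, 0.05, "recdom", spec, sp, seed = 8)
  r2 <- run_setting(d, 0.05, "recdom", spec, sp, seed = 8)
  expect_identical(r1$fold_auc, r2$fold_auc)
})

test_that("run_experiment enumerates the design and is reproducible", {
  arch <- architecture_spec(40, maf = 0.3, causal = list(
    list(snp = 2, model = "additive", effect = 2.5)))
  datasets <- list(
    A = simulate_cohort(arch, cohort_spec(60, 60), seed = 1),
    B = simulate_cohort(arch, cohort_spec(60, 60), seed = 2)
  )
  classifiers <- list(classifier_spec("SVM-linear", data.frame(cost = 1)),
                      classifier_spec("kNN",
                                      data.frame(k = 5L,
                                                 weight = "constant",
                                                 stringsAsFactors = FALSE)))
  res <- run_experiment(datasets, thresholds = c(0.05, 0.01),
                        schemes = c("additive", "genotypic"),
                        classifiers = classifiers, seed = 10)
  expect_equal(nrow(res), 2 * 2 * 2 * 2)
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
  res2 <- run_experiment(datasets, thresholds = c(0.05, 0.01),
                         schemes = c("additive", "genotypic"),
                         classifiers = classifiers, seed = 10)
  expect_equal(res$mean_auc, res2$mean_auc)
})
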