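# Derive a reproducible substream seed from a master seed and a name, so
# that every random component (splits, inner folds, classifier init) has
# its own independent, named stream. Kept below 2^31.
.substream <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(master) * 1000003 + h) %% .Machine$integer.max)
}

#' 5x2 cross-validation splits
#'
#' Five repetitions of a random half/half partition of the samples, each
#' half used once for training and once for testing (10 train/test pairs).
#' Splits are stratified by case/control status so both classes appear in
#' every half, and are fully determined by `seed` -- the same splits are
#' reused for every threshold, encoding and classifier evaluated on one
#' dataset, which the matched-rank inference downstream requires.
#'
#' @param status 0/1 integer case vector (or a [genotype_dataset()]).
#' @param seed integer seed.
#' @return list of 10 elements, each `list(train, test, rep, half)` of
#'   disjoint index vectors whose union is all samples.
#' @export
split_5x2 <- function(status, seed) {
  if (inherits(status, "genotype_dataset")) status <- case_status(status)
  if (length(unique(status)) < 2L) stop("both classes must be present")
  set.seed(as.integer(seed))
  folds <- list()
  for (r in 1:5) {
    half_a <- integer(0)
    for (cls in unique(status)) {
      idx <- sample(which(status == cls))
      half_a <- c(half_a, idx[seq_len(ceiling(length(idx) / 2))])
    }
    half_a <- sort(half_a)
    half_b <- setdiff(seq_along(status), half_a)
    folds[[2 * r - 1]] <- list(train = half_a, test = half_b,
                               rep = r, half = 1L)
    folds[[2 * r]] <- list(train = half_b, test = half_a,
                           rep = r, half = 2L)
  }
  folds
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random case scores
#' higher than a random control, with ties contributing 1/2. Computed from
#' mid-ranks, which is exactly equivalent to brute-force pair counting.
#'
#' @param scores real-valued classifier scores (higher = more case-like).
#' @param labels 0/1 (or logical) case indicators.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Inner grid search maximizing cross-validated AUC
#'
#' Evaluates every parameter combination of the classifier's grid by
#' stratified 5-fold cross-validation on the training fold and returns the
#' combination with the highest fold-averaged AUC. Ties are broken by
#' first occurrence in the declared grid order. A combination on which the
#' classifier fails is scored as AUC 0 (and recorded), not fatal. A
#' single-row grid is returned unchanged without running the inner folds.
#'
#' @param x standardized training feature matrix.
#' @param y 0/1 case vector.
#' @param spec a [classifier_spec()].
#' @param seed integer seed for the inner fold assignment and stochastic
#'   learners.
#' @param inner_folds number of inner folds (default 5).
#' @return list with `params` (best row of the grid as a list), `auc`
#'   (its mean inner AUC, NA for a single-row grid) and `table` (per-combo
#'   mean AUCs).
#' @export
inner_grid_search <- function(x, y, spec, seed, inner_folds = 5L) {
  grid <- unique(spec$grid)
  if (nrow(grid) <= 1L) {
    return(list(params = as.list(spec$grid[1L, , drop = FALSE]),
                auc = NA_real_, table = NULL))
  }
  set.seed(.substream(seed, "inner-folds"))
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(inner_folds), length(idx))
  }
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_auc <- rep(NA_real_, inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold_id != f
      fold_auc[f] <- tryCatch({
        m <- fit_classifier(spec, grid[g, , drop = FALSE],
                            x[tr, , drop = FALSE], y[tr],
                            seed = .substream(seed, paste0("fit", g, f)))
        auc(score_classifier(m, x[!tr, , drop = FALSE]), y[!tr])
      }, error = function(e) 0)
    }
    mean_auc[g] <- mean(fold_auc)
  }
  best <- which.max(mean_auc)  # first occurrence wins ties
  list(params = as.list(grid[best, , drop = FALSE]), auc = mean_auc[best],
       table = cbind(grid, mean_auc = mean_auc))
}

#' Evaluate one experimental setting by nested 5x2 cross-validation
#'
#' For each of the 10 outer folds: the five association tests are computed
#' on the training half only and SNPs are retained by [min_p_filter()] at
#' the setting's threshold; the retained SNPs are encoded under the
#' setting's scheme and standardized with training-half statistics; the
#' classifier's parameters are tuned by [inner_grid_search()]; the tuned
#' classifier is fit on the full training half and its AUC measured on the
#' held-out half. If a fold retains zero SNPs its AUC is recorded as 0.5
#' and flagged (an informationless classifier).
#'
#' @param x a QC'd [genotype_dataset()].
#' @param threshold association p-value cutoff for SNP selection.
#' @param scheme encoding scheme (see [encode()]).
#' @param spec a [classifier_spec()].
#' @param splits the 10 folds from [split_5x2()]; pass the same object for
#'   every setting on one dataset.
#' @param seed integer master seed for inner folds and classifier
#'   initialization.
#' @param scans optional list of 10 precomputed training-fold
#'   [assoc_scan()] data.frames (they depend only on the splits, so they
#'   can be shared across thresholds, encodings and classifiers).
#' @return list of class `auc_record`: `fold_auc` (10 values), `mean_auc`,
#'   `n_retained` per fold, `chosen` (per-fold tuned parameters),
#'   `degenerate` flags.
#' @export
run_setting <- function(x, threshold, scheme, spec, splits, seed,
                        scans = NULL) {
  status <- case_status(x)
  if (is.null(scans)) {
    scans <- lapply(splits, function(f) assoc_scan(x, samples = f$train))
  }
  nf <- length(splits)
  fold_auc <- numeric(nf)
  n_retained <- integer(nf)
  degenerate <- logical(nf)
  chosen <- vector("list", nf)
  for (f in seq_len(nf)) {
    fold <- splits[[f]]
    keep <- min_p_filter(scans[[f]], threshold)
    n_retained[f] <- length(keep)
    if (length(keep) == 0L) {
      fold_auc[f] <- 0.5
      degenerate[f] <- TRUE
      next
    }
    em <- encode(x, snps = keep, scheme = scheme)
    std <- fit_standardizer(em$x[fold$train, , drop = FALSE])
    xtr <- apply_standardizer(std, em$x[fold$train, , drop = FALSE])
    xte <- apply_standardizer(std, em$x[fold$test, , drop = FALSE])
    ytr <- status[fold$train]
    fseed <- .substream(seed, paste0("fold", f))
    gs <- inner_grid_search(xtr, ytr, spec, seed = fseed)
    model <- fit_classifier(spec, gs$params, xtr, ytr,
                            seed = .substream(fseed, "final"))
    fold_auc[f] <- auc(score_classifier(model, xte), status[fold$test])
    chosen[[f]] <- gs$params
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 n_retained = n_retained, chosen = chosen,
                 degenerate = degenerate),
            class = "auc_record")
}

#' Run a full benchmarking design over several datasets
#'
#' Enumerates datasets x thresholds x encodings x classifiers, evaluating
#' each setting with [run_setting()]. Within one dataset the 5x2 splits
#' and per-fold association scans are computed once and shared across all
#' settings (the splits must be identical across treatments for the
#' matched-rank inference downstream). A setting that fails is recorded
#' with `NA` AUC and the run continues.
#'
#' @param datasets named list of QC'd [genotype_dataset()] objects.
#' @param thresholds numeric vector of association p-value cutoffs.
#' @param schemes character vector of encoding schemes.
#' @param classifiers list of [classifier_spec()] objects.
#' @param seed integer master seed; per-dataset and per-setting seeds are
#'   derived as named substreams.
#' @param verbose print one line per completed setting.
#' @return data.frame of class `results_table`: columns `dataset`,
#'   `threshold`, `encoding`, `algorithm`, `mean_auc`, plus `auc1` ...
#'   `auc10` per-fold values.
#' @export
run_experiment <- function(datasets, thresholds = threshold_set(),
                           schemes = c("additive", "recdom", "genotypic"),
                           classifiers, seed = 1L, verbose = FALSE) {
  stopifnot(length(names(datasets)) == length(datasets))
  rows <- list()
  for (ds in names(datasets)) {
    x <- datasets[[ds]]
    dseed <- .substream(seed, paste0("dataset-", ds))
    splits <- split_5x2(x, seed = .substream(dseed, "splits"))
    scans <- lapply(splits, function(f) assoc_scan(x, samples = f$train))
    for (th in thresholds) for (sc in schemes) for (clf in classifiers) {
      rec <- tryCatch(
        run_setting(x, th, sc, clf, splits,
                    seed = .substream(dseed, paste0("set-", th, "-", sc,
                                                    "-", clf$name)),
                    scans = scans),
        error = function(e) e
      )
      row <- data.frame(dataset = ds, threshold = th, encoding = sc,
                        algorithm = clf$name, stringsAsFactors = FALSE)
      if (inherits(rec, "error")) {
        row$mean_auc <- NA_real_
        row[paste0("auc", 1:10)] <- NA_real_
        warning("setting failed (", ds, ", ", th, ", ", sc, ", ",
                clf$name, "): ", conditionMessage(rec))
      } else {
        row$mean_auc <- rec$mean_auc
        row[paste0("auc", 1:10)] <- as.list(rec$fold_auc)
      }
      rows[[length(rows) + 1L]] <- row
      if (verbose) {
        message(sprintf("%s thr=%g %s %s: mean AUC %.4f",
                        ds, th, sc, clf$name, row$mean_auc))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", class(out))
  out
}
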