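#' Classifier specification with a tuning grid
#'
#' Wraps one of the seven supported classifier families behind a uniform
#' fit/score contract: `fit` consumes a standardized numeric feature matrix
#' and a 0/1 case vector, `score` returns a real-valued ranking (higher =
#' more case-like), as required for AUC evaluation. Training is delegated
#' to established implementations (rpart, ranger, e1071, nnet) except for
#' kNN and LVQ1, which are implemented in-package so that both expose the
#' required real-valued decision score.
#'
#' Default tuning grids (exhaustively enumerated by the inner
#' cross-validation, in declared order; first occurrence wins ties):
#'
#' * `DT`: rpart complexity parameter
#'   `cp` in `{0.001, 0.003, 0.01, 0.03, 0.1, 0.2, 0.3}` (spanning weak to
#'   aggressive pruning);
#' * `RF`: number of trees in `{10, 30, 100, 300, 1000}`;
#' * `SVM-linear`: cost `C` in `2^{-5}, 2^{-3}, ..., 2^{11}`;
#' * `SVM-RBF`: the same cost grid crossed with
#'   `gamma` in `2^{-15}, 2^{-13}, ..., 2^{3}`;
#' * `kNN`: `k` in `{1, 3, 10, 30, 100}` crossed with constant or
#'   inverse-distance neighbor weighting;
#' * `MLP`: hidden units in `{2, 4, 8, 16, 32, #features}` (0 encodes
#'   "#features", resolved at fit time) crossed with weight decay
#'   `{0, 0.1}`;
#' * `LVQ`: no grid (a single multipass LVQ1 configuration).
#'
#' @param name one of `"DT"`, `"RF"`, `"SVM-linear"`, `"SVM-RBF"`, `"kNN"`,
#'   `"MLP"`, `"LVQ"`.
#' @param grid optional data.frame of parameter combinations replacing the
#'   default grid (column names must match the default grid's).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, grid = NULL) {
  name <- match.arg(name, c("DT", "RF", "SVM-linear", "SVM-RBF", "kNN",
                            "MLP", "LVQ"))
  if (is.null(grid)) grid <- default_grid(name)
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L && name != "LVQ") stop("empty tuning grid")
  structure(list(name = name, grid = grid), class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_grid <- function(name) {
  switch(name,
    "DT" = data.frame(cp = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.2, 0.3)),
    "RF" = data.frame(num_trees = c(10L, 30L, 100L, 300L, 1000L)),
    "SVM-linear" = data.frame(cost = 2^seq(-5, 11, by = 2)),
    "SVM-RBF" = expand.grid(cost = 2^seq(-5, 11, by = 2),
                            gamma = 2^seq(-15, 3, by = 2)),
    "kNN" = expand.grid(k = c(1L, 3L, 10L, 30L, 100L),
                        weight = c("constant", "inverse"),
                        stringsAsFactors = FALSE),
    "MLP" = expand.grid(size = c(2L, 4L, 8L, 16L, 32L, 0L),
                        decay = c(0, 0.1)),
    "LVQ" = data.frame(codebook = 5L)
  )
}

#' Fit a classifier under the fit/score contract
#'
#' @param spec a [classifier_spec()].
#' @param params one row of the spec's grid (data.frame or list).
#' @param x standardized numeric feature matrix (training fold).
#' @param y 0/1 integer case status aligned with `x`.
#' @param seed integer seed for stochastic learners.
#' @return a fitted model object of class `snpbench_model`.
#' @export
fit_classifier <- function(spec, params, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"), nrow(x) == length(y))
  params <- as.list(params)
  yf <- factor(ifelse(y == 1L, "case", "control"),
               levels = c("control", "case"))
  fit <- switch(spec$name,
    "DT" = {
      df <- data.frame(.y = yf, x, check.names = FALSE)
      set.seed(seed)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp,
                                                  xval = 0L))
    },
    "RF" = ranger::ranger(
      x = x, y = yf, num.trees = params$num_trees, probability = TRUE,
      num.threads = 1L, seed = seed
    ),
    "SVM-linear" = e1071::svm(x = x, y = yf, kernel = "linear",
                              cost = params$cost, scale = FALSE),
    "SVM-RBF" = e1071::svm(x = x, y = yf, kernel = "radial",
                           cost = params$cost, gamma = params$gamma,
                           scale = FALSE),
    "kNN" = list(x = x, y = y, k = min(params$k, nrow(x)),
                 weight = params$weight),
    "MLP" = {
      size <- if (params$size == 0L) ncol(x) else params$size
      set.seed(seed)
      nnet::nnet(x = x, y = as.numeric(y), size = size,
                 decay = params$decay, entropy = TRUE, maxit = 200L,
                 trace = FALSE, MaxNWts = 200000L)
    },
    "LVQ" = .lvq1_fit(x, y, codebook = params$codebook, seed = seed)
  )
  structure(list(name = spec$name, fit = fit), class = "snpbench_model")
}

#' Real-valued decision scores of a fitted classifier
#'
#' Higher scores mean "more case-like"; probabilities or margins depending
#' on the family, but always a ranking usable for AUC.
#'
#' @param model a fitted `snpbench_model` from [fit_classifier()].
#' @param x standardized feature matrix to score.
#' @return numeric vector of length `nrow(x)`.
#' @export
score_classifier <- function(model, x) {
  stopifnot(inherits(model, "snpbench_model"))
  switch(model$name,
    "DT" = {
      pr <- predict(model$fit,
                    newdata = as.data.frame(x, check.names = FALSE),
                    type = "prob")
      if ("case" %in% colnames(pr)) pr[, "case"] else rep(0, nrow(x))
    },
    "RF" = predict(model$fit, data = x,
                   num.threads = 1L)$predictions[, "case"],
    "SVM-linear" = ,
    "SVM-RBF" = {
      d <- attr(predict(model$fit, x, decision.values = TRUE),
                "decision.values")
      # e1071 orients the decision value toward the first named class
      lab <- strsplit(colnames(d)[1L], "/", fixed = TRUE)[[1L]][1L]
      if (lab == "case") d[, 1L] else -d[, 1L]
    },
    "kNN" = .knn_score(model$fit, x),
    "MLP" = as.numeric(predict(model$fit, x)),
    "LVQ" = .lvq1_score(model$fit, x)
  )
}

# -- k-nearest neighbors with probability scores ------------------------

.knn_score <- function(fit, x) {
  # squared Euclidean distances test x train via the expansion
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  tr <- fit$x
  d2 <- outer(rowSums(x^2), rowSums(tr^2), `+`) - 2 * tcrossprod(x, tr)
  d2[d2 < 0] <- 0
  k <- fit$k
  apply(d2, 1L, function(d) {
    nb <- order(d)[seq_len(k)]
    if (fit$weight == "constant") {
      mean(fit$y[nb])
    } else {
      w <- 1 / (sqrt(d[nb]) + 1e-8)
      sum(w * fit$y[nb]) / sum(w)
    }
  })
}

# -- multipass LVQ1 -----------------------------------------------------
# Plain LVQ1 with a small fixed codebook per class: prototypes are
# initialized from random training examples of their class, then updated
# over several passes through the shuffled training data with a linearly
# decaying learning rate. The decision score is the difference between the
# distance to the nearest control prototype and the distance to the
# nearest case prototype (positive = closer to a case prototype).

.lvq1_fit <- function(x, y, codebook = 5L, passes = 5L, lr0 = 0.3,
                      seed = 1L) {
  set.seed(seed)
  protos <- list()
  plab <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    nc <- min(codebook, length(idx))
    if (nc == 0L) stop("LVQ requires examples of both classes")
    pick <- sample(idx, nc)
    protos <- c(protos, lapply(pick, function(i) x[i, ]))
    plab <- c(plab, rep(cls, nc))
  }
  w <- do.call(rbind, protos)
  n <- nrow(x)
  total <- passes * n
  step <- 0L
  for (pass in seq_len(passes)) {
    for (i in sample.int(n)) {
      step <- step + 1L
      lr <- lr0 * (1 - (step - 1L) / total)
      d2 <- rowSums(sweep(w, 2L, x[i, ])^2)
      j <- which.min(d2)
      sgn <- if (plab[j] == y[i]) 1 else -1
      w[j, ] <- w[j, ] + sgn * lr * (x[i, ] - w[j, ])
    }
  }
  list(w = w, plab = plab)
}

.lvq1_score <- function(fit, x) {
  d2 <- outer(rowSums(x^2), rowSums(fit$w^2), `+`) - 2 * tcrossprod(x, fit$w)
  d2[d2 < 0] <- 0
  dcase <- apply(d2[, fit$plab == 1L, drop = FALSE], 1L, min)
  dctrl <- apply(d2[, fit$plab == 0L, drop = FALSE], 1L, min)
  sqrt(dctrl) - sqrt(dcase)
}
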