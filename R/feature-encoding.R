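#' Encode SNP genotypes as numeric features
#'
#' Transforms genotypes of the selected SNPs into a numeric feature matrix
#' under one of three schemes, each implying a different genetic risk
#' model:
#'
#' * `additive` (1 feature/SNP, `count`): minor-allele count --
#'   AA -> 0, AB -> 1, BB -> 2;
#' * `recdom` (2 features/SNP, `hasA`, `hasB`): presence of each allele --
#'   AA -> (1,0), AB -> (1,1), BB -> (0,1);
#' * `genotypic` (3 features/SNP, `isAA`, `isAB`, `isBB`): one-hot genotype
#'   indicators -- AA -> (1,0,0), AB -> (0,1,0), BB -> (0,0,1).
#'
#' All three encodings carry identical information (each is losslessly
#' invertible on non-missing genotypes); they differ only in how that
#' information is presented to a learner. Missing genotypes yield `NA`
#' features, resolved by training-mean imputation at standardization time
#' (see [fit_standardizer()]).
#'
#' @param x a [genotype_dataset()].
#' @param snps character vector of SNP ids to encode (subset of the
#'   dataset's SNPs), or NULL for all.
#' @param scheme `"additive"`, `"recdom"` or `"genotypic"`.
#' @return an object of class `encoded_matrix`: list with `x` (numeric
#'   samples-by-features matrix), `features` (data.frame `snp`,
#'   `component`, `name`) and `scheme`.
#' @export
encode <- function(x, snps = NULL, scheme = c("additive", "recdom",
                                              "genotypic")) {
  scheme <- match.arg(scheme)
  if (is.null(snps)) snps <- x$snps$id
  j <- match(snps, x$snps$id)
  if (anyNA(j)) stop("SNP(s) not in dataset: ",
                     paste(snps[is.na(j)], collapse = ", "))
  g <- x$geno[, j, drop = FALSE]
  storage.mode(g) <- "double"
  p <- length(j)

  if (scheme == "additive") {
    m <- g
    feats <- data.frame(snp = snps, component = "count",
                        stringsAsFactors = FALSE)
  } else if (scheme == "recdom") {
    hasA <- (g < 2) * 1
    hasB <- (g > 0) * 1
    m <- matrix(NA_real_, nrow(g), 2L * p)
    m[, seq_len(p) * 2L - 1L] <- hasA
    m[, seq_len(p) * 2L] <- hasB
    feats <- data.frame(
      snp = rep(snps, each = 2L),
      component = rep(c("hasA", "hasB"), p),
      stringsAsFactors = FALSE
    )
  } else {
    m <- matrix(NA_real_, nrow(g), 3L * p)
    m[, seq_len(p) * 3L - 2L] <- (g == 0) * 1
    m[, seq_len(p) * 3L - 1L] <- (g == 1) * 1
    m[, seq_len(p) * 3L] <- (g == 2) * 1
    feats <- data.frame(
      snp = rep(snps, each = 3L),
      component = rep(c("isAA", "isAB", "isBB"), p),
      stringsAsFactors = FALSE
    )
  }
  feats$name <- paste(feats$snp, feats$component, sep = ".")
  colnames(m) <- feats$name
  rownames(m) <- x$samples$iid
  structure(list(x = m, features = feats, scheme = scheme),
            class = "encoded_matrix")
}

#' Decode an encoded matrix back to genotype counts
#'
#' Inverse of [encode()] on non-missing genotypes; used to demonstrate
#' that the three encodings carry the same information.
#'
#' @param em an `encoded_matrix` from [encode()].
#' @return numeric matrix of minor-allele counts (0/1/2, NA missing).
#' @export
decode <- function(em) {
  stopifnot(inherits(em, "encoded_matrix"))
  m <- em$x
  p <- length(unique(em$features$snp))
  g <- switch(em$scheme,
    additive = m,
    recdom = m[, seq_len(p) * 2L, drop = FALSE] +
      (1 - m[, seq_len(p) * 2L - 1L, drop = FALSE]),
    genotypic = m[, seq_len(p) * 3L - 1L, drop = FALSE] +
      2 * m[, seq_len(p) * 3L, drop = FALSE]
  )
  colnames(g) <- unique(em$features$snp)
  g
}

#' Fit / apply feature standardization
#'
#' `fit_standardizer()` learns, from the training fold only, the per-feature
#' mean and (population, divide-by-n) standard deviation used to transform
#' every feature to zero mean and unit variance. Missing values are imputed
#' with the training-fold feature mean *before* centering, so they map to
#' exactly 0. Constant features (sigma = 0) also map to 0.
#' `apply_standardizer()` applies fitted parameters to any matrix with the
#' same features -- applying it to a row subset of a matrix is consistent
#' with applying it to the whole matrix (no re-fitting, hence no leakage
#' from the test fold).
#'
#' @param train an `encoded_matrix` from [encode()] or a numeric matrix
#'   (training fold).
#' @return `fit_standardizer()`: an object of class `standardizer` with
#'   fields `mu`, `sigma`, `features`.
#' @export
fit_standardizer <- function(train) {
  m <- if (inherits(train, "encoded_matrix")) train$x else as.matrix(train)
  n <- nrow(m)
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0  # all-missing feature
  # variance of the mean-imputed column: missing entries contribute 0
  ss <- colSums(sweep(m, 2L, mu)^2, na.rm = TRUE)
  sigma <- sqrt(ss / n)
  structure(list(mu = mu, sigma = sigma, features = colnames(m)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a fitted `standardizer`.
#' @param m an `encoded_matrix` or numeric matrix with the same features
#'   the parameters were fitted on.
#' @return `apply_standardizer()`: the standardized numeric matrix (no
#'   missing values).
#' @export
apply_standardizer <- function(params, m) {
  if (!inherits(params, "standardizer")) {
    stop("`params` must be a fitted standardizer (see fit_standardizer)")
  }
  x <- if (inherits(m, "encoded_matrix")) m$x else as.matrix(m)
  if (!identical(colnames(x), params$features)) {
    stop("feature names do not match the fitted standardizer")
  }
  x <- sweep(x, 2L, params$mu)
  x[is.na(x)] <- 0  # mean imputation: imputed value - mu = 0
  scale <- ifelse(params$sigma > 0, 1 / params$sigma, 0)
  sweep(x, 2L, scale, `*`)
}
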