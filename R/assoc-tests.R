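#' Case/control genotype contingency counts for one SNP
#'
#' The 2x3 table of genotype counts (major homozygote AA, heterozygote AB,
#' minor homozygote BB; A = major, B = minor allele) by case/control arm
#' that feeds all five single-marker association tests. Missing genotypes
#' must be excluded before counting.
#'
#' @param case,control length-3 non-negative count vectors
#'   `c(n_AA, n_AB, n_BB)`.
#' @return an object of class `contingency_counts`.
#' @export
contingency_counts <- function(case, control) {
  stopifnot(length(case) == 3L, length(control) == 3L,
            all(case >= 0), all(control >= 0))
  structure(list(case = as.numeric(case), control = as.numeric(control)),
            class = "contingency_counts")
}

# counts for every SNP at once: matrix with columns n1_0 n1_1 n1_2 n0_0 n0_1 n0_2
.count_genotypes <- function(geno, status) {
  case <- status == 1L
  gc <- geno[case, , drop = FALSE]
  g0 <- geno[!case, , drop = FALSE]
  cbind(
    n1_0 = colSums(gc == 0L, na.rm = TRUE),
    n1_1 = colSums(gc == 1L, na.rm = TRUE),
    n1_2 = colSums(gc == 2L, na.rm = TRUE),
    n0_0 = colSums(g0 == 0L, na.rm = TRUE),
    n0_1 = colSums(g0 == 1L, na.rm = TRUE),
    n0_2 = colSums(g0 == 2L, na.rm = TRUE)
  )
}

# vectorized 1-df chi-square on 2x2 tables given as parallel vectors
# (a b / c d); no continuity correction. Zero margin -> degenerate (0, 1).
.chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degen <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat <- numeric(length(a))
  ok <- !degen
  stat[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2 /
    (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  list(stat = stat,
       p = ifelse(degen, 1, stats::pchisq(stat, 1L, lower.tail = FALSE)),
       degenerate = degen)
}

# vectorized Cochran-Armitage trend chi-square, scores (0, 1, 2)
.chisq_trend <- function(cnt) {
  a0 <- cnt[, "n1_0"]; a1 <- cnt[, "n1_1"]; a2 <- cnt[, "n1_2"]
  b0 <- cnt[, "n0_0"]; b1 <- cnt[, "n0_1"]; b2 <- cnt[, "n0_2"]
  r <- a0 + a1 + a2           # cases
  s <- b0 + b1 + b2           # controls
  n0 <- a0 + b0; n1 <- a1 + b1; n2 <- a2 + b2
  n <- r + s
  sxr <- a1 + 2 * a2          # sum of scores among cases
  sxn <- n1 + 2 * n2          # sum of scores overall
  sx2n <- n1 + 4 * n2
  num <- n * (n * sxr - r * sxn)^2
  den <- r * s * (n * sx2n - sxn^2)
  degen <- den == 0 | r == 0 | s == 0
  stat <- ifelse(degen, 0, num / pmax(den, 1))
  list(stat = stat,
       p = ifelse(degen, 1, stats::pchisq(stat, 1L, lower.tail = FALSE)),
       degenerate = degen)
}

# vectorized genotypic (2x3) chi-square with df reduction: an all-zero
# genotype column is dropped and df reduced accordingly.
.chisq_genotypic <- function(cnt) {
  m <- nrow(cnt)
  r <- cnt[, "n1_0"] + cnt[, "n1_1"] + cnt[, "n1_2"]
  s <- cnt[, "n0_0"] + cnt[, "n0_1"] + cnt[, "n0_2"]
  n <- r + s
  stat <- numeric(m)
  for (j in 1:3) {
    cj <- cnt[, j] + cnt[, j + 3L]
    e1 <- r * cj / n
    e0 <- s * cj / n
    ok <- cj > 0 & n > 0
    stat[ok] <- stat[ok] + (cnt[ok, j] - e1[ok])^2 / e1[ok] +
      (cnt[ok, j + 3L] - e0[ok])^2 / e0[ok]
  }
  ncols <- (cnt[, 1L] + cnt[, 4L] > 0) + (cnt[, 2L] + cnt[, 5L] > 0) +
    (cnt[, 3L] + cnt[, 6L] > 0)
  df <- pmax(ncols - 1L, 0L)
  degen <- df == 0L | r == 0 | s == 0
  stat[degen] <- 0
  list(stat = stat,
       p = ifelse(degen, 1, stats::pchisq(stat, df, lower.tail = FALSE)),
       df = ifelse(degen, 1L, df), degenerate = degen)
}

.one_test <- function(counts, name) {
  stopifnot(inherits(counts, "contingency_counts"))
  cnt <- matrix(c(counts$case, counts$control), nrow = 1,
                dimnames = list(NULL,
                                c("n1_0", "n1_1", "n1_2",
                                  "n0_0", "n0_1", "n0_2")))
  res <- switch(name,
    allelic = {
      a <- 2 * cnt[, "n1_0"] + cnt[, "n1_1"]
      b <- cnt[, "n1_1"] + 2 * cnt[, "n1_2"]
      c_ <- 2 * cnt[, "n0_0"] + cnt[, "n0_1"]
      d <- cnt[, "n0_1"] + 2 * cnt[, "n0_2"]
      c(.chisq_2x2(a, b, c_, d), df = 1L)
    },
    dominant = c(.chisq_2x2(cnt[, "n1_0"], cnt[, "n1_1"] + cnt[, "n1_2"],
                            cnt[, "n0_0"], cnt[, "n0_1"] + cnt[, "n0_2"]),
                 df = 1L),
    recessive = c(.chisq_2x2(cnt[, "n1_0"] + cnt[, "n1_1"], cnt[, "n1_2"],
                             cnt[, "n0_0"] + cnt[, "n0_1"], cnt[, "n0_2"]),
                  df = 1L),
    genotypic = .chisq_genotypic(cnt),
    trend = c(.chisq_trend(cnt), df = 1L)
  )
  structure(list(test = name, statistic = unname(res$stat),
                 df = unname(as.integer(res$df)), p.value = unname(res$p),
                 degenerate = unname(res$degenerate)),
            class = "assoc_test_result")
}

#' Single-marker association tests on a 2x3 genotype table
#'
#' The five tests used for per-fold SNP selection, mirroring the
#' genome-wide single-marker model battery of PLINK's `--model` option:
#'
#' * `allelic_test()`: 1-df chi-square on the 2x2 allele table (each arm
#'   contributes two alleles per homozygote, one per heterozygote);
#' * `dominant_test()`: 1-df chi-square on minor-allele carriers
#'   (AB + BB) vs AA;
#' * `recessive_test()`: 1-df chi-square on BB vs (AA + AB);
#' * `genotypic_test()`: 2-df chi-square on the full 2x3 table (an
#'   all-zero genotype column is dropped and the df reduced, keeping the
#'   minimum-p filter total);
#' * `trend_test()`: Cochran-Armitage trend test with scores (0, 1, 2),
#'   1 df.
#'
#' No continuity correction is applied. A table that is degenerate for the
#' test's margin (e.g. no minor alleles at all) yields statistic 0,
#' p = 1 and `degenerate = TRUE`.
#'
#' @param counts a [contingency_counts()].
#' @return list of class `assoc_test_result` with `test`, `statistic`,
#'   `df`, `p.value`, `degenerate`.
#' @export
allelic_test <- function(counts) .one_test(counts, "allelic")

#' @rdname allelic_test
#' @export
dominant_test <- function(counts) .one_test(counts, "dominant")

#' @rdname allelic_test
#' @export
recessive_test <- function(counts) .one_test(counts, "recessive")

#' @rdname allelic_test
#' @export
genotypic_test <- function(counts) .one_test(counts, "genotypic")

#' @rdname allelic_test
#' @export
trend_test <- function(counts) .one_test(counts, "trend")

#' Genome-wide association scan over all SNPs of a dataset
#'
#' Computes the five single-marker tests of [allelic_test()] for every SNP
#' (vectorized), on a subset of samples if requested -- in the nested
#' cross-validation protocol the scan runs on the training fold only.
#' Missing genotypes are dropped per SNP before counting.
#'
#' @param x a [genotype_dataset()].
#' @param samples optional row indices restricting the scan (e.g. a
#'   training fold); default all samples.
#' @return data.frame with one row per SNP: `snp`, per-test `*_stat` and
#'   `*_p` columns, `genotypic_df`, and `min_p`, the minimum p-value over
#'   the five tests.
#' @export
assoc_scan <- function(x, samples = NULL) {
  geno <- x$geno
  status <- x$samples$status
  if (!is.null(samples)) {
    geno <- geno[samples, , drop = FALSE]
    status <- status[samples]
  }
  cnt <- .count_genotypes(geno, status)

  al <- .chisq_2x2(2 * cnt[, "n1_0"] + cnt[, "n1_1"],
                   cnt[, "n1_1"] + 2 * cnt[, "n1_2"],
                   2 * cnt[, "n0_0"] + cnt[, "n0_1"],
                   cnt[, "n0_1"] + 2 * cnt[, "n0_2"])
  dom <- .chisq_2x2(cnt[, "n1_0"], cnt[, "n1_1"] + cnt[, "n1_2"],
                    cnt[, "n0_0"], cnt[, "n0_1"] + cnt[, "n0_2"])
  rec <- .chisq_2x2(cnt[, "n1_0"] + cnt[, "n1_1"], cnt[, "n1_2"],
                    cnt[, "n0_0"] + cnt[, "n0_1"], cnt[, "n0_2"])
  gen <- .chisq_genotypic(cnt)
  tr <- .chisq_trend(cnt)

  data.frame(
    snp = x$snps$id,
    allelic_stat = al$stat, allelic_p = al$p,
    dominant_stat = dom$stat, dominant_p = dom$p,
    recessive_stat = rec$stat, recessive_p = rec$p,
    genotypic_stat = gen$stat, genotypic_df = gen$df, genotypic_p = gen$p,
    trend_stat = tr$stat, trend_p = tr$p,
    min_p = pmin(al$p, dom$p, rec$p, gen$p, tr$p),
    stringsAsFactors = FALSE
  )
}

#' Default genome-wide p-value thresholds
#'
#' The six selection thresholds applied to the per-SNP minimum p-value over
#' the five association tests, in strictly decreasing order.
#'
#' @return numeric vector `c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8)`.
#' @export
threshold_set <- function() 10^-(3:8)

#' Select SNPs by minimum association p-value on a training fold
#'
#' Retains every SNP whose minimum p-value over the five single-marker
#' tests, computed on the training samples only, is below `threshold`.
#' The returned subset is then applied unchanged to the paired test fold.
#' Retained sets are nested across thresholds by construction.
#'
#' @param x a [genotype_dataset()], or a precomputed [assoc_scan()]
#'   data.frame (in which case `samples` is ignored).
#' @param threshold p-value cutoff; SNPs with `min_p < threshold` are kept.
#' @param samples optional training-fold row indices (see [assoc_scan()]).
#' @return character vector of retained SNP ids (possibly empty).
#' @export
min_p_filter <- function(x, threshold, samples = NULL) {
  scan <- if (is.data.frame(x)) x else assoc_scan(x, samples = samples)
  scan$snp[scan$min_p < threshold]
}
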