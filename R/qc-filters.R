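#' Marker quality-control thresholds
#'
#' @param maf_min minimum minor allele frequency (markers below are
#'   excluded); default 0.05.
#' @param max_missing maximum missing-call fraction per marker; default
#'   0.05. (Stated as a genotyping-rate rule in GWAS practice; here it is
#'   the fraction of missing calls that may not be exceeded.)
#' @param hwe_alpha significance level of the Hardy-Weinberg equilibrium
#'   goodness-of-fit filter; default 0.001.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, max_missing = 0.05,
                          hwe_alpha = 0.001) {
  stopifnot(maf_min > 0, maf_min < 1, max_missing > 0, max_missing < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  structure(list(maf_min = maf_min, max_missing = max_missing,
                 hwe_alpha = hwe_alpha),
            class = "qc_thresholds")
}

#' Minor allele statistics for one SNP
#'
#' MAF and call rate are computed over non-missing calls only. If the two
#' alleles are exactly equifrequent the lexicographically smaller symbol is
#' designated minor, so the designation is deterministic.
#'
#' @param geno integer vector of counts of allele `a2` (0/1/2, NA missing).
#' @param a1,a2 allele symbols (a2 may be NA for a monomorphic SNP).
#' @return list with `minor` (allele symbol or NA), `maf` and `call_rate`.
#'   An all-missing SNP has call rate 0 and MAF 0.
#' @export
minor_allele_stats <- function(geno, a1, a2) {
  called <- !is.na(geno)
  call_rate <- mean(called)
  if (!any(called) || is.na(a2)) {
    return(list(minor = if (is.na(a2)) NA_character_ else a2,
                maf = 0, call_rate = call_rate))
  }
  f2 <- sum(geno[called]) / (2 * sum(called))  # frequency of a2
  if (f2 < 0.5) {
    list(minor = a2, maf = f2, call_rate = call_rate)
  } else if (f2 > 0.5) {
    list(minor = a1, maf = 1 - f2, call_rate = call_rate)
  } else {
    list(minor = min(a1, a2), maf = 0.5, call_rate = call_rate)
  }
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against the HWE expectations computed from the estimated allele
#' frequency. A monomorphic SNP fits HWE trivially (statistic 0, p = 1).
#'
#' @param n_aa,n_ab,n_bb observed genotype counts (major homozygote,
#'   heterozygote, minor homozygote).
#' @return list with `statistic`, `df` and `p.value`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n <= 0) stop("HWE test requires at least one called genotype")
  chi <- .hwe_chisq(n_aa, n_ab, n_bb)
  list(statistic = chi, df = 1L,
       p.value = stats::pchisq(chi, df = 1L, lower.tail = FALSE))
}

# vectorized HWE chi-square over parallel count vectors
.hwe_chisq <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  q <- (n_ab + 2 * n_bb) / (2 * n)  # minor allele frequency
  e <- cbind(n * (1 - q)^2, n * 2 * q * (1 - q), n * q^2)
  o <- cbind(n_aa, n_ab, n_bb)
  chi <- numeric(length(n))
  poly <- q > 0 & q < 1
  if (any(poly)) {
    chi[poly] <- rowSums((o[poly, , drop = FALSE] -
                          e[poly, , drop = FALSE])^2 /
                         e[poly, , drop = FALSE])
  }
  chi
}

# Vectorized per-SNP QC statistics for a set of samples.
# Returns data.frame(maf, call_rate, hwe_p) with one row per SNP.
.qc_stats <- function(geno) {
  called <- !is.na(geno)
  n_called <- colSums(called)
  call_rate <- n_called / nrow(geno)
  n0 <- colSums(geno == 0L, na.rm = TRUE)
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n2 <- colSums(geno == 2L, na.rm = TRUE)
  f2 <- ifelse(n_called > 0, (n1 + 2 * n2) / (2 * n_called), 0)
  maf <- pmin(f2, 1 - f2)
  maf[n_called == 0] <- 0
  # orient counts so the minor allele is counted; HWE chi-square is
  # symmetric in the allele labels so orientation does not matter
  ok <- n_called > 0
  hwe_p <- rep(1, ncol(geno))
  if (any(ok)) {
    chi <- .hwe_chisq(n0[ok], n1[ok], n2[ok])
    hwe_p[ok] <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  }
  data.frame(maf = maf, call_rate = call_rate, hwe_p = hwe_p)
}

# Cascade decision per SNP for one set of samples; returns a character
# vector of reasons ("pass" or first failing rule).
.qc_decide <- function(geno, thresholds) {
  s <- .qc_stats(geno)
  reason <- rep("pass", nrow(s))
  reason[s$hwe_p < thresholds$hwe_alpha] <- "hwe_fail"
  reason[1 - s$call_rate > thresholds$max_missing] <- "high_missing"
  reason[s$maf < thresholds$maf_min] <- "low_maf"
  reason
}

#' Apply the marker quality-control cascade
#'
#' Markers on the exclusion list are removed first; the remaining markers
#' then pass through the MAF, missingness and HWE filters in that order
#' (each marker is labelled with the first rule it fails). In
#' `mode = "per-cohort"` the cascade runs three times -- on cases alone, on
#' controls alone, and on the pooled samples -- and a marker survives only
#' if it passes all three passes, mirroring per-cohort-then-combined QC of
#' merged case-control studies.
#'
#' @param x a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @param exclude character vector of SNP ids to remove unconditionally.
#' @param mode `"combined"` (all samples at once, the default) or
#'   `"per-cohort"`.
#' @return list with `dataset` (the filtered [genotype_dataset()]) and
#'   `report`, a data.frame with one row per input SNP
#'   (`snp`, `reason` in `{excluded_list, low_maf, high_missing, hwe_fail,
#'   pass}`) carrying the reason counts as attribute `"counts"` and the
#'   mode/thresholds as attribute `"header"`.
#' @export
apply_qc <- function(x, thresholds = qc_thresholds(), exclude = character(),
                     mode = c("combined", "per-cohort")) {
  mode <- match.arg(mode)
  ids <- x$snps$id
  reason <- rep(NA_character_, length(ids))
  reason[ids %in% exclude] <- "excluded_list"
  todo <- is.na(reason)

  if (any(todo)) {
    g <- x$geno[, todo, drop = FALSE]
    if (mode == "combined") {
      reason[todo] <- .qc_decide(g, thresholds)
    } else {
      case <- x$samples$status == 1L
      r_case <- .qc_decide(g[case, , drop = FALSE], thresholds)
      r_ctrl <- .qc_decide(g[!case, , drop = FALSE], thresholds)
      r_all <- .qc_decide(g, thresholds)
      r <- r_case
      r[r == "pass"] <- r_ctrl[r == "pass"]
      r[r == "pass"] <- r_all[r == "pass"]
      reason[todo] <- r
    }
  }

  keep <- reason == "pass"
  if (!any(keep)) {
    warning("no SNPs survive QC; returning an empty dataset")
  }
  report <- data.frame(snp = ids, reason = reason, stringsAsFactors = FALSE)
  attr(report, "counts") <- table(factor(
    reason, levels = c("excluded_list", "low_maf", "high_missing",
                       "hwe_fail", "pass")))
  attr(report, "header") <- sprintf(
    "qc mode=%s maf_min=%g max_missing=%g (missing-call fraction above this is excluded) hwe_alpha=%g",
    mode, thresholds$maf_min, thresholds$max_missing, thresholds$hwe_alpha)
  list(dataset = subset_dataset(x, snps = which(keep)), report = report)
}
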