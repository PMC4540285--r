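#' Genetic architecture of a simulated case-control study
#'
#' Describes the marker panel and the disease model used by
#' [simulate_cohort()]. Genotypes at each SNP are drawn under
#' Hardy-Weinberg equilibrium from its minor-allele frequency `q`
#' (genotype probabilities `(1-q)^2`, `2q(1-q)`, `q^2`). Disease status
#' follows a logistic model whose linear predictor is
#' `baseline_log_odds + sum over causal SNPs of log(OR) x coding(g)`, where
#' the coding depends on the causal model:
#' * `additive`: minor-allele count 0/1/2;
#' * `dominant`: carrier indicator (g > 0);
#' * `recessive`: homozygous-minor indicator (g == 2);
#' * `genotypic`: two indicators (heterozygote, homozygous minor), each with
#'   its own odds ratio (`effect` must be length 2: `c(or_het, or_hom)`).
#'
#' @param n_snps number of biallelic autosomal SNPs.
#' @param maf per-SNP minor-allele frequency in `(0, 0.5]`; recycled to
#'   `n_snps`.
#' @param causal list of causal effects; each element a list with fields
#'   `snp` (1-based index), `model` (one of `"additive"`, `"dominant"`,
#'   `"recessive"`, `"genotypic"`) and `effect` (odds ratio(s) > 0; length 2
#'   for `"genotypic"`, length 1 otherwise).
#' @param baseline_log_odds intercept of the logistic disease model; the
#'   default `qlogis(0.1)` gives a baseline prevalence of about 10%.
#' @param missing_rate fraction of genotype calls set missing completely at
#'   random, in `[0, 1)`.
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_snps, maf = 0.3, causal = list(),
                              baseline_log_odds = stats::qlogis(0.1),
                              missing_rate = 0) {
  n_snps <- as.integer(n_snps)
  stopifnot(n_snps >= 1L, missing_rate >= 0, missing_rate < 1)
  maf <- rep_len(as.numeric(maf), n_snps)
  if (any(maf <= 0 | maf > 0.5)) stop("all MAF must lie in (0, 0.5]")
  idx <- vapply(causal, function(e) as.integer(e$snp), 1L)
  if (anyDuplicated(idx)) stop("causal SNP indices must be unique")
  if (any(idx < 1L | idx > n_snps)) stop("causal SNP index out of range")
  for (e in causal) {
    model <- match.arg(e$model,
                       c("additive", "dominant", "recessive", "genotypic"))
    want <- if (model == "genotypic") 2L else 1L
    if (length(e$effect) != want || any(e$effect <= 0)) {
      stop("causal effect for model '", model, "' must be ", want,
           " odds ratio(s) > 0")
    }
  }
  structure(
    list(n_snps = n_snps, maf = maf, causal = causal,
         baseline_log_odds = baseline_log_odds,
         missing_rate = missing_rate),
    class = "architecture_spec"
  )
}

#' Case/control quota for a simulated cohort
#'
#' @param n_cases,n_controls positive sample counts. Defaults mirror the
#'   typical size of one disease arm plus one birth-cohort control arm in a
#'   large public case-control genotyping effort (about 2,000 cases and
#'   1,500 controls).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 2000, n_controls = 1500) {
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(n_controls)
  stopifnot(n_cases > 0L, n_controls > 0L)
  structure(list(n_cases = n_cases, n_controls = n_controls),
            class = "cohort_spec")
}

#' Simulate a case-control genotype dataset
#'
#' Individuals are drawn from the population model of the architecture
#' (HWE genotypes, logistic disease status) and accumulated by rejection
#' until both case and control quotas are met exactly. MCAR missingness is
#' applied after phenotype assignment. Allele symbols are fixed as `A`
#' (major) and `B` (minor), so the simulated minor allele is the allele
#' whose frequency is the spec's MAF by construction.
#'
#' @param arch an [architecture_spec()].
#' @param cohort a [cohort_spec()].
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @param max_batches safety bound on rejection sampling: after this many
#'   batches (each of size about four times the remaining quota) an error
#'   names the unfilled quota. Guards against pathological prevalence.
#' @return a [genotype_dataset()] with cases first, then controls.
#' @export
simulate_cohort <- function(arch, cohort, seed, max_batches = 200L) {
  stopifnot(inherits(arch, "architecture_spec"),
            inherits(cohort, "cohort_spec"))
  set.seed(as.integer(seed))
  p <- arch$n_snps
  q <- arch$maf
  gprob <- cbind((1 - q)^2, 2 * q * (1 - q), q^2)  # P(0), P(1), P(2)

  need_case <- cohort$n_cases
  need_ctrl <- cohort$n_controls
  cases <- matrix(NA_integer_, 0L, p)
  ctrls <- matrix(NA_integer_, 0L, p)

  for (b in seq_len(max_batches)) {
    remaining <- (need_case - nrow(cases)) + (need_ctrl - nrow(ctrls))
    if (remaining <= 0L) break
    m <- max(200L, 4L * remaining)
    g <- .draw_hwe_genotypes(m, gprob)
    eta <- rep(arch$baseline_log_odds, m)
    for (e in arch$causal) {
      gj <- g[, e$snp]
      eta <- eta + switch(match.arg(e$model, c("additive", "dominant",
                                               "recessive", "genotypic")),
        additive  = log(e$effect) * gj,
        dominant  = log(e$effect) * (gj > 0L),
        recessive = log(e$effect) * (gj == 2L),
        genotypic = log(e$effect[1L]) * (gj == 1L) +
                    log(e$effect[2L]) * (gj == 2L)
      )
    }
    y <- stats::rbinom(m, 1L, stats::plogis(eta))
    new_cases <- g[y == 1L, , drop = FALSE]
    new_ctrls <- g[y == 0L, , drop = FALSE]
    kc <- min(nrow(new_cases), need_case - nrow(cases))
    k0 <- min(nrow(new_ctrls), need_ctrl - nrow(ctrls))
    if (kc > 0L) cases <- rbind(cases, new_cases[seq_len(kc), , drop = FALSE])
    if (k0 > 0L) ctrls <- rbind(ctrls, new_ctrls[seq_len(k0), , drop = FALSE])
  }
  if (nrow(cases) < need_case) {
    stop("case quota unreachable: got ", nrow(cases), " of ", need_case,
         " cases after ", max_batches, " batches (prevalence too low?)")
  }
  if (nrow(ctrls) < need_ctrl) {
    stop("control quota unreachable: got ", nrow(ctrls), " of ", need_ctrl,
         " controls after ", max_batches, " batches (prevalence too high?)")
  }

  geno <- rbind(cases, ctrls)
  n <- nrow(geno)
  if (arch$missing_rate > 0) {
    drop <- stats::runif(n * p) < arch$missing_rate
    geno[matrix(drop, n, p)] <- NA_integer_
  }

  ids <- sprintf("S%04d", seq_len(n))
  samples <- data.frame(
    fid = ids, iid = ids, sex = 0L,
    status = rep(c(1L, 0L), c(need_case, need_ctrl)),
    stringsAsFactors = FALSE
  )
  snps <- data.frame(
    id = sprintf("snp%04d", seq_len(p)),
    chr = "1", cm = 0, pos = seq_len(p) * 1000L,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE
  )
  genotype_dataset(samples, snps, geno)
}

.draw_hwe_genotypes <- function(m, gprob) {
  p <- nrow(gprob)
  u <- matrix(stats::runif(m * p), m, p)
  # inverse-CDF draw per SNP: g = (u > P0) + (u > P0 + P1)
  c0 <- matrix(gprob[, 1L], m, p, byrow = TRUE)
  c1 <- c0 + matrix(gprob[, 2L], m, p, byrow = TRUE)
  g <- (u > c0) + (u > c1)
  storage.mode(g) <- "integer"
  g
}

#' Write a simulated dataset as a PED/MAP fixture
#'
#' Thin wrapper over [write_ped_map()] writing `<prefix>.ped` and
#' `<prefix>.map`; round-trips losslessly through [read_ped_map()].
#'
#' @param x a [genotype_dataset()].
#' @param prefix output path prefix.
#' @return invisibly, the two paths written.
#' @export
write_fixture <- function(x, prefix) {
  write_ped_map(x, paste0(prefix, ".ped"), paste0(prefix, ".map"))
  invisible(paste0(prefix, c(".ped", ".map")))
}
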