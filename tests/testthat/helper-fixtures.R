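# Small in-code fixtures shared across test files.

# Hand-built dataset from a genotype matrix (counts of allele B, NA missing).
make_dataset <- function(geno, status, a1 = "A", a2 = "B") {
  n <- nrow(geno)
  p <- ncol(geno)
  ids <- sprintf("S%03d", seq_len(n))
  genotype_dataset(
    samples = data.frame(fid = ids, iid = ids, sex = 0L,
                         status = as.integer(status),
                         stringsAsFactors = FALSE),
    snps = data.frame(id = sprintf("snp%03d", seq_len(p)), chr = "1",
                      cm = 0, pos = seq_len(p), a1 = a1, a2 = a2,
                      stringsAsFactors = FALSE),
    geno = geno
  )
}

# Null-architecture cohort (no causal SNPs): every SNP is an independent
# null replicate.
make_null_dataset <- function(n_snps, n_cases, n_controls, maf = 0.3,
                              seed = 1) {
  simulate_cohort(
    architecture_spec(n_snps, maf = maf),
    cohort_spec(n_cases, n_controls),
    seed = seed
  )
}

# Brute-force AUC by pair counting: concordant pairs + half ties.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Independent enumeration of integer partitions (distinct algorithm from
# the recursion inside shaffer_true_counts): returns a list of partitions.
enumerate_partitions <- function(k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  gen <- function(remaining, maxpart, acc) {
    if (remaining == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    for (a in seq_len(min(remaining, maxpart))) {
      gen(remaining - a, a, c(acc, a))
    }
  }
  gen(k, k, integer(0))
  out
}
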