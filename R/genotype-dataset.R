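#' Case-control genotype dataset
#'
#' The central container of the pipeline: an ordered set of samples with a
#' binary case/control phenotype, an ordered set of biallelic SNP records,
#' and a samples-by-SNPs genotype matrix. Genotypes are stored internally as
#' the count of the SNP's second allele (`a2`, by convention the minor
#' allele) in `{0, 1, 2}`, with `NA` as the missing sentinel. The allele
#' symbols for each SNP are carried in the SNP table so that genotypes can
#' be written back to PED format losslessly.
#'
#' @param samples data.frame with columns `fid`, `iid`, `sex`
#'   (0 = unknown, 1 = male, 2 = female) and `status` (0 = control,
#'   1 = case).
#' @param snps data.frame with columns `id`, `chr`, `cm` (genetic distance),
#'   `pos`, `a1`, `a2` (allele symbols; `a1` is by convention the major
#'   allele). `a2` may be `NA` for a monomorphic SNP.
#' @param geno integer matrix, `nrow(samples)` x `nrow(snps)`, values in
#'   `{0, 1, 2, NA}`: the per-sample count of allele `a2`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, snps, geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(
    is.data.frame(samples), is.data.frame(snps),
    all(c("fid", "iid", "sex", "status") %in% names(samples)),
    all(c("id", "chr", "cm", "pos", "a1", "a2") %in% names(snps)),
    nrow(geno) == nrow(samples), ncol(geno) == nrow(snps)
  )
  if (!all(samples$status %in% c(0L, 1L))) {
    stop("phenotype must be binary: 0 (control) or 1 (case)")
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  rownames(geno) <- samples$iid
  colnames(geno) <- snps$id
  structure(
    list(samples = samples, snps = snps, geno = geno),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype_dataset: %d samples (%d cases / %d controls), %d SNPs\n",
    nrow(x$samples), sum(x$samples$status == 1L),
    sum(x$samples$status == 0L), nrow(x$snps)
  ))
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(nrow(x$samples), nrow(x$snps))

#' Number of samples / SNPs in a dataset
#'
#' @param x a [genotype_dataset()].
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_snps <- function(x) nrow(x$snps)

#' Subset a genotype dataset
#'
#' Order-preserving subsetting of samples and/or SNPs.
#'
#' @param x a [genotype_dataset()].
#' @param snps SNP ids (character) or column indices to keep.
#' @param samples row indices (integer/logical) to keep.
#' @return a `genotype_dataset`.
#' @export
subset_dataset <- function(x, snps = NULL, samples = NULL) {
  si <- seq_len(nrow(x$snps))
  if (!is.null(snps)) {
    si <- if (is.character(snps)) match(snps, x$snps$id) else si[snps]
    if (anyNA(si)) stop("unknown SNP id(s): ",
                        paste(snps[is.na(match(snps, x$snps$id))], collapse = ", "))
  }
  ri <- seq_len(nrow(x$samples))
  if (!is.null(samples)) ri <- ri[samples]
  genotype_dataset(
    samples = x$samples[ri, , drop = FALSE],
    snps = x$snps[si, , drop = FALSE],
    geno = x$geno[ri, si, drop = FALSE]
  )
}

#' Case/control status as 0/1 integer vector
#' @param x a [genotype_dataset()].
#' @return integer vector, 1 = case, 0 = control.
#' @export
case_status <- function(x) x$samples$status
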