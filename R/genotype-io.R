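#' Read a PLINK text PED/MAP file pair
#'
#' Parses whitespace-delimited PLINK text genotype files. The PED file has
#' six leading columns (`FID IID PAT MAT SEX PHENO`) followed by one pair of
#' allele tokens per SNP; the MAP file has one row per SNP
#' (`chr id cm pos`). Missing genotypes are the `0 0` allele pair; the
#' phenotype must be coded 1 (control) or 2 (case) -- every downstream stage
#' assumes a strict binary case-control design, so unknown phenotype codes
#' (0, -9) are rejected.
#'
#' Allele symbols are taken from the data: at each SNP, the more frequent
#' allele becomes `a1` (major) and the rarer `a2` (minor); an exact 50/50
#' tie is broken by making the lexicographically smaller symbol the minor
#' allele, so the designation is deterministic. More than two distinct
#' alleles at a SNP is a parse error.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return a [genotype_dataset()]; SNP order follows the MAP file.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_tok <- .read_tokens(map_path)
  if (length(map_tok) && any(lengths(map_tok) < 4L)) {
    stop("MAP line ", which(lengths(map_tok) < 4L)[1L],
         ": expected 4 columns (chr id cm pos)")
  }
  snps <- data.frame(
    id  = vapply(map_tok, `[`, "", 2L),
    chr = vapply(map_tok, `[`, "", 1L),
    cm  = as.numeric(vapply(map_tok, `[`, "", 3L)),
    pos = as.integer(vapply(map_tok, `[`, "", 4L)),
    a1 = NA_character_, a2 = NA_character_,
    stringsAsFactors = FALSE
  )
  p <- nrow(snps)

  ped_tok <- .read_tokens(ped_path)
  n <- length(ped_tok)
  expected <- 6L + 2L * p
  for (i in seq_len(n)) {
    if (length(ped_tok[[i]]) != expected) {
      stop("PED line ", i, ": expected ", expected, " fields (6 + 2 alleles x ",
           p, " SNPs), found ", length(ped_tok[[i]]))
    }
  }

  pheno <- vapply(ped_tok, `[`, "", 6L)
  if (!all(pheno %in% c("1", "2"))) {
    bad <- which(!(pheno %in% c("1", "2")))[1L]
    stop("PED line ", bad, ": phenotype code '", pheno[bad],
         "' is not 1 (control) or 2 (case)")
  }
  samples <- data.frame(
    fid = vapply(ped_tok, `[`, "", 1L),
    iid = vapply(ped_tok, `[`, "", 2L),
    sex = as.integer(vapply(ped_tok, `[`, "", 5L)),
    status = as.integer(pheno) - 1L,
    stringsAsFactors = FALSE
  )

  # allele tokens as an n x 2p character matrix
  am <- matrix("0", nrow = n, ncol = 2L * p)
  for (i in seq_len(n)) am[i, ] <- ped_tok[[i]][-(1:6)]

  geno <- matrix(NA_integer_, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    t1 <- am[, 2L * j - 1L]
    t2 <- am[, 2L * j]
    half <- xor(t1 == "0", t2 == "0")
    if (any(half)) {
      stop("PED: SNP ", snps$id[j], ", sample ", samples$iid[which(half)[1L]],
           ": half-missing genotype (one allele '0')")
    }
    obs <- c(t1, t2)
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop("PED: SNP ", snps$id[j], " has >2 distinct alleles: ",
           paste(alleles, collapse = ", "))
    }
    if (length(alleles) == 0L) next  # all missing; geno stays NA
    if (length(alleles) == 1L) {
      snps$a1[j] <- alleles
      geno[t1 != "0", j] <- 0L
      next
    }
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    # major first; exact tie -> lexicographically smaller symbol is minor
    if (cnt[1L] > cnt[2L]) {
      a1 <- alleles[1L]; a2 <- alleles[2L]
    } else if (cnt[2L] > cnt[1L]) {
      a1 <- alleles[2L]; a2 <- alleles[1L]
    } else {
      a2 <- alleles[1L]; a1 <- alleles[2L]  # alleles is sorted
    }
    snps$a1[j] <- a1
    snps$a2[j] <- a2
    called <- t1 != "0"
    geno[called, j] <- (t1[called] == a2) + (t2[called] == a2)
  }

  genotype_dataset(samples, snps, geno)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: emits single-space-delimited PED/MAP files.
#' Genotypes are written as unordered allele pairs (`a1 a1`, `a1 a2`,
#' `a2 a2`), missing as `0 0`; paternal/maternal ids are written as 0.
#' The round trip `read_ped_map(write_ped_map(x))` reproduces `x`.
#'
#' @param x a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return invisibly, a character vector of the two paths written.
#' @export
write_ped_map <- function(x, ped_path, map_path) {
  snps <- x$snps
  map_lines <- paste(snps$chr, snps$id, format(snps$cm, trim = TRUE),
                     snps$pos)
  writeLines(map_lines, map_path)

  a1 <- snps$a1
  a2 <- ifelse(is.na(snps$a2), snps$a1, snps$a2)
  n <- nrow(x$samples)
  p <- nrow(snps)
  gtok <- matrix("0 0", nrow = n, ncol = p)
  for (j in seq_len(p)) {
    g <- x$geno[, j]
    gtok[!is.na(g) & g == 0L, j] <- paste(a1[j], a1[j])
    gtok[!is.na(g) & g == 1L, j] <- paste(a1[j], a2[j])
    gtok[!is.na(g) & g == 2L, j] <- paste(a2[j], a2[j])
  }
  lead <- paste(x$samples$fid, x$samples$iid, 0, 0, x$samples$sex,
                x$samples$status + 1L)
  body <- apply(gtok, 1L, paste, collapse = " ")
  writeLines(if (p > 0L) paste(lead, body) else lead, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a marker exclusion list
#'
#' One SNP id per line; blank lines are ignored and duplicates collapse.
#'
#' @param path path to a plain-text file.
#' @return character vector of unique SNP ids (empty for an empty file).
#' @export
read_exclusion_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

.read_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
}
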