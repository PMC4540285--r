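#' Rank treatments within each benchmark problem
#'
#' For a problems-by-treatments matrix of performance values (mean AUCs),
#' assigns within each problem rank 1 to the best (highest) value and rank
#' k to the worst, with tied values receiving average ranks (half-integer
#' ranks allowed). The rank sums over problems always total
#' `n * k * (k + 1) / 2`.
#'
#' @param m numeric matrix, problems (rows) x treatments (columns), with
#'   column names; or a `results_table` pivoted via [results_matrix()].
#' @return an object of class `rank_summary`: list with `ranks` (n x k
#'   matrix), `rank_sums`, `avg_ranks`, `n`, `k`, `treatments`.
#' @export
rank_problems <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("the comparison table must have no missing cells")
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  ranks <- t(apply(m, 1L, function(r) rank(-r, ties.method = "average")))
  rank_summary(colSums(ranks), nrow(m), ranks = ranks)
}

#' Construct a rank summary from rank sums
#'
#' Used both by [rank_problems()] and to analyze published average-rank
#' tables directly (see [reconstruct_rank_sums()]). Validates rank-sum
#' conservation: the sums must total `n * k * (k + 1) / 2`.
#'
#' @param rank_sums named numeric vector of per-treatment rank sums.
#' @param n number of problems.
#' @param ranks optional full n x k rank matrix.
#' @return an object of class `rank_summary`.
#' @export
rank_summary <- function(rank_sums, n, ranks = NULL) {
  k <- length(rank_sums)
  stopifnot(k >= 2L, n >= 1L)
  total <- n * k * (k + 1) / 2
  if (abs(sum(rank_sums) - total) > 1e-8) {
    stop("rank sums total ", sum(rank_sums), " but must be n*k*(k+1)/2 = ",
         total)
  }
  treatments <- names(rank_sums)
  if (is.null(treatments)) treatments <- paste0("T", seq_len(k))
  structure(list(ranks = ranks, rank_sums = unname(rank_sums),
                 avg_ranks = unname(rank_sums) / n, n = n, k = k,
                 treatments = treatments),
            class = "rank_summary")
}

#' Recover exact rank sums from printed average ranks
#'
#' Average ranks reported to two decimals can be turned back into exact
#' rank sums when ties are resolved by average ranks: each rank sum is a
#' multiple of 0.5, so multiplying the printed average rank by `n` and
#' rounding to the nearest 0.5 recovers it exactly (as long as the
#' printing precision is finer than `0.25 / n`). Conservation of the total
#' `n * k * (k + 1) / 2` is enforced.
#'
#' @param avg_ranks named numeric vector of printed average ranks.
#' @param n number of problems the averages were taken over.
#' @return a [rank_summary()].
#' @export
reconstruct_rank_sums <- function(avg_ranks, n) {
  sums <- round(avg_ranks * n * 2) / 2
  rank_summary(sums, n)
}

#' Friedman and Iman-Davenport omnibus tests
#'
#' The Friedman chi-square statistic for k treatments over n matched
#' problems,
#' \deqn{F = \frac{12n}{k(k+1)} \left[ \sum_j R_j^2 - \frac{k(k+1)^2}{4} \right],}
#' where `R_j` are the average ranks, is approximately chi-square with
#' k - 1 df. The Iman-Davenport transform
#' \deqn{F_{ID} = \frac{(n-1) F}{n(k-1) - F}}
#' follows the F distribution with (k - 1, (k - 1)(n - 1)) df and is less
#' conservative; the reported p-value is its upper tail. When every
#' problem produces the identical ranking, `F` attains its maximum
#' `n(k-1)`, the transform diverges, and the p-value is reported as the
#' limiting 0 with `degenerate = TRUE`.
#'
#' @param rs a [rank_summary()].
#' @return list of class `friedman_result`: `statistic` (Friedman
#'   chi-square), `iman_davenport`, `df1`, `df2`, `p.value`
#'   (Iman-Davenport), `p.chisq` (chi-square approximation), `degenerate`.
#' @export
friedman_test_ranks <- function(rs) {
  stopifnot(inherits(rs, "rank_summary"))
  n <- rs$n; k <- rs$k
  if (n < 2L) stop("Friedman test requires n >= 2 problems")
  R <- rs$avg_ranks
  F_ <- 12 * n / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  p_chisq <- stats::pchisq(F_, df1, lower.tail = FALSE)
  degenerate <- (n * (k - 1) - F_) <= .Machine$double.eps * n * k
  if (degenerate) {
    fid <- Inf
    p <- 0
  } else {
    fid <- (n - 1) * F_ / (n * (k - 1) - F_)
    p <- stats::pf(fid, df1, df2, lower.tail = FALSE)
  }
  structure(list(statistic = F_, iman_davenport = fid, df1 = df1,
                 df2 = df2, p.value = p, p.chisq = p_chisq,
                 degenerate = degenerate),
            class = "friedman_result")
}

#' Pairwise z test between two treatments' average ranks
#'
#' \deqn{z = (R_i - R_j) / \sqrt{k(k+1)/(6n)}}
#' with a two-sided p-value from the normal approximation. The two-sided
#' tail is computed via `pnorm` on the negative half-line, which stays
#' accurate down to the 1e-300 scale (needed to reproduce published
#' adjusted p-values of order 1e-13 and below).
#'
#' @param rs a [rank_summary()].
#' @param i,j treatment names or indices.
#' @return list with `z`, `p.value`, `rank_diff` (`R_i - R_j`).
#' @export
pairwise_z <- function(rs, i, j) {
  stopifnot(inherits(rs, "rank_summary"))
  ii <- if (is.character(i)) match(i, rs$treatments) else i
  jj <- if (is.character(j)) match(j, rs$treatments) else j
  if (anyNA(c(ii, jj))) stop("unknown treatment")
  se <- sqrt(rs$k * (rs$k + 1) / (6 * rs$n))
  d <- rs$avg_ranks[ii] - rs$avg_ranks[jj]
  z <- d / se
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)), rank_diff = d)
}

#' Achievable numbers of true pairwise-equality hypotheses
#'
#' When k treatments are compared all-pairs, the number of pairwise
#' equality hypotheses that can be simultaneously true is constrained: if
#' the treatments split into groups of sizes `a_1, a_2, ...` (a partition
#' of k) with equality holding exactly within groups, the count of true
#' hypotheses is `sum(choose(a_i, 2))`. `shaffer_true_counts(k)` returns
#' the sorted set of all such achievable counts, the backbone of Shaffer's
#' static step-down correction. Always contains 0 and `k(k-1)/2`.
#'
#' @param k number of treatments (>= 2).
#' @return sorted integer vector.
#' @export
shaffer_true_counts <- function(k) {
  stopifnot(k >= 2L)
  # rec(r, maxp): achievable counts for partitions of r with parts <= maxp
  rec <- function(r, maxp) {
    if (r == 0L) return(0L)
    out <- integer(0)
    for (a in seq_len(min(r, maxp))) {
      out <- c(out, choose(a, 2) + rec(r - a, a))
    }
    unique(out)
  }
  sort(unique(as.integer(rec(as.integer(k), as.integer(k)))))
}

#' Shaffer static step-down multipliers
#'
#' For the sorted family of m = k(k-1)/2 pairwise p-values, the i-th
#' smallest raw p-value is multiplied by
#' `t_i = max(s in S(k) : s <= m - i + 1)`, the largest achievable number
#' of hypotheses that can still be true once the i - 1 smaller ones are
#' rejected. The sequence starts at `t_1 = m` and is non-increasing.
#'
#' @param k number of treatments.
#' @return integer vector of length `k(k-1)/2`.
#' @export
shaffer_multipliers <- function(k) {
  m <- k * (k - 1) / 2
  S <- shaffer_true_counts(k)
  vapply(seq_len(m), function(i) max(S[S <= m - i + 1]), 1L)
}

#' Shaffer static adjustment of an all-pairs p-value family
#'
#' Sorts the m raw p-values ascending, multiplies each by its step-down
#' multiplier (see [shaffer_multipliers()]), enforces monotonicity along
#' the sorted family by a running maximum, caps at 1, and maps the
#' adjusted values back to the original pair order. The family must be
#' complete: m must equal `k(k-1)/2` for some integer k.
#'
#' @param p numeric vector of all m pairwise raw p-values.
#' @return adjusted p-values in the input order.
#' @export
shaffer_adjust <- function(p) {
  m <- length(p)
  k <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(k - round(k)) > 1e-9) {
    stop("length(p) = ", m, " is not k(k-1)/2 for any integer k; ",
         "the Shaffer schedule requires the complete all-pairs family")
  }
  if (anyNA(p)) stop("missing p-values in the pairwise family")
  mult <- shaffer_multipliers(round(k))
  ord <- order(p)
  adj <- pmin(1, p[ord] * mult)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Nemenyi (Bonferroni-style) adjustment of an all-pairs family
#'
#' Multiplies every raw p-value by the number of pairwise comparisons m
#' and caps at 1. Never smaller than the Shaffer static adjustment on the
#' same family.
#'
#' @param p numeric vector of all m pairwise raw p-values.
#' @return adjusted p-values.
#' @export
nemenyi_adjust <- function(p) pmin(1, p * length(p))

#' All-pairs comparison of treatments with multiplicity correction
#'
#' Computes the pairwise z statistic and raw two-sided p for every
#' treatment pair, plus Nemenyi- and Shaffer-adjusted p-values. Pairs are
#' listed with the better treatment (lower average rank) first and ordered
#' by raw p-value.
#'
#' @param rs a [rank_summary()].
#' @return data.frame of class `pairwise_results`: `better`, `worse`,
#'   `rank_diff` (positive), `z`, `p_raw`, `p_nemenyi`, `p_shaffer`.
#' @export
posthoc_pairwise <- function(rs) {
  stopifnot(inherits(rs, "rank_summary"))
  pairs <- utils::combn(rs$k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    pz <- pairwise_z(rs, ij[1L], ij[2L])
    c(z = pz$z, p = pz$p.value, d = pz$rank_diff)
  })
  better <- ifelse(res["d", ] <= 0, pairs[1L, ], pairs[2L, ])
  worse <- ifelse(res["d", ] <= 0, pairs[2L, ], pairs[1L, ])
  out <- data.frame(
    better = rs$treatments[better],
    worse = rs$treatments[worse],
    rank_diff = abs(res["d", ]),
    z = res["z", ],
    p_raw = res["p", ],
    stringsAsFactors = FALSE
  )
  out$p_nemenyi <- nemenyi_adjust(out$p_raw)
  out$p_shaffer <- shaffer_adjust(out$p_raw)
  out <- out[order(out$p_raw, -out$rank_diff), ]
  rownames(out) <- NULL
  class(out) <- c("pairwise_results", class(out))
  out
}

#' Critical-distance grouping of treatments
#'
#' Groups treatments for a critical-distance-style diagram: treatments are
#' ordered by average rank and the maximal runs of consecutive treatments
#' within which no pairwise hypothesis is rejected (adjusted p >= alpha)
#' are emitted as connecting segments. Treatments whose difference could
#' not be declared significant end up connected.
#'
#' @param rs a [rank_summary()].
#' @param pairwise a [posthoc_pairwise()] table for the same summary.
#' @param alpha significance level (default 0.001, a stringent level
#'   suited to large benchmark families).
#' @param correction which adjusted p-value column to use.
#' @return list with `order` (treatments by increasing average rank),
#'   `avg_ranks`, and `groups`, a list of character vectors (the maximal
#'   connected segments).
#' @export
cd_groups <- function(rs, pairwise = posthoc_pairwise(rs), alpha = 0.001,
                      correction = c("shaffer", "nemenyi")) {
  correction <- match.arg(correction)
  pcol <- paste0("p_", correction)
  ord <- order(rs$avg_ranks)
  trt <- rs$treatments[ord]
  k <- rs$k
  # k x k non-rejection matrix
  conn <- matrix(TRUE, k, k, dimnames = list(trt, trt))
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise[[pcol]][r] < alpha) {
      a <- pairwise$better[r]; b <- pairwise$worse[r]
      conn[a, b] <- conn[b, a] <- FALSE
    }
  }
  segs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(conn[i:(j + 1), i:(j + 1)])) j <- j + 1
    segs[[length(segs) + 1L]] <- trt[i:j]
  }
  # keep only maximal segments
  keep <- vapply(seq_along(segs), function(a) {
    !any(vapply(seq_along(segs), function(b) {
      b != a && all(segs[[a]] %in% segs[[b]])
    }, TRUE))
  }, TRUE)
  segs <- unique(segs[keep])
  list(order = trt, avg_ranks = sort(rs$avg_ranks), groups = segs)
}

#' Pivot a results table into a problems-by-treatments matrix
#'
#' Each combination of the non-treatment design columns (e.g. dataset and
#' threshold, and algorithm when comparing encodings) defines one matched
#' problem; the treatment column spans the matrix columns.
#'
#' @param results a `results_table` from [run_experiment()] (or any
#'   data.frame with the design columns and a value column).
#' @param treatment name of the treatment column (`"encoding"` or
#'   `"algorithm"`).
#' @param value name of the value column (default `"mean_auc"`).
#' @return numeric matrix with problems as rows, treatments as columns.
#' @export
results_matrix <- function(results, treatment, value = "mean_auc") {
  stopifnot(treatment %in% names(results), value %in% names(results))
  idcols <- setdiff(intersect(names(results),
                              c("dataset", "threshold", "encoding",
                                "algorithm")),
                    treatment)
  problem <- interaction(results[idcols], drop = TRUE, lex.order = TRUE)
  trts <- unique(results[[treatment]])
  m <- matrix(NA_real_, nlevels(problem), length(trts),
              dimnames = list(levels(problem), trts))
  m[cbind(as.integer(problem), match(results[[treatment]], trts))] <-
    results[[value]]
  if (anyNA(m)) stop("incomplete design: some (problem, treatment) cells ",
                     "are missing")
  m
}

#' Compare treatments across benchmark problems
#'
#' Convenience wrapper running the full inference chain on a results
#' table: pivot to a problems-by-treatments matrix, rank within problems,
#' Friedman + Iman-Davenport omnibus test, all-pairs z tests with Nemenyi
#' and Shaffer corrections, and critical-distance grouping.
#'
#' @inheritParams results_matrix
#' @param alpha significance level for the grouping (default 0.001).
#' @return list of class `treatment_comparison`: `summary`
#'   ([rank_summary()]), `friedman`, `pairwise`, `groups`.
#' @export
compare_treatments <- function(results, treatment = c("encoding",
                                                      "algorithm"),
                               value = "mean_auc", alpha = 0.001) {
  treatment <- match.arg(treatment)
  rs <- rank_problems(results_matrix(results, treatment, value))
  fr <- friedman_test_ranks(rs)
  pw <- posthoc_pairwise(rs)
  structure(
    list(summary = rs, friedman = fr, pairwise = pw,
         groups = cd_groups(rs, pw, alpha = alpha), alpha = alpha),
    class = "treatment_comparison"
  )
}

#' @export
print.treatment_comparison <- function(x, ...) {
  rs <- x$summary
  cat(sprintf("Treatment comparison: k = %d treatments, n = %d problems\n",
              rs$k, rs$n))
  cat("average ranks (lower is better):\n")
  ar <- setNames(rs$avg_ranks, rs$treatments)
  print(round(sort(ar), 3))
  fr <- x$friedman
  cat(sprintf(
    "Friedman chi-square = %.4g; Iman-Davenport F(%d, %d) = %.4g; p = %.4g\n",
    fr$statistic, fr$df1, fr$df2, fr$iman_davenport, fr$p.value))
  cat(sprintf("pairwise (Shaffer-adjusted, alpha = %g):\n", x$alpha))
  pw <- x$pairwise
  pw$p_raw <- signif(pw$p_raw, 4)
  pw$p_shaffer <- signif(pw$p_shaffer, 4)
  pw$p_nemenyi <- signif(pw$p_nemenyi, 4)
  pw$z <- round(pw$z, 3)
  pw$rank_diff <- round(pw$rank_diff, 3)
  print(pw)
  cat("groups (no rejected difference within a group):\n")
  for (g in x$groups$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}
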