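#' Differential expression between two regions of one sample
#'
#' Per-gene two-sided Wilcoxon rank-sum test on the normalized layer between
#' two annotated regions, Bonferroni-corrected over the genes tested. The
#' fold change is computed on de-logged means with a pseudocount:
#' `log2FC = log2((mean(expm1(normA)) + 1) / (mean(expm1(normB)) + 1))`.
#' Genes are tested if detected in at least 3 spots of either group; a gene
#' is significant iff `|log2FC| > logfc_min` and adjusted p `< alpha`.
#'
#' @param sample An annotated `STSample`.
#' @param groupA,groupB Region labels (defaults `"TC"` vs `"LE"`).
#' @param logfc_min Fold-change cutoff (default 0.25).
#' @param alpha Adjusted-p cutoff (default 0.001).
#' @return A `DETable` data.frame: `gene`, `log2fc`, `p`, `p_adj`,
#'   `direction` (`"TC-up"`-style, named after `groupA`/`groupB`),
#'   `significant`.
#' @export
de_table <- function(sample, groupA = "TC", groupB = "LE",
                     logfc_min = 0.25, alpha = 0.001) {
  stop_if_not(!is.null(sample$norm), "run normalize_counts() first")
  ia <- which(sample$region == groupA)
  ib <- which(sample$region == groupB)
  stop_if_not(length(ia) >= 3 && length(ib) >= 3,
              "each group needs at least 3 spots for a stable rank-sum test")
  A <- sample$norm[ia, , drop = FALSE]
  B <- sample$norm[ib, , drop = FALSE]
  tested <- which(colSums(A > 0) >= 3 | colSums(B > 0) >= 3)
  m <- length(tested)
  stop_if_not(m > 0, "no genes pass the detection filter")
  log2fc <- log2((colMeans(expm1(A[, tested, drop = FALSE])) + 1) /
                   (colMeans(expm1(B[, tested, drop = FALSE])) + 1))
  p <- vapply(tested, function(j)
    rank_sum_test(sample$norm[ia, j], sample$norm[ib, j]), 0)
  p_adj <- pmin(1, p * m)  # Bonferroni over genes tested
  out <- data.frame(
    gene = colnames(sample$norm)[tested],
    log2fc = unname(log2fc), p = p, p_adj = p_adj,
    direction = ifelse(log2fc > 0, paste0(groupA, "-up"),
                       paste0(groupB, "-up")),
    significant = abs(log2fc) > logfc_min & p_adj < alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DETable", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution (via [stats::wilcox.test()]) when both groups
#' have at most 8 observations and no ties are present; otherwise the
#' normal approximation with midranks, tie-corrected variance, and
#' continuity correction.
#'
#' @param x,y Numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Consensus differential expression across samples
#'
#' A gene enters the consensus iff it is significant with the same direction
#' in at least `min_samples` per-sample tables. Its cumulative log2
#' fold-change sums the qualifying samples' values. Genes are ranked by the
#' number of supporting samples, then by absolute cumulative fold-change.
#'
#' @param tables List of `DETable`s from [de_table()].
#' @param min_samples Minimum supporting samples (default 10).
#' @return A `ConsensusTable` data.frame: `gene`, `direction`,
#'   `n_samples_significant`, `cum_log2fc`.
#' @export
consensus_genes <- function(tables, min_samples = 10) {
  stop_if_not(length(tables) >= 1, "need at least one DE table")
  stop_if_not(min_samples <= length(tables),
              "min_samples exceeds the number of tables")
  sig <- do.call(rbind, lapply(tables, function(tb)
    tb[tb$significant, c("gene", "direction", "log2fc")]))
  if (is.null(sig) || nrow(sig) == 0) {
    out <- data.frame(gene = character(), direction = character(),
                      n_samples_significant = integer(),
                      cum_log2fc = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("ConsensusTable", "data.frame")
    return(out)
  }
  key <- paste(sig$gene, sig$direction)
  n <- tapply(sig$log2fc, key, length)
  cum <- tapply(sig$log2fc, key, sum)
  keep <- n >= min_samples
  parts <- strsplit(names(n)[keep], " ", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    direction = vapply(parts, `[`, "", 2),
    n_samples_significant = as.integer(n[keep]),
    cum_log2fc = as.numeric(cum[keep]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_samples_significant, -abs(out$cum_log2fc)), ]
  rownames(out) <- NULL
  class(out) <- c("ConsensusTable", "data.frame")
  out
}

#' Region-by-sample whole-transcriptome correlation matrix
#'
#' Pearson correlation between region-mean normalized expression profiles
#' across samples: one profile per (sample, region) pair.
#'
#' @param samples Named list of annotated `STSample`s.
#' @param regions Regions to profile (default TC and LE).
#' @return Symmetric correlation matrix with `sample.region` dimnames.
#' @export
region_correlation_matrix <- function(samples, regions = c("TC", "LE")) {
  if (is.null(names(samples)))
    names(samples) <- paste0("s", seq_along(samples))
  profs <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    for (r in regions) {
      idx <- which(s$region == r)
      stop_if_not(length(idx) > 0,
                  sprintf("sample %s lacks region %s", nm, r))
      profs[[paste(nm, r, sep = ".")]] <- colMeans(s$norm[idx, ,
                                                          drop = FALSE])
    }
  }
  pm <- do.call(cbind, profs)
  stop_if_not(all(apply(pm, 2, stats::sd) > 0),
              "zero-variance expression profile")
  stats::cor(pm)
}
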