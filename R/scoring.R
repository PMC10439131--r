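#' Control-bin module score per spot
#'
#' Re-implementation of the standard single-cell module score: all genes are
#' binned into `n_bins` equal-frequency bins by mean expression; for each
#' signature gene, `n_ctrl` control genes are sampled with replacement from
#' its bin; the score is the mean expression of the signature genes minus
#' the mean expression of the pooled control draws, per spot.
#'
#' @param norm Spot x gene normalized expression matrix.
#' @param gene_set Character vector of signature genes; genes absent from
#'   the matrix are dropped with a warning.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes sampled per signature gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return Numeric vector of per-spot scores (named by spot).
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  missing <- setdiff(gene_set, colnames(norm))
  if (length(missing)) {
    warning("dropping ", length(missing), " signature gene(s) not measured")
    gene_set <- setdiff(gene_set, missing)
  }
  stop_if_not(length(gene_set) > 0, "empty gene set after filtering")
  avg <- colMeans(norm)
  ## equal-frequency bins; rank ties broken deterministically
  n_bins <- min(n_bins, ncol(norm))
  bin <- if (n_bins == 1) rep(1L, ncol(norm)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- colnames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  sig_mean <- rowMeans(norm[, gene_set, drop = FALSE])
  ctrl_mean <- rowMeans(norm[, ctrl, drop = FALSE])
  out <- sig_mean - ctrl_mean
  names(out) <- rownames(norm)
  out
}

#' Signed composite score from up- and down-regulated gene sets
#'
#' The contribution of genes expected up and genes expected down are
#' combined as `module_score(up) - module_score(down)`, so a spot matching
#' the program's direction on both arms scores high.
#'
#' @param norm Spot x gene normalized expression matrix.
#' @param up_set,down_set Character vectors (either may be empty, not both).
#' @param ... Passed to [module_score()].
#' @return Numeric vector of per-spot scores.
#' @export
signed_score <- function(norm, up_set, down_set = character(), ...) {
  stop_if_not(length(up_set) + length(down_set) > 0,
              "up_set and down_set are both empty")
  up <- if (length(up_set)) module_score(norm, up_set, ...) else 0
  down <- if (length(down_set)) module_score(norm, down_set, ...) else 0
  up - down
}

#' Rank-based single-sample gene-set score
#'
#' Genes are midranked ascending within the sample; the score is the set's
#' mean rank, min-max normalized by the smallest and largest mean ranks
#' achievable for a set of that size, centered to `[-0.5, 0.5]`:
#' a set of the top-expressed genes scores +0.5, of the bottom-expressed
#' genes -0.5.
#'
#' @param expr Numeric vector of expression values named by gene (one
#'   sample), or a gene x sample matrix (scored per column).
#' @param gene_set Character vector of set genes (must be measured).
#' @return Score in `[-0.5, 0.5]`, or a per-sample vector for a matrix.
#' @export
rank_score <- function(expr, gene_set) {
  if (is.matrix(expr)) {
    return(apply(expr, 2, rank_score, gene_set = gene_set))
  }
  stop_if_not(!is.null(names(expr)), "expression vector must be gene-named")
  gene_set <- unique(gene_set)
  stop_if_not(length(gene_set) >= 1, "empty gene set")
  stop_if_not(all(gene_set %in% names(expr)),
              "gene set contains unmeasured genes")
  n <- length(expr); k <- length(gene_set)
  stop_if_not(k <= n, "gene set larger than the transcriptome")
  r <- rank(expr, ties.method = "average")
  mean_rank <- mean(r[gene_set])
  mu_min <- (k + 1) / 2
  mu_max <- (2 * n - k + 1) / 2
  (mean_rank - mu_min) / (mu_max - mu_min) - 0.5
}

#' Compare signature scores across regions
#'
#' Paired mode reduces scores to per-sample region means and applies the
#' two-sided Wilcoxon signed-rank test across samples; unpaired mode
#' applies the two-sided rank-sum test at spot level. P-values are adjusted
#' across the supplied comparisons.
#'
#' @param scores Data.frame with columns `score`, `region`, `sample`, and
#'   optionally `signature` (each signature tested separately).
#' @param regions Length-2 character vector of region labels to compare.
#' @param paired_by_sample If `TRUE` (default), paired per-sample means.
#' @param correction `"bonferroni"` or `"BH"`.
#' @return Data.frame: `signature`, `statistic`, `p`, `p_adj`.
#' @export
compare_region_scores <- function(scores, regions = c("TC", "LE"),
                                  paired_by_sample = TRUE,
                                  correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (is.null(scores$signature)) scores$signature <- "signature"
  out <- do.call(rbind, lapply(split(scores, scores$signature), function(df) {
    a <- df[df$region == regions[1], ]
    b <- df[df$region == regions[2], ]
    stop_if_not(nrow(a) > 0 && nrow(b) > 0, "a region has no scores")
    if (paired_by_sample) {
      am <- tapply(a$score, a$sample, mean)
      bm <- tapply(b$score, b$sample, mean)
      common <- intersect(names(am), names(bm))
      stop_if_not(length(common) == length(union(names(am), names(bm))),
                  "paired mode requires both regions in every sample")
      if (all(am[common] == bm[common])) {
        ## all paired differences zero: no evidence against the null
        ht <- list(statistic = 0, p.value = 1)
      } else {
        ht <- suppressWarnings(stats::wilcox.test(am[common], bm[common],
                                                  paired = TRUE))
      }
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a$score, b$score))
    }
    data.frame(signature = df$signature[1],
               statistic = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- adjust_p(out$p, correction)
  rownames(out) <- NULL
  out
}
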