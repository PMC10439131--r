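#' Non-malignant neighbor composition of the TC and LE
#'
#' For each region of interest, collects the non-malignant spots directly
#' adjacent (hexagonal contact) to at least one spot of that region,
#' classifies them by their largest non-cancer deconvolution proportion, and
#' counts them per cell type. A non-malignant spot is counted at most once
#' per region; a spot touching both TC and LE contributes to both.
#'
#' @param sample An annotated `STSample` (regions and cell types assigned).
#' @param regions Regions whose borders are profiled (default TC and LE;
#'   transitory neighbors are excluded from the comparison by design).
#' @return Long-format data.frame: `region`, `cell_type`, `count`, with all
#'   (region, non-cancer cell type) combinations present.
#' @export
neighbor_composition <- function(sample, regions = c("TC", "LE")) {
  stop_if_not(!is.null(sample$cell_type), "run assign_noncancer_type() first")
  stop_if_not(any(sample$region %in% regions), "no spots in the regions")
  adj <- hex_adjacency(sample$lattice)
  types <- setdiff(colnames(sample$deconv), "cancer")
  ids <- sample$lattice$spot_id
  out <- expand.grid(region = regions, cell_type = types,
                     stringsAsFactors = FALSE)
  out$count <- 0L
  for (r in regions) {
    member <- ids[sample$region == r]
    nbr <- unique(unlist(adj[member], use.names = FALSE))
    nbr_idx <- match(nbr, ids)
    nbr_idx <- nbr_idx[!sample$malignant[nbr_idx]]
    if (!length(nbr_idx)) next
    tab <- table(sample$cell_type[nbr_idx])
    sel <- out$region == r
    out$count[sel] <- as.integer(tab[out$cell_type[sel]])
    out$count[sel][is.na(out$count[sel])] <- 0L
  }
  out
}

#' Compare TC-vs-LE neighbor counts across samples
#'
#' Per cell type, a two-sided Wilcoxon rank-sum test of the per-sample TC
#' counts against the per-sample LE counts, with Benjamini-Hochberg
#' correction across cell types. Cell types absent from every sample are
#' skipped with a warning.
#'
#' @param counts Data.frame binding [neighbor_composition()] outputs with a
#'   `sample` column added.
#' @return Data.frame: `cell_type`, `statistic`, `p`, `p_adj`, and the mean
#'   per-sample counts in each region.
#' @export
compare_composition <- function(counts) {
  stop_if_not(length(unique(counts$sample)) >= 2,
              "need at least 2 samples")
  res <- list()
  for (ct in unique(counts$cell_type)) {
    df <- counts[counts$cell_type == ct, ]
    a <- df$count[df$region == "TC"]
    b <- df$count[df$region == "LE"]
    if (all(c(a, b) == 0)) {
      warning("cell type '", ct, "' absent from all samples; skipped")
      next
    }
    ht <- if (length(unique(c(a, b))) == 1) {
      ## identical constant counts carry no evidence either way
      list(statistic = length(a) * length(b) / 2, p.value = 1)
    } else {
      suppressWarnings(stats::wilcox.test(a, b))
    }
    res[[ct]] <- data.frame(cell_type = ct, statistic = unname(ht$statistic),
                            p = ht$p.value, mean_TC = mean(a),
                            mean_LE = mean(b), stringsAsFactors = FALSE)
  }
  stop_if_not(length(res) > 0, "no cell type observed in any sample")
  out <- do.call(rbind, res)
  out$p_adj <- adjust_p(out$p, "BH")
  rownames(out) <- NULL
  out
}
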