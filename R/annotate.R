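#' Filter low-coverage spots and log-normalize counts
#'
#' Spots detecting fewer than `min_features` genes are removed. Counts are
#' scaled to the median library size and log-transformed:
#' `norm = log1p(counts / lib * median(lib))`. Gene order is preserved.
#'
#' @param sample An `STSample`.
#' @param min_features Minimum number of detected genes per spot
#'   (default 200; spots with fewer are excluded).
#' @return The sample, possibly with fewer spots, with a `norm` layer.
#' @export
normalize_counts <- function(sample, min_features = 200) {
  detected <- rowSums(sample$counts > 0)
  keep <- detected >= min_features
  if (!any(keep)) stop("all spots filtered out by the feature threshold",
                       call. = FALSE)
  sample <- subset_spots(sample, keep)
  lib <- rowSums(sample$counts)
  sample$norm <- log1p(sample$counts / lib * stats::median(lib))
  sample
}

## Row-subset every per-spot slot consistently.
subset_spots <- function(sample, keep) {
  idx <- which(keep)
  sample$lattice <- sample$lattice[idx, , drop = FALSE]
  rownames(sample$lattice) <- NULL
  for (ly in c("counts", "spliced", "unspliced", "norm")) {
    if (!is.null(sample[[ly]])) sample[[ly]] <- sample[[ly]][idx, ,
                                                             drop = FALSE]
  }
  sample$deconv <- sample$deconv[idx, , drop = FALSE]
  for (v in c("p_cnv", "pathology", "malignant", "cell_type", "cluster",
              "region")) {
    if (!is.null(sample[[v]])) sample[[v]] <- sample[[v]][idx]
  }
  if (!is.null(sample$truth)) {
    for (v in c("region", "cell_type", "pseudotime", "cnv_only")) {
      if (!is.null(sample$truth[[v]])) sample$truth[[v]] <-
          sample$truth[[v]][idx]
    }
  }
  sample
}

#' Call malignant spots by the dual-probability rule
#'
#' A spot is malignant iff its cancer deconvolution proportion exceeds
#' `threshold` OR its CNV mutant-versus-normal probability exceeds
#' `threshold` (strict inequalities), AND the pathologist annotated the spot
#' as squamous cell carcinoma (`pathology == "SCC"`).
#'
#' @param sample An `STSample`.
#' @param threshold Probability cutoff (default 0.99, strict `>`).
#' @return The sample with a logical `malignant` slot.
#' @export
call_malignant <- function(sample, threshold = 0.99) {
  stop_if_not("cancer" %in% colnames(sample$deconv),
              "deconv lacks a 'cancer' column")
  stop_if_not(!is.null(sample$p_cnv) && !is.null(sample$pathology),
              "p_cnv and pathology channels are required")
  sample$malignant <- unname(
    (sample$deconv[, "cancer"] > threshold | sample$p_cnv > threshold) &
      sample$pathology == "SCC")
  sample$region <- ifelse(sample$malignant, "unassigned", "non-malignant")
  sample
}

#' Type non-malignant spots by their largest non-cancer proportion
#'
#' Assigns each non-malignant spot the cell type with the largest
#' deconvolution proportion among non-cancer columns. Exact ties are broken
#' by the declared column order of the deconvolution matrix (first wins).
#'
#' @param sample An `STSample` after [call_malignant()].
#' @return The sample with a `cell_type` slot (`"cancer"` on malignant
#'   spots).
#' @export
assign_noncancer_type <- function(sample) {
  stop_if_not(!is.null(sample$malignant), "run call_malignant() first")
  nc <- sample$deconv[, colnames(sample$deconv) != "cancer", drop = FALSE]
  ## max.col with ties.method = "first" implements the documented tie rule
  type <- colnames(nc)[max.col(nc, ties.method = "first")]
  sample$cell_type <- ifelse(sample$malignant, "cancer", type)
  sample
}

#' Cluster malignant spots by community detection
#'
#' Builds a shared-nearest-neighbor (SNN) graph in principal-component space
#' of the normalized layer (malignant spots only) and partitions it with
#' Louvain community detection.
#'
#' @param sample An `STSample` after [normalize_counts()] and
#'   [call_malignant()].
#' @param resolution Louvain resolution (default 1.0).
#' @param n_pcs Number of principal components (default 30; reduced with a
#'   warning when fewer spots are available).
#' @param k Neighbors for the SNN graph (default 20).
#' @param seed Integer seed (community detection is stochastic).
#' @return The sample with an integer `cluster` slot on malignant spots
#'   (`NA` elsewhere).
#' @export
cluster_malignant <- function(sample, resolution = 1.0, n_pcs = 30,
                              k = 20, seed = 1) {
  stop_if_not(!is.null(sample$norm), "run normalize_counts() first")
  stop_if_not(!is.null(sample$malignant), "run call_malignant() first")
  mi <- which(sample$malignant)
  stop_if_not(length(mi) >= 2, "need at least 2 malignant spots")
  if (length(mi) <= n_pcs) {
    n_pcs <- max(2L, length(mi) - 1L)
    warning("fewer malignant spots than requested PCs; using ", n_pcs)
  }
  pcs <- pca_embed(sample$norm[mi, , drop = FALSE], n_pcs)
  k <- min(k, length(mi) - 1L)
  snn <- snn_graph(pcs, k)
  cl <- with_seed(seed, igraph::cluster_louvain(snn, resolution = resolution))
  sample$cluster <- rep(NA_integer_, n_spots(sample))
  sample$cluster[mi] <- as.integer(igraph::membership(cl))
  attr(sample$cluster, "pcs") <- pcs
  sample
}

## PCA embedding of a (spots x genes) matrix; columns are centered and
## unit-scaled (constant genes dropped from scaling).
pca_embed <- function(x, d) {
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE])
  d <- min(d, ncol(x), nrow(x) - 1L)
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = d)
  emb <- pr$x
  rownames(emb) <- rownames(x)
  attr(emb, "rotation") <- pr$rotation
  attr(emb, "genes") <- colnames(x)
  emb
}

## kNN indices by Euclidean distance (brute force; desk scale).
knn_index <- function(emb, k) {
  dm <- as.matrix(stats::dist(emb))
  diag(dm) <- Inf
  t(apply(dm, 1, function(r) order(r)[seq_len(k)]))
}

## Seurat-style SNN: Jaccard overlap of kNN sets, pruned below 1/15.
snn_graph <- function(emb, k) {
  nn <- knn_index(emb, k)
  n <- nrow(emb)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  ## include self so singleton neighborhoods still overlap
  adj <- adj + Matrix::Diagonal(n)
  ov <- Matrix::tcrossprod(adj)
  ks <- Matrix::rowSums(adj)
  jac <- as.matrix(ov) / (outer(ks, ks, `+`) - as.matrix(ov))
  jac[jac < 1 / 15] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Annotate malignant clusters as TC, transitory, and LE
#'
#' Builds an average-linkage hierarchical tree over cluster-mean PC
#' embeddings, cuts it into three nodal groups, and labels the group with
#' the highest mean core-marker expression as tumor core (TC), the group
#' with the highest mean edge-marker expression as leading edge (LE), and
#' the remainder as transitory.
#'
#' @param sample An `STSample` after [cluster_malignant()].
#' @param core_markers,edge_markers Marker gene sets (defaults CLDN4/SPRR1B
#'   and LAMC2/ITGA5).
#' @return The sample with `region` set on malignant spots and a
#'   `region_annotation` attribute (data.frame of cluster, nodal group,
#'   region, marker scores).
#' @export
annotate_regions <- function(sample,
                             core_markers = c("CLDN4", "SPRR1B"),
                             edge_markers = c("LAMC2", "ITGA5")) {
  stop_if_not(!is.null(sample$cluster), "run cluster_malignant() first")
  mi <- which(sample$malignant)
  cl <- sample$cluster[mi]
  ids <- sort(unique(cl))
  stop_if_not(length(ids) >= 3,
              "need at least 3 clusters to cut into 3 nodal groups")
  core_markers <- intersect(core_markers, colnames(sample$norm))
  edge_markers <- intersect(edge_markers, colnames(sample$norm))
  stop_if_not(length(core_markers) > 0 && length(edge_markers) > 0,
              "marker sets not present in the sample")
  pcs <- attr(sample$cluster, "pcs")
  cmeans <- do.call(rbind, lapply(ids, function(g)
    colMeans(pcs[cl == g, , drop = FALSE])))
  rownames(cmeans) <- ids
  tree <- stats::hclust(stats::dist(cmeans), method = "average")
  nodal <- stats::cutree(tree, k = 3)
  group_of_spot <- nodal[as.character(cl)]
  score <- function(markers, g)
    mean(sample$norm[mi[group_of_spot == g], markers, drop = FALSE])
  core_s <- vapply(1:3, function(g) score(core_markers, g), 0)
  edge_s <- vapply(1:3, function(g) score(edge_markers, g), 0)
  if (diff(range(core_s)) < 1e-12 || diff(range(edge_s)) < 1e-12)
    stop("marker scores do not separate the nodal groups; ",
         "labeling undefined", call. = FALSE)
  tc <- which.max(core_s); le <- which.max(edge_s)
  if (tc == le) stop("core and edge marker maxima coincide; ",
                     "regions cannot be labeled", call. = FALSE)
  lab <- rep("transitory", 3)
  lab[tc] <- "TC"; lab[le] <- "LE"
  sample$region[mi] <- lab[group_of_spot]
  ann <- data.frame(cluster = ids, nodal_group = as.integer(nodal),
                    region = lab[nodal],
                    core_score = core_s[nodal], edge_score = edge_s[nodal])
  attr(sample, "region_annotation") <- ann
  sample
}

#' Run the full annotation pipeline on a sample
#'
#' Convenience wrapper: [normalize_counts()], [call_malignant()],
#' [assign_noncancer_type()], [cluster_malignant()], [annotate_regions()].
#'
#' @param sample An `STSample`.
#' @param threshold Malignancy threshold (default 0.99).
#' @param resolution Louvain resolution (default 1.0).
#' @param seed Integer seed for clustering.
#' @param ... Passed to [annotate_regions()].
#' @return The annotated sample.
#' @export
annotate_sample <- function(sample, threshold = 0.99, resolution = 1.0,
                            seed = 1, ...) {
  sample <- normalize_counts(sample)
  sample <- call_malignant(sample, threshold)
  sample <- assign_noncancer_type(sample)
  sample <- cluster_malignant(sample, resolution = resolution, seed = seed)
  annotate_regions(sample, ...)
}
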