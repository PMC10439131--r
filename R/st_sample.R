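#' Spatial transcriptomics sample container
#'
#' An `STSample` bundles everything downstream stages need for one tissue
#' section: the hexagonal lattice, a spot x gene count matrix, optional
#' spliced/unspliced layers for velocity analysis, per-spot cell-type
#' deconvolution proportions, a per-spot copy-number ("mutant versus normal")
#' probability, a pathology label, and slots filled in by the annotation
#' pipeline (`norm`, `malignant`, `cell_type`, `cluster`, `region`).
#'
#' @param lattice Lattice data.frame (see [generate_hex_lattice()]); rows
#'   must match the count matrix rows.
#' @param counts Spot x gene matrix of non-negative integer counts with
#'   rownames = spot ids and colnames = gene names.
#' @param deconv Spot x cell-type matrix of proportions; rows must sum to 1
#'   within 1e-9 and must contain a `cancer` column.
#' @param p_cnv Numeric vector in `[0, 1]`, one value per spot.
#' @param pathology Character vector of pathologist labels per spot (the
#'   malignancy rule gates on the value `"SCC"`).
#' @param spliced,unspliced Optional same-shape layers of spliced and
#'   unspliced (pre-mRNA) counts.
#' @param truth Optional list of simulation ground truth (region, cell type,
#'   pseudotime, driver genes); carried for validation, never consumed by the
#'   analysis stages.
#' @return An object of class `STSample`.
#' @export
st_sample <- function(lattice, counts, deconv, p_cnv, pathology,
                      spliced = NULL, unspliced = NULL, truth = NULL) {
  n <- nrow(counts)
  stop_if_not(nrow(lattice) == n, "lattice and counts disagree on spot count")
  stop_if_not(!is.null(rownames(counts)) &&
                identical(rownames(counts), lattice$spot_id),
              "counts rownames must equal lattice spot_id")
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  stop_if_not(is.matrix(deconv) && nrow(deconv) == n &&
                "cancer" %in% colnames(deconv),
              "deconv must be a spot x cell-type matrix with a 'cancer' column")
  stop_if_not(max(abs(rowSums(deconv) - 1)) < 1e-9,
              "deconv rows must sum to 1 within 1e-9")
  stop_if_not(length(p_cnv) == n && all(p_cnv >= 0 & p_cnv <= 1),
              "p_cnv must be per-spot probabilities")
  stop_if_not(length(pathology) == n, "pathology must be per-spot")
  for (layer in list(spliced, unspliced)) {
    if (!is.null(layer)) {
      stop_if_not(identical(dim(layer), dim(counts)),
                  "spliced/unspliced layers must match counts in shape")
    }
  }
  structure(list(
    lattice = lattice, counts = counts,
    spliced = spliced, unspliced = unspliced,
    norm = NULL,
    deconv = deconv, p_cnv = p_cnv, pathology = pathology,
    malignant = NULL, cell_type = NULL, cluster = NULL,
    region = rep("unassigned", n),
    truth = truth
  ), class = "STSample")
}

#' @export
print.STSample <- function(x, ...) {
  cat("STSample:", nrow(x$counts), "spots x", ncol(x$counts), "genes\n")
  cat("  layers:", paste(c("counts",
                           if (!is.null(x$spliced)) "spliced",
                           if (!is.null(x$unspliced)) "unspliced",
                           if (!is.null(x$norm)) "norm"), collapse = ", "), "\n")
  if (!is.null(x$malignant)) {
    cat("  malignant:", sum(x$malignant), "of", length(x$malignant), "\n")
  }
  if (any(x$region != "unassigned")) {
    cat("  regions:", paste(names(table(x$region)), table(x$region),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spots / genes in a sample
#' @param sample An `STSample`.
#' @export
n_spots <- function(sample) nrow(sample$counts)

#' @rdname n_spots
#' @export
n_genes <- function(sample) ncol(sample$counts)

#' Write / read an STSample as plain-text files
#'
#' Count layers go to Matrix Market (`.mtx`) with `genes.tsv` /
#' `barcodes.tsv` companions; per-spot metadata (coordinates, deconvolution,
#' `p_cnv`, pathology, and any annotation columns) to `spots.csv`.
#'
#' @param sample An `STSample`.
#' @param dir Output directory (created if missing).
#' @return `write_st_sample` returns `dir` invisibly; `read_st_sample`
#'   returns an `STSample` (annotation slots are restored when present).
#' @export
write_st_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- c("counts", "spliced", "unspliced")
  for (ly in layers) {
    m <- sample[[ly]]
    if (is.null(m)) next
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE),
                    file.path(dir, paste0(ly, ".mtx")))
  }
  writeLines(colnames(sample$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(sample$counts), file.path(dir, "barcodes.tsv"))
  meta <- data.frame(sample$lattice,
                     p_cnv = sample$p_cnv,
                     pathology = sample$pathology,
                     region = sample$region,
                     stringsAsFactors = FALSE)
  dv <- as.data.frame(sample$deconv)
  names(dv) <- paste0("deconv.", colnames(sample$deconv))
  meta <- cbind(meta, dv)
  if (!is.null(sample$malignant)) meta$malignant <- sample$malignant
  if (!is.null(sample$cell_type)) meta$cell_type <- sample$cell_type
  if (!is.null(sample$cluster))   meta$cluster <- sample$cluster
  utils::write.csv(meta, file.path(dir, "spots.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_st_sample
#' @export
read_st_sample <- function(dir) {
  genes <- readLines(file.path(dir, "genes.tsv"))
  spots <- readLines(file.path(dir, "barcodes.tsv"))
  read_layer <- function(name) {
    f <- file.path(dir, paste0(name, ".mtx"))
    if (!file.exists(f)) return(NULL)
    m <- t(as.matrix(Matrix::readMM(f)))
    dimnames(m) <- list(spots, genes)
    m
  }
  meta <- utils::read.csv(file.path(dir, "spots.csv"),
                          stringsAsFactors = FALSE)
  lattice <- meta[, c("spot_id", "array_row", "array_col", "in_tissue")]
  dcols <- grep("^deconv\\.", names(meta), value = TRUE)
  deconv <- as.matrix(meta[, dcols])
  colnames(deconv) <- sub("^deconv\\.", "", dcols)
  ## proportions round-trip through text; renormalize to restore the
  ## rows-sum-to-one invariant exactly
  deconv <- deconv / rowSums(deconv)
  rownames(deconv) <- meta$spot_id
  out <- st_sample(lattice, read_layer("counts"), deconv,
                   meta$p_cnv, meta$pathology,
                   spliced = read_layer("spliced"),
                   unspliced = read_layer("unspliced"))
  out$region <- meta$region
  if ("malignant" %in% names(meta)) out$malignant <- meta$malignant
  if ("cell_type" %in% names(meta)) out$cell_type <- meta$cell_type
  if ("cluster" %in% names(meta))   out$cluster <- meta$cluster
  out
}
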