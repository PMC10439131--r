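make_channels_sample <- function(deconv_cancer, p_cnv, pathology) {
  n <- length(deconv_cancer)
  lat <- generate_hex_lattice(1, 2 * n)
  lat <- lat[seq_len(n), ]
  counts <- matrix(1L, n, 3, dimnames = list(lat$spot_id, c("A", "B", "C")))
  deconv <- cbind(cancer = deconv_cancer,
                  CAF = (1 - deconv_cancer) * 0.6,
                  macrophage = (1 - deconv_cancer) * 0.4)
  rownames(deconv) <- lat$spot_id
  st_sample(lat, counts, deconv, p_cnv, pathology)
}

test_that("malignancy rule follows the dual-threshold OR plus pathology gate", {
  s <- make_channels_sample(c(0.995, 0.50, 0.995, 0.99),
                            c(0.50, 0.995, 0.995, 0.99),
                            c("SCC", "SCC", "stroma", "SCC"))
  s <- call_malignant(s)
  ## deconvolution branch; CNV branch; pathology gate; strict boundary
  expect_identical(unname(s$malignant), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("malignancy rule equals the truth-table oracle on random triples", {
  set.seed(99)
  n <- 10000
  dc <- round(runif(n), 3)
  pc <- round(runif(n), 3)
  path <- sample(c("SCC", "stroma", "dysplasia"), n, replace = TRUE)
  s <- make_channels_sample(dc, pc, path)
  s <- call_malignant(s, threshold = 0.99)
  oracle <- vapply(seq_len(n), function(i) {
    (dc[i] > 0.99 || pc[i] > 0.99) && path[i] == "SCC"
  }, TRUE)
  expect_identical(unname(s$malignant), oracle)
})

test_that("non-cancer typing takes the largest non-cancer proportion", {
  lat <- generate_hex_lattice(1, 6)
  counts <- matrix(1L, 3, 2, dimnames = list(lat$spot_id, c("A", "B")))
  deconv <- rbind(c(0.60, 0.30, 0.10),
                  c(0.10, 0.45, 0.45),   # exact tie -> first declared column
                  c(0.98, 0.02, 0.00))
  colnames(deconv) <- c("cancer", "CAF", "macrophage")
  rownames(deconv) <- lat$spot_id
  s <- st_sample(lat, counts, deconv, p_cnv = c(0, 0, 0.999),
                 pathology = c("stroma", "stroma", "SCC"))
  s <- call_malignant(s)
  s <- assign_noncancer_type(s)
  expect_identical(unname(s$cell_type), c("CAF", "CAF", "cancer"))
})

test_that("normalization filters shallow spots and is scale invariant", {
  s <- simulate_st_sample(seed = 2)
  ## plant one spot detecting exactly 199 genes
  s$counts[5, ] <- 0L
  s$counts[5, seq_len(199)] <- 1L
  s2 <- normalize_counts(s, min_features = 200)
  expect_false(s$lattice$spot_id[5] %in% s2$lattice$spot_id)
  expect_equal(n_spots(s2), n_spots(s) - 1L)

  ## equal library sizes: norm is log1p of raw counts (scaling factor 1)
  lat <- generate_hex_lattice(2, 4)
  counts <- matrix(c(3L, 1L, 2L, 2L, 1L, 3L, 2L, 2L), 4, 2,
                   dimnames = list(lat$spot_id, c("A", "B")))
  deconv <- matrix(c(1, 0), 4, 2, byrow = TRUE,
                   dimnames = list(lat$spot_id, c("cancer", "CAF")))
  se <- st_sample(lat, counts, deconv, rep(0.5, 4), rep("SCC", 4))
  se <- normalize_counts(se, min_features = 1)
  expect_equal(se$norm, log1p(counts), tolerance = 1e-12)

  ## doubling all counts of a non-pivotal spot leaves its norm row unchanged
  s3 <- simulate_st_sample(seed = 4)
  i <- which.max(rowSums(s3$counts))    # already the deepest: median safe
  before <- normalize_counts(s3, min_features = 1)$norm[i, ]
  s3$counts[i, ] <- 2L * s3$counts[i, ]
  after <- normalize_counts(s3, min_features = 1)$norm[i, ]
  expect_equal(after, before, tolerance = 1e-12)

  s$counts[] <- 0L
  expect_error(normalize_counts(s), "all spots filtered")
})

test_that("clustering is deterministic and recovers planted blobs", {
  ## two well-separated expression blobs
  set.seed(7)
  lat <- generate_hex_lattice(8, 20)
  n <- nrow(lat)
  blob <- rep(1:2, length.out = n)
  counts <- matrix(rpois(n * 60, lambda = 5), n, 60,
                   dimnames = list(lat$spot_id, sprintf("g%02d", 1:60)))
  counts[blob == 2, 1:30] <- counts[blob == 2, 1:30] + 40L
  deconv <- matrix(c(1, 0), n, 2, byrow = TRUE,
                   dimnames = list(lat$spot_id, c("cancer", "CAF")))
  s <- st_sample(lat, counts, deconv, rep(0.999, n), rep("SCC", n))
  s <- normalize_counts(s, min_features = 1)
  s <- call_malignant(s)
  s <- cluster_malignant(s, seed = 42)
  cl <- s$cluster[s$malignant]
  ## adjusted Rand index 1 <=> perfect agreement up to label switching
  expect_equal(length(unique(cl)), 2L)
  expect_true(all(table(cl, blob) %in% c(0, table(blob)[1])))

  s2 <- cluster_malignant(s, seed = 42)
  expect_identical(unname(s$cluster), unname(s2$cluster))
})

test_that("region annotation recovers planted zones and rejects degeneracy", {
  s <- annotated_sample()
  m <- s$malignant
  acc <- mean(s$region[m] == s$truth$region[m])
  expect_gte(acc, 0.95)
  ## region labels partition malignant spots only
  expect_true(all(s$region[m] %in% c("TC", "transitory", "LE")))
  expect_true(all(s$region[!m] == "non-malignant"))

  ## zeroed core markers leave labeling undefined
  s3 <- simulate_st_sample(seed = 6)
  s3$counts[, c("CLDN4", "SPRR1B")] <- 0L
  s3 <- normalize_counts(s3)
  s3 <- call_malignant(s3)
  s3 <- cluster_malignant(s3, seed = 1)
  expect_error(annotate_regions(s3), "undefined|separate")
})

test_that("annotation pipeline is invariant to spot ordering", {
  s <- simulate_st_sample(seed = 8)
  perm <- withr::with_seed(1, sample(n_spots(s)))
  sp <- s
  sp$lattice <- sp$lattice[perm, ]; rownames(sp$lattice) <- NULL
  for (ly in c("counts", "spliced", "unspliced"))
    sp[[ly]] <- sp[[ly]][perm, ]
  sp$deconv <- sp$deconv[perm, ]
  sp$p_cnv <- sp$p_cnv[perm]; sp$pathology <- sp$pathology[perm]
  sp$region <- sp$region[perm]
  sp$truth <- NULL; s$truth <- NULL

  a <- annotate_sample(s, seed = 1)
  b <- annotate_sample(sp, seed = 1)
  ids <- a$lattice$spot_id
  expect_identical(a$malignant[ids %in% b$lattice$spot_id],
                   b$malignant[match(ids, b$lattice$spot_id)])
  expect_identical(a$cell_type, b$cell_type[match(ids, b$lattice$spot_id)])
})
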