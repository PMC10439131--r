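#' Steady-state degradation-rate estimate per gene
#'
#' Under the steady-state velocity model the unspliced/spliced ratio of
#' spots at transcriptional equilibrium equals the (splicing-rate-scaled)
#' degradation rate. Per gene, the estimate is the regression through the
#' origin `gamma_hat = sum(u*s) / sum(s^2)` restricted to spots in the top
#' and bottom `extreme_quantile` of smoothed spliced abundance.
#'
#' @param spliced,unspliced Spot x gene matrices (expected to be
#'   neighborhood-smoothed first; see [compute_velocity()]).
#' @param extreme_quantile Fraction of spots at each extreme (default 0.05).
#' @return Named numeric vector of `gamma_hat` (>= 0); genes with zero
#'   spliced signal are masked as `NA`.
#' @export
estimate_gamma <- function(spliced, unspliced, extreme_quantile = 0.05) {
  stop_if_not(identical(dim(spliced), dim(unspliced)),
              "layer shape mismatch")
  n <- nrow(spliced)
  n_ext <- max(1L, floor(extreme_quantile * n))
  gam <- vapply(seq_len(ncol(spliced)), function(j) {
    s <- spliced[, j]; u <- unspliced[, j]
    if (all(s == 0)) return(NA_real_)
    ord <- order(s)
    sel <- c(ord[seq_len(n_ext)], ord[seq.int(n - n_ext + 1L, n)])
    denom <- sum(s[sel]^2)
    if (denom == 0) return(NA_real_)
    max(0, sum(u[sel] * s[sel]) / denom)
  }, 0)
  names(gam) <- colnames(spliced)
  gam
}

## kNN-average ("moment") smoothing of a layer over an embedding graph;
## each spot is averaged with its k nearest embedding neighbors and itself.
knn_smooth <- function(layer, nn) {
  n <- nrow(layer)
  out <- layer
  for (i in seq_len(n)) {
    out[i, ] <- colMeans(layer[c(i, nn[i, ]), , drop = FALSE])
  }
  out
}

#' Compute steady-state RNA velocity for the malignant compartment
#'
#' Pipeline: restrict to malignant spots (when called after annotation),
#' smooth the spliced/unspliced layers over `k` nearest neighbors in a
#' principal-component embedding of the spliced layer (first/second-moment
#' smoothing), estimate per-gene degradation rates, and form the velocity
#' `v = u_smoothed - gamma_hat * s_smoothed`. The velocity is projected
#' into the `n_pcs`-dimensional embedding through the chain rule of the
#' log1p transform and the PC gene loadings.
#'
#' @param sample An `STSample` with spliced/unspliced layers (annotated
#'   samples are restricted to malignant spots).
#' @param gamma Optional precomputed `gamma_hat`; estimated when `NULL`.
#' @param n_pcs Embedding dimension (default 10).
#' @param k Smoothing / graph neighbors (default 30).
#' @param extreme_quantile Passed to [estimate_gamma()].
#' @return A `VelocityResult`: `gamma`, `velocity` (spot x gene), `Ms`/`Mu`
#'   (smoothed layers), `embedding`, `embedded_velocity`, `region`,
#'   `spot_id`, and the kNN transition scaffold used downstream.
#' @export
compute_velocity <- function(sample, gamma = NULL, n_pcs = 10, k = 30,
                             extreme_quantile = 0.05) {
  stop_if_not(!is.null(sample$spliced) && !is.null(sample$unspliced),
              "sample lacks spliced/unspliced layers")
  idx <- if (!is.null(sample$malignant)) which(sample$malignant) else
    seq_len(n_spots(sample))
  stop_if_not(length(idx) > n_pcs, "too few spots for the embedding")
  s_raw <- sample$spliced[idx, , drop = FALSE]
  u_raw <- sample$unspliced[idx, , drop = FALSE]
  k <- min(k, length(idx) - 1L)
  emb0 <- pca_embed(log1p(s_raw), n_pcs)
  nn0 <- knn_index(emb0, k)
  Ms <- knn_smooth(s_raw, nn0)
  Mu <- knn_smooth(u_raw, nn0)
  if (is.null(gamma)) gamma <- estimate_gamma(Ms, Mu, extreme_quantile)
  stop_if_not(length(gamma) == ncol(Ms), "gamma length mismatch")
  v <- Mu - sweep(Ms, 2, ifelse(is.na(gamma), 0, gamma), `*`)
  v[, is.na(gamma)] <- 0
  ## embedding of the smoothed spliced layer; velocity projected through the
  ## log1p chain rule and the scaled-PCA loadings
  emb <- pca_embed(log1p(Ms), n_pcs)
  ev <- project_velocity(v, Ms, emb)
  res <- structure(list(
    gamma = gamma, velocity = v, Ms = Ms, Mu = Mu,
    embedding = emb, embedded_velocity = ev,
    region = sample$region[idx], spot_id = rownames(s_raw),
    n_pcs = n_pcs, k = k
  ), class = "VelocityResult")
  res$scaffold <- transition_scaffold(emb, k)
  res
}

## Project gene-space velocity into the PCA embedding: tangent map of
## log1p + column scaling + rotation.
project_velocity <- function(v, Ms, emb) {
  genes <- attr(emb, "genes")
  rot <- attr(emb, "rotation")
  sds <- attr(emb, "scaled:scale")
  if (is.null(sds)) sds <- apply(log1p(Ms[, genes, drop = FALSE]), 2,
                                 stats::sd)
  v_log <- v[, genes, drop = FALSE] / (1 + Ms[, genes, drop = FALSE])
  v_log <- sweep(v_log, 2, sds, `/`)
  unname(v_log %*% rot)
}

#' @export
print.VelocityResult <- function(x, ...) {
  cat("VelocityResult:", nrow(x$velocity), "spots x", ncol(x$velocity),
      "genes; embedding d =", ncol(x$embedding), "\n")
  invisible(x)
}

#' Per-spot velocity confidence
#'
#' Agreement between a spot's velocity vector and its neighborhood: the
#' Pearson correlation between the spot's gene-space velocity and the mean
#' velocity of its `k` nearest embedding neighbors.
#'
#' @param vr A `VelocityResult`.
#' @param k Neighbors (default 30).
#' @return Numeric vector in `[-1, 1]`; spots with zero-variance velocity
#'   get 0 with a warning.
#' @export
velocity_confidence <- function(vr, k = 30) {
  n <- nrow(vr$velocity)
  stop_if_not(n >= k + 1, "need at least k+1 spots")
  nn <- if (k == vr$k) vr$scaffold$nn else knn_index(vr$embedding, k)
  conf <- numeric(n)
  flat <- FALSE
  for (i in seq_len(n)) {
    vi <- vr$velocity[i, ]
    vbar <- colMeans(vr$velocity[nn[i, ], , drop = FALSE])
    if (stats::sd(vi) == 0 || stats::sd(vbar) == 0) {
      conf[i] <- 0; flat <- TRUE
    } else {
      conf[i] <- stats::cor(vi, vbar)
    }
  }
  if (flat) warning("zero-variance velocity vector(s); confidence set to 0")
  names(conf) <- vr$spot_id
  conf
}

#' Fit a radial-basis vector field to embedded velocities
#'
#' Kernel ridge regression with a Gaussian kernel and an unpenalized
#' intercept: minimizes the squared residual to the training velocities
#' plus a ridge penalty on the kernel weights. As the ridge grows the field
#' shrinks to the mean training velocity.
#'
#' @param embedding Spot x d matrix of positions.
#' @param embedded_velocity Spot x d matrix of velocities.
#' @param bandwidth Gaussian kernel bandwidth (default: median pairwise
#'   distance between training points).
#' @param ridge Ridge penalty (default 1e-4).
#' @return A `VectorField` with `predict()` support; carries the training
#'   R-squared.
#' @export
fit_vector_field <- function(embedding, embedded_velocity,
                             bandwidth = NULL, ridge = 1e-4) {
  stop_if_not(nrow(embedding) >= ncol(embedding) + 1,
              "need at least d+1 spots")
  dm <- as.matrix(stats::dist(embedding))
  if (is.null(bandwidth)) bandwidth <- stats::median(dm[dm > 0])
  K <- exp(-dm^2 / (2 * bandwidth^2))
  b <- colMeans(embedded_velocity)
  target <- sweep(embedded_velocity, 2, b)
  n <- nrow(K)
  W <- tryCatch(
    solve(K + ridge * diag(n), target),
    error = function(e) {
      warning("singular kernel system; ridge increased")
      solve(K + (ridge + 1e-6 * max(diag(K))) * diag(n) + 1e-8 * diag(n),
            target)
    })
  fitted <- K %*% W + rep(1, n) %o% b
  ss_res <- sum((embedded_velocity - fitted)^2)
  ss_tot <- sum(sweep(embedded_velocity, 2, b)^2)
  structure(list(centers = embedding, weights = W, intercept = b,
                 bandwidth = bandwidth, ridge = ridge,
                 r_squared = 1 - ss_res / ss_tot),
            class = "VectorField")
}

#' Evaluate a fitted vector field
#' @param object A `VectorField`.
#' @param newdata Points (matrix, rows = positions) to evaluate at.
#' @param ... Unused.
#' @return Matrix of predicted velocity vectors.
#' @export
predict.VectorField <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  d2 <- outer(rowSums(newdata^2), rowSums(object$centers^2), `+`) -
    2 * newdata %*% t(object$centers)
  K <- exp(-pmax(d2, 0) / (2 * object$bandwidth^2))
  K %*% object$weights + rep(1, nrow(newdata)) %o% object$intercept
}
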