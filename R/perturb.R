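## Precompute the kNN scaffold used by the velocity-directed transition
## kernel: neighbor indices plus unit displacement vectors stored as one
## n x k matrix per embedding dimension (fully vectorized cosine later).
transition_scaffold <- function(embedding, k) {
  n <- nrow(embedding); d <- ncol(embedding)
  stop_if_not(k < n, "k must be smaller than the number of spots")
  nn <- knn_index(embedding, k)
  Ulist <- vector("list", d)
  norm <- matrix(0, n, k)
  for (dd in seq_len(d)) {
    Ud <- matrix(embedding[as.vector(nn), dd], n, k) - embedding[, dd]
    Ulist[[dd]] <- Ud
    norm <- norm + Ud^2
  }
  norm <- sqrt(norm)
  for (dd in seq_len(d)) Ulist[[dd]] <- Ulist[[dd]] / norm
  list(nn = nn, U = Ulist, k = k)
}

## Row-normalized transition weights over the kNN scaffold:
## P_ij proportional to exp(cos(v_i, x_j - x_i) / sigma); spots with zero
## velocity fall back to a uniform distribution over their neighbors.
transition_weights <- function(scaffold, embedded_velocity, sigma = 0.1) {
  n <- nrow(embedded_velocity)
  k <- scaffold$k
  vnorm <- sqrt(rowSums(embedded_velocity^2))
  cosm <- matrix(0, n, k)
  for (dd in seq_along(scaffold$U)) {
    cosm <- cosm + scaffold$U[[dd]] * embedded_velocity[, dd]
  }
  cosm <- cosm / ifelse(vnorm > 0, vnorm, 1)
  ## subtract the row max before exponentiating so sigma -> 0 stays finite
  w <- exp((cosm - apply(cosm, 1, max)) / sigma)
  zero <- vnorm == 0
  if (any(zero)) w[zero, ] <- 1
  w / rowSums(w)
}

#' Velocity-directed spot fate transition matrix
#'
#' Markov transition probabilities between spots: for each spot `i` and each
#' of its `k` nearest embedding neighbors `j`,
#' `P_ij` is proportional to `exp(cos(v_i, x_j - x_i) / sigma)`; rows are
#' normalized, there are no self-loops, and spots with zero velocity
#' transition uniformly over their neighbors.
#'
#' @param embedding Spot x d positions, or a `VelocityResult` (in which case
#'   `embedded_velocity` is taken from it).
#' @param embedded_velocity Spot x d velocity vectors.
#' @param k Neighbors (default 30).
#' @param sigma Softmax temperature (default 0.1).
#' @return Row-stochastic sparse spot x spot matrix.
#' @export
build_transition_matrix <- function(embedding, embedded_velocity = NULL,
                                    k = 30, sigma = 0.1) {
  if (inherits(embedding, "VelocityResult")) {
    vr <- embedding
    embedding <- vr$embedding
    if (is.null(embedded_velocity)) embedded_velocity <- vr$embedded_velocity
    sc <- if (k == vr$scaffold$k) vr$scaffold else
      transition_scaffold(embedding, k)
  } else {
    sc <- transition_scaffold(embedding, k)
  }
  w <- transition_weights(sc, embedded_velocity, sigma)
  n <- nrow(w)
  P <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(w)),
                            j = as.vector(sc$nn),
                            x = as.vector(w), dims = c(n, n))
  dimnames(P) <- list(rownames(embedding), rownames(embedding))
  P
}

#' Coarse-grain a spot transition matrix into a TC/transitory/LE state graph
#'
#' `Q[A, B]` is the mean, over spots of state `A`, of their total transition
#' probability into spots of state `B`. Derived flow signatures follow the
#' sum rules: `edge_outgoing = Q[LE, transitory] + Q[LE, TC]` and
#' `core_incoming = Q[LE, TC] + Q[transitory, TC]`.
#'
#' @param P Spot x spot row-stochastic matrix from
#'   [build_transition_matrix()].
#' @param labels State label per spot (must cover TC, transitory, LE).
#' @param states State set, in order (default TC, transitory, LE).
#' @return A `StateGraph`: `states`, `Q` (row-stochastic 3x3),
#'   `edge_outgoing`, `core_incoming`.
#' @export
coarse_state_graph <- function(P, labels,
                               states = c("TC", "transitory", "LE")) {
  stop_if_not(length(labels) == nrow(P), "labels must cover all spots of P")
  stop_if_not(all(states %in% labels), "empty state")
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  for (b in states) {
    mass <- Matrix::rowSums(P[, labels == b, drop = FALSE])
    for (a in states) Q[a, b] <- mean(mass[labels == a])
  }
  state_graph(Q)
}

state_graph <- function(Q) {
  structure(list(states = rownames(Q), Q = Q,
                 edge_outgoing = Q["LE", "transitory"] + Q["LE", "TC"],
                 core_incoming = Q["LE", "TC"] + Q["transitory", "TC"]),
            class = "StateGraph")
}

#' @export
print.StateGraph <- function(x, ...) {
  cat("StateGraph over", paste(x$states, collapse = "/"), "\n")
  print(round(x$Q, 4))
  cat(sprintf("edge_outgoing = %.4f, core_incoming = %.4f\n",
              x$edge_outgoing, x$core_incoming))
  invisible(x)
}

#' Serialize / read a state graph as JSON
#' @param sg A `StateGraph`.
#' @param path Output (input) file path.
#' @return `read_state_graph` returns a `StateGraph`.
#' @export
write_state_graph <- function(sg, path) {
  jsonlite::write_json(list(states = sg$states, Q = sg$Q,
                            edge_outgoing = sg$edge_outgoing,
                            core_incoming = sg$core_incoming),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_graph
#' @export
read_state_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- x$Q
  dimnames(Q) <- list(x$states, x$states)
  state_graph(Q)
}

#' Specify an in-silico perturbation
#'
#' @param targets Character vector of target genes.
#' @param direction `"up"` or `"down"`, recycled over targets.
#' @param magnitude Absolute scaling factor in screen units; 200 maps to a
#'   velocity override of one standard deviation of the target gene's
#'   smoothed spliced expression per unit time (checkpoint-gene variant
#'   uses 1000).
#' @return A `PerturbationSpec`.
#' @export
perturbation_spec <- function(targets, direction = "down", magnitude = 200) {
  direction <- rep_len(match.arg(direction, c("up", "down"),
                                 several.ok = TRUE), length(targets))
  stop_if_not(magnitude >= 0, "magnitude is an absolute value")
  structure(list(targets = targets, direction = direction,
                 magnitude = magnitude),
            class = "PerturbationSpec")
}

#' Apply an in-silico target perturbation to a velocity field
#'
#' For each target gene with nonzero expression, the gene-space velocity
#' column is overridden to `sign * (magnitude / 200) * sd(smoothed spliced)`
#' at every spot (sign +1 for `"up"`, -1 for `"down"`); the perturbed
#' velocity is re-projected into the embedding. Targets that are absent or
#' zero-expressed are dropped (an error if none remain). Non-target genes
#' are untouched, and a zero magnitude is an explicit no-op.
#'
#' @param vr A `VelocityResult`.
#' @param spec A `PerturbationSpec`.
#' @return A perturbed `VelocityResult` (same embedding and scaffold).
#' @export
apply_perturbation <- function(vr, spec) {
  stop_if_not(inherits(spec, "PerturbationSpec"),
              "spec must be a PerturbationSpec")
  if (spec$magnitude == 0) return(vr)  # explicit no-op
  present <- spec$targets %in% colnames(vr$velocity)
  expressed <- rep(FALSE, length(spec$targets))
  expressed[present] <- colSums(vr$Ms[, spec$targets[present],
                                      drop = FALSE]) > 0
  if (!all(expressed)) {
    dropped <- spec$targets[!expressed]
    if (!any(expressed)) stop("all perturbation targets absent or ",
                              "zero-expressed", call. = FALSE)
    warning("dropping unexpressed target(s): ",
            paste(dropped, collapse = ", "))
  }
  targets <- spec$targets[expressed]
  dirs <- spec$direction[expressed]
  v <- vr$velocity
  sds <- apply(vr$Ms[, targets, drop = FALSE], 2, stats::sd)
  for (t in seq_along(targets)) {
    sgn <- if (dirs[t] == "up") 1 else -1
    v[, targets[t]] <- sgn * (spec$magnitude / 200) * sds[t]
  }
  vr$velocity <- v
  vr$embedded_velocity <- project_velocity(v, vr$Ms, vr$embedding)
  vr$perturbation <- list(targets = targets, direction = dirs,
                          magnitude = spec$magnitude)
  vr
}

#' State graph of a (possibly perturbed) velocity result
#'
#' Convenience wrapper: velocity-directed transition weights on the
#' precomputed kNN scaffold, coarse-grained over the region labels.
#'
#' @param vr A `VelocityResult` carrying region labels.
#' @param sigma Softmax temperature (default 0.1).
#' @return A `StateGraph`.
#' @export
velocity_state_graph <- function(vr, sigma = 0.1) {
  w <- transition_weights(vr$scaffold, vr$embedded_velocity, sigma)
  states <- c("TC", "transitory", "LE")
  labels <- vr$region
  stop_if_not(all(states %in% labels), "empty state")
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  lab_nn <- matrix(labels[vr$scaffold$nn], nrow(w), ncol(w))
  for (b in states) {
    mass <- rowSums(w * (lab_nn == b))
    for (a in states) Q[a, b] <- mean(mass[labels == a])
  }
  state_graph(Q)
}
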