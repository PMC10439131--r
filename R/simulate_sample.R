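## Cell types carried by the deconvolution channel. "cancer" must be first:
## the non-cancer argmax rule and the tie-break on column order depend on a
## fixed, documented ordering of the remaining types.
CELL_TYPES <- c("cancer", "ecm.myCAF", "detox.iCAF", "intermediate.fib",
                "macrophage", "cytotoxic.CD8.T", "other")

#' Default configuration for the synthetic spatial sample generator
#'
#' The generator lays concentric tumor zones on a hexagonal lattice --
#' tumor core (TC) in the center, a transitory ring, and the leading edge
#' (LE) as the outermost malignant ring -- surrounded by stroma arranged in
#' cell-type bands, with a CAF-rich band hugging the LE. Expression is
#' negative binomial around zone- and pseudotime-modulated means;
#' spliced/unspliced layers follow first-order splicing kinetics along the
#' TC-to-LE pseudotime axis.
#'
#' @param n_rows,n_cols Lattice extent (default 42 x 60, about 1260 spots).
#' @param r_tc,r_trans,r_le Hex-distance radii of the TC disk, transitory
#'   ring, and LE ring (defaults 4, 7, 10; spots beyond `r_le` are stroma).
#' @param n_genes Total gene count (default 300, comfortably above the 200-detected-features spot filter).
#' @param core_markers,edge_markers Named marker genes planted for the TC and
#'   LE programs (defaults CLDN4/SPRR1B and LAMC2/ITGA5).
#' @param n_core_program,n_edge_program,n_trans_program Numbers of
#'   additional program genes per zone beyond the named markers (defaults
#'   10/10/8).
#' @param marker_fold Peak fold-elevation of zone programs over baseline
#'   (default 6, typical of strong regional markers).
#' @param library_size Target median library size per spot (default 2000).
#' @param dispersion Negative binomial `size` parameter (default 10).
#' @param channel_noise SD of the noise applied to the deconvolution and CNV
#'   probability channels (default 0.002; 0 gives deterministic channels).
#' @param cnv_only_frac Fraction of tumor spots whose malignancy is only
#'   detectable through the CNV channel (deconvolution below threshold;
#'   default 0.05).
#' @param t_max Real-time span of the TC-to-LE pseudotime axis in units of
#'   the splicing rate (default 10).
#' @param alpha_scale Transcription-rate scale: steady-state spliced mean of
#'   a driver gene (default 30 molecules).
#' @param bg_count Mean background count for spliced/unspliced layers in
#'   stroma (default 0.2).
#' @return A config list understood by [simulate_st_sample()].
#' @export
st_config <- function(n_rows = 42, n_cols = 60,
                      r_tc = 4, r_trans = 7, r_le = 10,
                      n_genes = 300,
                      core_markers = c("CLDN4", "SPRR1B"),
                      edge_markers = c("LAMC2", "ITGA5"),
                      n_core_program = 10, n_edge_program = 10,
                      n_trans_program = 8,
                      marker_fold = 6,
                      library_size = 2000,
                      dispersion = 10,
                      channel_noise = 0.002,
                      cnv_only_frac = 0.05,
                      t_max = 10,
                      alpha_scale = 30,
                      bg_count = 0.2) {
  as.list(environment())
}

## Gene panel implied by a config: markers, zone programs, stromal cell-type
## markers, and unstructured filler genes.
st_gene_panel <- function(config) {
  stop_if_not(length(config$core_markers) >= 1 &&
                length(config$edge_markers) >= 1, "empty marker sets")
  core <- c(config$core_markers,
            sprintf("COREP%02d", seq_len(config$n_core_program)))
  edge <- c(config$edge_markers,
            sprintf("EDGEP%02d", seq_len(config$n_edge_program)))
  trans <- sprintf("TRANSP%02d", seq_len(config$n_trans_program))
  stroma <- list(
    ecm.myCAF = c("LRRC15", "GJB2", "CAFM3", "CAFM4"),
    detox.iCAF = c("ADH1B", "GPX3", "ICAFM3", "ICAFM4"),
    intermediate.fib = sprintf("IFIBM%d", 1:4),
    macrophage = sprintf("MACM%d", 1:4),
    cytotoxic.CD8.T = sprintf("CD8M%d", 1:4),
    other = sprintf("OTHM%d", 1:4)
  )
  named <- c(core, edge, trans, unlist(stroma, use.names = FALSE))
  stop_if_not(config$n_genes > length(named),
              "n_genes too small for the marker panel")
  filler <- sprintf("G%04d", seq_len(config$n_genes - length(named)))
  list(genes = c(named, filler), core = core, edge = edge, trans = trans,
       stroma = stroma, filler = filler,
       drivers = edge)  # LE drivers: induced along the TC->LE axis
}

#' Simulate a spatial transcriptomics sample with planted tumor zoning
#'
#' Generates an [st_sample()] whose ground truth is known: concentric
#' TC/transitory/LE malignant zones with stroma outside, negative binomial
#' counts with zone-specific marker programs, deconvolution and CNV
#' probability channels concordant with malignancy, a pathologist label
#' (`"SCC"` exactly on malignant-zone spots), and spliced/unspliced layers
#' following splicing kinetics along the TC-to-LE pseudotime (the normalized
#' hex distance from the tumor center).
#'
#' @param config A list from [st_config()].
#' @param seed Integer seed; identical `(config, seed)` give byte-identical
#'   samples.
#' @return An `STSample` with a `truth` list (`region`, `cell_type`,
#'   `pseudotime`, `driver_genes`, `kinetics`).
#' @export
simulate_st_sample <- function(config = st_config(), seed = 1) {
  lat <- generate_hex_lattice(config$n_rows, config$n_cols)
  ## tumor center: lattice spot closest to the grid midpoint
  mid_r <- (config$n_rows - 1) / 2; mid_c <- (config$n_cols - 1) / 2
  ctr <- which.min((lat$array_row - mid_r)^2 + (lat$array_col - mid_c)^2)
  d <- hex_distance(lat$array_row, lat$array_col,
                    lat$array_row[ctr], lat$array_col[ctr])
  stop_if_not(config$r_tc < config$r_trans && config$r_trans < config$r_le,
              "zone radii must increase: r_tc < r_trans < r_le")
  stop_if_not(config$r_le < max(d),
              "zone radii exceed the lattice: no stroma would remain")
  region <- ifelse(d <= config$r_tc, "TC",
                   ifelse(d <= config$r_trans, "transitory",
                          ifelse(d <= config$r_le, "LE", "stroma")))
  tumor <- region != "stroma"
  pseudotime <- ifelse(tumor, d / config$r_le, NA_real_)

  panel <- st_gene_panel(config)
  genes <- panel$genes
  n <- nrow(lat); G <- length(genes)

  with_seed(seed, {
    ## ---- stroma cell-type bands (CAF band hugging the LE) ----
    cell_type <- rep("cancer", n)
    s_idx <- which(!tumor)
    band <- findInterval(d[s_idx], c(config$r_le + 2, config$r_le + 5))
    probs <- list(
      c(0, 0.70, 0.00, 0.30, 0.00, 0.00, 0.00),   # inner band: myCAF-rich
      c(0, 0.10, 0.40, 0.30, 0.20, 0.00, 0.00),   # mid band
      c(0, 0.00, 0.10, 0.10, 0.25, 0.25, 0.30))   # outer band
    for (b in 0:2) {
      sel <- s_idx[band == b]
      if (length(sel)) {
        cell_type[sel] <- sample(CELL_TYPES, length(sel), replace = TRUE,
                                 prob = probs[[b + 1]])
      }
    }

    ## ---- expected expression profile per spot x gene ----
    mu0 <- exp(stats::rnorm(G, mean = log(2), sd = 0.4))
    names(mu0) <- genes
    fold <- config$marker_fold
    E <- matrix(rep(mu0, each = n), n, G, dimnames = list(lat$spot_id, genes))
    t_ <- pseudotime
    ti <- which(tumor)
    ## zone identity programs: step-wise per-zone multipliers (discrete
    ## regional programs, as in annotated tumor compartments) with a mild
    ## pseudotime gradient on top
    zmult <- function(v) v[region[ti]]
    E[ti, panel$core] <- E[ti, panel$core] *
      zmult(c(TC = fold, transitory = 1 + (fold - 1) * 0.3, LE = 1)) *
      (2 - t_[ti]) / 2
    E[ti, panel$edge] <- E[ti, panel$edge] *
      zmult(c(TC = 1, transitory = 1 + (fold - 1) * 0.3, LE = fold)) *
      (1 + t_[ti]) / 2
    E[ti, panel$trans] <- E[ti, panel$trans] *
      zmult(c(TC = 1.2, transitory = fold * 0.8, LE = 1.2))
    for (ct in names(panel$stroma)) {
      sel <- which(cell_type == ct)
      if (length(sel)) E[sel, panel$stroma[[ct]]] <-
          E[sel, panel$stroma[[ct]]] * fold
    }

    ## ---- negative binomial counts at the target library size ----
    lib <- config$library_size *
      exp(stats::rnorm(n, 0, 0.1))            # mild per-spot depth variation
    mu <- E / rowSums(E) * lib
    counts <- matrix(stats::rnbinom(n * G, mu = as.vector(mu),
                                    size = config$dispersion),
                     n, G, dimnames = dimnames(E))

    ## ---- deconvolution + CNV probability channels ----
    ns <- function(m) if (config$channel_noise > 0)
      pmin(abs(stats::rnorm(m, 0, config$channel_noise)), 0.008) else rep(0, m)
    deconv <- matrix(0, n, length(CELL_TYPES),
                     dimnames = list(lat$spot_id, CELL_TYPES))
    p_cnv <- numeric(n)
    cnv_only <- rep(FALSE, n)
    if (config$cnv_only_frac > 0 && length(ti)) {
      cnv_only[sample(ti, round(config$cnv_only_frac * length(ti)))] <- TRUE
    }
    for (i in ti) {
      canc <- if (cnv_only[i]) 0.97 else 0.999 - ns(1)
      rest <- if (config$channel_noise > 0)
        stats::runif(length(CELL_TYPES) - 1) else rep(1, length(CELL_TYPES) - 1)
      deconv[i, ] <- c(canc, (1 - canc) * rest / sum(rest))
      p_cnv[i] <- 0.999 - ns(1)
    }
    for (i in s_idx) {
      canc <- if (config$channel_noise > 0) stats::runif(1, 0.02, 0.25) else 0.1
      w <- if (config$channel_noise > 0)
        stats::runif(length(CELL_TYPES) - 1, 0, 0.15) else
          rep(0.08, length(CELL_TYPES) - 1)
      names(w) <- CELL_TYPES[-1]
      w[cell_type[i]] <- 0.6
      deconv[i, ] <- c(canc, (1 - canc) * w / sum(w))
      p_cnv[i] <- if (config$channel_noise > 0) stats::runif(1, 0, 0.2) else 0.05
    }
    deconv <- deconv / rowSums(deconv)

    ## ---- splicing kinetics layers ----
    kin <- default_kinetics(panel, config)
    layers <- simulate_kinetics_layers(E, t_, kin, config)

    truth <- list(region = region, cell_type = ifelse(tumor, "cancer",
                                                      cell_type),
                  pseudotime = pseudotime,
                  driver_genes = panel$drivers, kinetics = kin,
                  cnv_only = cnv_only, center = lat$spot_id[ctr])
    out <- st_sample(lat, counts, deconv, p_cnv,
                     pathology = ifelse(tumor, "SCC", "stroma"),
                     spliced = layers$spliced, unspliced = layers$unspliced,
                     truth = truth)
    out
  })
}

## Kinetic parameter table for a gene panel: LE drivers are induced from
## zero along pseudotime; core-program genes are repressed from their
## steady state. beta is fixed to 1 (time measured in units of the splicing
## rate), so the steady-state ratio estimator recovers gamma directly.
default_kinetics <- function(panel, config) {
  drv <- panel$drivers
  core <- panel$core
  g_d <- exp(stats::runif(length(drv), log(0.25), log(1)))
  g_c <- exp(stats::runif(length(core), log(0.25), log(1)))
  data.frame(
    gene = c(drv, core),
    mode = rep(c("induction", "repression"), c(length(drv), length(core))),
    alpha = config$alpha_scale * c(g_d, g_c),
    beta = 1,
    gamma = c(g_d, g_c),
    stringsAsFactors = FALSE
  )
}

#' Closed-form first-order splicing kinetics
#'
#' Expected unspliced (`u`) and spliced (`s`) abundance under
#' `du/dt = alpha - beta u`, `ds/dt = beta u - gamma s`, for an induction
#' phase starting from `u = s = 0` (`mode = "induction"`) or a repression
#' phase starting from the steady state `u* = alpha/beta`, `s* = alpha/gamma`
#' with transcription switched off (`mode = "repression"`).
#'
#' @param t Time (vector), in units where `beta` is the splicing rate.
#' @param alpha Transcription rate (ignored after switch-off in repression).
#' @param beta Splicing rate, > 0.
#' @param gamma Degradation rate, > 0.
#' @param mode `"induction"` or `"repression"`.
#' @return A list with vectors `u` and `s`.
#' @export
kinetics_profile <- function(t, alpha, beta, gamma,
                             mode = c("induction", "repression")) {
  mode <- match.arg(mode)
  stop_if_not(beta > 0 && gamma > 0, "beta and gamma must be positive")
  if (abs(beta - gamma) < 1e-12) gamma <- gamma * (1 + 1e-9)
  if (mode == "induction") {
    u <- alpha / beta * (1 - exp(-beta * t))
    s <- alpha / gamma * (1 - exp(-gamma * t)) +
      alpha / (gamma - beta) * (exp(-gamma * t) - exp(-beta * t))
  } else {
    u0 <- alpha / beta; s0 <- alpha / gamma
    u <- u0 * exp(-beta * t)
    D <- beta * u0 / (gamma - beta)
    s <- (s0 - D) * exp(-gamma * t) + D * exp(-beta * t)
  }
  list(u = u, s = s)
}

## Build spliced/unspliced layers: kinetic genes follow the ODE along
## pseudotime; all other genes sit at steady state scaled to the spot's
## expected expression profile; stroma spots get background counts.
simulate_kinetics_layers <- function(E, pseudotime, kinetics, config,
                                     noise = TRUE) {
  n <- nrow(E); genes <- colnames(E)
  s_mean <- matrix(config$bg_count, n, ncol(E), dimnames = dimnames(E))
  u_mean <- s_mean
  ti <- which(!is.na(pseudotime))
  t_real <- pseudotime[ti] * config$t_max
  ## non-kinetic genes: steady state with gene-wise ratio u/s = gamma_tilde
  static <- setdiff(genes, kinetics$gene)
  gt <- exp(stats::runif(length(static), log(0.1), log(2)))
  names(gt) <- static
  s_mean[ti, static] <- 0.5 * E[ti, static]
  u_mean[ti, static] <- sweep(s_mean[ti, static, drop = FALSE], 2, gt[static],
                              `*`)
  for (j in seq_len(nrow(kinetics))) {
    k <- kinetics[j, ]
    prof <- kinetics_profile(t_real, k$alpha, k$beta, k$gamma, k$mode)
    u_mean[ti, k$gene] <- prof$u
    s_mean[ti, k$gene] <- prof$s
  }
  if (noise) {
    spliced <- matrix(stats::rpois(length(s_mean), as.vector(s_mean)),
                      n, ncol(E), dimnames = dimnames(E))
    unspliced <- matrix(stats::rpois(length(u_mean), as.vector(u_mean)),
                        n, ncol(E), dimnames = dimnames(E))
  } else {
    spliced <- s_mean; unspliced <- u_mean
  }
  list(spliced = spliced, unspliced = unspliced,
       s_mean = s_mean, u_mean = u_mean)
}

#' Simulate spliced/unspliced layers for an existing sample
#'
#' Regenerates the kinetic layers of a sample from an explicit kinetic
#' parameter table, using the sample's ground-truth pseudotime. Useful for
#' parameter-recovery experiments where the true `gamma` of every gene must
#' be known.
#'
#' @param sample An `STSample` with simulation `truth` (pseudotime).
#' @param kinetics Data.frame with columns `gene`, `mode`, `alpha`, `beta`,
#'   `gamma` (see [kinetics_profile()]).
#' @param seed Integer seed for the Poisson sampling noise.
#' @param noise If `FALSE`, the expected values are returned exactly
#'   (no Poisson sampling).
#' @param t_max Real-time span of the pseudotime axis (default 30, long
#'   enough that slow-degrading genes approach steady state).
#' @return The sample with replaced `spliced`/`unspliced` layers and its
#'   `truth$kinetics` updated.
#' @export
simulate_kinetics <- function(sample, kinetics, seed = 1, noise = TRUE,
                              t_max = 30) {
  stop_if_not(!is.null(sample$truth$pseudotime),
              "sample carries no ground-truth pseudotime")
  stop_if_not(all(kinetics$beta > 0) && all(kinetics$gamma > 0),
              "beta and gamma must be positive")
  stop_if_not(all(kinetics$gene %in% colnames(sample$counts)),
              "kinetics table names genes absent from the sample")
  cfg <- st_config(t_max = t_max)
  E <- matrix(1, n_spots(sample), n_genes(sample),
              dimnames = dimnames(sample$counts))
  with_seed(seed, {
    layers <- simulate_kinetics_layers(E, sample$truth$pseudotime, kinetics,
                                       cfg, noise = noise)
    sample$spliced <- layers$spliced
    sample$unspliced <- layers$unspliced
    sample$truth$kinetics <- kinetics
    sample
  })
}
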