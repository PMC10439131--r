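#' Default configuration for the synthetic survival cohort generator
#'
#' The cohort emulates a bulk expression survival dataset: per-patient
#' latent TC and LE program activities (bivariate normal with a weak
#' negative correlation, as observed between the two programs), expression
#' in which the signature genes are shifted by the latent activity, and
#' exponential survival with a proportional-hazards dependence on the
#' latent activities.
#'
#' @param n Patients (default 275, the size of the emulated HPV-negative
#'   OSCC cohort).
#' @param n_genes Transcriptome size (default 2000, a realistically
#'   filtered bulk panel; small panels inflate the compositional coupling
#'   of rank scores between signatures).
#' @param set_size Genes per signature (default 40).
#' @param beta_tc,beta_le Log hazard ratios per SD of the TC / LE latent
#'   activity (defaults 0 and `log(2)`: the LE program is prognostic).
#' @param score_cor Latent TC-LE correlation (default -0.2).
#' @param shift Expression shift per SD of latent activity applied to
#'   signature genes (default 1.5; strong enough that rank scores track the
#'   latent activity closely).
#' @param lambda0 Baseline hazard (default 0.1 events per unit time).
#' @param censoring Target censoring proportion (default 0.3).
#' @param model `"linear"` (hazard depends on the continuous latent score)
#'   or `"threshold"` (two clearly separated risk groups: the top
#'   `1 - cut_quantile` of patients form a high-risk cluster whose LE
#'   activity is offset by `separation` and whose hazard is multiplied by
#'   `exp(beta_le)`).
#' @param cut_quantile True group boundary quantile for the threshold model
#'   (default 0.6: 60% low risk, 40% high risk).
#' @param separation Latent offset between the two risk clusters in the
#'   threshold model (default 3 SD units: clearly separated groups).
#' @return Config list for [simulate_survival_cohort()].
#' @export
survival_config <- function(n = 275, n_genes = 2000, set_size = 40,
                            beta_tc = 0, beta_le = log(2),
                            score_cor = -0.2, shift = 1.5,
                            lambda0 = 0.1, censoring = 0.3,
                            model = c("linear", "threshold"),
                            cut_quantile = 0.6, separation = 3) {
  model <- match.arg(model)
  as.list(environment())
}

#' Simulate a survival cohort with planted prognostic signatures
#'
#' @param config List from [survival_config()].
#' @param seed Integer seed.
#' @return A `SurvivalCohort`: `expression` (gene x patient), `time`,
#'   `event`, gene sets `sig_tc`/`sig_le`, ground truth latents
#'   `z_tc`/`z_le`, and (threshold model) the true high-risk indicator
#'   `true_high`.
#' @export
simulate_survival_cohort <- function(config = survival_config(), seed = 1) {
  stop_if_not(config$n > 0 && config$lambda0 > 0,
              "n and lambda0 must be positive")
  with_seed(seed, {
    n <- config$n
    ## latent program activities, correlated
    z_tc <- stats::rnorm(n)
    rho <- config$score_cor
    z_le <- rho * z_tc + sqrt(1 - rho^2) * stats::rnorm(n)
    grp_high <- rep(FALSE, n)
    if (config$model == "threshold") {
      ## two separated risk clusters split at the cut quantile
      n_high <- round((1 - config$cut_quantile) * n)
      grp_high[sample.int(n, n_high)] <- TRUE
      z_le <- z_le + config$separation * grp_high
    }
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    sig_tc <- sprintf("TCSIG%03d", seq_len(config$set_size))
    sig_le <- sprintf("LESIG%03d", seq_len(config$set_size))
    genes <- c(sig_tc, sig_le, genes)
    expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                   dimnames = list(genes, sprintf("P%03d", seq_len(n))))
    expr[sig_tc, ] <- expr[sig_tc, ] +
      rep(config$shift * z_tc, each = length(sig_tc))
    expr[sig_le, ] <- expr[sig_le, ] +
      rep(config$shift * z_le, each = length(sig_le))
    ## proportional-hazards event times
    lp <- if (config$model == "linear") {
      config$beta_tc * z_tc + config$beta_le * z_le
    } else {
      config$beta_le * grp_high
    }
    lambda <- config$lambda0 * exp(lp)
    t_event <- stats::rexp(n, rate = lambda)
    if (config$censoring <= 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      ## censoring rate solving E[lc / (lc + lambda)] = target exactly
      f <- function(lc) mean(lc / (lc + lambda)) - config$censoring
      lc <- stats::uniroot(f, c(1e-8, 1e6 * config$lambda0))$root
      t_cens <- stats::rexp(n, rate = lc)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    structure(list(expression = expr, time = time, event = event,
                   sig_tc = sig_tc, sig_le = sig_le,
                   z_tc = z_tc, z_le = z_le,
                   true_high = if (config$model == "threshold") grp_high
                   else NULL,
                   config = config),
              class = "SurvivalCohort")
  })
}

#' @export
print.SurvivalCohort <- function(x, ...) {
  cat("SurvivalCohort:", length(x$time), "patients,",
      nrow(x$expression), "genes;",
      sum(x$event), "events,", sum(1 - x$event), "censored\n")
  invisible(x)
}

#' Write / read a survival cohort as CSV
#'
#' Clinical table (`patient_id`, `time`, `event`) plus an expression CSV
#' (genes x patients) and a JSON of the signature gene sets.
#'
#' @param cohort A `SurvivalCohort`.
#' @param dir Output directory.
#' @return `read_survival_cohort` returns a `SurvivalCohort`.
#' @export
write_survival_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(patient_id = colnames(cohort$expression),
                              time = cohort$time, event = cohort$event),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$expression),
                   file.path(dir, "expression.csv"))
  jsonlite::write_json(list(sig_tc = cohort$sig_tc, sig_le = cohort$sig_le),
                       file.path(dir, "gene_sets.json"))
  invisible(dir)
}

#' @rdname write_survival_cohort
#' @export
read_survival_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  expr <- as.matrix(utils::read.csv(file.path(dir, "expression.csv"),
                                    row.names = 1, check.names = FALSE))
  sets <- jsonlite::read_json(file.path(dir, "gene_sets.json"),
                              simplifyVector = TRUE)
  structure(list(expression = expr, time = clin$time, event = clin$event,
                 sig_tc = sets$sig_tc, sig_le = sets$sig_le,
                 z_tc = NULL, z_le = NULL, true_high = NULL,
                 config = NULL),
            class = "SurvivalCohort")
}
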