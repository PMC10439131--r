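#' Maximally selected log-rank cutpoint
#'
#' Scans candidate cutpoints (unique score values at which both resulting
#' groups contain at least `minprop` of the cohort) and returns the one
#' maximizing the absolute standardized two-group log-rank statistic.
#' Patients with score above the cutpoint form the high group. Ties in the
#' statistic resolve to the smaller cutpoint.
#'
#' @param score Numeric vector of per-patient scores.
#' @param time,event Survival time and event indicator (1 = event).
#' @param minprop Minimum group proportion (default 0.2; the pan-cancer
#'   variant of the source analysis used 0.1).
#' @return List of class `cutpoint`: `cutpoint`, `statistic` (signed
#'   standardized log-rank z), `candidates` (data.frame of all scanned
#'   cutpoints and statistics).
#' @export
optimal_cutpoint <- function(score, time, event, minprop = 0.2) {
  n <- length(score)
  stop_if_not(length(time) == n && length(event) == n,
              "score, time, event must have equal length")
  lo <- ceiling(minprop * n)
  cand <- sort(unique(score))
  ## cutting at c puts {score <= c} low: feasible iff both sides >= lo
  n_le <- vapply(cand, function(c) sum(score <= c), 0L)
  cand <- cand[n_le >= lo & (n - n_le) >= lo]
  stop_if_not(length(cand) > 0, "no feasible candidate cutpoint")
  z <- vapply(cand, function(c)
    logrank_z(time, event, score > c), 0)
  best <- which.max(abs(z))  # which.max takes the first = smallest cutpoint
  structure(list(cutpoint = cand[best], statistic = z[best],
                 candidates = data.frame(cutpoint = cand, z = z)),
            class = "cutpoint")
}

## Standardized two-group log-rank statistic (O - E) / sqrt(V) for the
## TRUE group.
logrank_z <- function(time, event, group) {
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  i <- 2L  # groupTRUE row (FALSE sorts first)
  (sd_$obs[i] - sd_$exp[i]) / sqrt(sd_$var[i, i])
}

#' Kaplan-Meier product-limit estimate per group
#'
#' @param time,event Survival time and event indicator.
#' @param group Group label per patient (single group if omitted).
#' @return Named list of data.frames (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`), one per group; survival is non-increasing with
#'   implicit `S(0) = 1`.
#' @export
km_estimator <- function(time, event, group = NULL) {
  stop_if_not(all(time >= 0), "negative survival times")
  if (is.null(group)) group <- rep("all", length(time))
  out <- lapply(split(seq_along(time), group), function(idx) {
    fit <- survival::survfit(
      survival::Surv(time[idx], event[idx]) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               surv = fit$surv)
  })
  out
}

#' Cox proportional-hazards fit for a score or group
#'
#' Partial-likelihood maximization with Efron tie handling. Reports the
#' hazard ratio with its 95% Wald confidence interval and p-value. A
#' monotone likelihood (complete separation) is reported through the
#' `separation` flag rather than returned silently.
#'
#' @param x Numeric score or two-level group (factor/character/logical).
#' @param time,event Survival time and event indicator.
#' @return List: `hr`, `ci` (length 2), `p`, `coef`, `se`, `separation`.
#' @export
cox_fit <- function(x, time, event) {
  if (is.character(x) || is.logical(x)) {
    ## "high"/"low" groups are oriented so the HR reads high-vs-low
    x <- if (is.character(x) && setequal(unique(x), c("high", "low")))
      factor(x, levels = c("low", "high")) else factor(x)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  co <- s$coefficients[1, ]
  list(hr = unname(exp(co["coef"])),
       ci = unname(c(s$conf.int[1, "lower .95"],
                     s$conf.int[1, "upper .95"])),
       p = unname(co["Pr(>|z|)"]),
       coef = unname(co["coef"]), se = unname(co["se(coef)"]),
       separation = sep)
}

#' Pearson correlation between two signature scores
#'
#' @param z_a,z_b Equal-length numeric vectors with positive variance.
#' @return List: `r`, `p` (two-sided t-test on r).
#' @export
score_correlation <- function(z_a, z_b) {
  stop_if_not(length(z_a) == length(z_b), "unequal lengths")
  stop_if_not(stats::sd(z_a) > 0 && stats::sd(z_b) > 0, "zero variance")
  ct <- stats::cor.test(z_a, z_b)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Score a survival cohort and fit its prognostic model
#'
#' Rank-scores the cohort expression for a gene set, finds the maximally
#' selected cutpoint, and fits the Cox model on the resulting high/low
#' groups; Kaplan-Meier curves per group are attached.
#'
#' @param cohort A `SurvivalCohort`.
#' @param gene_set Character vector of set genes.
#' @param minprop Minimum group proportion for the cutpoint (default 0.2).
#' @return List: `score`, `cutpoint`, `group`, `cox`, `km`.
#' @export
survival_fit <- function(cohort, gene_set, minprop = 0.2) {
  score <- rank_score(cohort$expression, gene_set)
  cp <- optimal_cutpoint(score, cohort$time, cohort$event, minprop)
  group <- ifelse(score > cp$cutpoint, "high", "low")
  list(score = score, cutpoint = cp, group = group,
       cox = cox_fit(group, cohort$time, cohort$event),
       km = km_estimator(cohort$time, cohort$event, group))
}
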