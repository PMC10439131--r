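## DGIdb interaction keywords with a defined direction.
UP_KEYWORDS <- c("activator", "agonist", "inducer", "partial agonist",
                 "positive modulator", "potentiator", "stimulator")
DOWN_KEYWORDS <- c("inhibitor", "antagonist", "partial antagonist",
                   "blocker", "inverse agonist", "negative modulator",
                   "suppressor")

#' Map a drug-gene interaction keyword to a regulation direction
#'
#' Case-insensitive exact membership in the curated keyword lists:
#' activator/agonist/inducer/partial agonist/positive modulator/potentiator/
#' stimulator map up; inhibitor/antagonist/partial antagonist/blocker/
#' inverse agonist/negative modulator/suppressor map down; anything else
#' (e.g. "binder") maps to `"none"` and the target is dropped from screens.
#'
#' @param keyword Character vector of interaction keywords.
#' @return Character vector in `{"up", "down", "none"}`.
#' @export
map_interaction_direction <- function(keyword) {
  kw <- tolower(trimws(keyword))
  ifelse(kw %in% UP_KEYWORDS, "up",
         ifelse(kw %in% DOWN_KEYWORDS, "down", "none"))
}

#' Symmetric trimmed mean (sort and drop)
#'
#' Drops `floor(trim * n)` values from each tail of the sorted vector and
#' averages the remainder.
#'
#' @param x Numeric vector.
#' @param trim Tail fraction (default 0.1).
#' @return Trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.1) {
  n <- length(x)
  k <- floor(trim * n)
  mean(sort(x)[seq.int(k + 1, n - k)])
}

#' Aggregate a drug's AAC measurements
#'
#' Step 1: per cell line, arithmetic mean of AAC across datasets. Step 2:
#' symmetric 10% trimmed mean across cell-line means (controls outlier
#' responses). Drugs measured in fewer than `min_cell_lines` cell lines are
#' excluded (`NA`).
#'
#' @param record A `DrugRecord` (list with `drug_id`, `aac` data.frame with
#'   columns `cell_line`, `dataset`, `aac`, and `targets`).
#' @param min_cell_lines Minimum cell lines required (default 25).
#' @param trim Trim fraction (default 0.1).
#' @return The record with `aggregated_aac` set (`NA` if excluded).
#' @export
aggregate_aac <- function(record, min_cell_lines = 25, trim = 0.1) {
  by_line <- tapply(record$aac$aac, record$aac$cell_line, mean)
  record$aggregated_aac <- if (length(by_line) < min_cell_lines) NA_real_
  else trimmed_mean(as.numeric(by_line), trim)
  record
}

#' Stratify drugs into high / low AAC groups at the median
#'
#' High iff aggregated AAC strictly exceeds the median; otherwise low
#' (values exactly at the median are assigned low; the strict >/< rule
#' leaves them unassigned, so the tie-break is pinned here).
#'
#' @param aac Numeric vector of aggregated AAC values.
#' @return Character vector in `{"high", "low"}`.
#' @export
stratify_by_median <- function(aac) {
  stop_if_not(length(aac) >= 2, "need at least 2 drugs")
  stop_if_not(stats::sd(aac) > 0, "all AAC values identical; no stratification")
  ifelse(aac > stats::median(aac), "high", "low")
}

#' Simulate a drug screen with a planted flow-reversal association
#'
#' A configurable fraction of drugs are "flow-reversing": they inhibit
#' (direction down) the planted leading-edge driver genes of a simulated
#' sample and receive AAC values shifted upward by `effect`. The remainder
#' target decoy genes with random directional keywords; a fraction carry
#' only direction-less keywords and are dropped by the screen, mirroring
#' the database filtering step.
#'
#' @param config List from [drug_screen_config()].
#' @param seed Integer seed.
#' @return List of `DrugRecord`s with a `truth` attribute naming the
#'   flow-reversing drugs.
#' @export
simulate_drug_screen <- function(config = drug_screen_config(), seed = 1) {
  with_seed(seed, {
    n_rev <- round(config$frac_reversing * config$n_drugs)
    rev_ids <- sprintf("drug_%03d", seq_len(config$n_drugs)) |>
      sample(n_rev)
    records <- lapply(seq_len(config$n_drugs), function(i) {
      id <- sprintf("drug_%03d", i)
      reversing <- id %in% rev_ids
      lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
      grid <- expand.grid(cell_line = lines,
                          dataset = sprintf("DS%d", seq_len(config$n_datasets)),
                          stringsAsFactors = FALSE)
      base <- stats::rnorm(1, config$aac_mean, config$aac_sd) +
        if (reversing) config$effect else 0
      aac <- base + stats::rnorm(nrow(grid), 0, config$noise_sd)
      if (any(aac < 0 | aac > 1)) {
        warning("AAC values outside [0, 1] clamped")
        aac <- pmin(pmax(aac, 0), 1)
      }
      grid$aac <- aac
      if (reversing) {
        ## flow-reversing drugs inhibit the planted LE-driver gene set
        genes <- config$driver_genes
        kw <- sample(DOWN_KEYWORDS, length(genes), replace = TRUE)
      } else if (stats::runif(1) < config$neutral_frac) {
        genes <- sample(config$decoy_genes, config$n_targets)
        kw <- sample(c("binder", "ligand", "multitarget"), length(genes),
                     replace = TRUE)
      } else {
        genes <- sample(config$decoy_genes, config$n_targets)
        kw <- sample(c(UP_KEYWORDS, DOWN_KEYWORDS), length(genes),
                     replace = TRUE)
      }
      list(drug_id = id, aac = grid,
           targets = data.frame(gene = genes, keyword = kw,
                                stringsAsFactors = FALSE))
    })
    attr(records, "truth") <- list(reversing = sort(rev_ids))
    records
  })
}

#' @rdname simulate_drug_screen
#' @param n_drugs,n_cell_lines,n_datasets Screen dimensions (defaults 40
#'   drugs, 50 cell lines, 5 datasets, mirroring the source screen scale).
#' @param frac_reversing Fraction of flow-reversing drugs (default 0.5).
#' @param effect AAC shift of flow-reversing drugs (default 0.2).
#' @param aac_mean,aac_sd Baseline per-drug AAC distribution (defaults
#'   0.16 / 0.04, centered near the reported screen-wide median).
#' @param noise_sd Per-measurement AAC noise (default 0.03).
#' @param n_targets Targets per drug (default 2).
#' @param driver_genes Planted LE-driver genes (targets of reversers).
#' @param decoy_genes Pool of non-driver target genes.
#' @param neutral_frac Fraction of non-reversing drugs with direction-less
#'   keywords only (default 0.1).
#' @export
drug_screen_config <- function(n_drugs = 40, n_cell_lines = 50,
                               n_datasets = 5, frac_reversing = 0.5,
                               effect = 0.2, aac_mean = 0.16, aac_sd = 0.04,
                               noise_sd = 0.03, n_targets = 2,
                               driver_genes = st_gene_panel(st_config())$drivers,
                               decoy_genes = sprintf("G%04d", 1:50),
                               neutral_frac = 0.1) {
  as.list(environment())
}

#' Run the in-silico drug perturbation screen
#'
#' Per retained drug: map each target's keyword to a direction, drop
#' direction-less targets, require at least one target with nonzero
#' expression, apply the signed-velocity perturbation, rebuild the state
#' graph, and record its flow signatures. Drugs are then stratified at the
#' median aggregated AAC and the signatures compared between high and low
#' groups by a two-sided Wilcoxon rank-sum test.
#'
#' @param vr A `VelocityResult` of an annotated sample.
#' @param records List of `DrugRecord`s (aggregation applied here if
#'   needed).
#' @param magnitude Perturbation scaling (default 200; sign supplied by the
#'   per-target direction).
#' @param sigma Transition-kernel temperature (default 0.1).
#' @param min_cell_lines Passed to [aggregate_aac()] (default 25).
#' @return A `ScreenResult`: `drugs` data.frame (drug, AAC, group,
#'   edge_outgoing, core_incoming), `tests` data.frame (one rank-sum test
#'   per signature), and the `baseline` state graph.
#' @export
run_screen <- function(vr, records, magnitude = 200, sigma = 0.1,
                       min_cell_lines = 25) {
  expressed_genes <- colnames(vr$Ms)[colSums(vr$Ms) > 0]
  rows <- list()
  for (rec in records) {
    if (is.null(rec$aggregated_aac))
      rec <- aggregate_aac(rec, min_cell_lines = min_cell_lines)
    if (is.na(rec$aggregated_aac)) next
    dir <- map_interaction_direction(rec$targets$keyword)
    keep <- dir != "none"
    if (!any(keep)) next                      # no directional information
    genes <- rec$targets$gene[keep]; dir <- dir[keep]
    hit <- genes %in% expressed_genes
    if (!any(hit)) next                       # no expressed target
    spec <- perturbation_spec(genes[hit], dir[hit], magnitude)
    sg <- velocity_state_graph(apply_perturbation(vr, spec), sigma)
    rows[[rec$drug_id]] <- data.frame(
      drug_id = rec$drug_id, aggregated_aac = rec$aggregated_aac,
      edge_outgoing = sg$edge_outgoing, core_incoming = sg$core_incoming,
      stringsAsFactors = FALSE)
  }
  stop_if_not(length(rows) >= 2, "fewer than 2 drugs retained by the screen")
  drugs <- do.call(rbind, rows)
  rownames(drugs) <- NULL
  drugs$group <- stratify_by_median(drugs$aggregated_aac)
  tests <- do.call(rbind, lapply(c("edge_outgoing", "core_incoming"),
                                 function(sig) {
    ht <- suppressWarnings(stats::wilcox.test(
      drugs[[sig]][drugs$group == "high"],
      drugs[[sig]][drugs$group == "low"]))
    data.frame(signature = sig, statistic = unname(ht$statistic),
               p = ht$p.value,
               mean_high = mean(drugs[[sig]][drugs$group == "high"]),
               mean_low = mean(drugs[[sig]][drugs$group == "low"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(drugs = drugs, tests = tests,
                 baseline = velocity_state_graph(vr, sigma)),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("ScreenResult:", nrow(x$drugs), "drugs retained\n")
  print(x$tests)
  invisible(x)
}

#' Group screened drugs by mechanism of action and compare signatures
#'
#' Drug names are matched to the mechanism table allowing a Levenshtein
#' distance of up to `max_dist` (case-insensitive). Classes are groups of
#' more than one drug sharing a mechanism string; flow signatures are
#' compared across classes with a Kruskal-Wallis test.
#'
#' @param screen A `ScreenResult`.
#' @param mechanisms Data.frame with columns `drug_id`, `mechanism`.
#' @param signature Signature column to compare (default `edge_outgoing`).
#' @param max_dist Maximum edit distance for name matching (default 3).
#' @return List: `classes` (data.frame drug/class) and `test`
#'   (Kruskal-Wallis statistic and p), or classes only when fewer than two
#'   classes exist.
#' @export
compare_drug_classes <- function(screen, mechanisms,
                                 signature = "edge_outgoing", max_dist = 3) {
  dm <- utils::adist(tolower(screen$drugs$drug_id),
                     tolower(mechanisms$drug_id))
  best <- apply(dm, 1, which.min)
  ok <- dm[cbind(seq_len(nrow(dm)), best)] <= max_dist
  cls <- ifelse(ok, mechanisms$mechanism[best], NA_character_)
  classes <- data.frame(drug_id = screen$drugs$drug_id, class = cls,
                        stringsAsFactors = FALSE)
  tab <- table(classes$class)
  keep <- classes$class %in% names(tab)[tab > 1]
  out <- list(classes = classes)
  if (length(unique(classes$class[keep])) >= 2) {
    kt <- stats::kruskal.test(screen$drugs[[signature]][keep],
                              factor(classes$class[keep]))
    out$test <- data.frame(statistic = unname(kt$statistic),
                           df = unname(kt$parameter), p = kt$p.value)
  }
  out
}

#' Write / read drug tables as CSV
#'
#' Long-format AAC table (`drug_id`, `cell_line`, `dataset`, `aac`) and
#' interaction table (`drug_id`, `target_gene`, `keyword`).
#'
#' @param records List of `DrugRecord`s.
#' @param aac_path,interactions_path CSV file paths.
#' @return `read_drug_records` returns a list of `DrugRecord`s.
#' @export
write_drug_records <- function(records, aac_path, interactions_path) {
  aac <- do.call(rbind, lapply(records, function(r)
    cbind(drug_id = r$drug_id, r$aac)))
  inter <- do.call(rbind, lapply(records, function(r)
    data.frame(drug_id = r$drug_id, target_gene = r$targets$gene,
               keyword = r$targets$keyword, stringsAsFactors = FALSE)))
  utils::write.csv(aac, aac_path, row.names = FALSE)
  utils::write.csv(inter, interactions_path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_drug_records
#' @export
read_drug_records <- function(aac_path, interactions_path) {
  aac <- utils::read.csv(aac_path, stringsAsFactors = FALSE)
  inter <- utils::read.csv(interactions_path, stringsAsFactors = FALSE)
  lapply(unique(aac$drug_id), function(id) {
    ti <- inter[inter$drug_id == id, ]
    list(drug_id = id,
         aac = aac[aac$drug_id == id, c("cell_line", "dataset", "aac")],
         targets = data.frame(gene = ti$target_gene, keyword = ti$keyword,
                              stringsAsFactors = FALSE))
  })
}
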