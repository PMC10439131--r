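test_that("simulated sample meets its stated contracts", {
  s <- simulate_st_sample(seed = 1)
  expect_s3_class(s, "STSample")
  expect_true(all(s$counts >= 0))
  expect_true(all(s$counts == round(s$counts)))
  expect_lt(max(abs(rowSums(s$deconv) - 1)), 1e-9)

  tumor <- s$truth$region != "stroma"
  ## pathology label SCC exactly on tumor-zone spots
  expect_identical(s$pathology == "SCC", tumor)
  expect_gte(mean(s$deconv[tumor, "cancer"]), 0.995)
  expect_lte(mean(s$deconv[!tumor, "cancer"]), 0.3)
  ## CNV channel concordant with malignancy
  expect_gt(min(s$p_cnv[tumor]), 0.99)
  expect_lt(max(s$p_cnv[!tumor]), 0.5)
  ## every tumor spot has pseudotime; stroma spots are non-cancer types
  expect_true(all(!is.na(s$truth$pseudotime[tumor])))
  expect_true(all(s$truth$cell_type[!tumor] != "cancer"))

  ## core markers higher in TC than LE on the raw matrix
  tc <- s$truth$region == "TC"; le <- s$truth$region == "LE"
  for (g in c("CLDN4", "SPRR1B")) {
    expect_gt(mean(s$counts[tc, g]), mean(s$counts[le, g]))
  }
  for (g in c("LAMC2", "ITGA5")) {
    expect_gt(mean(s$counts[le, g]), mean(s$counts[tc, g]))
  }
})

test_that("seed contract: identical seeds reproduce, different seeds vary", {
  a <- simulate_st_sample(seed = 11)
  b <- simulate_st_sample(seed = 11)
  c <- simulate_st_sample(seed = 12)
  expect_identical(a$counts, b$counts)
  expect_identical(a$deconv, b$deconv)
  expect_false(identical(a$counts, c$counts))
  ## geometry is seed-independent
  expect_identical(a$lattice, c$lattice)
  expect_identical(a$truth$region, c$truth$region)
})

test_that("noise-free channels are recovered exactly by the malignancy rule", {
  s <- simulate_st_sample(st_config(channel_noise = 0, cnv_only_frac = 0),
                          seed = 3)
  s <- call_malignant(s)
  expect_identical(unname(s$malignant), s$truth$region != "stroma")
})

test_that("generator rejects invalid configurations", {
  expect_error(simulate_st_sample(st_config(r_le = 100), seed = 1),
               "exceed")
  expect_error(simulate_st_sample(st_config(core_markers = character()),
                                  seed = 1), "empty marker")
  expect_error(simulate_st_sample(st_config(r_tc = 8, r_trans = 7), seed = 1),
               "increase")
})

test_that("kinetics closed form hits its fixed points and decay laws", {
  ## steady state u* = alpha/beta, s* = alpha/gamma
  p <- kinetics_profile(1e6, alpha = 1, beta = 1, gamma = 0.5, "induction")
  expect_equal(p$u, 1, tolerance = 1e-12)
  expect_equal(p$s, 2, tolerance = 1e-12)
  ## repression: u decays as u0 * exp(-beta t)
  t <- c(0.3, 1, 2.5)
  p <- kinetics_profile(t, alpha = 2, beta = 1.3, gamma = 0.6, "repression")
  expect_equal(p$u, (2 / 1.3) * exp(-1.3 * t), tolerance = 1e-12)
  expect_error(kinetics_profile(1, 1, beta = 0, gamma = 1), "positive")
})

test_that("closed-form kinetics agree with numerical ODE integration", {
  ## independent oracle: RK4 integration of du/dt = a - b u, ds/dt = b u - g s
  rk4 <- function(a, b, g, u0, s0, t_end, dt = 1e-4) {
    u <- u0; s <- s0; t <- 0
    f <- function(st) c(a - b * st[1], b * st[1] - g * st[2])
    st <- c(u, s)
    while (t < t_end - 1e-12) {
      h <- min(dt, t_end - t)
      k1 <- f(st); k2 <- f(st + h / 2 * k1)
      k3 <- f(st + h / 2 * k2); k4 <- f(st + h * k3)
      st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    st
  }
  for (par in list(c(3, 1, 0.4), c(1.5, 2, 1.1))) {
    a <- par[1]; b <- par[2]; g <- par[3]
    p <- kinetics_profile(0.8, a, b, g, "induction")
    num <- rk4(a, b, g, 0, 0, 0.8)
    expect_equal(c(p$u, p$s), num, tolerance = 1e-8)
    pr <- kinetics_profile(0.8, a, b, g, "repression")
    numr <- rk4(0, b, g, a / b, a / g, 0.8)
    expect_equal(c(pr$u, pr$s), numr, tolerance = 1e-8)
  }
})

test_that("noise-free kinetic layers satisfy the closed form to 1e-9", {
  s <- simulate_st_sample(seed = 5)
  kin <- data.frame(gene = c("LAMC2", "CLDN4"),
                    mode = c("induction", "repression"),
                    alpha = c(12, 20), beta = 1, gamma = c(0.4, 0.8))
  s2 <- simulate_kinetics(s, kin, seed = 1, noise = FALSE, t_max = 10)
  ti <- which(!is.na(s$truth$pseudotime))
  t_real <- s$truth$pseudotime[ti] * 10
  for (j in seq_len(nrow(kin))) {
    prof <- kinetics_profile(t_real, kin$alpha[j], kin$beta[j],
                             kin$gamma[j], kin$mode[j])
    expect_equal(unname(s2$unspliced[ti, kin$gene[j]]), prof$u,
                 tolerance = 1e-9)
    expect_equal(unname(s2$spliced[ti, kin$gene[j]]), prof$s,
                 tolerance = 1e-9)
  }
  expect_error(simulate_kinetics(s, transform(kin, gamma = -1), seed = 1),
               "positive")
})

test_that("survival cohort generator honors censoring and determinism", {
  co <- simulate_survival_cohort(survival_config(n = 400, censoring = 0),
                                 seed = 2)
  expect_true(all(co$event == 1L))
  co2 <- simulate_survival_cohort(survival_config(n = 400, censoring = 0.4),
                                  seed = 2)
  expect_lt(abs(mean(1 - co2$event) - 0.4), 0.10)
  expect_identical(
    simulate_survival_cohort(survival_config(n = 100), seed = 9)$time,
    simulate_survival_cohort(survival_config(n = 100), seed = 9)$time)
  expect_error(simulate_survival_cohort(survival_config(n = 0), seed = 1),
               "positive")
})

test_that("drug screen generator plants the documented structure", {
  cfg <- drug_screen_config(n_drugs = 10, n_cell_lines = 30, n_datasets = 2)
  recs <- suppressWarnings(simulate_drug_screen(cfg, seed = 4))
  expect_length(recs, 10L)
  truth <- attr(recs, "truth")$reversing
  expect_length(truth, 5L)
  for (r in recs) {
    expect_true(all(r$aac$aac >= 0 & r$aac$aac <= 1))
    if (r$drug_id %in% truth) {
      expect_setequal(r$targets$gene, cfg$driver_genes)
      expect_true(all(map_interaction_direction(r$targets$keyword) == "down"))
    }
  }
  ## reversing drugs carry the planted AAC shift
  agg <- vapply(recs, function(r) aggregate_aac(r)$aggregated_aac, 0)
  ids <- vapply(recs, `[[`, "", "drug_id")
  expect_gt(mean(agg[ids %in% truth]), mean(agg[!ids %in% truth]))
})
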