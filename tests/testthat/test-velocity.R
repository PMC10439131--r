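test_that("gamma estimation recovers exact ratios and masks dead genes", {
  withr::with_seed(41, {
    s <- matrix(runif(600, 0, 10), 200, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  })
  u <- s
  u[, "a"] <- 0.5 * s[, "a"]      # exact line u = 0.5 s
  u[, "b"] <- 0                   # u == 0 -> gamma 0
  s[, "c"] <- 0                   # zero spliced -> masked
  g <- estimate_gamma(s, u)
  expect_equal(unname(g["a"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(g["b"]), 0)
  expect_true(is.na(g["c"]))
})

test_that("velocity vanishes at steady state and flips with gamma", {
  vr <- velocity_fixture()
  ## a gene-wise steady-state spot: u = gamma * s exactly
  Ms <- vr$Ms; Mu <- sweep(Ms, 2, ifelse(is.na(vr$gamma), 0, vr$gamma), `*`)
  v0 <- Mu - sweep(Ms, 2, ifelse(is.na(vr$gamma), 0, vr$gamma), `*`)
  expect_equal(max(abs(v0)), 0, tolerance = 1e-12)

  ## doubling gamma makes velocity negative wherever u < gamma * s
  g2 <- 2 * vr$gamma
  v2 <- vr$Mu - sweep(vr$Ms, 2, ifelse(is.na(g2), 0, g2), `*`)
  ok <- !is.na(rep(vr$gamma, each = nrow(vr$Ms)))
  below <- vr$Mu < sweep(vr$Ms, 2, ifelse(is.na(vr$gamma), 0, vr$gamma), `*`)
  expect_true(all(v2[below & ok & vr$Ms > 0] < 0))
})

test_that("planted kinetics give TC->LE directed embedded velocity", {
  vr <- velocity_fixture()
  tc <- vr$region == "TC"
  le_centroid <- colMeans(vr$embedding[vr$region == "LE", ])
  to_le <- sweep(-vr$embedding[tc, ], 2, -le_centroid)
  frac <- mean(rowSums(vr$embedded_velocity[tc, ] * to_le) > 0)
  expect_gte(frac, 0.9)
})

test_that("velocity confidence is 1 for coherent fields, 0-centered for noise", {
  vr <- velocity_fixture()
  vr2 <- vr
  withr::with_seed(3, {
    vrow <- rnorm(ncol(vr$velocity))
  })
  vr2$velocity <- matrix(vrow, nrow(vr$velocity), ncol(vr$velocity),
                         byrow = TRUE)
  conf <- velocity_confidence(vr2)
  expect_equal(unname(conf), rep(1, length(conf)), tolerance = 1e-9)

  ## i.i.d. random velocities: mean confidence near 0
  vr3 <- vr
  withr::with_seed(4, {
    vr3$velocity <- matrix(rnorm(length(vr$velocity)), nrow(vr$velocity))
  })
  conf3 <- velocity_confidence(vr3)
  expect_lt(abs(mean(conf3)), 3 / sqrt(ncol(vr$velocity)))

  ## scrambled spots fall to the bottom of the confidence ranking
  vr4 <- vr
  n <- nrow(vr$velocity)
  withr::with_seed(5, {
    bad <- sample(n, round(0.1 * n))
    vr4$velocity[bad, ] <- matrix(rnorm(length(bad) * ncol(vr$velocity)),
                                  length(bad))
  })
  conf4 <- velocity_confidence(vr4)
  cut10 <- quantile(conf4, 0.1)
  expect_gte(mean(conf4[bad] <= quantile(conf4, 0.25)), 0.8)
})

test_that("kernel ridge vector field reproduces linear fields and shrinks to the mean", {
  withr::with_seed(6, {
    x <- matrix(rnorm(60 * 3), 60, 3)
  })
  A <- matrix(c(0.5, -0.2, 0, 0.1, 0.3, -0.4, 0, 0.2, -0.1), 3, 3)
  v <- x %*% A
  vf <- fit_vector_field(x, v, ridge = 1e-10)
  expect_lt(max(abs(predict(vf, x) - v)), 1e-3)
  expect_gt(vf$r_squared, 0.999)

  vf_inf <- fit_vector_field(x, v, ridge = 1e12)
  pred <- predict(vf_inf, x)
  expect_equal(pred, matrix(colMeans(v), 60, 3, byrow = TRUE),
               tolerance = 1e-6)

  ## fitted field preserves the planted TC->LE flow direction
  vr <- velocity_fixture()
  vf2 <- fit_vector_field(vr$embedding, vr$embedded_velocity)
  fitted <- predict(vf2, vr$embedding)
  tc <- vr$region == "TC"
  to_le <- sweep(-vr$embedding[tc, ], 2,
                 -colMeans(vr$embedding[vr$region == "LE", ]))
  expect_gte(mean(rowSums(fitted[tc, ] * to_le) > 0), 0.9)
})

test_that("transition matrix is row-stochastic and matches brute force", {
  vr <- velocity_fixture()
  P <- build_transition_matrix(vr, k = 30, sigma = 0.1)
  expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-9)
  expect_true(all(P@x >= 0))
  expect_equal(unname(Matrix::diag(P)), rep(0, nrow(P)))

  ## independent recomputation from the definition on 200 random spots
  emb <- vr$embedding; ev <- vr$embedded_velocity
  dm <- as.matrix(dist(emb))
  withr::with_seed(8, {
    pick <- sample(nrow(emb), 200)
  })
  for (i in pick) {
    nbr <- order(replace(dm[i, ], i, Inf))[1:30]
    vi <- ev[i, ]
    if (sqrt(sum(vi^2)) == 0) {
      w <- rep(1, 30)
    } else {
      cosang <- vapply(nbr, function(j) {
        d <- emb[j, ] - emb[i, ]
        sum(vi * d) / sqrt(sum(vi^2)) / sqrt(sum(d^2))
      }, 0)
      w <- exp((cosang - max(cosang)) / 0.1)
    }
    w <- w / sum(w)
    expect_equal(as.numeric(P[i, nbr]), unname(w), tolerance = 1e-9)
  }
})

test_that("softmax limit concentrates on the pointed-at neighbor", {
  ## cross layout: center spot's velocity points exactly at one neighbor
  emb <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  ev <- matrix(0, 5, 2)
  ev[1, ] <- c(1, 0)
  P <- build_transition_matrix(emb, ev, k = 4, sigma = 1e-4)
  expect_equal(P[1, 2], 1, tolerance = 1e-9)
})

test_that("coarse state graph applies the documented sum rules", {
  ## hand-built 6-spot transition matrix, two spots per state
  labels <- rep(c("TC", "transitory", "LE"), each = 2)
  P <- matrix(0, 6, 6)
  P[1, 2] <- 1                        # TC -> TC
  P[2, 3] <- 0.6; P[2, 5] <- 0.4      # TC -> transitory/LE
  P[3, 1] <- 0.5; P[3, 4] <- 0.5      # transitory -> TC/transitory
  P[4, 1] <- 1                        # transitory -> TC
  P[5, 3] <- 0.2; P[5, 1] <- 0.1; P[5, 6] <- 0.7
  P[6, 5] <- 1
  sg <- coarse_state_graph(P, labels)
  expect_lt(max(abs(rowSums(sg$Q) - 1)), 1e-9)
  ## Q[LE, transitory] = mean(0.2, 0) = 0.1; Q[LE, TC] = mean(0.1, 0) = 0.05
  expect_equal(sg$Q["LE", "transitory"], 0.1, tolerance = 1e-12)
  expect_equal(sg$edge_outgoing, 0.1 + 0.05, tolerance = 1e-12)
  ## Q[transitory, TC] = mean(0.5, 1) = 0.75
  expect_equal(sg$core_incoming, 0.05 + 0.75, tolerance = 1e-12)
  expect_error(coarse_state_graph(P, rep(c("TC", "LE"), 3)), "empty state")
})

test_that("perturbation overrides target velocity and is a no-op at M = 0", {
  vr <- velocity_fixture()
  drivers <- annotated_sample()$truth$driver_genes
  base <- velocity_state_graph(vr)
  expect_lt(max(abs(rowSums(base$Q) - 1)), 1e-9)

  p0 <- apply_perturbation(vr, perturbation_spec(drivers, "down", 0))
  sg0 <- velocity_state_graph(p0)
  expect_equal(sg0$Q, base$Q, tolerance = 1e-12)

  pd <- apply_perturbation(vr, perturbation_spec(drivers, "down", 200))
  sds <- apply(vr$Ms[, drivers], 2, sd)
  for (g in drivers) {
    expect_equal(unique(pd$velocity[, g]), -sds[[g]], tolerance = 1e-12)
  }
  ## non-target genes untouched
  others <- setdiff(colnames(vr$velocity), drivers)
  expect_identical(pd$velocity[, others], vr$velocity[, others])

  expect_error(apply_perturbation(
    vr, perturbation_spec("NOT_A_GENE", "down", 200)), "absent")
})

test_that("down-perturbing LE drivers reverses flow; up-perturbing does not", {
  vr <- velocity_fixture()
  drivers <- annotated_sample()$truth$driver_genes
  base <- velocity_state_graph(vr)$edge_outgoing
  down <- velocity_state_graph(
    apply_perturbation(vr, perturbation_spec(drivers, "down", 200)))
  up <- velocity_state_graph(
    apply_perturbation(vr, perturbation_spec(drivers, "up", 200)))
  expect_gt(down$edge_outgoing, base)
  expect_lte(up$edge_outgoing, base)
})

test_that("edge_outgoing drug ranking is stable across sigma", {
  vr <- velocity_fixture()
  drivers <- annotated_sample()$truth$driver_genes
  specs <- list(rev1 = perturbation_spec(drivers, "down", 200),
                rev2 = perturbation_spec(drivers[1:6], "down", 200),
                decoy = perturbation_spec(c("G0001", "G0002"), "up", 200))
  ranks <- sapply(c(0.02, 0.1, 0.5), function(sg) {
    eo <- vapply(specs, function(sp)
      velocity_state_graph(apply_perturbation(vr, sp), sigma = sg)$edge_outgoing,
      0)
    rank(eo)
  })
  ## the full-driver reversal outranks the decoy at every temperature
  expect_true(all(ranks["rev1", ] > ranks["decoy", ]))
})
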