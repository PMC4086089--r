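# Potentials of mean force, local/global scores, Z-scores, weight fitting.

test_that("uniform counts give exactly zero scores (inverse-Boltzmann)", {
  for (B in c(12, 40)) {
    u <- homomod:::potential_from_counts(matrix(5, 7, B), rep(35, B))
    expect_true(all(u == 0))
    u2 <- homomod:::potential_from_counts(matrix(3, 20, B), NULL)
    expect_true(all(u2 == 0))
  }
  # empty bins stay finite thanks to the pseudocount
  sparse <- matrix(0, 4, 10); sparse[1, 1] <- 100
  expect_true(all(is.finite(homomod:::potential_from_counts(sparse, NULL))))
})

test_that("training preferences reflect the training set", {
  helixset <- lapply(1:20, function(k) {
    make_toy_structure(30, "helix", seed = 200 + k)
  })
  pt <- train_potential(helixset, "torsion")
  helical_bin <- homomod:::torsion_bin(-57, -47)
  extended_bin <- homomod:::torsion_bin(-119, 113)
  expect_lt(pt$scores["A", helical_bin], pt$scores["A", extended_bin])
  expect_true(all(is.finite(pt$scores)))
  expect_error(train_potential(helixset[1:5], "torsion"), "20")
})

test_that("scores live in [0,1], window=1 disables smoothing", {
  pots <- toy_potentials()
  b <- make_toy_structure(30, "helix_bundle", seed = 888)
  prof <- score_local(b, pots)
  expect_true(all(prof$score >= 0 & prof$score <= 1))
  expect_equal(nrow(prof), 30)
  p1 <- score_local(b, pots, window = 1)
  expect_equal(p1$distance_w, p1$distance)
  expect_equal(p1$torsion_w, p1$torsion)
  g <- score_global(prof)
  expect_gte(g, min(prof$score)); expect_lte(g, max(prof$score))
  # permuting residues leaves the mean unchanged
  expect_equal(score_global(prof[sample(nrow(prof)), ]), g)
})

test_that("Z-scores use the population convention", {
  ref <- c(0.9, 0.8, 0.85, 0.7, 0.95)
  expect_equal(z_score(mean(ref), ref), 0)
  s <- sqrt(mean((ref - mean(ref))^2))
  expect_equal(z_score(mean(ref) + s, ref), 1.0)
  zz <- vapply(ref, z_score, numeric(1), reference = ref)
  expect_equal(mean(zz), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((zz - mean(zz))^2)), 1, tolerance = 1e-12)
  expect_error(z_score(0.5, c(0.7, 0.7)), "spread")
  expect_error(z_score(0.5, 0.7), "2")
})

test_that("native structures outscore perturbed decoys", {
  pots <- toy_potentials()
  natives <- lapply(1:8, function(k) {
    make_toy_structure(30, "helix_bundle", seed = 300 + k)
  })
  sn <- vapply(natives, function(s) score_global(score_local(s, pots)),
               numeric(1))
  sd3 <- vapply(seq_along(natives), function(k) {
    score_global(score_local(perturb_structure(natives[[k]], 3,
                                               seed = 400 + k), pots))
  }, numeric(1))
  expect_gt(mean(sn), mean(sd3))
})

test_that("a perfectly separating term receives the dominant weight", {
  set.seed(3)
  n <- 400
  terms <- data.frame(distance_w = rnorm(n), torsion_w = rnorm(n),
                      burial_w = rnorm(n))
  lab <- ifelse(terms$torsion_w < 0, 0.9, 0.3)
  w <- fit_weights_from_terms(terms, lab)
  expect_equal(which.max(abs(w[-1])), 2L)
  pred <- stats::plogis(w[1] + as.matrix(terms) %*% w[-1])
  acc <- mean((pred > 0.5) == (lab >= 0.6))
  expect_gt(acc, 0.9)
  # determinism
  expect_identical(fit_weights_from_terms(terms, lab), w)
  expect_error(fit_weights_from_terms(terms, rep(1, n)), "single-class")
  expect_error(fit_weights_from_terms(terms[1:20, ], lab[1:20]), "100")
})

test_that("fitted weights generalize to held-out decoys", {
  pots <- toy_potentials()
  mk <- function(seeds, noises) {
    lapply(seq_along(seeds), function(k) {
      ref <- make_toy_structure(32, "helix_bundle", seed = seeds[k])
      res <- if (k %% 2 == 1) seq(6 + k %% 8, 19 + k %% 8) else NULL
      list(ref = ref,
           mod = perturb_structure(ref, noises[(k - 1) %% length(noises) + 1],
                                   seed = seeds[k] * 3, residues = res))
    })
  }
  train <- mk(500 + 1:12, c(0.4, 1, 1.8, 3))
  w <- fit_weights(lapply(train, `[[`, "mod"), lapply(train, `[[`, "ref"),
                   pots)
  test <- mk(900 + 1:6, c(0.5, 1.3, 2.2, 3))
  sc <- c(); tr <- c()
  for (d in test) {
    prof <- score_local(d$mod, pots, weights = w)
    ld <- lddt(d$mod, d$ref)
    m <- match(paste(prof$chain, prof$resno),
               paste(ld$per_residue$chain, ld$per_residue$resno))
    sc <- c(sc, prof$score); tr <- c(tr, ld$per_residue$lddt[m])
  }
  expect_gt(stats::cor(sc, tr, method = "spearman"), 0.4)
})
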