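# Feature-density calibration and joint GMQE estimation.

make_records <- function(n = 120, seed = 3) {
  # synthetic records where s* is a noisy monotone function of feature f1
  # and exactly equals feature f2
  homomod:::with_seed(seed, {
    s <- stats::runif(n)
    data.frame(f1 = pmin(1, pmax(0, s + stats::rnorm(n, 0, 0.1))), f2 = s,
               s_star = s)
  })
}

test_that("per-bin densities are normalized and relevance reflects signal", {
  r <- make_records()
  cal <- calibrate_gmqe(r[, c("f1", "f2")], r$s_star)
  grid <- cal$grid
  for (fd in cal$features) {
    for (b in fd$bins) {
      integral <- sum(diff(grid) * (head(b$density, -1) +
                                      tail(b$density, -1)) / 2)
      expect_equal(integral, 1, tolerance = 1e-6)
      expect_true(all(b$density >= 0))
    }
  }
  expect_gt(cal$features$f2$relevance, 0.95)
  # a constant feature gets zero relevance and a flat density
  rc <- cbind(r[, c("f1", "f2")], flat = 1)
  expect_warning(cal2 <- calibrate_gmqe(rc, r$s_star), "constant")
  expect_equal(cal2$features$flat$relevance, 0)
})

test_that("perfectly informative features put the density peak at s*", {
  r <- make_records()
  cal <- calibrate_gmqe(r[, c("f1", "f2")], r$s_star)
  # for the exact feature f2, each bin's density must peak near the bin's
  # own s* values (within one grid step of their median)
  fd <- cal$features$f2
  for (b in fd$bins) {
    peak <- cal$grid[which.max(b$density)]
    expect_lt(abs(peak - stats::median(b$centers)), 0.06)
  }
})

test_that("joint argmax matches a fine-grid scan and is order-invariant", {
  r <- make_records()
  cal <- calibrate_gmqe(r[, c("f1", "f2")], r$s_star)
  fine <- seq(0, 1, length.out = 1001)
  for (v in c(0.15, 0.5, 0.85)) {
    feats <- c(f1 = v, f2 = v)
    est <- joint_estimate(feats, cal)
    expect_gte(est$gmqe, 0); expect_lte(est$gmqe, 1)
    scan <- fine[which.max(homomod:::joint_log_density(feats, cal, fine))]
    expect_lt(abs(est$gmqe - scan), 0.011)  # within one grid step
    # single informative feature: argmax equals that feature's PDF argmax
    single <- joint_estimate(c(f2 = v), cal)
    expect_equal(single$gmqe, unname(single$per_feature["f2"]))
    # feature order must not matter
    expect_equal(joint_estimate(feats[c(2, 1)], cal)$gmqe, est$gmqe)
  }
  # out-of-range values are clamped and flagged
  est <- joint_estimate(c(f1 = 7, f2 = 0.5), cal)
  expect_true("f1" %in% est$clamped)
})

test_that("calibration contract is enforced", {
  r <- make_records(30)
  expect_error(calibrate_gmqe(r[, 1:2], r$s_star), "50")
  r2 <- make_records(60)
  expect_error(calibrate_gmqe(r2[, 1:2], r2$s_star * 2), "0,1|\\[0,1\\]")
})

test_that("ranking sorts by gmqe with documented tie-breaks", {
  r <- make_records()
  cal <- calibrate_gmqe(r[, c("f1", "f2")], r$s_star)
  mk_hit <- function(entry, f1, f2, ident) {
    list(entry = entry, chain = "A", alignment = NULL,
         features = c(f1 = f1, f2 = f2, seq_identity = ident),
         gmqe = NA_real_)
  }
  hits <- list(mk_hit("B", 0.3, 0.3, 0.5), mk_hit("A", 0.9, 0.9, 0.2),
               mk_hit("C", 0.3, 0.3, 0.9))
  ranked <- rank_templates(hits, cal)
  expect_equal(vapply(ranked, function(h) h$entry, character(1))[1], "A")
  # equal gmqe: higher identity first
  expect_equal(vapply(ranked, function(h) h$entry, character(1))[2:3],
               c("C", "B"))
  # output is a permutation of the input
  expect_setequal(vapply(ranked, function(h) h$entry, character(1)),
                  c("A", "B", "C"))
})

test_that("densities survive JSON serialization", {
  r <- make_records()
  cal <- calibrate_gmqe(r[, c("f1", "f2")], r$s_star)
  path <- withr::local_tempfile(fileext = ".json")
  save_densities(cal, path)
  cal2 <- load_densities(path)
  feats <- c(f1 = 0.4, f2 = 0.4)
  expect_equal(joint_estimate(feats, cal2)$gmqe,
               joint_estimate(feats, cal)$gmqe)
  expect_equal(cal2$features$f1$relevance, cal$features$f1$relevance,
               tolerance = 1e-12)
})

test_that("the combined estimate is bounded and monotone", {
  vals <- expand.grid(g = c(0, 0.3, 0.7, 1), q = c(0, 0.4, 1))
  ce <- mapply(combined_estimate, vals$g, vals$q)
  expect_true(all(ce >= 0 & ce <= 1))
  for (g in c(0.2, 0.6)) {
    expect_gte(combined_estimate(g, 0.9), combined_estimate(g, 0.3))
    expect_gte(combined_estimate(0.9, g), combined_estimate(0.3, g))
  }
  # fitted weights keep the monotonicity contract even on adversarial data
  set.seed(1)
  w <- fit_combined_weights(runif(60), runif(60), runif(60))
  expect_gte(w[2], 0); expect_gte(w[3], 0)
})
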