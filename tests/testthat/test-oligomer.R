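# Interface detection, features, conservation classifier and the
# size-weighted oligomeric decision.

test_that("interface detection matches a brute-force contact count", {
  cx <- make_complex(2, "none", seed = 4)
  ifs <- detect_interfaces(cx, 5.0)
  expect_length(ifs, 1)
  # independent all-pairs recount
  atoms <- as_atoms(cx)
  atoms <- atoms[atoms$kind == "polymer", ]
  a <- atoms[atoms$chain == "A", ]; b <- atoms[atoms$chain == "B", ]
  pairs <- c()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= 5.0) pairs <- c(pairs, paste(a$resno[i], b$resno[j]))
    }
  }
  expect_setequal(paste(ifs[[1]]$contacts$resno_a, ifs[[1]]$contacts$resno_b),
                  unique(pairs))
  expect_gte(nrow(ifs[[1]]$contacts), 5)
  # monomer and far-apart chains yield no interfaces
  expect_length(detect_interfaces(make_complex(1, "none", seed = 4)), 0)
  far <- as_atoms(cx)
  far$x[far$chain == "B"] <- far$x[far$chain == "B"] + 50
  expect_length(detect_interfaces(hm_assembly("F", "1", far)), 0)
})

test_that("contact sets grow monotonically with the cutoff", {
  cx <- make_complex(2, "none", seed = 7)
  key <- function(ifs) {
    if (length(ifs) == 0) return(character(0))
    paste(ifs[[1]]$contacts$resno_a, ifs[[1]]$contacts$resno_b)
  }
  k4 <- key(detect_interfaces(cx, 4.0))
  k5 <- key(detect_interfaces(cx, 5.0))
  k6 <- key(detect_interfaces(cx, 6.0))
  expect_true(all(k4 %in% k5))
  expect_true(all(k5 %in% k6))
})

test_that("interface features behave on the self-template", {
  cx <- make_complex(2, "none", seed = 4)
  lib <- add_structure(template_library(), assembly_to_structure(cx, "CPLX"))
  tseq <- chain_sequence(cx, "A")$seq
  hits <- search_templates(lib, tseq)
  entry <- lib$entries[["CPLX.1"]]
  ifs <- detect_interfaces(entry$assembly)
  f <- interface_features(ifs[[1]], hits[[1]]$alignment, entry$chains$A,
                          lib, hits, self_entry = "CPLX.1")
  expect_equal(unname(f["identity"]), 1.0)
  expect_equal(unname(f["consensus"]), 0)  # no other template in the set
  # an all-isoleucine interface has the scale's isoleucine hydrophobicity
  tpl <- entry$chains$A
  tpl$seq <- strrep("I", nchar(tpl$seq))
  f2 <- interface_features(ifs[[1]], hits[[1]]$alignment, tpl)
  expect_equal(unname(f2["hydrophobicity"]), unname(KYTE_DOOLITTLE["I"]))
})

test_that("classifier separates a separable table and is seed-stable", {
  tab <- make_interface_table(500, seed = 11, margin = 0.05,
                              deterministic = TRUE)
  train <- tab[1:350, ]; test <- tab[351:500, ]
  clf <- train_interface_classifier(train, seed = 5)
  p <- predict_conservation(clf, test)
  expect_true(all(p >= 0 & p <= 1))
  acc <- mean((p > 0.5) == (test$conserved == 1))
  expect_gt(acc, 0.9)
  clf2 <- train_interface_classifier(train, seed = 5)
  expect_identical(predict_conservation(clf2, test), p)
  # degenerate label sets are rejected
  single <- train; single$conserved <- 1
  expect_error(train_interface_classifier(single, seed = 1), "single class")
  expect_error(train_interface_classifier(train[1:10, ], seed = 1), "50")
})

test_that("predicted probabilities track the true link monotonically", {
  tab <- make_interface_table(500, seed = 21)
  true_p <- attr(tab, "true_p")
  train_idx <- 1:300
  clf <- train_interface_classifier(tab[train_idx, ], seed = 2)
  p <- predict_conservation(clf, tab[-train_idx, ])
  rho <- stats::cor(p, true_p[-train_idx], method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("the size-weighted decision computes the stated average", {
  d <- decide_oligomer(c(10, 30), c(1.0, 0.5), threshold = 0.5)
  expect_equal(d$weighted_average, 0.625)
  expect_equal(d$predicted, "conserved_oligomer")
  # direct-sum recomputation and order invariance over random cases
  set.seed(9)
  for (k in 1:20) {
    n <- sample(1:6, 1)
    sizes <- sample(1:50, n, TRUE)
    probs <- runif(n)
    d1 <- decide_oligomer(sizes, probs)
    expect_equal(d1$weighted_average, sum(sizes * probs) / sum(sizes))
    perm <- sample(n)
    expect_equal(decide_oligomer(sizes[perm], probs[perm])$weighted_average,
                 d1$weighted_average)
  }
  expect_equal(decide_oligomer(c(5, 5), c(1, 1), 0.99)$predicted,
               "conserved_oligomer")
  expect_equal(decide_oligomer(integer(0), numeric(0))$predicted, "monomer")
})
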