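# Local alignment, alignment features, search and the similarity landscape.

test_that("self-alignment recovers the matrix diagonal and full identity", {
  mat <- substitution_matrix()
  s <- "MKTAYIAKQR"
  aln <- local_align(s, s)
  expect_equal(aln$score, sum(diag(mat[strsplit(s, "")[[1]],
                                       strsplit(s, "")[[1]]])))
  expect_equal(nrow(aln$columns), nchar(s))
  expect_true(all(aln$columns$ai == aln$columns$bi))
})

test_that("optimal scores match exhaustive enumeration for short sequences", {
  mat <- substitution_matrix()
  alphabet <- c("A", "R", "W", "G", "C")
  set.seed(42)
  for (k in 1:12) {
    a <- paste(sample(alphabet, sample(3:6, 1), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(3:6, 1), TRUE), collapse = "")
    expect_equal(local_align(a, b, mat)$score,
                 brute_force_local_score(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent aligner", {
  skip_if_not_installed("Biostrings")
  mat <- substitution_matrix()
  set.seed(7)
  for (k in 1:6) {
    a <- paste(sample(homomod:::AA1, sample(10:30, 1), TRUE), collapse = "")
    b <- paste(sample(homomod:::AA1, sample(10:30, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    expect_equal(local_align(a, b, mat)$score, Biostrings::score(ref))
  }
})

test_that("alignment score is symmetric and input is validated", {
  mat <- substitution_matrix()
  a <- "MKWVTFISLLLF"; b <- "MKWVTAISLF"
  expect_equal(local_align(a, b, mat)$score, local_align(b, a, mat)$score)
  expect_error(local_align("MK1T", b), "position 3")
  expect_error(local_align("", b), "empty")
})

test_that("alignment features count what they claim to count", {
  # constructed alignment: 4 aligned columns, half identical
  tpl <- list(chain = "A", seq = "AGCW", ss = "HHHH",
              rel_acc = c(0.9, 0.1, 0.9, 0.1))
  aln <- structure(list(a = "AGLY", b = "AGCW", score = 10,
                        columns = data.frame(ai = 1:4, bi = 1:4)),
                   class = "hm_alignment")
  pred <- list(ss = "HHCC", burial = "eebb")
  f <- alignment_features(aln, tpl, pred)
  expect_equal(unname(f["seq_identity"]), 0.5)
  expect_equal(unname(f["coverage"]), 1.0)
  expect_equal(unname(f["ss_agreement"]), 0.5)
  # template burial (acc < 0.25) is e,b,e,b -> agreement with eebb = 0.5
  expect_equal(unname(f["acc_agreement"]), 0.5)
  # features only see aligned columns: gapped columns do not contribute
  f2 <- alignment_features(structure(list(a = "AGLY", b = "AGCW", score = 10,
      columns = data.frame(ai = c(1, 2, 3, 4, NA), bi = c(1, 2, 3, NA, 4))),
      class = "hm_alignment"), tpl, pred)
  expect_equal(unname(f2["seq_identity"]),
               2 / 3)  # only 3 aligned columns now, 2 identical
  # degenerate: no aligned columns
  empty <- structure(list(a = "AG", b = "CW", score = 0,
                          columns = data.frame(ai = 1:2, bi = c(NA, NA))),
                     class = "hm_alignment")
  expect_error(alignment_features(empty, tpl, pred), "undefined")
})

test_that("feature fractions stay in range with identity below similarity", {
  lib <- template_library()
  lib <- add_structure(lib, assembly_to_structure(
    make_toy_structure(30, "helix_bundle", seed = 3), "T1"))
  tgt <- make_toy_structure(30, "helix_bundle", seed = 11)
  hom <- make_homolog(tgt, 0.3, 0.03, 0.8, seed = 5)
  lib <- add_structure(lib, assembly_to_structure(hom$template, "T2"))
  hits <- search_templates(lib, chain_sequence(tgt, "A")$seq, min_score = 10)
  for (h in hits) {
    f <- h$features
    frac <- f[c("seq_identity", "seq_similarity", "ss_agreement",
                "acc_agreement", "coverage")]
    expect_true(all(frac >= 0 & frac <= 1))
    expect_lte(f[["seq_identity"]], f[["seq_similarity"]])
  }
})

test_that("search returns one hit per chain, deterministically ordered", {
  lib <- template_library()
  cx <- make_complex(2, "none", seed = 4)
  lib <- add_structure(lib, assembly_to_structure(cx, "CPLX"))
  lib <- add_structure(lib, assembly_to_structure(
    make_toy_structure(25, "strand_pair", seed = 9), "DEC"))
  tseq <- chain_sequence(cx, "A")$seq
  hits <- search_templates(lib, tseq)
  expect_lte(length(hits), nrow(library_index(lib)))
  expect_equal(hits[[1]]$entry, "CPLX.1")
  expect_equal(unname(hits[[1]]$features["seq_identity"]), 1.0)
  # threshold above every score empties the hit list
  expect_length(search_templates(lib, tseq, min_score = 1e6), 0)
  expect_error(search_templates(lib, ""), "empty")
})

test_that("similarity landscape embeds distances and clusters sensibly", {
  lib <- template_library()
  t1 <- make_toy_structure(24, "helix", seed = 3)
  hom <- make_homolog(t1, 0.05, 0, 0.1, seed = 2)   # near-identical pair
  far <- make_toy_structure(24, "strand_pair", seed = 31)
  lib <- add_structure(lib, assembly_to_structure(t1, "T1"))
  lib <- add_structure(lib, assembly_to_structure(hom$template, "T2"))
  lib <- add_structure(lib, assembly_to_structure(far, "T3"))
  hits <- search_templates(lib, chain_sequence(t1, "A")$seq, min_score = 1)
  land <- similarity_landscape(hits, lib, identity_threshold = 0.7)
  expect_equal(nrow(land), length(hits))
  expect_setequal(land$entry, c("T1.1", "T2.1", "T3.1"))
  # the identical template pair lands closer than the unrelated one
  rowidx <- function(e) which(land$entry == e)
  d <- function(i, j) sqrt(sum((land[i, c("x", "y")] - land[j, c("x", "y")])^2))
  expect_lt(d(rowidx("T1.1"), rowidx("T2.1")),
            d(rowidx("T1.1"), rowidx("T3.1")))
  expect_equal(land$cluster[rowidx("T1.1")], land$cluster[rowidx("T2.1")])
  # cluster count non-increasing as the threshold loosens
  n50 <- length(unique(similarity_landscape(hits, lib, 0.5)$cluster))
  n90 <- length(unique(similarity_landscape(hits, lib, 0.9)$cluster))
  expect_lte(n50, n90)
})

test_that("a metric 3-point configuration is embedded exactly", {
  # distances from identities 0.9/0.7/0.6 form a valid metric; classical
  # MDS on 3 points must reproduce them
  d <- matrix(c(0, 0.1, 0.3, 0.1, 0, 0.4, 0.3, 0.4, 0), 3, 3)
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  emb <- unname(as.matrix(dist(xy)))
  expect_equal(emb, unname(d), tolerance = 1e-6)
})
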