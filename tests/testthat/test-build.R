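# Coordinate transfer, side chains, gap closure, oligomer assembly and
# ligand transfer.

self_hit <- function(cx, lib) {
  search_templates(lib, chain_sequence(cx, "A")$seq)[[1]]
}

test_that("self-modelling reproduces the template exactly", {
  cx <- make_complex(2, "site_ligand", seed = 4)
  lib <- add_structure(template_library(), assembly_to_structure(cx, "CPLX"))
  m <- build_model(self_hit(cx, lib), lib)
  expect_true(all(m$provenance$state == "aligned_copied"))
  # backbone atoms equal the template chain A backbone
  tpl <- as_atoms(cx)
  tpl <- tpl[tpl$chain == "A" & tpl$elety %in% c("N", "CA", "C", "O"), ]
  mod <- m$atoms[m$atoms$chain == "A" &
                   m$atoms$elety %in% c("N", "CA", "C", "O"), ]
  expect_equal(mod$x, tpl$x, tolerance = 1e-9)
  expect_equal(lddt(m, cx)$global, 1.0)
  # oligomeric copy reproduces the template inter-chain geometry
  expect_setequal(m$chains, c("A", "B"))
  ca_dist <- function(atoms, c1, c2) {
    a <- atoms[atoms$chain == c1 & atoms$elety == "CA", c("x", "y", "z")]
    b <- atoms[atoms$chain == c2 & atoms$elety == "CA", c("x", "y", "z")]
    sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
           2 * as.matrix(a) %*% t(as.matrix(b)))
  }
  expect_lt(max(abs(ca_dist(m$atoms, "A", "B") -
                      ca_dist(as_atoms(cx), "A", "B"))), 0.5)
  # ligand carried over
  expect_equal(m$ligands[[1]]$status, "placed")
  expect_true("LIG" %in% m$atoms$resname)
})

test_that("substitutions are truncated to an ideal CB", {
  h <- make_toy_structure(sequence = strrep("L", 12), fold = "helix")
  lib <- add_structure(template_library(), assembly_to_structure(h, "POLYL"))
  # target differs at position 6: LEU -> ALA
  tseq <- paste0(strrep("L", 5), "A", strrep("L", 6))
  hit <- search_templates(lib, tseq)[[1]]
  entry <- lib$entries[["POLYL.1"]]
  m <- transfer_backbone(hit$alignment, entry$assembly, entry$chains$A)
  m <- build_sidechains(m, entry$assembly, entry$chains$A)
  expect_equal(m$provenance$state[6], "substituted_truncated")
  res6 <- m$atoms[m$atoms$resno == 6, ]
  expect_setequal(res6$elety, c("N", "CA", "C", "O", "CB"))
  g <- function(nm) unlist(res6[res6$elety == nm, c("x", "y", "z")])
  expect_equal(sqrt(sum((g("CB") - g("CA"))^2)), 1.53, tolerance = 0.01)
  # glycine target gets no CB
  tseq_g <- paste0(strrep("L", 5), "G", strrep("L", 6))
  hitg <- search_templates(lib, tseq_g)[[1]]
  mg <- build_sidechains(transfer_backbone(hitg$alignment, entry$assembly,
                                           entry$chains$A),
                         entry$assembly, entry$chains$A)
  expect_false("CB" %in% mg$atoms$elety[mg$atoms$resno == 6])
  expect_equal(mg$provenance$state[6], "substituted_truncated")
})

test_that("insertions are unmodelled, then short ones are interpolated", {
  tpl <- make_toy_structure(14, "helix", seed = 2)
  tseq0 <- chain_sequence(tpl, "A")$seq
  # 2-residue insertion in the target after template position 7
  tseq <- paste0(substr(tseq0, 1, 7), "AA", substr(tseq0, 8, 14))
  cols <- data.frame(ai = c(1:7, 8, 9, 10:16),
                     bi = c(1:7, NA, NA, 8:14))
  aln <- structure(list(a = tseq, b = tseq0, score = NA_real_,
                        columns = cols), class = "hm_alignment")
  entry_chain <- list(chain = "A", seq = tseq0,
                      map = chain_sequence(tpl, "A")$map)
  m <- transfer_backbone(aln, tpl, entry_chain)
  expect_equal(m$provenance$state[8:9], c("unmodelled", "unmodelled"))
  m2 <- close_short_gaps(m)
  expect_equal(m2$provenance$state[8:9], c("interpolated", "interpolated"))
  # interpolated CAs are evenly spaced between the anchors
  ca <- function(pos) {
    unlist(m2$atoms[m2$atoms$resno == pos & m2$atoms$elety == "CA",
                    c("x", "y", "z")])
  }
  seg <- ca(10) - ca(7)
  expect_equal(ca(8), ca(7) + seg / 3, tolerance = 1e-9)
  expect_equal(ca(9), ca(7) + 2 * seg / 3, tolerance = 1e-9)
  # provenance states always partition the target
  expect_setequal(m2$provenance$pos, seq_len(nchar(tseq)))
  expect_false(any(is.na(m2$provenance$state)))
})

test_that("long insertions stay open and are reported as chain breaks", {
  tpl <- make_toy_structure(14, "helix", seed = 2)
  tseq0 <- chain_sequence(tpl, "A")$seq
  tseq <- paste0(substr(tseq0, 1, 7), strrep("A", 5), substr(tseq0, 8, 14))
  cols <- data.frame(ai = seq_len(19),
                     bi = c(1:7, rep(NA, 5), 8:14))
  aln <- structure(list(a = tseq, b = tseq0, score = NA_real_,
                        columns = cols), class = "hm_alignment")
  entry_chain <- list(chain = "A", seq = tseq0,
                      map = chain_sequence(tpl, "A")$map)
  m <- close_short_gaps(transfer_backbone(aln, tpl, entry_chain))
  expect_true(all(m$provenance$state[8:12] == "unmodelled"))
  breaks <- attr(m, "chain_breaks")
  expect_length(breaks, 1)
  expect_equal(unname(breaks[[1]]), c(8, 12))
})

test_that("monomer decision suppresses oligomer expansion", {
  cx <- make_complex(2, "none", seed = 4)
  lib <- add_structure(template_library(), assembly_to_structure(cx, "CPLX"))
  hit <- self_hit(cx, lib)
  entry <- lib$entries[["CPLX.1"]]
  m <- transfer_backbone(hit$alignment, entry$assembly, entry$chains$A)
  m <- build_sidechains(m, entry$assembly, entry$chains$A)
  mono <- assemble_oligomer(m, entry$assembly,
                            decide_oligomer(10, 0.1))
  expect_equal(mono$chains, "A")
  dimer <- assemble_oligomer(m, entry$assembly,
                             decide_oligomer(10, 0.9))
  expect_setequal(dimer$chains, c("A", "B"))
  # copies are rigid: intra-chain distance sets identical
  d_of <- function(atoms, ch) {
    as.vector(dist(atoms[atoms$chain == ch, c("x", "y", "z")]))
  }
  expect_equal(d_of(dimer$atoms, "A"), d_of(dimer$atoms, "B"),
               tolerance = 1e-9)
})

test_that("ligand transfer is strict about conservation and geometry", {
  cx <- make_complex(2, "site_ligand", seed = 4)
  lib <- add_structure(template_library(), assembly_to_structure(cx, "CPLX"))
  entry <- lib$entries[["CPLX.1"]]
  hit <- self_hit(cx, lib)
  build <- function(aln) {
    m <- transfer_backbone(aln, entry$assembly, entry$chains$A)
    m <- build_sidechains(m, entry$assembly, entry$chains$A)
    transfer_ligands(m, entry, entry$chains$A)
  }
  placed <- build(hit$alignment)
  expect_equal(placed$ligands[[1]]$status, "placed")
  expect_equal(placed$ligands[[1]]$reason, "ok")
  # mutate one coordinating residue in the target -> rejected
  lig <- entry$assembly$atoms[entry$assembly$atoms$kind == "ligand", ]
  poly <- entry$assembly$atoms[entry$assembly$atoms$kind == "polymer", ]
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  mind <- apply(as.matrix(poly[, c("x", "y", "z")]), 1, function(p) {
    min(sqrt(colSums((t(lxyz) - p)^2)))
  })
  coord_res <- unique(poly$resno[mind <= 4.0])
  tseq <- chain_sequence(cx, "A")$seq
  mutated <- strsplit(tseq, "")[[1]]
  mutated[coord_res[1]] <- if (mutated[coord_res[1]] == "G") "W" else "G"
  aln_mut <- local_align(paste(mutated, collapse = ""), tseq)
  rejected <- build(aln_mut)
  expect_equal(rejected$ligands[[1]]$status, "rejected")
  expect_equal(rejected$ligands[[1]]$reason, "coordination_not_conserved")
  # monotonicity: mutating any single coordinating residue never turns a
  # rejection into a placement
  for (rn in coord_res) {
    mm <- strsplit(tseq, "")[[1]]
    mm[rn] <- if (mm[rn] == "G") "W" else "G"
    st <- build(local_align(paste(mm, collapse = ""), tseq))$ligands[[1]]
    expect_equal(st$status, "rejected")
  }
  # artificial clash: pull a model atom onto the ligand
  m <- transfer_backbone(hit$alignment, entry$assembly, entry$chains$A)
  m <- build_sidechains(m, entry$assembly, entry$chains$A)
  m$atoms[1, c("x", "y", "z")] <- lig[1, c("x", "y", "z")] + c(1, 0, 0)
  clash <- transfer_ligands(m, entry, entry$chains$A)
  expect_equal(clash$ligands[[1]]$reason, "clash")
  # category exclusion: non-relevant ligands are never transferred
  entry2 <- entry
  entry2$ligand_annotations$category <- "non_functional"
  excl <- transfer_ligands(build_sidechains(
    transfer_backbone(hit$alignment, entry$assembly, entry$chains$A),
    entry$assembly, entry$chains$A), entry2, entry$chains$A)
  expect_equal(excl$ligands[[1]]$reason, "category_excluded")
})
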