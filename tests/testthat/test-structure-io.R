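# Structure containers, dialect round-trips, and assembly expansion.

test_that("PDB and mmCIF round-trips preserve atoms, kinds and assemblies", {
  cx <- make_complex(2, "site_ligand", seed = 4)
  s <- assembly_to_structure(cx, "CPLX")
  s$assemblies <- list(list(id = "1", gens = list(
    list(chains = unique(s$atoms$chain), mats = list(diag(4))))))
  for (dialect in c("pdb", "mmcif")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    suppressMessages(write_structure(s, path, dialect))
    r <- read_structure(path, dialect)
    expect_equal(nrow(r$atoms), nrow(s$atoms))
    expect_equal(r$atoms$kind, s$atoms$kind)
    expect_equal(r$atoms$resname, s$atoms$resname)
    # coordinates are written to 3 decimals
    expect_equal(r$atoms$x, s$atoms$x, tolerance = 1e-3)
    expect_equal(r$atoms$z, s$atoms$z, tolerance = 1e-3)
    expect_length(r$assemblies, 1)
  }
})

test_that("coordinates survive an independent PDB reader", {
  skip_if_not_installed("bio3d")
  h <- make_toy_structure(15, "helix", seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  suppressMessages(write_structure(h, path, "pdb"))
  ext <- bio3d::read.pdb(path)
  expect_equal(nrow(ext$atom), nrow(h$atoms))
  expect_equal(ext$atom$x, round(h$atoms$x, 3))
  expect_equal(ext$atom$resno, h$atoms$resno)
})

test_that("degenerate and invalid inputs are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), path)
  expect_error(read_structure(path, "pdb"), "empty structure")
  nan_model <- make_toy_structure(6, "helix", seed = 1)
  nan_model$atoms$x[3] <- NaN
  expect_error(write_structure(nan_model, path, "pdb"), "non-finite")
  nuc <- atom_table(chain = "A", resno = 1:2, resname = c("DA", "DG"),
                    elety = "P", element = "P", x = 0:1, y = 0, z = 0)
  expect_error(hm_structure("NUC", nuc), "nucleic")
  big <- make_toy_structure(6, "helix", seed = 1)
  big$atoms <- big$atoms[rep(seq_len(nrow(big$atoms)), 4000), ]
  expect_error(write_structure(big, path, "pdb"), "mmcif")
})

test_that("water-only chains yield no polymer sequence", {
  w <- atom_table(chain = "A", resno = 1:3, resname = "HOH", elety = "O",
                  element = "O", x = 1:3, y = 0, z = 0)
  expect_true(all(w$kind == "water"))
  expect_error(chain_sequence(w, "A"), "no polymer")
})

test_that("assembly expansion applies transforms and preserves geometry", {
  h <- make_toy_structure(12, "helix", seed = 1)
  s <- assembly_to_structure(h, "SYMM")
  m2 <- diag(4)
  m2[1:3, 1:3] <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  m2[1:3, 4] <- c(25, 0, 0)
  s$assemblies <- list(list(id = "1", gens = list(
    list(chains = "A", mats = list(diag(4), m2)))))
  asm <- build_assemblies(s)
  expect_length(asm, 1)
  expect_equal(asm[[1]]$oligomeric_state, 2)
  expect_setequal(unique(asm[[1]]$atoms$chain), c("A", "A-2"))
  # rigid-motion invariance of intra-chain distances
  d_of <- function(atoms) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    as.vector(dist(xyz))
  }
  d1 <- d_of(asm[[1]]$atoms[asm[[1]]$atoms$chain == "A", ])
  d2 <- d_of(asm[[1]]$atoms[asm[[1]]$atoms$chain == "A-2", ])
  expect_lt(max(abs(d1 - d2)), 1e-6)
  # no instructions: identity fallback
  s0 <- assembly_to_structure(h, "PLAIN")
  asm0 <- build_assemblies(s0)
  expect_length(asm0, 1)
  expect_equal(asm0[[1]]$atoms$x, s0$atoms$x)
  # singular transform rejected at construction
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(hm_structure("B", h$atoms, assemblies = list(
    list(id = "1", gens = list(list(chains = "A", mats = list(bad)))))),
    "rigid")
})

test_that("multi-character chain ids are remapped in the PDB dialect", {
  h <- make_toy_structure(8, "helix", seed = 1)
  a2 <- h$atoms; a2$chain <- "A-2"
  asm <- hm_assembly("X", "1", rbind(h$atoms, a2))
  path <- withr::local_tempfile(fileext = ".pdb")
  expect_message(write_structure(asm, path, "pdb"), "remap")
  r <- read_structure(path, "pdb")
  expect_length(unique(r$atoms$chain), 2)
  expect_true(all(nchar(unique(r$atoms$chain)) == 1))
})
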