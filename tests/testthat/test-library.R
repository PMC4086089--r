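# Ligand classification (rules then overrides) and the template library.

test_that("identity rules classify common ligands", {
  h <- make_toy_structure(10, "helix", seed = 1)
  mk_lig <- function(resname, elety, element, offset = c(12, 0, 0)) {
    ca <- h$atoms[h$atoms$elety == "CA" & h$atoms$resno == 5, ]
    atom_table(chain = "X", resno = 100, resname = resname, elety = elety,
               element = element, x = ca$x + offset[1], y = ca$y + offset[2],
               z = ca$z + offset[3], kind = "ligand")
  }
  ctx <- function(lig) hm_assembly("T", "1", rbind(h$atoms, lig))
  k <- mk_lig("K", "K", "K")
  expect_equal(classify_ligand(k, ctx(k))$category, "non_functional")
  gol <- mk_lig("GOL", "C1", "C")
  expect_equal(classify_ligand(gol, ctx(gol))$category, "non_functional")
  hem <- mk_lig("HEM", "FE", "FE")
  expect_equal(classify_ligand(hem, ctx(hem))$category,
               "biologically_relevant")
  unk <- mk_lig("QQQ", "C1", "C")
  ann <- classify_ligand(unk, ctx(unk))
  expect_equal(ann$category, "biologically_relevant")
  expect_equal(ann$note, "unclassified")
  # an atom 1.5 A from the polymer is a covalent modification, whatever
  # its identity says
  close <- mk_lig("GOL", "C1", "C", offset = c(1.5, 0, 0))
  expect_equal(classify_ligand(close, ctx(close))$category,
               "covalent_modification")
})

test_that("overrides replace rule annotations and report dangling refs", {
  ann <- data.frame(chain = "X", resno = 100L, ins = "", resname = "K",
                    category = "non_functional", source = "rule",
                    note = "solvent ion", stringsAsFactors = FALSE)
  ov <- data.frame(chain = "X", resno = 100L,
                   category = "biologically_relevant",
                   note = "channel ion", stringsAsFactors = FALSE)
  out <- apply_overrides(ann, ov)
  expect_equal(out$category, "biologically_relevant")
  expect_equal(out$source, "override")
  # empty override set is the identity
  out2 <- apply_overrides(ann, NULL)
  expect_equal(out2$category, ann$category)
  # dangling reference: warning, annotations untouched
  bad <- data.frame(chain = "Z", resno = 9L, category = "non_functional")
  expect_warning(out3 <- apply_overrides(ann, bad), "absent")
  expect_equal(out3$category, ann$category)
  expect_equal(nrow(attr(out3, "dangling")), 1)
  # malformed records are an error
  expect_error(apply_overrides(ann, data.frame(chain = "X")), "lack")
  expect_error(
    apply_overrides(ann, data.frame(chain = "X", resno = 100L,
                                    category = "nonsense")),
    "category")
})

test_that("library construction indexes every chain exactly once", {
  lib <- template_library()
  cx <- make_complex(2, "site_ligand", seed = 4)
  lib <- add_structure(lib, assembly_to_structure(cx, "CPLX"))
  h <- make_toy_structure(20, "helix", seed = 5)
  lib <- add_structure(lib, assembly_to_structure(h, "HLX"))
  idx <- library_index(lib)
  expect_equal(nrow(idx), 3)  # 2 complex chains + 1 helix chain
  expect_false(any(duplicated(paste(idx$entry, idx$chain))))
  # per-chain annotation lengths agree
  for (e in lib$entries) {
    for (pc in e$chains) {
      expect_equal(nchar(pc$seq), nchar(pc$ss))
      expect_equal(nchar(pc$seq), length(pc$rel_acc))
    }
  }
  # idempotent re-add
  lib2 <- add_structure(lib, assembly_to_structure(cx, "CPLX"))
  expect_equal(length(lib2$entries), length(lib$entries))
})

test_that("save/load round-trips the library and checks integrity", {
  lib <- template_library()
  lib <- add_structure(lib, assembly_to_structure(
    make_complex(2, "site_ligand", seed = 4), "CPLX"))
  dir <- withr::local_tempdir()
  save_library(lib, dir)
  lib2 <- load_library(dir)
  expect_identical(library_index(lib2), library_index(lib))
  e1 <- lib$entries[[1]]; e2 <- lib2$entries[[1]]
  expect_equal(e2$ligand_annotations$category, e1$ligand_annotations$category)
  expect_equal(e2$chains$A$rel_acc, e1$chains$A$rel_acc, tolerance = 1e-6)
  expect_equal(as.numeric(e2$assembly$atoms$x),
               as.numeric(e1$assembly$atoms$x), tolerance = 1e-3)
  # corrupted sidecar is named in the error
  sidecar <- list.files(dir, "CPLX.*json$", full.names = TRUE)
  writeLines("{ not json", sidecar)
  expect_error(load_library(dir), "CPLX")
  # missing coordinate file is an integrity error
  save_library(lib, dir)
  file.remove(list.files(dir, "\\.cif$", full.names = TRUE))
  expect_error(load_library(dir), "missing")
  # version mismatch is an explicit migration error
  save_library(lib, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  man$version <- "0"
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_library(dir), "version")
})
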