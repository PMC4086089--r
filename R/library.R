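# Template library: annotated bio-unit entries with a searchable sequence
# index, two-stage ligand classification (automatic rules, then curated
# overrides), and an on-disk layout of coordinate files + JSON sidecars.

LIBRARY_FORMAT_VERSION <- "1"

#' Load the default ligand classification rule table
#'
#' @return list with `solvent_ions`, `buffers_cryoprotectants`, `cofactors`,
#'   `functional_metals` character vectors.
#' @export
default_ligand_rules <- function() {
  jsonlite::read_json(system.file("extdata", "ligand_rules.json",
                                  package = "homomod"),
                      simplifyVector = TRUE)
}

#' Classify a ligand residue by chemical identity and context
#'
#' Stage one of the two-stage annotation: a covalent bond to the polymer
#' (any heavy-atom pair closer than `covalent_cutoff`) forces
#' `covalent_modification`; otherwise the first matching identity list in
#' the rule table decides between `non_functional` (solvent ions, buffers,
#' cryoprotectants) and `biologically_relevant` (cofactors, functional
#' metals). Unmatched ligands default to `biologically_relevant` with note
#' `"unclassified"` so that they are vetted later by the transfer checks.
#'
#' @param res atom table rows of one ligand residue.
#' @param context structure-like object supplying the polymer environment.
#' @param rules rule table (see [default_ligand_rules()]).
#' @param covalent_cutoff heavy-atom distance in Angstrom (default 1.7).
#' @return one-row data.frame: `chain`, `resno`, `ins`, `resname`,
#'   `category`, `source`, `note`.
#' @export
classify_ligand <- function(res, context, rules = default_ligand_rules(),
                            covalent_cutoff = 1.7) {
  stopifnot(all(res$kind == "ligand"))
  atoms <- as_atoms(context)
  poly <- atoms[atoms$kind == "polymer" & atoms$element != "H", , drop = FALSE]
  lig_xyz <- atom_xyz(res[res$element != "H", , drop = FALSE])
  category <- NULL; note <- ""
  if (nrow(poly) > 0 && nrow(lig_xyz) > 0) {
    pxyz <- atom_xyz(poly)
    mind <- min(apply(lig_xyz, 1, function(p) {
      min(sqrt(colSums((t(pxyz) - p)^2)))
    }))
    if (mind < covalent_cutoff) {
      category <- "covalent_modification"
      note <- sprintf("heavy-atom contact %.2f A to polymer", mind)
    }
  }
  name <- res$resname[1]
  if (is.null(category)) {
    if (name %in% rules$solvent_ions) {
      category <- "non_functional"; note <- "solvent ion"
    } else if (name %in% rules$buffers_cryoprotectants) {
      category <- "non_functional"; note <- "buffer/cryoprotectant"
    } else if (name %in% rules$cofactors) {
      category <- "biologically_relevant"; note <- "cofactor"
    } else if (name %in% rules$functional_metals) {
      category <- "biologically_relevant"; note <- "functional metal"
    } else {
      category <- "biologically_relevant"; note <- "unclassified"
    }
  }
  data.frame(chain = res$chain[1], resno = res$resno[1], ins = res$ins[1],
             resname = name, category = category, source = "rule",
             note = note, stringsAsFactors = FALSE)
}

#' @keywords internal
annotate_ligands <- function(assembly, rules = default_ligand_rules()) {
  atoms <- as_atoms(assembly)
  lig <- atoms[atoms$kind == "ligand", , drop = FALSE]
  if (nrow(lig) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      ins = character(), resname = character(),
                      category = character(), source = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  key <- paste(lig$chain, lig$resno, lig$ins, sep = "|")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    classify_ligand(lig[key == k, , drop = FALSE], assembly, rules)
  }))
  rownames(out) <- NULL
  out
}

#' Apply curated overrides to ligand annotations
#'
#' Stage two of the annotation process: override records (matched on chain,
#' residue number and insertion code) replace the rule-derived category and
#' are marked `source = "override"`. Overrides referencing ligands that do
#' not exist are returned in the `dangling` attribute and reported as a
#' warning; everything else is untouched.
#'
#' @param annotations annotation data.frame from [classify_ligand()].
#' @param overrides data.frame or JSON file path with records
#'   `{chain, resno, ins (optional), category, note (optional)}`.
#' @return annotations with overrides applied; attribute `dangling` lists
#'   unmatched override records.
#' @export
apply_overrides <- function(annotations, overrides) {
  if (is.character(overrides)) {
    overrides <- tryCatch(
      jsonlite::read_json(overrides, simplifyVector = TRUE),
      error = function(e) stop("malformed override file: ", conditionMessage(e)))
    if (length(overrides) == 0) overrides <- NULL
  }
  if (is.null(overrides) || NROW(overrides) == 0) {
    attr(annotations, "dangling") <- data.frame()
    return(annotations)
  }
  overrides <- as.data.frame(overrides, stringsAsFactors = FALSE)
  required <- c("chain", "resno", "category")
  missing_cols <- setdiff(required, names(overrides))
  if (length(missing_cols) > 0) {
    stop("override records lack field(s): ", paste(missing_cols, collapse = ", "))
  }
  valid <- c("biologically_relevant", "covalent_modification", "non_functional")
  for (k in seq_len(nrow(overrides))) {
    if (!overrides$category[k] %in% valid) {
      stop("override record ", k, ": unknown category '",
           overrides$category[k], "'")
    }
  }
  if (is.null(overrides$ins)) overrides$ins <- ""
  if (is.null(overrides$note)) overrides$note <- "curated override"
  akey <- paste(annotations$chain, annotations$resno, annotations$ins)
  dangling <- integer(0)
  for (k in seq_len(nrow(overrides))) {
    okey <- paste(overrides$chain[k], overrides$resno[k], overrides$ins[k])
    hit <- which(akey == okey)
    if (length(hit) == 0) {
      dangling <- c(dangling, k)
    } else {
      annotations$category[hit] <- overrides$category[k]
      annotations$source[hit] <- "override"
      annotations$note[hit] <- overrides$note[k]
    }
  }
  if (length(dangling) > 0) {
    warning(length(dangling), " override record(s) reference ligands ",
            "absent from the entry (records ",
            paste(dangling, collapse = ", "), ")")
  }
  attr(annotations, "dangling") <- overrides[dangling, , drop = FALSE]
  annotations
}

#' Create an empty template library
#'
#' @return object of class `hm_library` with no entries.
#' @export
template_library <- function() {
  structure(list(entries = list(), version = LIBRARY_FORMAT_VERSION),
            class = "hm_library")
}

#' @export
print.hm_library <- function(x, ...) {
  cat("<hm_library>", length(x$entries), "entries,",
      nrow(library_index(x)), "indexed chains\n")
  invisible(x)
}

# Build one annotated TemplateEntry from an assembly.
#' @keywords internal
make_template_entry <- function(assembly, rules = default_ligand_rules(),
                                overrides = NULL, sasa_points = 64) {
  chains <- polymer_chain_ids(assembly)
  acc <- solvent_accessibility(assembly, n_points = sasa_points)
  per_chain <- lapply(chains, function(ch) {
    cs <- chain_sequence(assembly, ch)
    ss <- secondary_structure(assembly, ch)
    acc_ch <- acc[acc$chain == ch, , drop = FALSE]
    acc_vec <- acc_ch$rel_acc[match(paste(cs$map$resno, cs$map$ins),
                                    paste(acc_ch$resno, acc_ch$ins))]
    stopifnot(nchar(cs$seq) == nchar(ss),
              nchar(cs$seq) == length(acc_vec))
    list(chain = ch, seq = cs$seq, map = cs$map, ss = ss,
         rel_acc = acc_vec, tags = detect_tags(cs$seq))
  })
  names(per_chain) <- chains
  ann <- annotate_ligands(assembly, rules)
  if (!is.null(overrides)) ann <- apply_overrides(ann, overrides)
  list(assembly = assembly, chains = per_chain, ligand_annotations = ann)
}

#' Add a structure to a template library
#'
#' Expands the structure into its bio-unit assemblies and stores one
#' annotated entry per assembly, keyed `(structure id, biounit id)`.
#' Re-adding a structure replaces its previous entries. Assemblies without
#' polymer chains are skipped with a message.
#'
#' @param lib an `hm_library`.
#' @param s an [hm_structure()].
#' @param rules ligand rule table.
#' @param overrides optional curated override records for this structure.
#' @param sasa_points SASA sampling density used for annotation.
#' @return the updated library.
#' @export
add_structure <- function(lib, s, rules = default_ligand_rules(),
                          overrides = NULL, sasa_points = 64) {
  stopifnot(inherits(lib, "hm_library"), inherits(s, "hm_structure"))
  assemblies <- build_assemblies(s)
  stale <- vapply(lib$entries, function(e) e$assembly$source == s$id,
                  logical(1))
  lib$entries <- lib$entries[!stale]
  added <- 0
  for (a in assemblies) {
    if (a$oligomeric_state == 0) {
      message("skipping ", s$id, " biounit ", a$biounit_id,
              ": no polymer chain")
      next
    }
    key <- paste(s$id, a$biounit_id, sep = ".")
    lib$entries[[key]] <- make_template_entry(a, rules, overrides,
                                              sasa_points = sasa_points)
    added <- added + 1
  }
  if (added == 0) message("structure ", s$id, " contributed no entries")
  lib
}

#' Sequence index of a template library
#'
#' @param lib an `hm_library`.
#' @return data.frame with one row per (entry, chain): `entry`, `chain`,
#'   `seq`.
#' @export
library_index <- function(lib) {
  rows <- list()
  for (key in names(lib$entries)) {
    e <- lib$entries[[key]]
    for (pc in e$chains) {
      rows[[length(rows) + 1]] <- data.frame(
        entry = key, chain = pc$chain, seq = pc$seq, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(entry = character(), chain = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Save a template library to a directory
#'
#' Layout: one mmCIF coordinate file and one JSON sidecar per entry plus a
#' `manifest.json` carrying the format version and entry list. [load_library()]
#' restores an identical library.
#'
#' @param lib an `hm_library`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
save_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (key in names(lib$entries)) {
    e <- lib$entries[[key]]
    stem <- gsub("[^A-Za-z0-9._-]", "_", key)
    # mmCIF keeps multi-character chain ids of oligomeric copies intact
    coord <- paste0(stem, ".cif")
    sidecar <- paste0(stem, ".json")
    write_structure(e$assembly, file.path(dir, coord), "mmcif")
    side <- list(
      source = e$assembly$source, biounit_id = e$assembly$biounit_id,
      chain_ids = names(e$chains),
      chains = lapply(e$chains, function(pc) {
        list(chain = pc$chain, seq = pc$seq, ss = pc$ss,
             rel_acc = pc$rel_acc, map = pc$map, tags = pc$tags)
      }),
      ligand_annotations = e$ligand_annotations)
    jsonlite::write_json(side, file.path(dir, sidecar), auto_unbox = TRUE,
                         digits = NA, null = "null")
    entries[[key]] <- list(coord = coord, sidecar = sidecar)
  }
  jsonlite::write_json(list(version = LIBRARY_FORMAT_VERSION,
                            entries = entries),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a template library from a directory
#'
#' @param dir directory written by [save_library()].
#' @return an `hm_library`.
#' @export
load_library <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (!identical(manifest$version, LIBRARY_FORMAT_VERSION)) {
    stop("library format version ", manifest$version,
         " does not match code version ", LIBRARY_FORMAT_VERSION,
         "; rebuild the library")
  }
  lib <- template_library()
  for (key in names(manifest$entries)) {
    rec <- manifest$entries[[key]]
    coord <- file.path(dir, rec$coord)
    sidecar <- file.path(dir, rec$sidecar)
    if (!file.exists(coord) || !file.exists(sidecar)) {
      stop("library integrity error: files for entry '", key, "' missing")
    }
    side <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                     error = function(e) {
                       stop("corrupted sidecar for entry '", key, "': ",
                            conditionMessage(e))
                     })
    s <- read_structure(coord, "mmcif")
    assembly <- hm_assembly(side$source, side$biounit_id, s$atoms)
    chains <- lapply(seq_along(side$chain_ids), function(i) {
      pc <- if (is.data.frame(side$chains)) {
        as.list(side$chains[i, ])
      } else side$chains[[i]]
      pc$map <- as.data.frame(pc$map, stringsAsFactors = FALSE)
      pc$tags <- as.data.frame(pc$tags, stringsAsFactors = FALSE)
      pc$rel_acc <- as.numeric(unlist(pc$rel_acc))
      pc
    })
    names(chains) <- unlist(side$chain_ids)
    ann <- as.data.frame(side$ligand_annotations, stringsAsFactors = FALSE)
    lib$entries[[key]] <- list(assembly = assembly, chains = chains,
                               ligand_annotations = ann)
  }
  lib
}
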