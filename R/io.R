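# Reading and writing coordinate files. Two dialects are supported: PDB
# (ATOM/HETATM records plus REMARK 350 assembly operators) and a focused
# mmCIF subset (atom_site plus pdbx_struct_assembly_gen/oper_list).

#' Read a macromolecular structure
#'
#' Parses polymer chains, ligands and waters together with any biological
#' assembly instructions present. Only the first NMR model is read; alternate
#' locations are collapsed to the highest-occupancy conformer (ties broken
#' alphabetically by altloc id). Missing residues appear as numbering gaps.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"mmcif"`; guessed from the extension by default.
#' @return an [hm_structure()].
#' @export
read_structure <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  dialect <- match.arg(dialect, c("pdb", "mmcif"))
  s <- switch(dialect,
              pdb = read_pdb_file(path),
              mmcif = read_mmcif_file(path))
  if (nrow(s$atoms) == 0) stop("empty structure: no atom records in ", path)
  s
}

#' @keywords internal
collapse_altloc <- function(atoms, altloc) {
  if (all(altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety, sep = "|")
  ord <- order(key, -atoms$occ, altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' @keywords internal
read_pdb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  endmdl <- which(grepl("^ENDMDL", lines))
  if (length(endmdl) > 0) {
    is_atom[seq_along(lines) > endmdl[1]] <- FALSE
  }
  rec <- lines[is_atom]
  atoms <- NULL
  if (length(rec) > 0) {
    sub_ <- function(a, b) trimws(substr(rec, a, b))
    xyz <- suppressWarnings(cbind(as.numeric(substr(rec, 31, 38)),
                                  as.numeric(substr(rec, 39, 46)),
                                  as.numeric(substr(rec, 47, 54))))
    if (any(!is.finite(xyz))) {
      bad <- which(!stats::complete.cases(xyz))[1]
      stop("unparseable coordinates at ATOM record ", bad, " of ", path)
    }
    occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
    bfc <- suppressWarnings(as.numeric(substr(rec, 61, 66)))
    el <- sub_(77, 78)
    atoms <- atom_table(
      chain = sub_(22, 22), resno = sub_(23, 26), ins = sub_(27, 27),
      resname = sub_(18, 20), elety = sub_(13, 16),
      element = ifelse(el == "", NA, el),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = ifelse(is.na(occ), 1, occ), b = ifelse(is.na(bfc), 0, bfc)
    )
    rownames(atoms) <- seq_len(nrow(atoms))
    atoms <- collapse_altloc(atoms, substr(rec, 17, 17))
    het <- grepl("^HETATM", rec)
  }
  id <- "unnamed"
  header <- lines[grepl("^HEADER", lines)]
  if (length(header) > 0 && nchar(header[1]) >= 66) {
    id0 <- trimws(substr(header[1], 63, 66))
    if (nzchar(id0)) id <- id0
  }
  hm_structure(id = id, atoms = atoms %||% atom_table(character(), integer(),
               character(), character(), numeric(), numeric(), numeric()),
               assemblies = parse_remark350(lines),
               metadata = list(path = path))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
parse_remark350 <- function(lines) {
  r350 <- lines[grepl("^REMARK 350", lines)]
  if (length(r350) == 0) return(list())
  assemblies <- list()
  cur_id <- NULL; cur_chains <- NULL
  rows <- list()  # accumulating BIOMT rows per operator
  flush_gen <- function() {
    if (is.null(cur_chains) || length(rows) == 0) return(NULL)
    mats <- lapply(rows, function(m) {
      mm <- diag(4); mm[1:3, ] <- do.call(rbind, m); mm
    })
    list(chains = cur_chains, mats = unname(mats))
  }
  add_gen <- function(gen) {
    if (is.null(gen)) return()
    i <- which(vapply(assemblies, function(a) a$id == cur_id, logical(1)))
    if (length(i) == 0) {
      assemblies[[length(assemblies) + 1]] <<- list(id = cur_id, gens = list(gen))
    } else {
      assemblies[[i]]$gens <<- c(assemblies[[i]]$gens, list(gen))
    }
  }
  for (ln in r350) {
    body <- substr(ln, 12, nchar(ln))
    if (grepl("BIOMOLECULE:", body)) {
      add_gen(flush_gen()); rows <- list(); cur_chains <- NULL
      cur_id <- trimws(sub(".*BIOMOLECULE:", "", body))
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", body)) {
      add_gen(flush_gen()); rows <- list()
      cur_chains <- trimws(strsplit(
        sub(".*CHAINS:", "", body), ",")[[1]])
      cur_chains <- cur_chains[nzchar(cur_chains)]
    } else if (grepl("BIOMT[123]", body)) {
      tok <- strsplit(trimws(body), "\\s+")[[1]]
      krow <- as.integer(sub("BIOMT", "", tok[1]))
      op <- tok[2]
      vals <- as.numeric(tok[3:6])
      if (any(!is.finite(vals))) stop("malformed BIOMT record: ", ln)
      if (is.null(rows[[op]])) rows[[op]] <- list()
      rows[[op]][[krow]] <- vals
    }
  }
  add_gen(flush_gen())
  assemblies
}

#' Write a structure, assembly or model to disk
#'
#' Output is re-readable by [read_structure()]. In the PDB dialect chain ids
#' longer than one character (oligomeric copies such as `A-2`) are remapped
#' to unused single characters; the mapping is logged as a message and
#' recorded in REMARK 300 lines.
#'
#' @param s an [hm_structure()], [hm_assembly()] or `hm_model`.
#' @param path output path.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @return invisibly, the path.
#' @export
write_structure <- function(s, path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  atoms <- as_atoms(s)
  if (nrow(atoms) == 0) stop("refusing to write an empty structure")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates; cannot write")
  }
  id <- if (!is.null(s$id)) s$id else if (!is.null(s$source)) s$source else "MODL"
  assemblies <- if (!is.null(s$assemblies)) s$assemblies else list()
  if (dialect == "pdb") {
    write_pdb_file(id, atoms, assemblies, path)
  } else {
    write_mmcif_file(id, atoms, assemblies, path)
  }
  invisible(path)
}

#' @keywords internal
remap_chain_ids <- function(chains) {
  pool <- c(LETTERS, letters, as.character(0:9))
  map <- stats::setNames(chains, chains)
  long <- chains[nchar(chains) > 1]
  used <- chains[nchar(chains) == 1]
  for (ch in long) {
    cand <- setdiff(pool, used)
    if (length(cand) == 0) stop("too many chains for the PDB dialect")
    map[ch] <- cand[1]
    used <- c(used, cand[1])
  }
  map
}

#' @keywords internal
write_pdb_file <- function(id, atoms, assemblies, path) {
  if (nrow(atoms) > 99999) {
    stop("more than 99999 atoms: the PDB dialect cannot hold this; ",
         "use dialect = 'mmcif'")
  }
  chains <- unique(atoms$chain)
  map <- remap_chain_ids(chains)
  out <- c(sprintf("HEADER    %-40s%9s   %4s",
                   "HOMOMOD STRUCTURE", "", substr(id, 1, 4)))
  if (any(map != names(map))) {
    remapped <- names(map)[map != names(map)]
    for (ch in remapped) {
      out <- c(out, sprintf("REMARK 300 CHAIN REMAP %s -> %s", ch, map[ch]))
    }
    message("PDB chain remap: ",
            paste(remapped, "->", map[remapped], collapse = ", "))
  }
  for (asm in assemblies) {
    out <- c(out, sprintf("REMARK 350 BIOMOLECULE: %s", asm$id))
    for (gen in asm$gens) {
      out <- c(out, sprintf("REMARK 350 APPLY THE FOLLOWING TO CHAINS: %s",
                            paste(map[gen$chains], collapse = ", ")))
      for (k in seq_along(gen$mats)) {
        m <- gen$mats[[k]]
        for (r in 1:3) {
          out <- c(out, sprintf(
            "REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f     %10.5f",
            r, k, m[r, 1], m[r, 2], m[r, 3], m[r, 4]))
        }
      }
    }
  }
  fmt_name <- function(elety, element) {
    ifelse(nchar(elety) >= 4, substr(elety, 1, 4),
           ifelse(nchar(element) == 1, sprintf(" %-3s", elety),
                  sprintf("%-4s", elety)))
  }
  rectype <- ifelse(atoms$kind == "polymer", "ATOM  ", "HETATM")
  out <- c(out, sprintf(
    "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rectype, seq_len(nrow(atoms)), fmt_name(atoms$elety, atoms$element),
    atoms$resname, map[atoms$chain], atoms$resno,
    ifelse(nzchar(atoms$ins), atoms$ins, " "),
    atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b, atoms$element),
    "END")
  writeLines(out, path)
}

#' @keywords internal
write_mmcif_file <- function(id, atoms, assemblies, path) {
  q <- function(x) ifelse(nzchar(x), x, "?")
  out <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", id)), "#")
  if (length(assemblies) > 0) {
    out <- c(out, "loop_",
             "_pdbx_struct_assembly_gen.assembly_id",
             "_pdbx_struct_assembly_gen.oper_expression",
             "_pdbx_struct_assembly_gen.asym_id_list")
    opers <- list(); oper_n <- 0
    for (asm in assemblies) {
      for (gen in asm$gens) {
        ids <- integer(0)
        for (m in gen$mats) {
          oper_n <- oper_n + 1
          opers[[oper_n]] <- m
          ids <- c(ids, oper_n)
        }
        out <- c(out, sprintf("%s %s %s", asm$id,
                              paste(ids, collapse = ","),
                              paste(gen$chains, collapse = ",")))
      }
    }
    out <- c(out, "#", "loop_", "_pdbx_struct_oper_list.id",
             sprintf("_pdbx_struct_oper_list.matrix[%d][%d]",
                     rep(1:3, each = 3), rep(1:3, 3)),
             sprintf("_pdbx_struct_oper_list.vector[%d]", 1:3))
    for (k in seq_along(opers)) {
      m <- opers[[k]]
      out <- c(out, paste(c(k, sprintf("%.6f", t(m[1:3, 1:3])),
                            sprintf("%.5f", m[1:3, 4])), collapse = " "))
    }
  }
  out <- c(out, "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv")
  rectype <- ifelse(atoms$kind == "polymer", "ATOM", "HETATM")
  out <- c(out, sprintf(
    "%s %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
    rectype, seq_len(nrow(atoms)), q(atoms$element), atoms$elety,
    atoms$resname, atoms$chain, atoms$resno, q(atoms$ins),
    atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b), "#")
  writeLines(out, path)
}

# Minimal mmCIF loop reader: returns a named list of data.frames keyed by
# category, each with item-named character columns. Handles whitespace-
# separated rows and single-quoted values; sufficient for the subset this
# package writes plus simple externally produced files.
#' @keywords internal
read_mmcif_loops <- function(lines) {
  cats <- list()
  i <- 1; n <- length(lines)
  tokenize <- function(ln) {
    m <- gregexpr("'[^']*'|\\S+", ln)[[1]]
    tok <- regmatches(ln, list(m))[[1]]
    gsub("^'|'$", "", tok)
  }
  while (i <= n) {
    ln <- trimws(lines[i])
    if (identical(ln, "loop_")) {
      items <- character()
      i <- i + 1
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        items <- c(items, trimws(lines[i])); i <- i + 1
      }
      rows <- list()
      while (i <= n) {
        ln2 <- trimws(lines[i])
        if (ln2 == "" || grepl("^(#|loop_|_|data_)", ln2)) break
        tok <- tokenize(ln2)
        if (length(tok) != length(items)) {
          stop("mmCIF row at line ", i, " has ", length(tok),
               " values for ", length(items), " items")
        }
        rows[[length(rows) + 1]] <- tok
        i <- i + 1
      }
      if (length(rows) > 0) {
        cat_name <- sub("\\..*$", "", items[1])
        df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(df) <- sub("^[^.]*\\.", "", items)
        cats[[sub("^_", "", cat_name)]] <- df
      }
    } else {
      i <- i + 1
    }
  }
  cats
}

#' @keywords internal
read_mmcif_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  id_line <- grep("^data_", lines, value = TRUE)
  id <- if (length(id_line) > 0) sub("^data_", "", id_line[1]) else "unnamed"
  cats <- read_mmcif_loops(lines)
  site <- cats[["atom_site"]]
  atoms <- NULL
  if (!is.null(site)) {
    pick <- function(cands, default = NA) {
      for (cn in cands) if (cn %in% names(site)) return(site[[cn]])
      rep(default, nrow(site))
    }
    ins <- pick(c("pdbx_PDB_ins_code"), "?")
    ins[ins %in% c("?", ".")] <- ""
    el <- pick(c("type_symbol"))
    el[el %in% c("?", ".")] <- NA
    num <- function(v, default = NA_real_) {
      v[v %in% c("?", ".")] <- NA
      out <- suppressWarnings(as.numeric(v))
      out[is.na(out)] <- default
      out
    }
    xyz <- cbind(num(site$Cartn_x), num(site$Cartn_y), num(site$Cartn_z))
    if (any(!is.finite(xyz))) {
      stop("unparseable _atom_site coordinates in ", path)
    }
    atoms <- atom_table(
      chain = pick(c("auth_asym_id", "label_asym_id"), "A"),
      resno = num(pick(c("auth_seq_id", "label_seq_id"), "1"), 1),
      ins = ins,
      resname = pick(c("label_comp_id", "auth_comp_id")),
      elety = pick(c("label_atom_id", "auth_atom_id")),
      element = el,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = num(pick("occupancy", "1"), 1),
      b = num(pick("B_iso_or_equiv", "0"), 0))
  } else {
    atoms <- atom_table(character(), integer(), character(), character(),
                        numeric(), numeric(), numeric())
  }
  assemblies <- list()
  gen <- cats[["pdbx_struct_assembly_gen"]]
  ops <- cats[["pdbx_struct_oper_list"]]
  if (!is.null(gen) && !is.null(ops)) {
    mats <- lapply(seq_len(nrow(ops)), function(k) {
      m <- diag(4)
      for (r in 1:3) for (cc in 1:3) {
        m[r, cc] <- as.numeric(ops[[sprintf("matrix[%d][%d]", r, cc)]][k])
      }
      for (r in 1:3) m[r, 4] <- as.numeric(ops[[sprintf("vector[%d]", r)]][k])
      m
    })
    names(mats) <- ops$id
    for (k in seq_len(nrow(gen))) {
      aid <- gen$assembly_id[k]
      g <- list(chains = strsplit(gen$asym_id_list[k], ",")[[1]],
                mats = unname(mats[strsplit(gen$oper_expression[k], ",")[[1]]]))
      i <- which(vapply(assemblies, function(a) a$id == aid, logical(1)))
      if (length(i) == 0) {
        assemblies[[length(assemblies) + 1]] <- list(id = aid, gens = list(g))
      } else {
        assemblies[[i]]$gens <- c(assemblies[[i]]$gens, list(g))
      }
    }
  }
  hm_structure(id = id, atoms = atoms, assemblies = assemblies,
               metadata = list(path = path))
}
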