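# Core structure containers. A structure is a list with an atom table (one
# row per atom, bio3d-style) plus assembly instructions; an assembly is a
# transformed copy organized as the biologically relevant oligomer.

#' Create an atom table
#'
#' The atom table is the package's core container: one row per atom with
#' chain, residue and coordinate columns. Residue `kind` (polymer, ligand,
#' water) is derived from the residue name when not supplied.
#'
#' @param chain,resno,resname,elety,x,y,z atom fields (vectors, recycled).
#' @param ins insertion code, default `""`.
#' @param element element symbol; guessed from the atom name when missing.
#' @param occ,b occupancy and B-factor.
#' @param kind residue kind; derived from `resname` when `NULL`.
#' @return data.frame with class-stable columns.
#' @export
atom_table <- function(chain, resno, resname, elety, x, y, z,
                       ins = "", element = NULL, occ = 1, b = 0,
                       kind = NULL) {
  n <- max(length(chain), length(resno), length(elety), length(x))
  df <- data.frame(
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno), n),
    ins = rep_len(as.character(ins), n),
    resname = rep_len(toupper(as.character(resname)), n),
    elety = rep_len(as.character(elety), n),
    element = if (is.null(element)) rep_len(NA_character_, n) else
      rep_len(toupper(element), n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    occ = rep_len(as.numeric(occ), n),
    b = rep_len(as.numeric(b), n),
    stringsAsFactors = FALSE
  )
  miss <- is.na(df$element)
  if (any(miss)) df$element[miss] <- guess_element(df$elety[miss])
  df$kind <- if (is.null(kind)) residue_kind(df$resname) else rep_len(kind, n)
  df
}

#' @keywords internal
guess_element <- function(elety) {
  el <- sub("^[0-9]*", "", toupper(elety))
  two <- substr(el, 1, 2)
  one <- substr(el, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "CL", "BR", "MN", "CU", "SE"), two, one)
}

#' @keywords internal
residue_kind <- function(resname) {
  resname <- toupper(resname)
  ifelse(resname %in% WATER_CODES, "water",
         ifelse(resname %in% AA3, "polymer", "ligand"))
}

#' Construct a structure object
#'
#' @param id entry identifier.
#' @param atoms atom table (see [atom_table()]).
#' @param assemblies list of assembly instructions; each is a list with `id`
#'   and `gens`, where every generator holds `chains` (chain ids) and `mats`
#'   (a list of 4x4 transform matrices).
#' @param metadata free-form header list.
#' @return object of class `hm_structure`.
#' @export
hm_structure <- function(id, atoms, assemblies = list(), metadata = list()) {
  stopifnot(is.data.frame(atoms))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  nuc <- atoms$resname %in% NUCLEIC_CODES & !(atoms$resname %in% WATER_CODES)
  if (any(nuc)) {
    stop("nucleic-acid residues are not supported (found ",
         paste(unique(atoms$resname[nuc]), collapse = ", "), ")")
  }
  for (asm in assemblies) {
    for (gen in asm$gens) {
      for (m in gen$mats) {
        if (abs(det(m[1:3, 1:3]) - 1) > 1e-6) {
          stop("assembly transform is not a proper rigid motion ",
               "(rotation determinant != +1)")
        }
      }
    }
  }
  structure(list(id = id, atoms = atoms, assemblies = assemblies,
                 metadata = metadata),
            class = "hm_structure")
}

#' Construct an assembly (bio-unit) object
#'
#' @param source source structure id.
#' @param biounit_id assembly identifier.
#' @param atoms transformed atom table with unique chain ids.
#' @return object of class `hm_assembly`.
#' @export
hm_assembly <- function(source, biounit_id, atoms) {
  polymer_chains <- unique(atoms$chain[atoms$kind == "polymer"])
  structure(list(source = source, biounit_id = biounit_id, atoms = atoms,
                 oligomeric_state = length(polymer_chains)),
            class = "hm_assembly")
}

#' Extract the atom table from any structure-like object
#'
#' @param x an `hm_structure`, `hm_assembly`, `hm_model` or bare atom table.
#' @return the atom data.frame.
#' @export
as_atoms <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && !is.null(x$atoms)) return(x$atoms)
  stop("cannot extract an atom table from class ",
       paste(class(x), collapse = "/"))
}

#' @keywords internal
atom_xyz <- function(atoms) {
  as.matrix(as_atoms(atoms)[, c("x", "y", "z")])
}

#' @keywords internal
polymer_chain_ids <- function(x) {
  a <- as_atoms(x)
  unique(a$chain[a$kind == "polymer"])
}

# Residue-level split of a chain's polymer atoms, ordered by (resno, ins).
#' @keywords internal
chain_polymer_residues <- function(x, chain) {
  a <- as_atoms(x)
  a <- a[a$chain == chain & a$kind == "polymer", , drop = FALSE]
  if (nrow(a) == 0) return(list())
  key <- paste(a$resno, a$ins, sep = "|")
  split(a, factor(key, levels = unique(key)))
}

#' @keywords internal
residue_label <- function(res) {
  paste0(res$chain[1], res$resno[1], res$ins[1])
}

#' @export
print.hm_structure <- function(x, ...) {
  a <- x$atoms
  cat("<hm_structure>", x$id, "\n",
      " chains:", paste(unique(a$chain), collapse = " "), "\n",
      " atoms:", nrow(a),
      " (polymer", sum(a$kind == "polymer"),
      "/ ligand", sum(a$kind == "ligand"),
      "/ water", sum(a$kind == "water"), ")\n",
      " assemblies:", length(x$assemblies), "\n")
  invisible(x)
}

#' @export
print.hm_assembly <- function(x, ...) {
  cat("<hm_assembly>", x$source, "biounit", x$biounit_id,
      "oligomeric state", x$oligomeric_state, "\n",
      " chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Expand assembly instructions into bio-unit assemblies
#'
#' Applies each assembly instruction's transforms to its chain selection,
#' producing transformed chain copies with unique ids (a second copy of chain
#' `A` is named `A-2`, etc.). With no instructions, returns a single identity
#' assembly of the deposited coordinates. Waters and ligands are carried
#' along with their chains.
#'
#' @param s an [hm_structure()].
#' @return list of [hm_assembly()] objects.
#' @export
build_assemblies <- function(s) {
  stopifnot(inherits(s, "hm_structure"))
  if (length(s$assemblies) == 0) {
    return(list(hm_assembly(s$id, "1", s$atoms)))
  }
  lapply(s$assemblies, function(asm) {
    pieces <- list()
    copy_count <- new.env()
    for (gen in asm$gens) {
      sel <- s$atoms[s$atoms$chain %in% gen$chains, , drop = FALSE]
      if (nrow(sel) == 0) next
      for (m in gen$mats) {
        if (abs(det(m[1:3, 1:3])) < 1e-10) stop("singular assembly transform")
        piece <- sel
        piece[, c("x", "y", "z")] <- apply_transform(atom_xyz(sel), m)
        for (ch in unique(piece$chain)) {
          k <- if (is.null(copy_count[[ch]])) 1L else copy_count[[ch]] + 1L
          copy_count[[ch]] <- k
          if (k > 1L) {
            piece$chain[piece$chain == ch] <- paste0(ch, "-", k)
          }
        }
        pieces[[length(pieces) + 1]] <- piece
      }
    }
    hm_assembly(s$id, asm$id, do.call(rbind, pieces))
  })
}
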