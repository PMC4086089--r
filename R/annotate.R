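# Per-chain derived annotations: sequence extraction, Shrake-Rupley solvent
# accessibility, dihedral-based secondary structure, purification-tag
# detection, and propensity-based target-property prediction.

#' Extract the one-letter sequence of a chain
#'
#' Ligands and waters are excluded; residues with unknown three-letter codes
#' become `X`. Positions are 1-based and map bijectively onto the chain's
#' polymer residues; numbering gaps (missing residues) are recorded but not
#' padded with placeholders.
#'
#' @param x structure-like object.
#' @param chain chain id.
#' @return list with `seq` (string), `map` (data.frame: `pos`, `resno`,
#'   `ins`) and `gaps` (positions after which author numbering jumps).
#' @export
chain_sequence <- function(x, chain) {
  res <- chain_polymer_residues(x, chain)
  if (length(res) == 0) {
    stop("chain ", chain, " has no polymer residues")
  }
  resname <- vapply(res, function(r) r$resname[1], character(1))
  resno <- vapply(res, function(r) r$resno[1], integer(1))
  ins <- vapply(res, function(r) r$ins[1], character(1))
  seq1 <- aa_three_to_one(resname)
  gaps <- unname(which(diff(resno) > 1 & ins[-length(ins)] == ins[-1]))
  list(seq = paste(seq1, collapse = ""),
       map = data.frame(pos = seq_along(res), resno = resno, ins = ins,
                        stringsAsFactors = FALSE),
       gaps = gaps)
}

#' Relative solvent accessibility per residue
#'
#' Shrake-Rupley sphere sampling: each heavy atom is surrounded by `n_points`
#' quasi-uniform probe-sphere points; the accessible fraction times the
#' sphere area gives atomic SASA, summed per residue and divided by the
#' residue type's maximum reference area, clamped to `[0, 1]`. Sampling is
#' done in the structure's principal-axis frame, so values are invariant
#' under rigid motions of the input.
#'
#' @param x structure-like object (all heavy atoms occlude, waters excluded).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sphere sample points per atom (default 256).
#' @return data.frame with `chain`, `resno`, `ins`, `resname`, `rel_acc`
#'   (NA when a residue has no heavy atoms).
#' @export
solvent_accessibility <- function(x, probe = 1.4, n_points = 256) {
  atoms <- as_atoms(x)
  atoms <- atoms[atoms$kind != "water" & atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms")
  xyz <- canonical_frame(atom_xyz(atoms))
  radii <- vdw_radius(atoms$element) + probe
  pts <- sphere_points(n_points)
  n <- nrow(atoms)
  # neighbour lists via a generous distance cut (max radius sum)
  maxr <- max(radii)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < radii[i] + radii[nb]]
    sp <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        dj <- colSums((t(sp[!buried, , drop = FALSE]) - xyz[j, ])^2)
        hit <- dj < radii[j]^2
        buried[!buried][hit] <- TRUE
      }
      acc <- sum(!buried)
    }
    sasa[i] <- 4 * pi * radii[i]^2 * acc / n_points
  }
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  polymer <- atoms$kind == "polymer"
  res_keys <- unique(key[polymer])
  out <- do.call(rbind, lapply(res_keys, function(k) {
    sel <- key == k & polymer
    first <- which(sel)[1]
    total <- sum(sasa[sel])
    maxs <- MAX_SASA[atoms$resname[first]]
    rel <- if (is.na(maxs)) NA_real_ else max(0, min(1, total / maxs))
    data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
               ins = atoms$ins[first], resname = atoms$resname[first],
               sasa = total, rel_acc = rel, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Dihedral windows for the 3-state assignment (degrees).
SS_WINDOWS <- list(
  H = list(phi = c(-100, -30), psi = c(-80, -5), min_run = 4),
  E = list(phi = c(-170, -70), psi = c(70, 170), min_run = 3)
)

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' A residue is helical (`H`) when its phi/psi fall in the helical window
#' over a run of at least 4 consecutive residues, extended (`E`) for runs of
#' at least 3 in the extended window, else coil (`C`). Chain termini and
#' residues flanking chain breaks (CA-CA distance > 4.5 A) have undefined
#' dihedrals and are forced to `C`.
#'
#' @param x structure-like object.
#' @param chain chain id.
#' @param windows window definition list (see `SS_WINDOWS`).
#' @return string over `{H, E, C}`, one character per polymer residue.
#' @export
secondary_structure <- function(x, chain, windows = SS_WINDOWS) {
  res <- chain_polymer_residues(x, chain)
  n <- length(res)
  if (n == 0) stop("chain ", chain, " has no polymer residues")
  bb <- function(r, name) {
    i <- which(r$elety == name)[1]
    if (is.na(i)) return(NULL)
    c(r$x[i], r$y[i], r$z[i])
  }
  N <- lapply(res, bb, "N"); CA <- lapply(res, bb, "CA"); C <- lapply(res, bb, "C")
  connected <- function(i, j) {
    if (is.null(CA[[i]]) || is.null(CA[[j]])) return(FALSE)
    sqrt(sum((CA[[i]] - CA[[j]])^2)) < 4.5
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !is.null(C[[i - 1]]) && !is.null(N[[i]]) &&
        !is.null(CA[[i]]) && !is.null(C[[i]]) && connected(i - 1, i)) {
      phi[i] <- dihedral(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    }
    if (i < n && !is.null(N[[i]]) && !is.null(CA[[i]]) &&
        !is.null(C[[i]]) && !is.null(N[[i + 1]]) && connected(i, i + 1)) {
      psi[i] <- dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
    }
  }
  in_window <- function(v, w) !is.na(v) & v >= w[1] & v <= w[2]
  state <- rep("C", n)
  for (st in c("E", "H")) {
    w <- windows[[st]]
    ok <- in_window(phi, w$phi) & in_window(psi, w$psi)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= w$min_run) {
        state[starts[k]:ends[k]] <- st
      }
    }
  }
  paste(state, collapse = "")
}

# Motif table for purification tags: regular expressions anchored to a
# terminal margin. Shipped as data so users can extend it.
TAG_MOTIFS <- list(
  list(kind = "poly-histidine", pattern = "H{6,}", terminal_margin = 10),
  list(kind = "strep-tag", pattern = "WSHPQFEK", terminal_margin = 15),
  list(kind = "flag-tag", pattern = "DYKDDDDK", terminal_margin = 15),
  list(kind = "tandem-affinity", pattern = "EKRRWKKNFIAVSAANRFKKISSSGAL",
       terminal_margin = 40)
)

#' Detect purification tags in a sequence
#'
#' Scans for shipped tag motifs (poly-histidine runs, Strep, FLAG, TAP)
#' within a terminal margin of either sequence end. Matches in the middle of
#' the chain are ignored: genuine purification tags are terminal fusions.
#'
#' @param seq one-letter sequence string.
#' @param motifs motif table (see `TAG_MOTIFS`).
#' @return data.frame with `kind`, `start`, `end` (1-based inclusive);
#'   zero rows when nothing matches. Regions do not overlap.
#' @export
detect_tags <- function(seq, motifs = TAG_MOTIFS) {
  n <- nchar(seq)
  hits <- list()
  for (mo in motifs) {
    m <- gregexpr(mo$pattern, seq)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      start <- m[k]
      end <- start + attr(m, "match.length")[k] - 1
      near_n <- start <= mo$terminal_margin
      near_c <- (n - end) < mo$terminal_margin
      if (near_n || near_c) {
        hits[[length(hits) + 1]] <- data.frame(
          kind = mo$kind, start = start, end = end, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, -out$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  last_end <- 0
  for (i in seq_len(nrow(out))) {
    if (out$start[i] <= last_end) keep[i] <- FALSE
    else last_end <- out$end[i]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict target secondary structure and burial from sequence
#'
#' Sliding-window residue propensities (Chou-Fasman scales for the 3-state
#' secondary structure, Kyte-Doolittle hydropathy for buried/exposed). A
#' window mean helix propensity above threshold and above the strand mean
#' votes `H`, the converse votes `E`, else `C`; window-mean hydropathy above
#' 0 votes buried (`b`). Deterministic; used to score agreement with template
#' annotations when the target structure is unknown.
#'
#' @param target one-letter sequence string.
#' @param window odd window size (default 5).
#' @return list with `ss` (string over HEC) and `burial` (string over be).
#' @export
predict_target_properties <- function(target, window = 5) {
  n <- nchar(target)
  aa <- strsplit(toupper(target), "")[[1]]
  if (n < window) {
    warning("sequence shorter than the prediction window; returning all-C/all-e")
    return(list(ss = strrep("C", n), burial = strrep("e", n)))
  }
  val <- function(scale) {
    v <- scale[aa]
    v[is.na(v)] <- 1.0
    v
  }
  h <- val(CF_HELIX); e <- val(CF_STRAND)
  kd <- KYTE_DOOLITTLE[aa]; kd[is.na(kd)] <- 0
  half <- (window - 1) / 2
  smooth <- function(v) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      w <- max(1, i - half):min(n, i + half)
      out[i] <- mean(v[w])
    }
    out
  }
  hs <- smooth(h); es <- smooth(e); kds <- smooth(kd)
  ss <- ifelse(hs >= 1.05 & hs >= es, "H",
               ifelse(es >= 1.05, "E", "C"))
  burial <- ifelse(kds > 0, "b", "e")
  list(ss = paste(ss, collapse = ""), burial = paste(burial, collapse = ""))
}
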