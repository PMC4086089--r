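# Model building by coordinate transfer: backbone and side chains are copied
# from the template through the target-template alignment, short insertions
# are closed by interpolation, oligomeric copies are generated by
# superposition onto the template chains, and annotated relevant ligands are
# carried over when their coordination is conserved.

#' Transfer template backbone coordinates onto the target
#'
#' Aligned target residues receive the template's N, CA, C, O coordinates;
#' target insertions (and columns referencing template residues with missing
#' backbone atoms) stay unmodelled at this stage; template residues deleted
#' in the target are skipped.
#'
#' @param aln `hm_alignment` with the target as first sequence.
#' @param template_assembly the template entry's assembly.
#' @param template_chain the aligned chain's annotation list (fields `chain`,
#'   `seq`, `map`).
#' @return object of class `hm_model`: `atoms` (chain `A`, resno = target
#'   position), `provenance` (pos, state, src_resno), `target_seq`.
#' @export
transfer_backbone <- function(aln, template_assembly, template_chain) {
  target <- toupper(aln$a)
  n <- nchar(target)
  taa <- strsplit(target, "")[[1]]
  res <- chain_polymer_residues(template_assembly, template_chain$chain)
  res_by_pos <- stats::setNames(res, as.character(seq_along(res)))
  provenance <- data.frame(pos = seq_len(n), state = "unmodelled",
                           src_resno = NA_integer_,
                           stringsAsFactors = FALSE)
  pieces <- list()
  cols <- aln$columns
  for (k in seq_len(nrow(cols))) {
    ai <- cols$ai[k]; bi <- cols$bi[k]
    if (is.na(ai) || is.na(bi)) next
    src <- res_by_pos[[as.character(bi)]]
    bb <- src[src$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% bb$elety)) {
      warning("template residue at position ", bi,
              " lacks backbone atoms; target position ", ai, " unmodelled")
      next
    }
    bb$chain <- "A"
    bb$resno <- as.integer(ai)
    bb$ins <- ""
    bb$resname <- aa_one_to_three(taa[ai])
    bb$kind <- "polymer"
    bb$b <- 0
    pieces[[length(pieces) + 1]] <- bb
    provenance$state[ai] <- "aligned_copied"
    provenance$src_resno[ai] <- src$resno[1]
  }
  if (length(pieces) == 0) stop("no aligned residues could be modelled")
  atoms <- do.call(rbind, pieces)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = provenance,
                 target_seq = target, chains = "A",
                 template = template_assembly$source,
                 alignment = aln, ligands = list(), scores = NULL,
                 oligo = NULL),
            class = "hm_model")
}

#' @export
print.hm_model <- function(x, ...) {
  tab <- table(x$provenance$state)
  cat("<hm_model> target length", nchar(x$target_seq),
      "template", x$template, "\n ",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

# Ideal tetrahedral CB position from backbone N, CA, C.
#' @keywords internal
ideal_cb <- function(N, CA, C, bond = 1.53) {
  u1 <- vunit(N - CA); u2 <- vunit(C - CA)
  bis <- -vunit(u1 + u2)
  nrm <- vunit(vcross(u1, u2))
  # angle chosen so that N-CA-CB matches the tetrahedral 110.5 degrees
  t <- acos(min(1, -cos(110.5 * pi / 180) / sum(-bis * u1)))
  CA + bond * (cos(t) * bis + sin(t) * nrm)
}

#' Add side chains by conservation-aware transfer
#'
#' Identical target/template residues copy the template's full side chain;
#' substituted residues are truncated to an ideally placed CB (bond 1.53 A,
#' tetrahedral geometry) and marked `substituted_truncated`; glycine gets no
#' CB. Incomplete template side chains fall back to truncation.
#'
#' @param model `hm_model` from [transfer_backbone()].
#' @param template_assembly,template_chain as in [transfer_backbone()].
#' @return the model with side-chain atoms added.
#' @export
build_sidechains <- function(model, template_assembly, template_chain) {
  res <- chain_polymer_residues(template_assembly, template_chain$chain)
  taa <- strsplit(model$target_seq, "")[[1]]
  tpl_aa <- strsplit(template_chain$seq, "")[[1]]
  cols <- model$alignment$columns
  atoms <- model$atoms
  extra <- list()
  backbone <- c("N", "CA", "C", "O")
  for (k in seq_len(nrow(cols))) {
    ai <- cols$ai[k]; bi <- cols$bi[k]
    if (is.na(ai) || is.na(bi)) next
    if (model$provenance$state[ai] != "aligned_copied") next
    mine <- atoms[atoms$resno == ai & atoms$kind == "polymer", , drop = FALSE]
    get <- function(name) {
      i <- which(mine$elety == name)[1]
      c(mine$x[i], mine$y[i], mine$z[i])
    }
    src <- res[[bi]]
    side <- src[!(src$elety %in% backbone) & src$element != "H", , drop = FALSE]
    identical_res <- taa[ai] == tpl_aa[bi]
    if (taa[ai] == "G") {
      # glycine gets no CB; a substitution onto glycine is still a truncation
      if (!identical_res) model$provenance$state[ai] <- "substituted_truncated"
      next
    }
    complete <- nrow(side) > 0 && "CB" %in% side$elety
    if (identical_res && complete) {
      side$chain <- "A"; side$resno <- ai; side$ins <- ""
      side$resname <- aa_one_to_three(taa[ai]); side$kind <- "polymer"
      side$b <- 0
      extra[[length(extra) + 1]] <- side
    } else {
      if (identical_res && !complete) {
        message("template side chain incomplete at position ", bi,
                "; truncating target residue ", ai)
      }
      cb <- ideal_cb(get("N"), get("CA"), get("C"))
      extra[[length(extra) + 1]] <- atom_table(
        chain = "A", resno = ai, resname = aa_one_to_three(taa[ai]),
        elety = "CB", element = "C", x = cb[1], y = cb[2], z = cb[3],
        kind = "polymer")
      if (!identical_res) {
        model$provenance$state[ai] <- "substituted_truncated"
      }
    }
  }
  if (length(extra) > 0) {
    atoms <- rbind(atoms, do.call(rbind, extra))
    atoms <- atoms[order(atoms$resno,
                         match(atoms$elety,
                               c("N", "CA", "C", "O", "CB"),
                               nomatch = 99)), , drop = FALSE]
    rownames(atoms) <- NULL
  }
  model$atoms <- atoms
  model
}

#' Close short insertions by interpolation
#'
#' Unmodelled runs of up to `max_gap` residues flanked by modelled anchors
#' get CA positions linearly interpolated on the anchor-anchor segment with
#' idealized N/C/O placed along it; their state becomes `interpolated`.
#' Longer runs stay unmodelled and are reported as chain breaks.
#'
#' @param model an `hm_model`.
#' @param max_gap largest insertion length closed (default 3).
#' @return the model; attribute `chain_breaks` lists unclosed runs.
#' @export
close_short_gaps <- function(model, max_gap = 3) {
  prov <- model$provenance
  unm <- prov$state == "unmodelled"
  breaks <- list()
  r <- rle(unm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  taa <- strsplit(model$target_seq, "")[[1]]
  ca_of <- function(pos) {
    a <- model$atoms
    i <- which(a$resno == pos & a$elety == "CA")[1]
    if (is.na(i)) return(NULL)
    c(a$x[i], a$y[i], a$z[i])
  }
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    len <- e - s + 1
    anchored <- s > 1 && e < nrow(prov) &&
      prov$state[s - 1] != "unmodelled" && prov$state[e + 1] != "unmodelled"
    if (!anchored || len > max_gap) {
      breaks[[length(breaks) + 1]] <- c(start = s, end = e)
      next
    }
    p0 <- ca_of(s - 1); p1 <- ca_of(e + 1)
    if (is.null(p0) || is.null(p1)) {
      breaks[[length(breaks) + 1]] <- c(start = s, end = e)
      next
    }
    u <- p1 - p0
    seg <- sqrt(sum(u^2))
    dir <- if (seg > 1e-6) u / seg else c(1, 0, 0)
    perp <- vcross(dir, c(0, 0, 1))
    if (sqrt(sum(perp^2)) < 1e-6) perp <- vcross(dir, c(0, 1, 0))
    perp <- vunit(perp)
    for (q in seq_len(len)) {
      pos <- s + q - 1
      frac <- q / (len + 1)
      ca <- p0 + frac * u
      newa <- atom_table(
        chain = "A", resno = pos, resname = aa_one_to_three(taa[pos]),
        elety = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
        x = c(ca[1] - 1.2 * dir[1], ca[1], ca[1] + 1.2 * dir[1],
              ca[1] + 1.2 * dir[1] + 1.23 * perp[1]),
        y = c(ca[2] - 1.2 * dir[2], ca[2], ca[2] + 1.2 * dir[2],
              ca[2] + 1.2 * dir[2] + 1.23 * perp[2]),
        z = c(ca[3] - 1.2 * dir[3], ca[3], ca[3] + 1.2 * dir[3],
              ca[3] + 1.2 * dir[3] + 1.23 * perp[3]),
        kind = "polymer")
      model$atoms <- rbind(model$atoms, newa)
      model$provenance$state[pos] <- "interpolated"
    }
  }
  model$atoms <- model$atoms[order(model$atoms$resno), , drop = FALSE]
  rownames(model$atoms) <- NULL
  attr(model, "chain_breaks") <- breaks
  model
}

#' Expand the model to the template's oligomeric state
#'
#' When the decision is `conserved_oligomer`, the monomer is superposed
#' (Kabsch over shared CA pairs) onto every polymer chain of the template
#' assembly and one rigid copy is emitted per chain (ids `A`, `B`, ...).
#' Otherwise the single-chain model is returned unchanged apart from the
#' recorded decision. Homo-oligomeric templates are assumed to share residue
#' numbering across chains.
#'
#' @param model monomeric `hm_model`.
#' @param template_assembly the template's assembly.
#' @param decision output of [decide_oligomer()].
#' @return the model with `chains` and `atoms` expanded and `oligo` set.
#' @export
assemble_oligomer <- function(model, template_assembly, decision) {
  model$oligo <- decision
  if (!identical(decision$predicted, "conserved_oligomer")) return(model)
  chains <- polymer_chain_ids(template_assembly)
  if (length(chains) < 2) return(model)
  mono <- model$atoms[model$atoms$chain == "A", , drop = FALSE]
  prov <- model$provenance
  copied <- prov$pos[prov$state == "aligned_copied"]
  pieces <- list()
  pool <- c(LETTERS, letters)
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    res <- chain_polymer_residues(template_assembly, ch)
    resno_map <- vapply(res, function(r) r$resno[1], integer(1))
    mp <- list(); tp <- list()
    for (pos in copied) {
      src <- prov$src_resno[pos]
      ri <- which(resno_map == src)[1]
      if (is.na(ri)) next
      tr <- res[[ri]]
      tca <- which(tr$elety == "CA")[1]
      mca <- which(mono$resno == pos & mono$elety == "CA")[1]
      if (is.na(tca) || is.na(mca)) next
      mp[[length(mp) + 1]] <- c(mono$x[mca], mono$y[mca], mono$z[mca])
      tp[[length(tp) + 1]] <- c(tr$x[tca], tr$y[tca], tr$z[tca])
    }
    if (length(mp) < 3) {
      warning("fewer than 3 shared CA pairs for template chain ", ch,
              "; oligomeric copy skipped")
      next
    }
    fit <- kabsch_superpose(do.call(rbind, mp), do.call(rbind, tp))
    piece <- mono
    piece[, c("x", "y", "z")] <- apply_rigid(atom_xyz(mono), fit$rotation,
                                             fit$translation)
    piece$chain <- pool[ci]
    pieces[[length(pieces) + 1]] <- piece
  }
  if (length(pieces) == 0) return(model)
  model$atoms <- do.call(rbind, pieces)
  rownames(model$atoms) <- NULL
  model$chains <- vapply(seq_along(pieces),
                         function(i) pieces[[i]]$chain[1], character(1))
  model
}

#' Transfer annotated ligands from the template
#'
#' Only `biologically_relevant` ligands are considered (everything else is
#' rejected with reason `category_excluded`). A ligand's coordinating
#' residues are the template polymer residues with any heavy atom within
#' `coord_cutoff` of it; transfer requires every coordinating residue to be
#' aligned to an identical target residue (`coordination_not_conserved`
#' otherwise). The ligand keeps its template-frame coordinates; it is placed
#' only if no model heavy atom comes closer than `clash_cutoff`
#' (`clash`) and at least one lies within `contact_cutoff` (`no_contact`).
#'
#' @param model `hm_model` (monomer or assembled oligomer, template frame).
#' @param template_entry library entry supplying ligand annotations.
#' @param template_chain the aligned chain's annotation list.
#' @param coord_cutoff,clash_cutoff,contact_cutoff distances in Angstrom
#'   (defaults 4.0, 2.2, 4.5).
#' @return the model with `ligands` (status records) and accepted ligand
#'   atoms appended on chain `"L"`.
#' @export
transfer_ligands <- function(model, template_entry, template_chain,
                             coord_cutoff = 4.0, clash_cutoff = 2.2,
                             contact_cutoff = 4.5) {
  ann <- template_entry$ligand_annotations
  model$ligands <- list()
  if (is.null(ann) || nrow(ann) == 0) return(model)
  tatoms <- as_atoms(template_entry$assembly)
  taa <- strsplit(model$target_seq, "")[[1]]
  tpl_aa <- strsplit(template_chain$seq, "")[[1]]
  map <- template_chain$map
  cols <- model$alignment$columns
  paired <- !is.na(cols$ai) & !is.na(cols$bi)
  b2a <- stats::setNames(cols$ai[paired], cols$bi[paired])
  model_poly <- model$atoms[model$atoms$kind == "polymer" &
                              model$atoms$element != "H", , drop = FALSE]
  mxyz <- atom_xyz(model_poly)
  for (k in seq_len(nrow(ann))) {
    rec <- ann[k, ]
    lig <- tatoms[tatoms$chain == rec$chain & tatoms$resno == rec$resno &
                    tatoms$ins == rec$ins & tatoms$kind == "ligand", ,
                  drop = FALSE]
    status <- list(resname = rec$resname, chain = rec$chain,
                   resno = rec$resno, category = rec$category,
                   status = "rejected", reason = "")
    if (rec$category != "biologically_relevant") {
      status$reason <- "category_excluded"
      model$ligands[[length(model$ligands) + 1]] <- status
      next
    }
    lxyz <- atom_xyz(lig[lig$element != "H", , drop = FALSE])
    # coordinating residues: polymer residues with a heavy atom near the
    # ligand, mapped through the alignment by residue number
    poly <- tatoms[tatoms$kind == "polymer" & tatoms$element != "H", ,
                   drop = FALSE]
    pxyz <- atom_xyz(poly)
    mind <- apply(pxyz, 1, function(p) min(sqrt(colSums((t(lxyz) - p)^2))))
    near <- poly[mind <= coord_cutoff, , drop = FALSE]
    coord_resno <- unique(near$resno)
    conserved <- TRUE
    for (rn in coord_resno) {
      bpos <- map$pos[match(rn, map$resno)]
      if (is.na(bpos)) { conserved <- FALSE; break }
      apos <- b2a[as.character(bpos)]
      if (is.na(apos) || length(apos) == 0 ||
          taa[apos] != tpl_aa[bpos]) {
        conserved <- FALSE; break
      }
    }
    if (length(coord_resno) == 0) conserved <- FALSE
    if (!conserved) {
      status$reason <- "coordination_not_conserved"
      model$ligands[[length(model$ligands) + 1]] <- status
      next
    }
    dmat <- sqrt(outer(rowSums(lxyz^2), rowSums(mxyz^2), "+") -
                   2 * lxyz %*% t(mxyz))
    if (min(dmat) < clash_cutoff) {
      status$reason <- "clash"
    } else if (min(dmat) > contact_cutoff) {
      status$reason <- "no_contact"
    } else {
      status$status <- "placed"
      status$reason <- "ok"
      placed <- lig
      placed$chain <- "L"
      model$atoms <- rbind(model$atoms, placed)
    }
    model$ligands[[length(model$ligands) + 1]] <- status
  }
  rownames(model$atoms) <- NULL
  model
}

#' Build a model from one template hit
#'
#' Convenience wrapper chaining backbone transfer, side-chain building,
#' short-gap closure, the oligomeric decision (classifier-based when one is
#' supplied, otherwise interface sequence identity is used as the
#' conservation probability) and ligand transfer.
#'
#' @param hit a search hit (entry, chain, alignment, features).
#' @param lib the library the hit refers to.
#' @param classifier optional `hm_oligo_classifier`.
#' @param hits full hit list (for the interface consensus feature).
#' @param oligo_threshold decision threshold.
#' @return an `hm_model`.
#' @export
build_model <- function(hit, lib, classifier = NULL, hits = list(),
                        oligo_threshold = 0.5) {
  entry <- lib$entries[[hit$entry]]
  tc <- entry$chains[[hit$chain]]
  model <- transfer_backbone(hit$alignment, entry$assembly, tc)
  model <- build_sidechains(model, entry$assembly, tc)
  model <- close_short_gaps(model)
  interfaces <- detect_interfaces(entry$assembly)
  interfaces <- Filter(function(i) tc$chain %in% i$chains, interfaces)
  sizes <- integer(0); probs <- numeric(0)
  if (length(interfaces) > 0) {
    feats <- lapply(interfaces, function(i) {
      suppressWarnings(interface_features(i, hit$alignment, tc, lib, hits,
                                          self_entry = hit$entry))
    })
    keep <- !vapply(feats, is.null, logical(1))
    interfaces <- interfaces[keep]; feats <- feats[keep]
    if (length(interfaces) > 0) {
      sizes <- vapply(interfaces, function(i) i$size, numeric(1))
      if (!is.null(classifier)) {
        nd <- as.data.frame(do.call(rbind, feats))
        probs <- predict_conservation(classifier, nd)
      } else {
        probs <- vapply(feats, function(f) f[["identity"]], numeric(1))
      }
    }
  }
  decision <- decide_oligomer(sizes, probs, threshold = oligo_threshold)
  model <- assemble_oligomer(model, entry$assembly, decision)
  model <- transfer_ligands(model, entry, tc)
  model
}
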