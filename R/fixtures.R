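# Deterministic fixture generation: ideal-geometry toy folds, mutated and
# noised homolog pairs with known alignments and realized-similarity labels,
# homo-oligomeric complexes with designed interfaces and ligand sites, and
# end-to-end calibration benchmarks. Everything any other module needs for
# calibration and testing is generated here, without downloads.

# Run code under a seed without disturbing the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Ideal backbone geometry (Engh-Huber-like averages).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180)

FOLD_PHIPSI <- list(helix = c(-57, -47), strand = c(-119, 113),
                    loop = c(-120, 60))

# Residue pools biased to the fold element, so that sequence-based
# property prediction has genuine signal on fixtures.
FOLD_POOLS <- list(helix = c("A", "E", "L", "M", "K", "Q", "R"),
                   strand = c("V", "I", "F", "Y", "T", "C", "W"),
                   loop = c("G", "P", "S", "N", "D", "T"))

#' @keywords internal
fold_elements <- function(fold, n) {
  switch(fold,
    helix = rep("helix", n),
    strand_pair = {
      half <- floor((n - 4) / 2)
      c(rep("strand", half), rep("loop", n - 2 * half), rep("strand", half))
    },
    helix_bundle = {
      seg <- max(6, floor((n - 8) / 3))
      el <- character(0)
      while (length(el) < n) {
        el <- c(el, rep("helix", seg), rep("loop", 4))
      }
      el[seq_len(n)]
    },
    stop("unknown fold: ", fold))
}

# Build an ideal-geometry chain from per-residue phi/psi, with O and CB.
#' @keywords internal
build_backbone <- function(aa, phi, psi, chain = "A") {
  g <- BB_GEOM
  n <- length(aa)
  rows <- list()
  # seed atoms for residue 1
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C <- CA + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    res3 <- aa_one_to_three(aa[i])
    Nn <- if (i < n) place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, psi[i]) else {
      place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, 180)
    }
    O <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o, psi[i] + 180)
    atoms <- list(N = N, CA = CA, C = C, O = O)
    if (aa[i] != "G") atoms$CB <- ideal_cb(N, CA, C)
    for (an in names(atoms)) {
      p <- atoms[[an]]
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, resno = i, ins = "", resname = res3, elety = an,
        element = substr(an, 1, 1), x = p[1], y = p[2], z = p[3],
        occ = 1, b = 0, kind = "polymer", stringsAsFactors = FALSE)
    }
    if (i < n) {
      CAn <- place_atom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, g$omega)
      Cn <- place_atom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi[i + 1])
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate an ideal-geometry toy structure
#'
#' Builds a single chain with ideal backbone geometry from the fold's
#' canonical phi/psi values (helix -57/-47, strand -119/113), carbonyl
#' oxygens, and CB stubs (glycine excepted). Sequences, when not given, are
#' drawn from fold-element-biased residue pools so that propensity-based
#' prediction carries signal. Same spec + seed gives identical output.
#'
#' @param length chain length (>= 4); ignored when `sequence` is given.
#' @param fold `"helix"`, `"strand_pair"` or `"helix_bundle"`.
#' @param seed RNG seed for the sequence draw.
#' @param sequence optional explicit one-letter sequence.
#' @param id structure id stamp.
#' @return an [hm_assembly()] with one chain `A`.
#' @export
make_toy_structure <- function(length = 30, fold = "helix", seed = 1,
                               sequence = NULL, id = NULL) {
  if (!is.null(sequence)) length <- nchar(sequence)
  if (length < 4) stop("toy structures need length >= 4")
  elements <- fold_elements(fold, length)
  aa <- if (!is.null(sequence)) strsplit(toupper(sequence), "")[[1]] else {
    with_seed(seed, vapply(elements, function(el) {
      sample(FOLD_POOLS[[el]], 1)
    }, character(1)))
  }
  pp <- do.call(rbind, FOLD_PHIPSI[elements])
  atoms <- build_backbone(aa, pp[, 1], pp[, 2])
  if (is.null(id)) id <- sprintf("TOY_%s_%d_%d", fold, length, seed)
  hm_assembly(id, "1", atoms)
}

#' Convert an assembly into a structure entry
#'
#' Wraps an assembly's coordinates as a deposited structure (no assembly
#' instructions beyond the identity), ready for [add_structure()].
#'
#' @param assembly an [hm_assembly()].
#' @param id optional id override.
#' @return an [hm_structure()].
#' @export
assembly_to_structure <- function(assembly, id = NULL) {
  hm_structure(id %||% assembly$source, as_atoms(assembly))
}

#' Derive a homolog template from a structure
#'
#' Applies conservative point substitutions (drawn from high-scoring
#' exchange partners), short deletions, and Gaussian coordinate noise to a
#' copy of the input, recording the true residue-level alignment. The
#' realized-similarity label is the lDDT of the template-derived model
#' (template coordinates mapped through the true alignment) against the
#' original, i.e. exactly what a model built from this template can achieve.
#'
#' @param assembly source assembly (first polymer chain is used).
#' @param sub_rate per-residue substitution probability in [0,1].
#' @param indel_rate per-residue deletion-start probability in [0,1].
#' @param coord_noise Gaussian coordinate noise sd in Angstrom.
#' @param seed RNG seed.
#' @return list: `template` (an `hm_assembly`), `alignment`
#'   (`hm_alignment`, target = original), `label` (realized lDDT).
#' @export
make_homolog <- function(assembly, sub_rate = 0.1, indel_rate = 0.02,
                         coord_noise = 0.5, seed = 1) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  ch <- polymer_chain_ids(assembly)[1]
  atoms <- as_atoms(assembly)
  atoms <- atoms[atoms$chain == ch, , drop = FALSE]
  res <- chain_polymer_residues(atoms, ch)
  n <- length(res)
  partners <- exchange_partners()
  out <- with_seed(seed + 7L, {
    deleted <- rep(FALSE, n)
    i <- 2
    while (i < n) {  # keep both termini so anchors exist
      if (stats::runif(1) < indel_rate) {
        len <- sample(1:2, 1)
        deleted[i:min(i + len - 1, n - 1)] <- TRUE
        i <- i + len + 1
      } else i <- i + 1
    }
    new_rows <- list()
    target_seq <- vapply(res, function(r) aa_three_to_one(r$resname[1]),
                         character(1))
    template_aa <- character(0)
    ai <- integer(0); bi <- integer(0)
    bpos <- 0L
    for (k in seq_len(n)) {
      if (deleted[k]) {
        ai <- c(ai, k); bi <- c(bi, NA)  # target residue unmatched
        next
      }
      bpos <- bpos + 1L
      r <- res[[k]]
      aa_old <- aa_three_to_one(r$resname[1])
      aa_new <- aa_old
      if (aa_old %in% names(partners) && stats::runif(1) < sub_rate) {
        aa_new <- sample(partners[[aa_old]], 1)
      }
      r$resname <- aa_one_to_three(aa_new)
      if (aa_new == "G") {
        r <- r[r$elety != "CB", , drop = FALSE]
      } else if (!"CB" %in% r$elety && all(c("N", "CA", "C") %in% r$elety)) {
        gp <- function(nm) {
          j <- which(r$elety == nm)[1]; c(r$x[j], r$y[j], r$z[j])
        }
        cb <- ideal_cb(gp("N"), gp("CA"), gp("C"))
        r <- rbind(r, atom_table(chain = ch, resno = r$resno[1],
                                 resname = r$resname[1], elety = "CB",
                                 element = "C", x = cb[1], y = cb[2],
                                 z = cb[3], ins = r$ins[1], kind = "polymer"))
      }
      new_rows[[length(new_rows) + 1]] <- r
      template_aa <- c(template_aa, aa_new)
      ai <- c(ai, k); bi <- c(bi, bpos)
    }
    t_atoms <- do.call(rbind, new_rows)
    rownames(t_atoms) <- NULL
    if (coord_noise > 0) {
      t_atoms$x <- t_atoms$x + stats::rnorm(nrow(t_atoms), 0, coord_noise)
      t_atoms$y <- t_atoms$y + stats::rnorm(nrow(t_atoms), 0, coord_noise)
      t_atoms$z <- t_atoms$z + stats::rnorm(nrow(t_atoms), 0, coord_noise)
    }
    list(atoms = t_atoms,
         aln = structure(list(a = paste(target_seq, collapse = ""),
                              b = paste(template_aa, collapse = ""),
                              score = NA_real_,
                              columns = data.frame(ai = ai, bi = bi)),
                         class = "hm_alignment"))
  })
  template <- hm_assembly(paste0(assembly$source, "_H", seed), "1", out$atoms)
  # realized similarity: template coordinates transferred through the true
  # alignment and compared to the original
  cols <- out$aln$columns
  paired <- !is.na(cols$ai) & !is.na(cols$bi)
  tres <- chain_polymer_residues(out$atoms, ch)
  model_rows <- lapply(which(paired), function(k) {
    r <- tres[[cols$bi[k]]]
    r$resno <- cols$ai[k]
    r
  })
  pseudo <- do.call(rbind, model_rows)
  label <- lddt(pseudo, atoms)$global
  list(template = template, alignment = out$aln, label = label)
}

#' Generate a homo-oligomeric complex with a designed interface
#'
#' `n_chains` copies of a toy helix are arranged around the z axis at a
#' center offset chosen (deterministically) so that adjacent chains share at
#' least 5 contacting residue pairs at 5 A without steric collapse.
#' Optionally a small-molecule ligand (`LIG`) is nested against chain A so
#' that at least 3 residues coordinate it within 4 A.
#'
#' @param n_chains number of chains (>= 1).
#' @param ligand `"none"` or `"site_ligand"`.
#' @param seed RNG seed (sequence draw).
#' @param length chain length.
#' @return an [hm_assembly()]; ligand rows carry chain `"X"`.
#' @export
make_complex <- function(n_chains = 2, ligand = c("none", "site_ligand"),
                         seed = 1, length = 24) {
  ligand <- match.arg(ligand)
  stopifnot(n_chains >= 1)
  base <- make_toy_structure(length = length, fold = "helix", seed = seed,
                             id = sprintf("CPX_%d_%d", n_chains, seed))
  atoms <- as_atoms(base)
  # center the helix and align its principal axis with z so that copies
  # placed on a circle around z pack side by side
  xyz <- atom_xyz(atoms)
  ctr <- colMeans(xyz)
  xyz0 <- sweep(xyz, 2, ctr)
  ax <- svd(xyz0)$v[, 1]
  z <- c(0, 0, 1)
  cr <- vcross(ax, z)
  if (sqrt(sum(cr^2)) > 1e-8) {
    k <- vunit(cr)
    th <- acos(max(-1, min(1, sum(ax * z))))
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    xyz0 <- xyz0 %*% t(R)
  }
  atoms[, c("x", "y", "z")] <- xyz0
  pieces <- list()
  if (n_chains == 1) {
    pieces[[1]] <- atoms
  } else {
    # find a center-to-axis offset giving >= 5 contact pairs, no collapse
    for (offset in seq(12, 4, by = -0.25)) {
      pieces <- lapply(seq_len(n_chains), function(k) {
        ang <- 360 * (k - 1) / n_chains
        rot <- rotation_z(ang)
        p <- atoms
        shifted <- sweep(atom_xyz(atoms), 2, c(offset, 0, 0), "+")
        p[, c("x", "y", "z")] <- shifted %*% t(rot)
        p$chain <- c(LETTERS, letters)[k]
        p
      })
      asm <- hm_assembly(base$source, "1", do.call(rbind, pieces))
      ifs <- detect_interfaces(asm, 5.0)
      mind <- min(vapply(seq_len(n_chains - 1), function(i) {
        a <- atom_xyz(pieces[[i]]); b <- atom_xyz(pieces[[i + 1]])
        min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)))
      }, numeric(1)))
      if (length(ifs) > 0 && max(vapply(ifs, function(i) nrow(i$contacts),
                                        numeric(1))) >= 5 && mind > 2.8) {
        break
      }
    }
  }
  all_atoms <- do.call(rbind, pieces)
  if (ligand == "site_ligand") {
    # nest a two-atom ligand against one helix face of chain A: anchor on
    # the CBs of residues (mid-2, mid+1, mid+2), which share a face, then
    # slide outward until the site is clash-free but still coordinated by
    # at least 3 residues within 4 A
    first_chain <- all_atoms$chain[1]
    a <- all_atoms[all_atoms$chain == first_chain, , drop = FALSE]
    chain_ctr <- colMeans(atom_xyz(a))
    pxyz <- atom_xyz(all_atoms[all_atoms$element != "H", , drop = FALSE])
    mid <- floor(length / 2)
    placed <- NULL
    # helix faces wind by ~100 degrees per residue: scan anchor triads
    # until one faces away from the partner chains
    for (m in mid + c(0, -1, 1, -2, 2, -3, 3)) {
      face <- c(m - 2, m + 1, m + 2)
      cbs <- a[a$elety == "CB" & a$resno %in% face, , drop = FALSE]
      if (nrow(cbs) < 3) next
      cen <- colMeans(atom_xyz(cbs))
      outward <- c(cen[1] - chain_ctr[1], cen[2] - chain_ctr[2], 0)
      if (sqrt(sum(outward^2)) < 1e-6) next
      dir <- vunit(outward)
      for (t in seq(0, 3, by = 0.05)) {
        p1 <- cen + t * dir
        p2 <- p1 + 1.5 * dir
        dd <- pmin(sqrt(colSums((t(pxyz) - p1)^2)),
                   sqrt(colSums((t(pxyz) - p2)^2)))
        n_coord <- length(unique(all_atoms$resno[dd <= 4.0]))
        if (min(dd) >= 2.9 && n_coord >= 3) {
          placed <- rbind(p1, p2)
          break
        }
      }
      if (!is.null(placed)) break
    }
    if (is.null(placed)) stop("could not place a coordinated ligand site")
    lig <- atom_table(chain = "X", resno = 500, resname = "LIG",
                      elety = c("C1", "C2"), element = "C",
                      x = placed[, 1], y = placed[, 2], z = placed[, 3],
                      kind = "ligand")
    all_atoms <- rbind(all_atoms, lig)
  }
  rownames(all_atoms) <- NULL
  hm_assembly(base$source, "1", all_atoms)
}

#' Add Gaussian coordinate noise to a structure
#'
#' With `residues` given, only those residue numbers are perturbed,
#' producing decoys with locally confined errors (the regime per-residue
#' quality estimation is meant to resolve); otherwise the whole structure is
#' noised.
#'
#' @param x structure-like object.
#' @param sd noise standard deviation in Angstrom.
#' @param seed RNG seed.
#' @param residues optional residue numbers to perturb.
#' @return object of the same class with perturbed coordinates.
#' @export
perturb_structure <- function(x, sd, seed = 1, residues = NULL) {
  atoms <- as_atoms(x)
  sel <- if (is.null(residues)) rep(TRUE, nrow(atoms)) else
    atoms$resno %in% residues
  n <- sum(sel)
  with_seed(seed, {
    atoms$x[sel] <- atoms$x[sel] + stats::rnorm(n, 0, sd)
    atoms$y[sel] <- atoms$y[sel] + stats::rnorm(n, 0, sd)
    atoms$z[sel] <- atoms$z[sel] + stats::rnorm(n, 0, sd)
  })
  if (is.data.frame(x)) return(atoms)
  x$atoms <- atoms
  x
}

#' Generate a calibration benchmark
#'
#' Draws `n_pairs` target/template homolog pairs along a divergence gradient
#' that couples substitution rate, deletion rate and coordinate noise (with
#' independent lognormal jitter on each, the way sequence and structure
#' divergence co-vary in real homolog sets), computes the alignment features
#' of each pair from a fresh local alignment against the annotated template,
#' and records the realized lDDT label. Also emits a decoy battery (noised
#' copies of the targets paired with their references) for quality-weight
#' fitting.
#'
#' @param n_pairs number of target/template pairs (>= 50 for calibration).
#' @param seed RNG seed; every derived draw is seeded from it.
#' @param lengths range of target lengths.
#' @param max_sub,max_indel,max_noise divergence-gradient ceilings
#'   (substitution fraction, deletion-start fraction, noise sd in Angstrom).
#' @param n_decoys decoy pairs to emit (noise sd spread over 0.3-3 A).
#' @param sasa_points annotation SASA density.
#' @return list: `records` (features + `label` data.frame), `pairs` (list of
#'   target/template/alignment), `decoys` (list of model/reference pairs).
#' @export
make_benchmark <- function(n_pairs = 100, seed = 1, lengths = c(30, 48),
                           max_sub = 0.5, max_indel = 0.06, max_noise = 2.6,
                           n_decoys = 20, sasa_points = 48) {
  stopifnot(n_pairs >= 1)
  seed <- as.integer(seed %% 1000000L)  # derived seeds stay below 2^31
  params <- with_seed(seed, {
    data.frame(
      len = sample(seq(lengths[1], lengths[2]), n_pairs, replace = TRUE),
      fold = sample(c("helix", "helix_bundle", "strand_pair"), n_pairs,
                    replace = TRUE, prob = c(0.3, 0.5, 0.2)),
      d = stats::runif(n_pairs, 0.05, 0.95),
      j1 = exp(stats::rnorm(n_pairs, 0, 0.35)),
      j2 = exp(stats::rnorm(n_pairs, 0, 0.35)),
      j3 = exp(stats::rnorm(n_pairs, 0, 0.35)),
      stringsAsFactors = FALSE)
  })
  records <- list(); pairs <- list()
  for (k in seq_len(n_pairs)) {
    p <- params[k, ]
    target <- make_toy_structure(length = p$len, fold = p$fold,
                                 seed = seed * 1000 + k)
    hom <- make_homolog(target,
                        sub_rate = min(1, max_sub * p$d * p$j1),
                        indel_rate = min(1, max_indel * p$d * p$j2),
                        coord_noise = max_noise * p$d * p$j3,
                        seed = seed * 1000 + k)
    tseq <- chain_sequence(target, "A")$seq
    tpl_ch <- list(chain = "A",
                   seq = chain_sequence(hom$template, "A")$seq,
                   map = chain_sequence(hom$template, "A")$map,
                   ss = secondary_structure(hom$template, "A"),
                   rel_acc = solvent_accessibility(
                     hom$template, n_points = sasa_points)$rel_acc)
    aln <- local_align(tseq, tpl_ch$seq)
    feats <- if (nrow(aln$columns) > 0 &&
                 any(!is.na(aln$columns$ai) & !is.na(aln$columns$bi))) {
      alignment_features(aln, tpl_ch, predict_target_properties(tseq))
    } else {
      c(seq_identity = 0, seq_similarity = 0, norm_score = 0,
        ss_agreement = 0, acc_agreement = 0, coverage = 0)
    }
    records[[k]] <- c(feats, label = hom$label)
    pairs[[k]] <- list(target = target, template = hom$template,
                       alignment = hom$alignment, label = hom$label)
  }
  decoys <- lapply(seq_len(n_decoys), function(k) {
    ref <- pairs[[((k - 1) %% n_pairs) + 1]]$target
    sdv <- 0.3 + (k - 1) / max(1, n_decoys - 1) * 2.7
    # alternate globally and locally perturbed decoys: local errors are
    # what the windowed per-residue score must resolve
    residues <- if (k %% 2 == 0) NULL else with_seed(seed * 31 + k, {
      nres <- max(as_atoms(ref)$resno)
      len <- max(5, round(nres * 0.45))
      start <- sample(seq_len(nres - len + 1), 1)
      seq(start, start + len - 1)
    })
    list(model = perturb_structure(ref, sdv, seed = seed * 77 + k,
                                   residues = residues),
         reference = ref, noise = sdv, perturbed_residues = residues)
  })
  list(records = as.data.frame(do.call(rbind, records)),
       pairs = pairs, decoys = decoys)
}

#' Synthetic interface-conservation training table
#'
#' Feature rows (identity, similarity, hydrophobicity, consensus) with
#' labels drawn from a monotone logistic link on identity and consensus;
#' `margin > 0` removes rows near the decision boundary, giving a cleanly
#' separable table.
#'
#' @param n rows.
#' @param seed RNG seed.
#' @param margin half-width of an excluded identity band around 0.5.
#' @param deterministic if TRUE the label is exactly `identity > 0.5`.
#' @return data.frame with the four features and `conserved`.
#' @export
make_interface_table <- function(n = 500, seed = 1, margin = 0,
                                 deterministic = FALSE) {
  with_seed(seed, {
    identity <- stats::runif(n)
    if (margin > 0) {
      out <- abs(identity - 0.5) < margin
      identity[out] <- 0.5 + sign(identity[out] - 0.5 + 1e-9) *
        (margin + stats::runif(sum(out)) * (0.5 - margin))
    }
    similarity <- pmin(1, identity + stats::runif(n, 0, 0.3))
    hydrophobicity <- stats::runif(n, -2.5, 3.5)
    consensus <- stats::runif(n)
    p <- stats::plogis(8 * (identity - 0.5) + 2 * (consensus - 0.5))
    conserved <- if (deterministic) as.integer(identity > 0.5) else
      as.integer(stats::runif(n) < p)
    out <- data.frame(identity = identity, similarity = similarity,
                      hydrophobicity = hydrophobicity, consensus = consensus,
                      conserved = conserved)
    attr(out, "true_p") <- p  # kept out of the feature columns
    out
  })
}
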