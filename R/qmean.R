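# Statistical potentials of mean force and composite model quality scores:
# an inverse-Boltzmann -log odds score per structural feature (CB-CB
# distances, phi/psi torsions, burial), windowed per-residue reliability
# scores mapped to [0,1], a global mean score, and a Z-score against a
# reference battery of well-formed structures.

DIST_EDGES <- seq(0, 20, by = 0.5)
TORSION_BIN_DEG <- 30
BURIAL_EDGES <- seq(0, 1, by = 0.1)

# -log((obs + 1)/(rows + B)) relative to a reference distribution with the
# same pseudocount convention; uniform counts give exactly zero everywhere.
#' @keywords internal
potential_from_counts <- function(counts, reference_counts = NULL) {
  counts <- as.matrix(counts)
  B <- ncol(counts)
  p_obs <- (counts + 1) / (rowSums(counts) + B)
  if (is.null(reference_counts)) {
    ref <- rep(1 / B, B)
  } else {
    ref <- (reference_counts + 1) / (sum(reference_counts) + B)
  }
  -log(sweep(p_obs, 2, ref, "/"))
}

# Interaction centre per residue: CB, or CA for glycine.
#' @keywords internal
interaction_centres <- function(atoms) {
  atoms <- atoms[atoms$kind == "polymer", , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  res_keys <- unique(key)
  rows <- lapply(res_keys, function(k) {
    r <- atoms[key == k, , drop = FALSE]
    name <- if (r$resname[1] == "GLY") "CA" else "CB"
    i <- which(r$elety == name)[1]
    if (is.na(i)) i <- which(r$elety == "CA")[1]
    if (is.na(i)) return(NULL)
    data.frame(chain = r$chain[1], resno = r$resno[1], ins = r$ins[1],
               resname = r$resname[1], aa = aa_three_to_one(r$resname[1]),
               x = r$x[i], y = r$y[i], z = r$z[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' @keywords internal
pair_type <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}

#' @keywords internal
backbone_dihedrals <- function(x, chain) {
  res <- chain_polymer_residues(x, chain)
  n <- length(res)
  bb <- function(r, name) {
    i <- which(r$elety == name)[1]
    if (is.na(i)) return(NULL)
    c(r$x[i], r$y[i], r$z[i])
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  aa <- vapply(res, function(r) aa_three_to_one(r$resname[1]), character(1))
  resno <- vapply(res, function(r) r$resno[1], integer(1))
  # continuity follows residue numbering, not geometry: a distorted peptide
  # bond still has torsions (and they should score badly), whereas a
  # numbering gap is a genuine chain break
  for (i in seq_len(n)) {
    Ni <- bb(res[[i]], "N"); CAi <- bb(res[[i]], "CA"); Ci <- bb(res[[i]], "C")
    if (i > 1 && resno[i] - resno[i - 1] == 1) {
      Cp <- bb(res[[i - 1]], "C")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
        phi[i] <- dihedral(Cp, Ni, CAi, Ci)
      }
    }
    if (i < n && resno[i + 1] - resno[i] == 1) {
      Nn <- bb(res[[i + 1]], "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn)) {
        psi[i] <- dihedral(Ni, CAi, Ci, Nn)
      }
    }
  }
  data.frame(aa = aa, phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' @keywords internal
torsion_bin <- function(phi, psi, width = TORSION_BIN_DEG) {
  nb <- 360 / width
  # quotients are rounded before flooring so that values sitting exactly on
  # a bin edge cannot flip bins under 1e-13-level rigid-motion jitter
  pb <- pmin(floor(round((phi + 180) / width, 9)) + 1, nb)
  sb <- pmin(floor(round((psi + 180) / width, 9)) + 1, nb)
  (pb - 1) * nb + sb
}

#' Train a potential of mean force
#'
#' Counts feature occurrences over a training set of structures and converts
#' them to -log odds scores against a reference state with pseudocount 1 per
#' bin (no empty-bin infinities). Kinds: `distance` (CB-CB, CA for glycine,
#' sequence separation >= 3, 0.5 A bins on 0-20 A, binned by unordered
#' residue-type pair, type-agnostic reference), `torsion` (30-degree phi/psi
#' bins per residue type, uniform reference), `burial` (relative-accessibility
#' bins of 0.1 per residue type, type-agnostic reference).
#'
#' @param training list of structure-like objects (assemblies).
#' @param kind `"distance"`, `"torsion"` or `"burial"`.
#' @param min_structures guard on training-set size (default 20).
#' @param sasa_points SASA sampling density for the burial kind.
#' @return object of class `hm_potential`: `kind`, `scores` (type x bin
#'   matrix), bin metadata, training metadata.
#' @export
train_potential <- function(training, kind = c("distance", "torsion", "burial"),
                            min_structures = 20, sasa_points = 64) {
  kind <- match.arg(kind)
  if (length(training) < min_structures) {
    stop("need at least ", min_structures, " training structures")
  }
  if (kind == "distance") {
    B <- length(DIST_EDGES) - 1
    types <- pair_type(rep(AA1, each = 20), rep(AA1, 20))
    types <- sort(unique(types))
    counts <- matrix(0, length(types), B, dimnames = list(types, NULL))
    for (s in training) {
      cen <- interaction_centres(as_atoms(s))
      for (ch in unique(cen$chain)) {
        cc <- cen[cen$chain == ch, , drop = FALSE]
        n <- nrow(cc)
        if (n < 4) next
        xyz <- as.matrix(cc[, c("x", "y", "z")])
        for (i in seq_len(n - 3)) {
          for (j in (i + 3):n) {
            d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
            if (d >= 20) next
            b <- min(floor(round(d / 0.5, 9)) + 1, B)
            pt <- pair_type(cc$aa[i], cc$aa[j])
            if (pt %in% types) counts[pt, b] <- counts[pt, b] + 1
          }
        }
      }
    }
    scores <- potential_from_counts(counts, colSums(counts))
    pot <- list(kind = kind, scores = scores, edges = DIST_EDGES,
                types = types)
  } else if (kind == "torsion") {
    nb <- (360 / TORSION_BIN_DEG)^2
    counts <- matrix(0, 20, nb, dimnames = list(AA1, NULL))
    for (s in training) {
      for (ch in polymer_chain_ids(s)) {
        dh <- backbone_dihedrals(s, ch)
        ok <- !is.na(dh$phi) & !is.na(dh$psi) & dh$aa %in% AA1
        if (!any(ok)) next
        bins <- torsion_bin(dh$phi[ok], dh$psi[ok])
        for (k in which(ok)) {
          counts[dh$aa[k], torsion_bin(dh$phi[k], dh$psi[k])] <-
            counts[dh$aa[k], torsion_bin(dh$phi[k], dh$psi[k])] + 1
        }
      }
    }
    scores <- potential_from_counts(counts, NULL)
    pot <- list(kind = kind, scores = scores, bin_deg = TORSION_BIN_DEG,
                types = AA1)
  } else {
    B <- length(BURIAL_EDGES) - 1
    counts <- matrix(0, 20, B, dimnames = list(AA1, NULL))
    for (s in training) {
      acc <- solvent_accessibility(s, n_points = sasa_points)
      aa <- aa_three_to_one(acc$resname)
      ok <- !is.na(acc$rel_acc) & aa %in% AA1
      b <- pmin(floor(round(acc$rel_acc[ok] / 0.1, 9)) + 1, B)
      for (k in seq_along(b)) {
        counts[aa[ok][k], b[k]] <- counts[aa[ok][k], b[k]] + 1
      }
    }
    scores <- potential_from_counts(counts, colSums(counts))
    pot <- list(kind = kind, scores = scores, edges = BURIAL_EDGES,
                types = AA1)
  }
  pot$n_training <- length(training)
  structure(pot, class = "hm_potential")
}

# Per-residue raw pseudo-energy terms of a model under trained potentials.
#' @keywords internal
raw_terms <- function(x, potentials, sasa_points = 64) {
  atoms <- as_atoms(x)
  atoms <- atoms[atoms$kind == "polymer", , drop = FALSE]
  cen <- interaction_centres(atoms)
  n <- nrow(cen)
  terms <- data.frame(chain = cen$chain, resno = cen$resno, ins = cen$ins,
                      distance = NA_real_, torsion = NA_real_,
                      burial = NA_real_, stringsAsFactors = FALSE)
  pot <- function(kind) {
    for (p in potentials) if (p$kind == kind) return(p)
    NULL
  }
  pd <- pot("distance")
  if (!is.null(pd)) {
    xyz <- as.matrix(cen[, c("x", "y", "z")])
    B <- length(pd$edges) - 1
    acc_sum <- numeric(n); acc_n <- integer(0)
    cnt <- integer(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        same_chain <- cen$chain[i] == cen$chain[j]
        sep <- abs(cen$resno[i] - cen$resno[j])
        if (same_chain && sep < 3) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d >= max(pd$edges)) next
        b <- min(floor(round(d / 0.5, 9)) + 1, B)
        sc <- pd$scores[pair_type(cen$aa[i], cen$aa[j]), b]
        acc_sum[i] <- acc_sum[i] + sc; cnt[i] <- cnt[i] + 1
        acc_sum[j] <- acc_sum[j] + sc; cnt[j] <- cnt[j] + 1
      }
    }
    terms$distance <- ifelse(cnt > 0, acc_sum / pmax(cnt, 1), NA)
  }
  pt <- pot("torsion")
  if (!is.null(pt)) {
    for (ch in unique(cen$chain)) {
      dh <- backbone_dihedrals(x, ch)
      res <- chain_polymer_residues(x, ch)
      resno <- vapply(res, function(r) r$resno[1], integer(1))
      ins <- vapply(res, function(r) r$ins[1], character(1))
      ok <- !is.na(dh$phi) & !is.na(dh$psi) & dh$aa %in% AA1
      for (k in which(ok)) {
        row <- which(terms$chain == ch & terms$resno == resno[k] &
                       terms$ins == ins[k])
        if (length(row) == 1) {
          terms$torsion[row] <- pt$scores[dh$aa[k],
                                          torsion_bin(dh$phi[k], dh$psi[k])]
        }
      }
    }
  }
  pb <- pot("burial")
  if (!is.null(pb)) {
    acc <- solvent_accessibility(x, n_points = sasa_points)
    aa <- aa_three_to_one(acc$resname)
    B <- length(pb$edges) - 1
    for (k in seq_len(nrow(acc))) {
      if (is.na(acc$rel_acc[k]) || !(aa[k] %in% AA1)) next
      row <- which(terms$chain == acc$chain[k] & terms$resno == acc$resno[k] &
                     terms$ins == acc$ins[k])
      if (length(row) == 1) {
        b <- min(floor(round(acc$rel_acc[k] / 0.1, 9)) + 1, B)
        terms$burial[row] <- pb$scores[aa[k], b]
      }
    }
  }
  terms
}

#' Per-residue reliability scores
#'
#' Raw pseudo-energy terms are averaged over a centred sliding window
#' (truncated at chain termini) and combined through a logistic into a
#' reliability score in [0,1]; higher means more native-like. Unmodelled
#' residues receive no score.
#'
#' @param model structure-like object (typically an `hm_model`).
#' @param potentials list of trained `hm_potential` objects.
#' @param weights c(intercept, distance, torsion, burial); the energy terms
#'   enter negatively under the defaults so that low energy maps to high
#'   reliability.
#' @param window odd window size (default 9).
#' @param sasa_points SASA sampling density.
#' @return data.frame with per-residue `chain`, `resno`, raw terms, windowed
#'   terms and `score` in [0,1]; class `hm_profile`.
#' @export
score_local <- function(model, potentials,
                        weights = c(0, -1, -1, -1), window = 9,
                        sasa_points = 64) {
  terms <- raw_terms(model, potentials, sasa_points = sasa_points)
  if (nrow(terms) == 0) stop("no modelled residues to score")
  if (nrow(terms) < window) {
    warning("fewer residues than the smoothing window; window truncated")
  }
  half <- (window - 1) / 2
  smooth <- function(v, chain) {
    out <- rep(NA_real_, length(v))
    for (ch in unique(chain)) {
      idx <- which(chain == ch)
      for (ii in seq_along(idx)) {
        w <- idx[max(1, ii - half):min(length(idx), ii + half)]
        vals <- v[w]
        out[idx[ii]] <- if (all(is.na(vals))) NA else mean(vals, na.rm = TRUE)
      }
    }
    out
  }
  sm <- terms
  for (cn in c("distance", "torsion", "burial")) {
    sm[[paste0(cn, "_w")]] <- smooth(terms[[cn]], terms$chain)
  }
  lin <- rep(weights[1], nrow(sm))
  for (k in seq_along(c("distance", "torsion", "burial"))) {
    cn <- c("distance", "torsion", "burial")[k]
    v <- sm[[paste0(cn, "_w")]]
    v[is.na(v)] <- 0
    lin <- lin + weights[k + 1] * v
  }
  sm$score <- stats::plogis(lin)
  class(sm) <- c("hm_profile", class(sm))
  sm
}

#' Global quality score
#'
#' @param profile an `hm_profile` from [score_local()].
#' @return arithmetic mean of the per-residue reliability scores.
#' @export
score_global <- function(profile) {
  s <- profile$score[!is.na(profile$score)]
  if (length(s) == 0) stop("empty score profile")
  mean(s)
}

#' Z-score against a reference score set
#'
#' Relates a model's global score to the score distribution of a battery of
#' well-formed reference structures (population standard deviation, so the
#' reference members themselves standardize to mean 0, sd 1).
#'
#' @param global global score of the model.
#' @param reference numeric vector of reference global scores (length >= 2).
#' @return the Z-score.
#' @export
z_score <- function(global, reference) {
  if (length(reference) < 2) stop("reference set needs at least 2 members")
  m <- mean(reference)
  s <- sqrt(mean((reference - m)^2))
  if (s <= 0) stop("reference scores have zero spread; enlarge the set")
  (global - m) / s
}

#' Fit combination weights for the local score
#'
#' Logistic regression of a good/bad residue indicator (true per-residue
#' lDDT >= `lddt_cut`) on the windowed raw terms of decoy models.
#'
#' @param terms data.frame with columns `distance_w`, `torsion_w`,
#'   `burial_w` (windowed raw terms per residue).
#' @param lddt numeric true per-residue lDDT, same length.
#' @param lddt_cut reliability cutoff (default 0.6).
#' @return weight vector c(intercept, distance, torsion, burial).
#' @export
fit_weights_from_terms <- function(terms, lddt, lddt_cut = 0.6) {
  stopifnot(nrow(terms) == length(lddt))
  keep <- stats::complete.cases(terms[, c("distance_w", "torsion_w",
                                          "burial_w")]) & !is.na(lddt)
  d <- terms[keep, ]; y <- as.integer(lddt[keep] >= lddt_cut)
  if (sum(keep) < 100) stop("need at least 100 residue observations")
  if (length(unique(y)) < 2) {
    stop("labels are single-class; cannot fit weights")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ distance_w + torsion_w + burial_w, data = d,
               family = stats::binomial()))
  w <- unname(stats::coef(fit))
  w[is.na(w)] <- 0
  w
}

#' Fit local-score weights on decoy models
#'
#' @param models list of structure-like decoy models.
#' @param references list of matching reference structures.
#' @param potentials trained potentials.
#' @param window smoothing window.
#' @param ... passed to [fit_weights_from_terms()].
#' @return weight vector c(intercept, distance, torsion, burial).
#' @export
fit_weights <- function(models, references, potentials, window = 9, ...) {
  stopifnot(length(models) == length(references))
  rows <- list(); labels <- numeric(0)
  for (k in seq_along(models)) {
    prof <- score_local(models[[k]], potentials, window = window)
    ld <- lddt(models[[k]], references[[k]])
    key_p <- paste(prof$chain, prof$resno)
    key_l <- paste(ld$per_residue$chain, ld$per_residue$resno)
    m <- match(key_p, key_l)
    rows[[k]] <- prof
    labels <- c(labels, ld$per_residue$lddt[m])
  }
  fit_weights_from_terms(do.call(rbind, rows), labels, ...)
}
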