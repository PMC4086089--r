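# Superposition-free model evaluation: the local Distance Difference Test.
# The assessed set is every reference heavy-atom pair from different
# residues within the inclusion radius; a distance is preserved at a
# threshold when the model reproduces it within that tolerance. Missing
# model atoms count as violations.

#' Local Distance Difference Test
#'
#' Computes per-residue and global fractions of preserved reference
#' interatomic distances, averaged over the tolerance thresholds. The score
#' needs no superposition and is invariant under rigid motions of either
#' structure. Residues are matched by (chain, residue number, insertion
#' code); when the two structures share no chain ids, chains are matched by
#' order of appearance.
#'
#' @param model structure-like object to assess.
#' @param reference structure-like reference.
#' @param radius inclusion radius in Angstrom (default 15).
#' @param thresholds tolerance thresholds in Angstrom (default 0.5, 1, 2, 4).
#' @return list of class `hm_lddt`: `global`, `per_residue` (data.frame
#'   `chain`, `resno`, `ins`, `lddt`, `n_distances`), `radius`, `thresholds`.
#' @export
lddt <- function(model, reference, radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  ref <- as_atoms(reference)
  mod <- as_atoms(model)
  ref <- ref[ref$kind == "polymer" & ref$element != "H", , drop = FALSE]
  mod <- mod[mod$kind == "polymer" & mod$element != "H", , drop = FALSE]
  if (nrow(ref) == 0 || nrow(mod) == 0) {
    stop("no polymer heavy atoms to compare")
  }
  ref_chains <- unique(ref$chain)
  mod_chains <- unique(mod$chain)
  if (length(intersect(ref_chains, mod_chains)) == 0) {
    if (length(ref_chains) != length(mod_chains)) {
      stop("no residue correspondence: chain ids disjoint and chain counts differ")
    }
    mod$chain <- ref_chains[match(mod$chain, mod_chains)]
  }
  rkey <- paste(ref$chain, ref$resno, ref$ins, ref$elety, sep = "|")
  mkey <- paste(mod$chain, mod$resno, mod$ins, mod$elety, sep = "|")
  m_at <- match(rkey, mkey)
  rxyz <- atom_xyz(ref)
  n <- nrow(ref)
  d2 <- outer(rowSums(rxyz^2), rowSums(rxyz^2), "+") - 2 * rxyz %*% t(rxyz)
  d2[d2 < 0] <- 0
  res_id <- paste(ref$chain, ref$resno, ref$ins, sep = "|")
  same_res <- outer(res_id, res_id, "==")
  upper <- upper.tri(d2)
  sel <- upper & !same_res & d2 <= radius^2
  pair_idx <- which(sel, arr.ind = TRUE)
  if (nrow(pair_idx) == 0) stop("no assessable distances within the radius")
  dref <- sqrt(d2[sel])
  i1 <- pair_idx[, 1]; i2 <- pair_idx[, 2]
  mi1 <- m_at[i1]; mi2 <- m_at[i2]
  have <- !is.na(mi1) & !is.na(mi2)
  dmod <- rep(NA_real_, length(dref))
  if (any(have)) {
    mxyz <- atom_xyz(mod)
    dmod[have] <- sqrt(rowSums((mxyz[mi1[have], , drop = FALSE] -
                                  mxyz[mi2[have], , drop = FALSE])^2))
  }
  # preserved-count per pair, summed over thresholds; missing atoms score 0
  pres <- rep(0L, length(dref))
  diffd <- abs(dmod - dref)
  for (t in thresholds) {
    pres <- pres + ifelse(!is.na(diffd) & diffd < t, 1L, 0L)
  }
  nt <- length(thresholds)
  global <- sum(pres) / (length(dref) * nt)
  res_levels <- unique(res_id)
  acc <- stats::setNames(rep(0, length(res_levels)), res_levels)
  cnt <- stats::setNames(rep(0, length(res_levels)), res_levels)
  r1 <- res_id[i1]; r2 <- res_id[i2]
  for (k in seq_along(dref)) {
    acc[r1[k]] <- acc[r1[k]] + pres[k]; cnt[r1[k]] <- cnt[r1[k]] + nt
    acc[r2[k]] <- acc[r2[k]] + pres[k]; cnt[r2[k]] <- cnt[r2[k]] + nt
  }
  first <- match(res_levels, res_id)
  per_residue <- data.frame(
    chain = ref$chain[first], resno = ref$resno[first], ins = ref$ins[first],
    lddt = ifelse(cnt > 0, acc / cnt, NA),
    n_distances = as.integer(cnt / nt),
    stringsAsFactors = FALSE)
  rownames(per_residue) <- NULL
  structure(list(global = global, per_residue = per_residue,
                 radius = radius, thresholds = thresholds),
            class = "hm_lddt")
}

#' @export
print.hm_lddt <- function(x, ...) {
  cat("<hm_lddt> global", sprintf("%.4f", x$global), "over",
      sum(x$per_residue$n_distances) / 2, "distances,",
      nrow(x$per_residue), "residues\n")
  invisible(x)
}
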