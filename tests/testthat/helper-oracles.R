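# Independent brute-force oracles and small shared fixtures. These stay
# deliberately naive: enumeration and direct counting, no shared code paths
# with the implementation they check.

# Exhaustive affine-gap local alignment score: every local alignment is a
# pair of strictly increasing index sequences of equal length k (the aligned
# columns); internal unaligned stretches are charged as affine gaps. All
# such pairs are enumerated, which is feasible for lengths <= 6.
brute_force_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  gap_cost <- function(len) if (len > 0) gap_open + gap_extend * len else 0
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k)
    ib <- utils::combn(m, k)
    for (ci in seq_len(ncol(ia))) {
      for (cj in seq_len(ncol(ib))) {
        i <- ia[, ci]; j <- ib[, cj]
        score <- sum(mat[cbind(sa[i], sb[j])])
        if (k > 1) {
          score <- score - sum(vapply(diff(i) - 1, gap_cost, numeric(1))) -
            sum(vapply(diff(j) - 1, gap_cost, numeric(1)))
        }
        if (score > best) best <- score
      }
    }
  }
  best
}

# Direct lDDT recomputation by explicit loops over atom pairs.
brute_force_lddt <- function(model, reference, radius = 15,
                             thresholds = c(0.5, 1, 2, 4)) {
  ref <- as_atoms(reference)
  mod <- as_atoms(model)
  ref <- ref[ref$kind == "polymer" & ref$element != "H", , drop = FALSE]
  mod <- mod[mod$kind == "polymer" & mod$element != "H", , drop = FALSE]
  mkey <- paste(mod$chain, mod$resno, mod$ins, mod$elety)
  rkey <- paste(ref$chain, ref$resno, ref$ins, ref$elety)
  res_of <- paste(ref$chain, ref$resno, ref$ins)
  residues <- unique(res_of)
  acc <- setNames(rep(0, length(residues)), residues)
  cnt <- setNames(rep(0, length(residues)), residues)
  tot_p <- 0; tot_n <- 0
  n <- nrow(ref)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (res_of[i] == res_of[j]) next
      dref <- sqrt(sum((c(ref$x[i], ref$y[i], ref$z[i]) -
                          c(ref$x[j], ref$y[j], ref$z[j]))^2))
      if (dref > radius) next
      mi <- match(rkey[i], mkey); mj <- match(rkey[j], mkey)
      for (t in thresholds) {
        ok <- FALSE
        if (!is.na(mi) && !is.na(mj)) {
          dmod <- sqrt(sum((c(mod$x[mi], mod$y[mi], mod$z[mi]) -
                              c(mod$x[mj], mod$y[mj], mod$z[mj]))^2))
          ok <- abs(dmod - dref) < t
        }
        tot_p <- tot_p + ok; tot_n <- tot_n + 1
        acc[res_of[i]] <- acc[res_of[i]] + ok
        cnt[res_of[i]] <- cnt[res_of[i]] + 1
        acc[res_of[j]] <- acc[res_of[j]] + ok
        cnt[res_of[j]] <- cnt[res_of[j]] + 1
      }
    }
  }
  list(global = tot_p / tot_n, per_residue = acc / cnt)
}

# Random proper rotation matrix.
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigidly_move <- function(x, rotation = random_rotation(),
                         translation = stats::runif(3, -25, 25)) {
  atoms <- as_atoms(x)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(rotation), 2, translation, "+")
  if (is.data.frame(x)) return(atoms)
  x$atoms <- atoms
  x
}

# Shared small training set for potentials (built once per test run).
toy_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(1:20, function(k) {
        make_toy_structure(length = 28 + k %% 10,
                           fold = c("helix", "helix_bundle",
                                    "strand_pair")[k %% 3 + 1],
                           seed = 100 + k)
      })
    }
    cache
  }
})

toy_potentials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- toy_training_set()
      cache <<- list(train_potential(tr, "distance"),
                     train_potential(tr, "torsion"),
                     train_potential(tr, "burial"))
    }
    cache
  }
})
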