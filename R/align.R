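# Local sequence alignment and template search. A single affine-gap
# Smith-Waterman aligner with deterministic traceback stands behind the
# search; alignment-derived features are the inputs to GMQE ranking.

#' Affine-gap Smith-Waterman local alignment
#'
#' Optimal local alignment under an affine gap model (opening a gap costs
#' `gap_open + gap_extend`, each further gapped column `gap_extend`).
#' Traceback is deterministic: on score ties the diagonal move wins over the
#' vertical (gap in `b`), which wins over the horizontal; among equal cell
#' scores the traceback starts from the first-encountered maximum
#' (row-major). Positions are 1-based.
#'
#' @param a,b sequences (one-letter strings) over the 20 amino acids plus X.
#' @param mat substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalties (defaults 11 and 1).
#' @return object of class `hm_alignment`: list with `a`, `b`, `score`, and
#'   `columns`, a data.frame with `ai`/`bi` (index or NA for a gap).
#' @export
local_align <- function(a, b, mat = substitution_matrix(),
                        gap_open = 11, gap_extend = 1) {
  sa <- strsplit(toupper(a), "")[[1]]
  sb <- strsplit(toupper(b), "")[[1]]
  if (length(sa) == 0 || length(sb) == 0) stop("empty sequence")
  alphabet <- rownames(mat)
  bad <- which(!(sa %in% alphabet))
  if (length(bad) > 0) stop("invalid character '", sa[bad[1]],
                            "' at position ", bad[1], " of first sequence")
  bad <- which(!(sb %in% alphabet))
  if (length(bad) > 0) stop("invalid character '", sb[bad[1]],
                            "' at position ", bad[1], " of second sequence")
  n <- length(sa); m <- length(sb)
  sub <- mat[sa, sb, drop = FALSE]
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)    # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best_prev <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- best_prev + sub[i, j]
      if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- 0
    }
  }
  score <- max(M)
  cols <- data.frame(ai = integer(0), bi = integer(0))
  if (score > 0) {
    hit <- which(t(M) == score, arr.ind = FALSE)[1]  # row-major first max
    j <- (hit - 1) %% (m + 1) + 1
    i <- (hit - 1) %/% (m + 1) + 1
    ai <- integer(0); bi <- integer(0)
    state <- "M"
    while (i > 1 && j > 1) {
      if (state == "M") {
        if (M[i, j] <= 0) break
        ai <- c(i - 1, ai); bi <- c(j - 1, bi)
        prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
        pick <- which.max(prev)  # ties: M > X > Y > stop
        i <- i - 1; j <- j - 1
        state <- c("M", "X", "Y", "stop")[pick]
        if (state == "stop") break
      } else if (state == "X") {
        ai <- c(i - 1, ai); bi <- c(NA, bi)
        from_open <- M[i - 1, j] - gap_open - gap_extend
        state <- if (X[i, j] == from_open) "M" else "X"
        i <- i - 1
      } else {
        ai <- c(NA, ai); bi <- c(j - 1, bi)
        from_open <- M[i, j - 1] - gap_open - gap_extend
        state <- if (Y[i, j] == from_open) "M" else "Y"
        j <- j - 1
      }
    }
    cols <- data.frame(ai = as.integer(ai), bi = as.integer(bi))
  }
  structure(list(a = a, b = b, score = score, columns = cols),
            class = "hm_alignment")
}

#' @export
print.hm_alignment <- function(x, ...) {
  cat("<hm_alignment> score", x$score, "over", nrow(x$columns), "columns\n")
  sa <- strsplit(x$a, "")[[1]]; sb <- strsplit(x$b, "")[[1]]
  la <- paste(ifelse(is.na(x$columns$ai), "-", sa[x$columns$ai]), collapse = "")
  lb <- paste(ifelse(is.na(x$columns$bi), "-", sb[x$columns$bi]), collapse = "")
  cat(" ", la, "\n ", lb, "\n")
  invisible(x)
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param aln an `hm_alignment`.
#' @param path output path.
#' @param names sequence names (length 2).
#' @export
write_alignment_fasta <- function(aln, path, names = c("target", "template")) {
  sa <- strsplit(aln$a, "")[[1]]; sb <- strsplit(aln$b, "")[[1]]
  la <- paste(ifelse(is.na(aln$columns$ai), "-", sa[aln$columns$ai]),
              collapse = "")
  lb <- paste(ifelse(is.na(aln$columns$bi), "-", sb[aln$columns$bi]),
              collapse = "")
  writeLines(c(paste0(">", names[1]), la, paste0(">", names[2]), lb), path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}

#' Read an aligned-FASTA target-template alignment
#'
#' The first record is taken as the target, the second as the template; gap
#' characters `-` or `.` mark unaligned columns.
#'
#' @param path aligned FASTA with exactly two records of equal length.
#' @return an `hm_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  seqs <- read_fasta(path)
  if (length(seqs) != 2) stop("expected exactly 2 aligned sequences")
  rows <- lapply(seqs, function(s) strsplit(gsub("\\.", "-", s), "")[[1]])
  if (length(rows[[1]]) != length(rows[[2]])) {
    stop("aligned sequences differ in length")
  }
  ga <- rows[[1]] == "-"; gb <- rows[[2]] == "-"
  keep <- !(ga & gb)
  ai <- ifelse(ga, NA, cumsum(!ga))[keep]
  bi <- ifelse(gb, NA, cumsum(!gb))[keep]
  structure(list(a = paste(rows[[1]][!ga], collapse = ""),
                 b = paste(rows[[2]][!gb], collapse = ""),
                 score = NA_real_,
                 columns = data.frame(ai = as.integer(ai),
                                      bi = as.integer(bi))),
            class = "hm_alignment")
}

#' Alignment-derived quality features
#'
#' Computes the length-normalized features consumed by GMQE. All fractions
#' use the aligned (non-gap) column count as denominator; `coverage` is the
#' aligned fraction of the target. Template secondary structure and burial
#' come from the library annotations; template accessibility is binarized at
#' relative SASA `acc_threshold` (buried below, exposed above).
#'
#' @param aln `hm_alignment` of target (`a`) against a template chain (`b`).
#' @param template_chain per-chain annotation list of a library entry
#'   (fields `seq`, `ss`, `rel_acc`).
#' @param target_pred target predictions from [predict_target_properties()].
#' @param mat substitution matrix used for the similarity count.
#' @param acc_threshold burial threshold on relative accessibility.
#' @return named numeric vector: `seq_identity`, `seq_similarity`,
#'   `norm_score`, `ss_agreement`, `acc_agreement`, `coverage`.
#' @export
alignment_features <- function(aln, template_chain, target_pred,
                               mat = substitution_matrix(),
                               acc_threshold = 0.25) {
  cols <- aln$columns
  paired <- !is.na(cols$ai) & !is.na(cols$bi)
  nal <- sum(paired)
  if (nal == 0) stop("alignment has no aligned columns; features undefined")
  sa <- strsplit(toupper(aln$a), "")[[1]]
  sb <- strsplit(toupper(aln$b), "")[[1]]
  ia <- cols$ai[paired]; ib <- cols$bi[paired]
  ra <- sa[ia]; rb <- sb[ib]
  identity <- sum(ra == rb) / nal
  similarity <- sum(mat[cbind(ra, rb)] > 0) / nal
  norm_score <- if (is.na(aln$score)) NA_real_ else aln$score / nal
  t_ss <- strsplit(template_chain$ss, "")[[1]][ib]
  q_ss <- strsplit(target_pred$ss, "")[[1]][ia]
  ss_agreement <- mean(t_ss == q_ss)
  t_bur <- ifelse(template_chain$rel_acc[ib] < acc_threshold, "b", "e")
  q_bur <- strsplit(target_pred$burial, "")[[1]][ia]
  ok <- !is.na(t_bur)
  acc_agreement <- if (any(ok)) mean(t_bur[ok] == q_bur[ok]) else 0.5
  coverage <- length(unique(ia)) / length(sa)
  c(seq_identity = identity, seq_similarity = similarity,
    norm_score = norm_score, ss_agreement = ss_agreement,
    acc_agreement = acc_agreement, coverage = coverage)
}

#' Search a template library with a target sequence
#'
#' Aligns the target against every indexed template chain and returns one
#' hit per (entry, chain) whose raw alignment score reaches `min_score`,
#' with features computed against the entry's annotations. Hits are ordered
#' by raw score (descending), ties broken by entry id then chain id.
#'
#' @param lib an `hm_library`.
#' @param target target sequence string.
#' @param min_score minimum raw Smith-Waterman score (default 15).
#' @param mat,gap_open,gap_extend aligner parameters.
#' @return list of hits; each hit is a list with `entry`, `chain`,
#'   `alignment`, `features`, and `gmqe` (NA until ranked).
#' @export
search_templates <- function(lib, target, min_score = 15,
                             mat = substitution_matrix(),
                             gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(lib, "hm_library"))
  if (!nzchar(target)) stop("empty target sequence")
  if (length(lib$entries) == 0) return(list())
  pred <- predict_target_properties(target)
  idx <- library_index(lib)
  hits <- list()
  for (k in seq_len(nrow(idx))) {
    aln <- local_align(target, idx$seq[k], mat, gap_open, gap_extend)
    if (aln$score < min_score || nrow(aln$columns) == 0) next
    tc <- lib$entries[[idx$entry[k]]]$chains[[idx$chain[k]]]
    feats <- alignment_features(aln, tc, pred, mat)
    hits[[length(hits) + 1]] <- list(entry = idx$entry[k],
                                     chain = idx$chain[k],
                                     alignment = aln, features = feats,
                                     gmqe = NA_real_)
  }
  if (length(hits) == 0) return(hits)
  ord <- order(-vapply(hits, function(h) h$alignment$score, numeric(1)),
               vapply(hits, function(h) h$entry, character(1)),
               vapply(hits, function(h) h$chain, character(1)))
  hits[ord]
}

#' Pairwise-similarity template landscape
#'
#' Embeds the hit templates in 2D so that distances reflect pairwise
#' sequence dissimilarity (1 - identity from all-against-all local
#' alignments, classical multidimensional scaling) and groups them by
#' single-linkage clustering at an identity threshold.
#'
#' @param hits hit list from [search_templates()].
#' @param lib the library the hits refer to.
#' @param identity_threshold templates linked at or above this pairwise
#'   identity join a cluster (default 0.7).
#' @param mat substitution matrix for the template-template alignments.
#' @return data.frame with `entry`, `chain`, `x`, `y`, `cluster`.
#' @export
similarity_landscape <- function(hits, lib, identity_threshold = 0.7,
                                 mat = substitution_matrix()) {
  n <- length(hits)
  if (n == 0) stop("no hits")
  labels <- vapply(hits, function(h) paste(h$entry, h$chain), character(1))
  if (n == 1) {
    return(data.frame(entry = hits[[1]]$entry, chain = hits[[1]]$chain,
                      x = 0, y = 0, cluster = 1L, stringsAsFactors = FALSE))
  }
  seqs <- vapply(hits, function(h) {
    lib$entries[[h$entry]]$chains[[h$chain]]$seq
  }, character(1))
  idm <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- local_align(seqs[i], seqs[j], mat)
      paired <- !is.na(aln$columns$ai) & !is.na(aln$columns$bi)
      idv <- if (sum(paired) == 0) 0 else {
        sa <- strsplit(seqs[i], "")[[1]][aln$columns$ai[paired]]
        sb <- strsplit(seqs[j], "")[[1]][aln$columns$bi[paired]]
        sum(sa == sb) / sum(paired)
      }
      idm[i, j] <- idm[j, i] <- idv
    }
  }
  d <- 1 - idm
  xy <- stats::cmdscale(stats::as.dist(d), k = min(2, n - 1))
  if (ncol(xy) < 2) xy <- cbind(xy, rep(0, nrow(xy)))
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                      h = 1 - identity_threshold)
  data.frame(entry = vapply(hits, function(h) h$entry, character(1)),
             chain = vapply(hits, function(h) h$chain, character(1)),
             x = xy[, 1], y = xy[, 2], cluster = as.integer(cl),
             stringsAsFactors = FALSE)
}
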