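# Global model quality estimation (GMQE). Each alignment feature is turned
# into a conditional probability density of the realized model-vs-native
# structural similarity; densities are combined by relevance-weighted
# log-density summation and the joint maximum over [0,1] is the GMQE.

GMQE_GRID <- seq(0, 1, length.out = 101)

# Gaussian kernel density on [0,1] with reflection at both boundaries, so
# mass never leaks outside the unit interval.
#' @keywords internal
reflected_kde <- function(centers, bw, at) {
  k <- function(u) stats::dnorm(u)
  dens <- vapply(at, function(s) {
    mean(k((s - centers) / bw) +
         k((s + centers) / bw) +            # reflect at 0
         k((s - (2 - centers)) / bw)) / bw  # reflect at 1
  }, numeric(1))
  pmax(dens, 1e-12)
}

# Trapezoid integral on a uniform grid.
#' @keywords internal
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @keywords internal
silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.349
  spread <- min(s, iqr)
  if (!is.finite(spread) || spread < 1e-3) spread <- 1e-3
  max(0.9 * spread * n^(-1/5), 0.02)
}

#' Calibrate per-feature similarity densities
#'
#' For each feature the records are split into `n_bins` equal-count bins of
#' the feature value; within every bin a reflected Gaussian kernel density
#' of the realized similarity `s*` is estimated on a fixed grid over [0,1].
#' A feature's relevance weight is the absolute Spearman correlation between
#' its values and `s*`; a constant (degenerate) feature gets relevance 0 and
#' a uniform density with a warning.
#'
#' @param features matrix or data.frame of feature values (rows = records).
#' @param s_star realized structural similarity per record, in [0,1]
#'   (on fixture benchmarks: the lDDT of the model built from the template
#'   against the known target structure).
#' @param n_bins equal-count feature bins (default 10).
#' @param grid similarity grid (default 101 points on [0,1]).
#' @return object of class `hm_densities`: per-feature bin edges, per-bin
#'   kernel centers/bandwidths, grid densities, and relevance weights.
#' @export
calibrate_gmqe <- function(features, s_star, n_bins = 10, grid = GMQE_GRID) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(s_star))
  if (nrow(features) < 50) {
    stop("calibration needs at least 50 records spanning the similarity range")
  }
  if (any(s_star < 0 | s_star > 1)) stop("similarity labels must lie in [0,1]")
  out <- list()
  for (fname in names(features)) {
    v <- features[[fname]]
    if (stats::sd(v) < 1e-12) {
      warning("feature '", fname, "' is constant; relevance set to 0")
      out[[fname]] <- list(relevance = 0, edges = c(-Inf, Inf),
                           bins = list(list(centers = NA, bw = NA,
                                            density = rep(1, length(grid)))))
      next
    }
    probs <- seq(0, 1, length.out = n_bins + 1)
    edges <- unique(stats::quantile(v, probs, names = FALSE, type = 7))
    if (length(edges) < 3) {
      edges <- c(min(v) - 1e-9, stats::median(v), max(v) + 1e-9)
    }
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    bin <- cut(v, edges, labels = FALSE, include.lowest = TRUE)
    bins <- lapply(seq_len(length(edges) - 1), function(b) {
      sb <- s_star[bin == b]
      if (length(sb) == 0) sb <- s_star
      bw <- silverman_bw(sb)
      d <- reflected_kde(sb, bw, grid)
      d <- d / trapz(grid, d)  # exact unit mass on the stored grid
      list(centers = sb, bw = bw, density = d)
    })
    rel <- abs(stats::cor(v, s_star, method = "spearman"))
    if (!is.finite(rel)) rel <- 0
    out[[fname]] <- list(relevance = rel, edges = edges, bins = bins)
  }
  structure(list(features = out, grid = grid), class = "hm_densities")
}

# Evaluate one feature's conditional density at arbitrary similarity values.
#' @keywords internal
density_at <- function(densities, fname, value, at) {
  fd <- densities$features[[fname]]
  b <- findInterval(value, fd$edges, all.inside = TRUE)
  binrec <- fd$bins[[b]]
  if (length(binrec$centers) == 1 && is.na(binrec$centers[1])) {
    return(rep(1, length(at)))
  }
  reflected_kde(binrec$centers, binrec$bw, at)
}

#' Joint GMQE estimate for one feature vector
#'
#' The joint log-density over the similarity grid is the relevance-weighted
#' sum of per-feature conditional log-densities; the GMQE is the grid value
#' maximizing it (ties resolved towards the lowest similarity, the
#' conservative choice). Feature values outside the calibrated range are
#' clamped to the nearest bin and flagged.
#'
#' @param features named numeric vector of feature values.
#' @param densities an `hm_densities` from [calibrate_gmqe()].
#' @return object of class `hm_gmqe`: `gmqe`, `joint` (log-density over the
#'   grid), `grid`, `per_feature` (argmax per feature), `clamped`.
#' @export
joint_estimate <- function(features, densities) {
  stopifnot(inherits(densities, "hm_densities"))
  grid <- densities$grid
  joint <- rep(0, length(grid))
  per_feature <- c()
  clamped <- character(0)
  for (fname in names(densities$features)) {
    if (!fname %in% names(features)) next
    fd <- densities$features[[fname]]
    v <- features[[fname]]
    finite_edges <- fd$edges[is.finite(fd$edges)]
    if (length(finite_edges) > 0 &&
        (v < min(finite_edges) || v > max(finite_edges))) {
      clamped <- c(clamped, fname)
    }
    b <- findInterval(v, fd$edges, all.inside = TRUE)
    d <- fd$bins[[b]]$density
    joint <- joint + fd$relevance * log(d)
    per_feature[fname] <- grid[which.max(d)]
  }
  structure(list(gmqe = grid[which.max(joint)], joint = joint, grid = grid,
                 per_feature = per_feature, clamped = clamped),
            class = "hm_gmqe")
}

# Joint log-density at arbitrary similarity values (used for fine-grid
# verification of the argmax).
#' @keywords internal
joint_log_density <- function(features, densities, at) {
  joint <- rep(0, length(at))
  for (fname in names(densities$features)) {
    if (!fname %in% names(features)) next
    fd <- densities$features[[fname]]
    joint <- joint + fd$relevance *
      log(density_at(densities, fname, features[[fname]], at))
  }
  joint
}

#' Rank search hits by GMQE
#'
#' Attaches a GMQE to every hit and sorts descending; ties are broken by
#' sequence identity (descending) then template id (ascending). The sort is
#' stable and the output is a permutation of the input.
#'
#' @param hits hit list from [search_templates()].
#' @param densities calibrated `hm_densities`.
#' @return the hit list, ranked, each with `gmqe` filled in.
#' @export
rank_templates <- function(hits, densities) {
  if (length(hits) == 0) return(hits)
  for (k in seq_along(hits)) {
    hits[[k]]$gmqe <- joint_estimate(hits[[k]]$features, densities)$gmqe
  }
  ord <- order(-vapply(hits, function(h) h$gmqe, numeric(1)),
               -vapply(hits, function(h) h$features[["seq_identity"]],
                       numeric(1)),
               vapply(hits, function(h) paste(h$entry, h$chain), character(1)))
  hits[ord]
}

#' Combine GMQE with the global potential-based quality score
#'
#' Logistic of a weighted sum with non-negative slope weights, so the
#' combined estimate is monotone non-decreasing in both inputs and always in
#' [0,1]. Default weights are package defaults; [fit_combined_weights()]
#' refits them on a calibration benchmark.
#'
#' @param gmqe alignment-based estimate in [0,1].
#' @param qmean_global potential-based global score in [0,1].
#' @param weights numeric c(intercept, w_gmqe, w_qmean); slopes are clamped
#'   to be non-negative.
#' @return combined quality estimate in [0,1].
#' @export
combined_estimate <- function(gmqe, qmean_global,
                              weights = c(-4.5, 5.5, 3.5)) {
  stopifnot(is.finite(gmqe), is.finite(qmean_global))
  w <- c(weights[1], max(0, weights[2]), max(0, weights[3]))
  stats::plogis(w[1] + w[2] * gmqe + w[3] * qmean_global)
}

#' Fit combined-estimate weights on a benchmark
#'
#' Quasibinomial logistic regression of the realized similarity labels on
#' (gmqe, qmean_global); negative slopes are truncated at 0 to preserve the
#' monotonicity contract.
#'
#' @param gmqe,qmean_global,label equal-length numeric vectors; `label` in
#'   [0,1].
#' @return weight vector c(intercept, w_gmqe, w_qmean).
#' @export
fit_combined_weights <- function(gmqe, qmean_global, label) {
  fit <- stats::glm(label ~ gmqe + qmean_global,
                    family = stats::quasibinomial())
  w <- unname(stats::coef(fit))
  c(w[1], max(0, w[2]), max(0, w[3]))
}

#' Serialize calibrated densities to JSON
#'
#' @param densities an `hm_densities`.
#' @param path output file.
#' @export
save_densities <- function(densities, path) {
  obj <- list(grid = densities$grid,
              features = lapply(densities$features, function(fd) {
                list(relevance = fd$relevance, edges = fd$edges,
                     bins = lapply(fd$bins, function(b) {
                       list(centers = b$centers, bw = b$bw)
                     }))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}

#' Load calibrated densities from JSON
#'
#' @param path file written by [save_densities()].
#' @return an `hm_densities`.
#' @export
load_densities <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  grid <- as.numeric(unlist(obj$grid))
  feats <- lapply(obj$features, function(fd) {
    edges <- suppressWarnings(as.numeric(unlist(fd$edges)))
    bins <- lapply(fd$bins, function(b) {
      centers <- suppressWarnings(as.numeric(unlist(b$centers)))
      bw <- suppressWarnings(as.numeric(unlist(b$bw)))
      dens <- if (all(is.na(centers))) rep(1, length(grid)) else {
        d0 <- reflected_kde(centers, bw, grid)
        d0 / trapz(grid, d0)
      }
      list(centers = centers, bw = bw, density = dens)
    })
    list(relevance = as.numeric(fd$relevance), edges = edges, bins = bins)
  })
  structure(list(features = feats, grid = grid), class = "hm_densities")
}
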