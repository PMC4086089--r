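# Homo-oligomer conservation: interface detection and features, a random
# forest over interface properties, and a size-weighted decision on whether
# the template's quaternary structure carries over to the target.

#' Detect inter-chain interfaces in an assembly
#'
#' Two polymer chains share an interface when any inter-chain heavy-atom
#' pair lies within `cutoff`. Each contacting chain pair yields one record
#' with its contacting residue pairs and the interface residue set (size =
#' number of distinct interface residues over both chains).
#'
#' @param assembly structure-like object.
#' @param cutoff heavy-atom contact distance in Angstrom (default 5.0).
#' @return list of interface records: `chains` (pair), `contacts`
#'   (data.frame of residue pairs), `residues` (data.frame chain/resno/ins),
#'   `size`.
#' @export
detect_interfaces <- function(assembly, cutoff = 5.0) {
  atoms <- as_atoms(assembly)
  atoms <- atoms[atoms$kind == "polymer" & atoms$element != "H", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (length(chains) < 2) return(list())
  out <- list()
  for (i in seq_len(length(chains) - 1)) {
    for (j in (i + 1):length(chains)) {
      a <- atoms[atoms$chain == chains[i], , drop = FALSE]
      b <- atoms[atoms$chain == chains[j], , drop = FALSE]
      axyz <- atom_xyz(a); bxyz <- atom_xyz(b)
      d2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), "+") -
        2 * axyz %*% t(bxyz)
      hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      pairs <- unique(data.frame(
        resno_a = a$resno[hit[, 1]], ins_a = a$ins[hit[, 1]],
        resno_b = b$resno[hit[, 2]], ins_b = b$ins[hit[, 2]],
        stringsAsFactors = FALSE))
      res_a <- unique(data.frame(chain = chains[i],
                                 resno = pairs$resno_a, ins = pairs$ins_a,
                                 stringsAsFactors = FALSE))
      res_b <- unique(data.frame(chain = chains[j],
                                 resno = pairs$resno_b, ins = pairs$ins_b,
                                 stringsAsFactors = FALSE))
      residues <- rbind(res_a, res_b)
      out[[length(out) + 1]] <- list(chains = c(chains[i], chains[j]),
                                     contacts = pairs, residues = residues,
                                     size = nrow(residues))
    }
  }
  out
}

#' Interface conservation features
#'
#' Sequence identity and similarity restricted to aligned columns touching
#' the interface residues, mean Kyte-Doolittle hydrophobicity of the
#' interface residues, and the consensus fraction: how many of the other
#' template hits carry an equivalent interface (sharing at least
#' `equiv_overlap` of the interface residue positions after mapping through
#' the alignments).
#'
#' @param interface record from [detect_interfaces()].
#' @param aln target-template `hm_alignment` covering the interface chain.
#' @param template_chain the aligned chain's annotation list (with `map`).
#' @param lib library (for consensus lookups).
#' @param hits all search hits (consensus denominator excludes the hit the
#'   interface belongs to); empty or length-1 lists give consensus 0.
#' @param self_entry entry key the interface belongs to.
#' @param equiv_overlap positional overlap for interface equivalence.
#' @return named numeric vector `identity`, `similarity`, `hydrophobicity`,
#'   `consensus`, or NULL when the interface is entirely unaligned.
#' @export
interface_features <- function(interface, aln, template_chain, lib = NULL,
                               hits = list(), self_entry = NULL,
                               equiv_overlap = 0.5) {
  map <- template_chain$map
  ifres <- interface$residues[interface$residues$chain == template_chain$chain, ,
                              drop = FALSE]
  pos <- map$pos[match(paste(ifres$resno, ifres$ins),
                       paste(map$resno, map$ins))]
  pos <- pos[!is.na(pos)]
  cols <- aln$columns
  paired <- !is.na(cols$ai) & !is.na(cols$bi)
  touch <- paired & cols$bi %in% pos
  if (!any(touch)) {
    warning("interface residues entirely unaligned; features undefined")
    return(NULL)
  }
  sa <- strsplit(toupper(aln$a), "")[[1]]
  sb <- strsplit(toupper(aln$b), "")[[1]]
  ra <- sa[cols$ai[touch]]; rb <- sb[cols$bi[touch]]
  mat <- substitution_matrix()
  identity <- mean(ra == rb)
  similarity <- mean(mat[cbind(ra, rb)] > 0)
  tb <- strsplit(template_chain$seq, "")[[1]][pos]
  kd <- KYTE_DOOLITTLE[tb]
  hydrophobicity <- mean(kd, na.rm = TRUE)
  # consensus: fraction of other hits whose assembly has an equivalent
  # interface at >= equiv_overlap shared target positions
  consensus <- 0
  others <- Filter(function(h) is.null(self_entry) || h$entry != self_entry,
                   hits)
  if (length(others) > 0 && !is.null(lib)) {
    target_pos <- sort(unique(cols$ai[touch]))
    n_equiv <- 0
    for (h in others) {
      he <- lib$entries[[h$entry]]
      ifs <- detect_interfaces(he$assembly)
      found <- FALSE
      for (oi in ifs) {
        hc <- he$chains[[h$chain]]
        ores <- oi$residues[oi$residues$chain == h$chain, , drop = FALSE]
        opos <- hc$map$pos[match(paste(ores$resno, ores$ins),
                                 paste(hc$map$resno, hc$map$ins))]
        opos <- opos[!is.na(opos)]
        ocols <- h$alignment$columns
        op <- !is.na(ocols$ai) & !is.na(ocols$bi) & ocols$bi %in% opos
        otarget <- unique(ocols$ai[op])
        if (length(target_pos) > 0 &&
            length(intersect(otarget, target_pos)) / length(target_pos) >=
            equiv_overlap) {
          found <- TRUE; break
        }
      }
      if (found) n_equiv <- n_equiv + 1
    }
    consensus <- n_equiv / length(others)
  }
  c(identity = identity, similarity = similarity,
    hydrophobicity = hydrophobicity, consensus = consensus)
}

#' Train the interface conservation classifier
#'
#' Random forest over interface feature rows with binary conservation
#' labels. Seeded for reproducibility; the fitted object carries its seed
#' and feature order as metadata.
#'
#' @param table data.frame with feature columns and a `conserved` column
#'   (0/1 or logical).
#' @param seed RNG seed.
#' @param ntree number of trees (default 200).
#' @return object of class `hm_oligo_classifier`.
#' @export
train_interface_classifier <- function(table, seed = 1, ntree = 200) {
  stopifnot(is.data.frame(table), "conserved" %in% names(table))
  if (nrow(table) < 50) stop("need at least 50 labeled rows")
  y <- factor(as.integer(as.logical(table$conserved)), levels = c(0, 1))
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  x <- table[, setdiff(names(table), "conserved"), drop = FALSE]
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  structure(list(forest = rf, seed = seed, features = names(x),
                 ntree = ntree),
            class = "hm_oligo_classifier")
}

#' Predict interface conservation probabilities
#'
#' @param classifier an `hm_oligo_classifier`.
#' @param newdata data.frame with the classifier's feature columns.
#' @return numeric vector of conservation probabilities in [0,1].
#' @export
predict_conservation <- function(classifier, newdata) {
  stopifnot(inherits(classifier, "hm_oligo_classifier"))
  missing_cols <- setdiff(classifier$features, names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  p <- stats::predict(classifier$forest,
                      newdata[, classifier$features, drop = FALSE],
                      type = "prob")
  unname(p[, "1"])
}

#' Size-weighted oligomeric-state decision
#'
#' The per-interface conservation probabilities are averaged with interface
#' sizes as weights; the template's oligomeric state is predicted conserved
#' when this weighted average strictly exceeds the threshold. With no
#' scoreable interfaces the prediction is `monomer`.
#'
#' @param sizes integer interface sizes.
#' @param probabilities conservation probability per interface.
#' @param threshold decision threshold (default 0.5).
#' @return list: `predicted` ("conserved_oligomer" or "monomer"),
#'   `weighted_average`, `threshold`, `sizes`, `probabilities`.
#' @export
decide_oligomer <- function(sizes, probabilities, threshold = 0.5) {
  ok <- is.finite(probabilities) & is.finite(sizes) & sizes >= 1
  sizes <- sizes[ok]; probabilities <- probabilities[ok]
  if (length(sizes) == 0) {
    return(list(predicted = "monomer", weighted_average = NA_real_,
                threshold = threshold, sizes = integer(0),
                probabilities = numeric(0)))
  }
  wavg <- sum(sizes * probabilities) / sum(sizes)
  list(predicted = if (wavg > threshold) "conserved_oligomer" else "monomer",
       weighted_average = wavg, threshold = threshold,
       sizes = sizes, probabilities = probabilities)
}
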