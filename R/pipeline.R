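# End-to-end orchestration: search -> rank -> build -> score -> report.

#' Run the automated modelling pipeline
#'
#' Searches the library with the target sequence, ranks hits by GMQE, builds
#' a model from the top-ranked template (auto mode) or from each requested
#' template (manual mode), scores it, and assembles a report bundling the
#' alignment, oligomeric decision, ligand statuses, per-residue reliability
#' scores, global score, Z-score, GMQE and the combined estimate. When no
#' template clears the score threshold the result carries
#' `status = "no_template"` rather than failing.
#'
#' @param target target sequence (string) or path to a FASTA file.
#' @param lib an `hm_library` or a directory readable by [load_library()].
#' @param densities calibrated `hm_densities` (or path to a JSON file).
#' @param potentials list of trained `hm_potential` objects.
#' @param templates NULL for auto mode, or character vector of
#'   `"entry/chain"` keys for manual selection.
#' @param classifier optional interface-conservation classifier.
#' @param weights local-score combination weights.
#' @param combined_weights weights for [combined_estimate()].
#' @param reference_scores reference global scores for the Z-score (NULL
#'   skips the Z-score).
#' @param min_score search score threshold.
#' @return list of class `hm_result`: `status`, `models` (each with `model`,
#'   `report`), `hits`.
#' @export
run_pipeline <- function(target, lib, densities, potentials,
                         templates = NULL, classifier = NULL,
                         weights = c(0, -1, -1, -1),
                         combined_weights = c(-4.5, 5.5, 3.5),
                         reference_scores = NULL, min_score = 15) {
  if (is.character(lib)) lib <- load_library(lib)
  if (is.character(densities)) densities <- load_densities(densities)
  if (file.exists(target) && !grepl("^[A-Za-z]+$", target)) {
    target <- unname(read_fasta(target)[1])
  }
  target <- toupper(gsub("\\s", "", target))
  hits <- search_templates(lib, target, min_score = min_score)
  if (length(hits) == 0) {
    return(structure(list(status = "no_template", models = list(),
                          hits = list()),
                     class = "hm_result"))
  }
  hits <- rank_templates(hits, densities)
  chosen <- if (is.null(templates)) hits[1] else {
    keys <- vapply(hits, function(h) paste(h$entry, h$chain, sep = "/"),
                   character(1))
    sel <- hits[keys %in% templates]
    if (length(sel) == 0) {
      return(structure(list(status = "no_template", models = list(),
                            hits = hits),
                       class = "hm_result"))
    }
    sel
  }
  models <- lapply(chosen, function(hit) {
    model <- build_model(hit, lib, classifier = classifier, hits = hits)
    profile <- score_local(model, potentials, weights = weights)
    global <- score_global(profile)
    z <- if (!is.null(reference_scores)) {
      z_score(global, reference_scores)
    } else NULL
    combined <- combined_estimate(hit$gmqe, global, combined_weights)
    model$scores <- list(profile = profile, global = global, z = z,
                         gmqe = hit$gmqe, combined = combined)
    # per-residue reliability into the B-factor column, one value per atom
    prof_key <- paste(profile$chain, profile$resno)
    atom_key <- paste(model$atoms$chain, model$atoms$resno)
    idx <- match(atom_key, prof_key)
    model$atoms$b <- ifelse(is.na(idx), 0, round(profile$score[idx], 3))
    report <- list(
      template = paste(hit$entry, hit$chain, sep = "/"),
      alignment = alignment_strings(hit$alignment),
      features = as.list(hit$features),
      gmqe = hit$gmqe,
      oligo = model$oligo[c("predicted", "weighted_average", "threshold")],
      ligands = model$ligands,
      provenance = model$provenance,
      per_residue_score = data.frame(
        chain = profile$chain, resno = profile$resno,
        score = profile$score, stringsAsFactors = FALSE),
      global_score = global,
      z_score = z,
      combined = combined,
      chain_breaks = attr(model, "chain_breaks"))
    list(model = model, report = report)
  })
  structure(list(status = "ok", models = models, hits = hits),
            class = "hm_result")
}

#' @keywords internal
alignment_strings <- function(aln) {
  sa <- strsplit(aln$a, "")[[1]]; sb <- strsplit(aln$b, "")[[1]]
  list(target = paste(ifelse(is.na(aln$columns$ai), "-",
                             sa[aln$columns$ai]), collapse = ""),
       template = paste(ifelse(is.na(aln$columns$bi), "-",
                               sb[aln$columns$bi]), collapse = ""))
}

#' Write a pipeline result to disk
#'
#' Emits, per model, coordinates (PDB, reliability scores in the B-factor
#' column), the JSON report, and a human-readable modelling log.
#'
#' @param result an `hm_result` from [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(status = result$status,
                            n_models = length(result$models)),
                       file.path(dir, "status.json"), auto_unbox = TRUE)
  for (k in seq_along(result$models)) {
    mk <- result$models[[k]]
    stem <- file.path(dir, sprintf("model_%02d", k))
    suppressMessages(write_structure(mk$model, paste0(stem, ".pdb"), "pdb"))
    jsonlite::write_json(mk$report, paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", force = TRUE)
    log_lines <- c(
      sprintf("template: %s", mk$report$template),
      sprintf("GMQE: %.3f  global score: %.3f  combined: %.3f",
              mk$report$gmqe, mk$report$global_score, mk$report$combined),
      if (!is.null(mk$report$z_score))
        sprintf("Z-score: %.2f", mk$report$z_score),
      sprintf("oligomeric prediction: %s", mk$report$oligo$predicted),
      sprintf("ligands placed: %d / %d",
              sum(vapply(mk$report$ligands,
                         function(l) identical(l$status, "placed"),
                         logical(1))),
              length(mk$report$ligands)),
      "residue states:",
      sprintf("  %s: %d",
              names(table(mk$report$provenance$state)),
              as.integer(table(mk$report$provenance$state))))
    writeLines(log_lines, paste0(stem, ".log"))
  }
  invisible(dir)
}
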