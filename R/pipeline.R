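# End-to-end orchestration: conserved residues -> surface screen ->
# clustering -> DBU ranking -> per-DBU orientation and base-location
# prediction, with optional evaluation against a reference complex.

#' Pipeline configuration
#'
#' Collects every tunable of the method with its default: 4.5 A binding
#' cutoff, 4.0 A model-contact cutoff, RSA 0.25, 11 A clustering stop,
#' Gaussian widths 2.0 / 5.0 A, 2.0 A clash stop, 5.0 A diversity RMSD.
#'
#' @param binding_cutoff,contact_cutoff,rsa_cutoff,stop_distance method
#'   thresholds (Angstrom / fraction).
#' @param kernel_sigma,core_sigma,clash_distance,diversity_rmsd see
#'   [density_params()].
#' @param topk number of top-ranked DBUs to analyse (default 1).
#' @param bases base types to predict (default all four).
#' @param base_atoms contact scope for "a base": `"residue"` (default,
#'   whole nucleotide) or `"base"` (base moiety only).
#' @param seed RNG seed recorded with the run (default 0).
#' @return list of class `run_config`.
#' @export
run_config <- function(binding_cutoff = 4.5, contact_cutoff = 4.0,
                       rsa_cutoff = 0.25, stop_distance = 11,
                       kernel_sigma = 2.0, core_sigma = 5.0,
                       clash_distance = 2.0, diversity_rmsd = 5.0,
                       topk = 1, bases = STANDARD_BASES,
                       base_atoms = c("residue", "base"), seed = 0) {
  structure(list(binding_cutoff = binding_cutoff,
                 contact_cutoff = contact_cutoff, rsa_cutoff = rsa_cutoff,
                 stop_distance = stop_distance, kernel_sigma = kernel_sigma,
                 core_sigma = core_sigma, clash_distance = clash_distance,
                 diversity_rmsd = diversity_rmsd, topk = topk,
                 bases = match.arg(bases, STANDARD_BASES, several.ok = TRUE),
                 base_atoms = match.arg(base_atoms), seed = seed),
            class = "run_config")
}

#' Run the full prediction pipeline
#'
#' @param query a `pdb_structure` (bound or unbound protein; DNA present in
#'   the query is ignored for prediction and only used when `reference` is
#'   not supplied but evaluation is requested).
#' @param kb a `knowledgebase`.
#' @param conserved character vector of conserved residue keys, or `"all"`
#'   to treat every protein residue as conserved (e.g. when an external
#'   residue predictor supplies the set).
#' @param config a [run_config()].
#' @param reference optional reference complex for evaluation.
#' @param verbose log per-stage counts via `message()` (default TRUE).
#' @return list of class `pipeline_result`: `config`, `conserved`,
#'   `surface`, `clusters`, `dbus`, and `predictions` (one entry per
#'   analysed DBU: `dbu`, `orientation`, `base_predictions` per base,
#'   `top` = overall best placement, `evaluation` when a reference was
#'   given).
#' @export
run_pipeline <- function(query, kb, conserved = "all",
                         config = run_config(), reference = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  rt <- residue_table(query)
  if (identical(conserved, "all"))
    conserved <- rt$reskey[rt$kind == "protein"]
  say("conserved residues: %d", length(conserved))
  surface <- surface_filter(query, conserved, config$rsa_cutoff)
  say("surface residues (RSA > %.2f): %d", config$rsa_cutoff,
      length(surface))
  clusters <- cluster_atoms(query, surface, config$stop_distance)
  say("spatial clusters (stop %.1f A): %d", config$stop_distance,
      length(clusters))
  dbus <- rank_dbus(clusters, kb$propensities, query)
  say("accepted DBUs (score > expectation): %d", length(dbus))
  params <- density_params(config$kernel_sigma, config$core_sigma,
                           config$clash_distance, config$diversity_rmsd)
  preds <- list()
  for (d in utils::head(dbus, config$topk)) {
    orient <- tryCatch(predict_orientation(d, query, kb$frames),
                       error = function(e) {
                         say("orientation failed for DBU %d: %s", d$rank,
                             conditionMessage(e))
                         NULL
                       })
    bp <- list()
    for (b in config$bases)
      bp[[b]] <- predict_base_location(d, query, kb, b, params)
    ok <- Filter(function(p) p$status == "ok" &&
                   length(p$placements) > 0, bp)
    top <- NULL
    if (length(ok) > 0) {
      dens <- vapply(ok, function(p) p$placements[[1]]$density, numeric(1))
      top <- ok[[which.max(dens)]]$placements[[1]]
    }
    say("DBU %d: %d placements kept (top base %s, density %.4f)",
        d$rank, sum(vapply(bp, function(p) length(p$placements),
                           integer(1))),
        if (is.null(top)) "none" else top$base,
        if (is.null(top)) NA_real_ else top$density)
    entry <- list(dbu = d, orientation = orient, base_predictions = bp,
                  top = top)
    ref <- if (!is.null(reference)) reference else
      if (any(query$atoms$kind == "dna")) query else NULL
    if (!is.null(ref) && !is.null(top) && !is.null(orient)) {
      best <- bp[[top$base]]
      entry$evaluation <- evaluate_prediction(best, orient, d, ref)
      entry$residue_metrics <- residue_metrics(surface, ref,
                                               config$binding_cutoff)
    }
    preds[[length(preds) + 1]] <- entry
  }
  structure(list(config = config, conserved = conserved, surface = surface,
                 clusters = clusters, dbus = dbus, predictions = preds),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", length(x$conserved), " conserved -> ",
      length(x$surface), " surface -> ", length(x$clusters),
      " clusters -> ", length(x$dbus), " DBUs; ", length(x$predictions),
      " analysed\n", sep = "")
  for (p in x$predictions) {
    cat(sprintf("-- DBU rank %d (score %.3f, %d residues)\n",
                p$dbu$rank, p$dbu$score, p$dbu$size))
    if (!is.null(p$orientation)) print(p$orientation)
    if (!is.null(p$top))
      cat(sprintf("   top placement: base %s density %.4f at (%.2f, %.2f, %.2f)\n",
                  p$top$base, p$top$density, p$top$centroid[1],
                  p$top$centroid[2], p$top$centroid[3]))
    if (!is.null(p$evaluation)) print(p$evaluation)
  }
  invisible(x)
}
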