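# End-to-end orchestration: reduction -> per-compound forests -> concordance
# and importance -> missingness QC -> reports -> interaction screening.

#' Run the full pharmacogenomic mining pipeline
#'
#' Applies the three-step reduction, fits one random forest per compound on
#' its non-missing AUCs, scores concordance (CCC between observed AUCs and
#' OOB predictions) and per-alteration permutation importance, quantifies
#' the missingness impact, assembles Reports 1-2 and screens the Report-1
#' compound pairs for drug-gene interactions via logit-AUC two-way ANOVA.
#'
#' Per-drug seeds are derived deterministically from the master seed and
#' the compound's row index, so adding or removing compounds does not shift
#' other models. Compounds screened on fewer than 10 cell lines are
#' recorded and skipped.
#'
#' @param study A `matched_study` (or the `study` element of a
#'   [make_study()] result).
#' @param drivers Character vector of driver-gene symbols.
#' @param min_proportion,min_correlation Reduction parameters.
#' @param num_trees,min_node_size Forest parameters.
#' @param seed Master seed.
#' @param ccc_threshold Report-1 lower-CCC-bound threshold (x100).
#' @param auc_tolerance Candidate-pair mean-AUC tolerance.
#' @param alpha Per-model significance level after Bonferroni correction.
#' @param out_dir If non-`NULL`, CSV/JSON artifacts (reports, cluster map,
#'   QC, per-drug summaries, interaction results, provenance) are written
#'   there.
#' @param verbose Log per-drug progress?
#' @return A `pipeline_result`: list with `reduction`, `drug_results`,
#'   `qc`, `report1`, `report2`, `candidates`, `interactions`, `skipped`,
#'   `params`.
#' @export
run_pipeline <- function(study, drivers,
                         min_proportion = 0.05, min_correlation = 0.95,
                         num_trees = 500, min_node_size = 5, seed = 1,
                         ccc_threshold = 20, auc_tolerance = 0.02,
                         alpha = 0.005, out_dir = NULL, verbose = FALSE) {
  if (inherits(study, "synthetic_study")) {
    if (missing(drivers)) drivers <- study$drivers
    study <- study$study
  }
  stopifnot(inherits(study, "matched_study"))
  t0 <- Sys.time()
  reduction <- reduce_alterations(study$alterations, drivers,
    min_proportion = min_proportion, min_correlation = min_correlation
  )
  X_all <- reduction$retained
  if (ncol(X_all) == 0L) stop("reduction stage removed every alteration")

  compounds <- rownames(study$responses)
  drug_results <- list()
  qc_rows <- list()
  skipped <- character()
  for (d in seq_along(compounds)) {
    cmp <- compounds[d]
    y_full <- study$responses[cmp, ]
    dm <- tryCatch(drop_missing(y_full, X_all), error = function(e) e)
    if (inherits(dm, "error")) {
      warning("skipping compound ", cmp, " at the missingness stage: ", conditionMessage(dm))
      skipped <- c(skipped, cmp)
      next
    }
    fit <- fit_forest(dm$X, dm$y,
      num_trees = num_trees,
      min_node_size = min_node_size, seed = seed + d
    )
    imp <- permutation_importance(fit,
      seed = seed + 1000L * d, alpha = alpha,
      keep_per_tree = FALSE
    )
    res <- list(
      compound = cmp,
      ccc = concordance_result(fit$y, oob_predictions(fit),
        fair_threshold = ccc_threshold
      ),
      mean_auc = fit$mean_auc,
      sample_size = fit$sample_size,
      stability = stability_indicator(fit),
      importance = imp,
      B = fit$B, m = fit$m, seed = fit$seed
    )
    drug_results[[cmp]] <- res
    qc_rows[[cmp]] <- cbind(
      compound = cmp,
      missingness_impact(X_all, dm$kept,
        min_proportion = min_proportion,
        min_correlation = min_correlation
      )
    )
    if (verbose) {
      message(sprintf(
        "[%d/%d] %s: n = %d, CCC = %.1f, %d significant alteration(s)",
        d, length(compounds), cmp, res$sample_size, res$ccc$ccc,
        sum(imp$significant)
      ))
    }
  }
  if (!length(drug_results)) stop("no compound could be modelled")

  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  importance_tables <- lapply(drug_results, `[[`, "importance")
  report1 <- build_report1(drug_results, threshold = ccc_threshold)
  report2 <- build_report2(report1, importance_tables, reduction$clusters)
  candidates <- candidate_pairs(report1, importance_tables, auc_tolerance)
  interactions <- lapply(seq_len(nrow(candidates)), function(k) {
    row <- candidates[k, ]
    interaction_anova(pair_interaction_data(
      study, row$compound_a, row$compound_b,
      row$top_alteration_a, row$top_alteration_b
    ))
  })

  result <- structure(
    list(
      reduction = reduction,
      drug_results = drug_results,
      qc = qc,
      report1 = report1,
      report2 = report2,
      candidates = candidates,
      interactions = interactions,
      skipped = skipped,
      params = list(
        min_proportion = min_proportion, min_correlation = min_correlation,
        num_trees = num_trees, min_node_size = min_node_size,
        seed = seed, ccc_threshold = ccc_threshold,
        auc_tolerance = auc_tolerance, alpha = alpha,
        elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
      )
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pharmacogenomic mining pipeline\n")
  print(x$reduction)
  cat(sprintf(
    " %d compound model(s) (%d skipped), %d in Report 1, %d alteration(s) in Report 2\n",
    length(x$drug_results), length(x$skipped), nrow(x$report1), nrow(x$report2)
  ))
  cat(sprintf(
    " %d candidate pair(s) tested for interaction | elapsed %.1f s\n",
    nrow(x$candidates), x$params$elapsed_sec
  ))
  invisible(x)
}

# CSV/JSON artifact writer; one file per report plus provenance.
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$report1, file.path(out_dir, "report1.csv"), row.names = FALSE)
  write.csv(result$report2, file.path(out_dir, "report2.csv"), row.names = FALSE)
  write.csv(result$qc, file.path(out_dir, "missingness_qc.csv"), row.names = FALSE)
  write.csv(result$candidates, file.path(out_dir, "candidate_pairs.csv"),
    row.names = FALSE
  )
  cl <- result$reduction$clusters
  write.csv(
    data.frame(
      alteration = cl$alteration, cluster_id = cl$cluster_id,
      representative_flag = as.integer(cl$representative)
    ),
    file.path(out_dir, "cluster_map.csv"),
    row.names = FALSE
  )
  for (cmp in names(result$drug_results)) {
    res <- result$drug_results[[cmp]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", cmp)
    write.csv(res$importance,
      file.path(out_dir, paste0("importance_", safe, ".csv")),
      row.names = FALSE
    )
  }
  summaries <- lapply(result$drug_results, function(res) {
    list(
      compound = res$compound, B = res$B, m = res$m, seed = res$seed,
      sample_size = res$sample_size, mean_auc = res$mean_auc,
      ccc = res$ccc$ccc, ci_lower = res$ccc$ci_lower,
      ci_upper = res$ccc$ci_upper, label = res$ccc$label,
      stability = res$stability$value,
      stability_reached = res$stability$reached,
      n_significant = sum(res$importance$significant)
    )
  })
  jsonlite::write_json(unname(summaries),
    file.path(out_dir, "drug_summaries.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (length(result$interactions)) {
    jsonlite::write_json(
      lapply(seq_along(result$interactions), function(k) {
        ir <- result$interactions[[k]]
        list(
          pair = ir$pair, anova = ir$anova,
          t_tests = ir$t_tests, groups = ir$groups
        )
      }),
      file.path(out_dir, "interactions.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    boxes <- do.call(rbind, lapply(result$interactions, function(ir) {
      cbind(pair = paste(ir$pair, collapse = " vs "), ir$groups)
    }))
    write.csv(boxes, file.path(out_dir, "interaction_boxplots.csv"),
      row.names = FALSE
    )
  }
  jsonlite::write_json(
    c(result$params[setdiff(names(result$params), "elapsed_sec")],
      list(
        variance_threshold = result$reduction$params$variance_threshold,
        distance_threshold = result$reduction$params$distance_threshold,
        n_alterations_in = result$reduction$n_input,
        step1_kept = result$reduction$step1_kept,
        step2_excluded = result$reduction$step2_excluded,
        predictors_in_models = result$reduction$step3_clusters,
        n_compounds = length(result$drug_results),
        skipped = result$skipped,
        elapsed_sec = result$params$elapsed_sec,
        r_version = as.character(getRversion())
      )
    ),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
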