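# Tabular reports: compounds with at least fair concordance (Report 1) and
# the alterations that influence them, ranked by significance frequency
# (Report 2).

#' Report 1: compounds with at least fair concordance
#'
#' Keeps the compounds whose lower CCC confidence bound exceeds the
#' threshold, in decreasing order of CCC (ties broken alphabetically), and
#' lists each one's significantly influential alterations in decreasing
#' order of importance.
#'
#' @param drug_results Named list, one element per compound, each a list
#'   with `compound`, `ccc` (a [concordance_result()]), `mean_auc`,
#'   `sample_size` and `importance` (an `importance_table`).
#' @param threshold Lower-CCC-bound inclusion threshold on the x100 scale
#'   (default 20, "at least fair"; lowering it admits less predictable
#'   compounds).
#' @return Data frame with one row per included compound: compound, ccc,
#'   ci_lower, ci_upper, mean_auc, sample_size, n_significant,
#'   significant_alterations (comma-separated, decreasing importance).
#' @export
build_report1 <- function(drug_results, threshold = 20) {
  rows <- lapply(drug_results, function(res) {
    if (res$ccc$ci_lower <= threshold) {
      return(NULL)
    }
    sig <- res$importance[res$importance$significant, , drop = FALSE]
    data.frame(
      compound = res$compound,
      ccc = res$ccc$ccc,
      ci_lower = res$ccc$ci_lower,
      ci_upper = res$ccc$ci_upper,
      mean_auc = res$mean_auc,
      sample_size = res$sample_size,
      n_significant = nrow(sig),
      significant_alterations = paste(sig$alteration, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(
      compound = character(), ccc = numeric(), ci_lower = numeric(),
      ci_upper = numeric(), mean_auc = numeric(), sample_size = integer(),
      n_significant = integer(), significant_alterations = character(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ccc, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report 2: alterations ranked by significance frequency
#'
#' For every alteration significant for at least one Report-1 compound:
#' how many Report-1 compounds it influences (significance frequency), its
#' redundancy cluster (id, size, members — merged alterations count as
#' being as important as their representative), and the influenced
#' compounds in decreasing order of CCC. Rows are sorted by decreasing
#' significance frequency, ties broken alphabetically.
#'
#' @param report1 A [build_report1()] data frame.
#' @param importance_tables Named list of `importance_table`s, at least
#'   covering the Report-1 compounds.
#' @param clusters Cluster map from [step3_redundancy_clusters()] /
#'   [reduce_alterations()].
#' @return Data frame: alteration, significance_frequency, cluster_id,
#'   cluster_size, cluster_members, compounds.
#' @export
build_report2 <- function(report1, importance_tables, clusters) {
  empty <- data.frame(
    alteration = character(), significance_frequency = integer(),
    cluster_id = integer(), cluster_size = integer(),
    cluster_members = character(), compounds = character(),
    stringsAsFactors = FALSE
  )
  if (!nrow(report1)) {
    return(empty)
  }
  hits <- do.call(rbind, lapply(report1$compound, function(cmp) {
    tab <- importance_tables[[cmp]]
    if (is.null(tab)) stop("no importance table for compound ", cmp)
    sig <- tab[tab$significant, , drop = FALSE]
    if (!nrow(sig)) {
      return(NULL)
    }
    data.frame(
      alteration = sig$alteration, compound = cmp,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(hits) || !nrow(hits)) {
    return(empty)
  }
  missing_map <- setdiff(hits$alteration, clusters$alteration)
  if (length(missing_map)) {
    stop(
      "alteration absent from cluster map: ",
      paste(head(missing_map, 5L), collapse = ", ")
    )
  }
  ccc_of <- setNames(report1$ccc, report1$compound)
  rows <- lapply(split(hits, hits$alteration), function(h) {
    cmp <- h$compound[order(-ccc_of[h$compound], h$compound)]
    info <- clusters[clusters$alteration == h$alteration[1], , drop = FALSE]
    members <- clusters$alteration[clusters$cluster_id == info$cluster_id]
    data.frame(
      alteration = h$alteration[1],
      significance_frequency = nrow(h),
      cluster_id = info$cluster_id,
      cluster_size = info$cluster_size,
      cluster_members = paste(members, collapse = ","),
      compounds = paste(cmp, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$significance_frequency, out$alteration), , drop = FALSE]
  rownames(out) <- NULL
  out
}
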