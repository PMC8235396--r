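# Drug-gene interaction screening: pairs of compounds with similar average
# AUC but different most-influential alterations, tested by two-way ANOVA
# on logit-transformed AUC (compound x joint alteration status).

#' Screen Report-1 compound pairs for interaction candidates
#'
#' A candidate pair has similar mean AUCs (absolute difference within the
#' tolerance) but different top alterations (each compound's most important
#' significant alteration). Compounds without any significant alteration
#' cannot nominate a top alteration and are skipped.
#'
#' @param report1 A [build_report1()] data frame.
#' @param importance_tables Named list of `importance_table`s covering the
#'   Report-1 compounds.
#' @param auc_tolerance Maximum absolute mean-AUC difference.
#' @return Data frame of unordered pairs, ascending by AUC difference:
#'   compound_a, compound_b, mean_auc_a, mean_auc_b, auc_difference,
#'   top_alteration_a, top_alteration_b.
#' @export
candidate_pairs <- function(report1, importance_tables, auc_tolerance = 0.02) {
  empty <- data.frame(
    compound_a = character(), compound_b = character(),
    mean_auc_a = numeric(), mean_auc_b = numeric(),
    auc_difference = numeric(),
    top_alteration_a = character(), top_alteration_b = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(report1) < 2L) {
    return(empty)
  }
  top_of <- vapply(report1$compound, function(cmp) {
    tab <- importance_tables[[cmp]]
    sig <- tab[tab$significant, , drop = FALSE]
    if (!nrow(sig)) NA_character_ else sig$alteration[1L] # sorted by imp
  }, character(1))
  eligible <- report1[!is.na(top_of[report1$compound]), , drop = FALSE]
  if (nrow(eligible) < 2L) {
    return(empty)
  }
  pairs <- utils::combn(seq_len(nrow(eligible)), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    a <- eligible[ij[1], ]
    b <- eligible[ij[2], ]
    diff <- abs(a$mean_auc - b$mean_auc)
    if (diff > auc_tolerance || top_of[a$compound] == top_of[b$compound]) {
      return(NULL)
    }
    data.frame(
      compound_a = a$compound, compound_b = b$compound,
      mean_auc_a = a$mean_auc, mean_auc_b = b$mean_auc,
      auc_difference = diff,
      top_alteration_a = top_of[a$compound],
      top_alteration_b = top_of[b$compound],
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$auc_difference, out$compound_a, out$compound_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Logit transform of a dose-response AUC
#'
#' `log(a / (1 - a))` after clipping into `[eps, 1 - eps]`; screens do
#' report AUC = 1 exactly, and clipping bounds its influence.
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @param eps Clipping margin.
#' @return Logit-scale value(s).
#' @export
logit_auc <- function(auc, eps = 1e-3) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) stop("AUC out of range [0, 1]")
  qlogis(pmin(pmax(auc, eps), 1 - eps))
}

#' Assemble the long table for one compound pair
#'
#' Each cell line contributes one row per compound for which its AUC is
#' observed, with the joint status of the two alterations coded as a
#' four-level combination factor (`00`, `10`, `01`, `11`: first digit =
#' alteration A, second = alteration B).
#'
#' @param study A `matched_study`.
#' @param compound_a,compound_b Compound labels (rows of the response
#'   matrix).
#' @param alteration_a,alteration_b Alteration labels (columns of the
#'   alteration matrix).
#' @param eps Clipping margin for [logit_auc()].
#' @return Data frame: cell_line, compound, combination, auc, logit_auc.
#' @export
pair_interaction_data <- function(study, compound_a, compound_b,
                                  alteration_a, alteration_b, eps = 1e-3) {
  stopifnot(inherits(study, "matched_study"))
  for (cmp in c(compound_a, compound_b)) {
    if (!cmp %in% rownames(study$responses)) stop("unknown compound: ", cmp)
  }
  for (alt in c(alteration_a, alteration_b)) {
    if (!alt %in% colnames(study$alterations)) stop("unknown alteration: ", alt)
  }
  combination <- factor(
    paste0(study$alterations[, alteration_a], study$alterations[, alteration_b]),
    levels = c("00", "10", "01", "11")
  )
  out <- do.call(rbind, lapply(c(compound_a, compound_b), function(cmp) {
    auc <- study$responses[cmp, ]
    ok <- !is.na(auc)
    data.frame(
      cell_line = study$cell_lines[ok],
      compound = cmp,
      combination = combination[ok],
      auc = unname(auc[ok]),
      logit_auc = logit_auc(unname(auc[ok]), eps),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Two-way interaction ANOVA on logit AUC
#'
#' Tests the compound x alteration-combination interaction by a nested
#' model comparison: additive model (`logit_auc ~ compound + combination`)
#' against the full factorial (`logit_auc ~ compound * combination`). Under
#' the unbalanced designs real screens produce this is the unambiguous
#' (Type-III-equivalent, order-free) interaction F-test; on balanced data
#' it coincides with the classical two-way ANOVA interaction term.
#' Attaches per-combination two-sample t-tests (compound A vs B within each
#' combination, as in per-panel boxplot annotations) and per-cell summary
#' statistics sufficient to redraw the boxplots.
#'
#' @param data Data frame with columns `logit_auc`, `compound` (2 levels)
#'   and `combination` (factor), e.g. from [pair_interaction_data()].
#' @return An `interaction_result`: list with `pair`, `anova` (F, df1,
#'   df2, p_value), `t_tests` and `groups` data frames.
#' @export
interaction_anova <- function(data) {
  req <- c("logit_auc", "compound", "combination")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "))
  }
  data$compound <- factor(data$compound)
  data$combination <- droplevels(factor(data$combination))
  if (nlevels(data$compound) < 2L) stop("compound factor has a single level")
  if (nlevels(data$combination) < 2L) stop("combination factor has a single level")
  cell_n <- table(data$compound, data$combination)
  if (sum(colSums(cell_n > 0) == 2) < 2L) {
    stop("need at least 2 combinations observed for both compounds")
  }
  additive <- lm(logit_auc ~ compound + combination, data = data)
  full <- lm(logit_auc ~ compound * combination, data = data)
  cmp <- anova(additive, full)
  res <- list(
    pair = levels(data$compound),
    anova = data.frame(
      F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
      p_value = cmp$`Pr(>F)`[2]
    ),
    t_tests = do.call(rbind, lapply(levels(data$combination), function(lv) {
      sub <- data[data$combination == lv, ]
      ns <- table(sub$compound)
      p <- if (all(ns >= 2)) {
        tryCatch(
          t.test(logit_auc ~ compound, data = sub)$p.value,
          error = function(e) NA_real_
        )
      } else {
        NA_real_
      }
      data.frame(
        combination = lv, n_a = as.integer(ns[1]), n_b = as.integer(ns[2]),
        p_value = p, stringsAsFactors = FALSE
      )
    })),
    groups = do.call(rbind, lapply(split(
      data,
      list(data$compound, data$combination)
    ), function(g) {
      if (!nrow(g)) {
        return(NULL)
      }
      q <- quantile(g$logit_auc, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      inlier <- g$logit_auc[g$logit_auc >= q[1] - 1.5 * iqr &
        g$logit_auc <= q[3] + 1.5 * iqr]
      data.frame(
        compound = as.character(g$compound[1]),
        combination = as.character(g$combination[1]),
        n = nrow(g),
        mean = mean(g$logit_auc), median = q[2],
        q25 = q[1], q75 = q[3],
        whisker_lo = min(inlier), whisker_hi = max(inlier),
        stringsAsFactors = FALSE
      )
    }))
  )
  rownames(res$groups) <- NULL
  class(res) <- "interaction_result"
  res
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "Drug-gene interaction test: %s vs %s\n",
    x$pair[1], x$pair[2]
  ))
  cat(sprintf(
    " interaction F(%d, %d) = %.2f, p = %.3g\n",
    x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value
  ))
  invisible(x)
}
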