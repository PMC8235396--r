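# Independent oracles and fixture builders shared across test files.

# Labelled binary matrix in the package's cells x alterations orientation.
toy_alterations <- function(values, n_cells = nrow(values)) {
  x <- as.matrix(values)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- sprintf("CL%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("G%03d_MUT", seq_len(ncol(x)))
  x
}

random_alterations <- function(n, p, prevalence = NULL) {
  if (is.null(prevalence)) prevalence <- runif(p, 0.2, 0.8)
  toy_alterations(vapply(prevalence, function(q) rbinom(n, 1L, q), integer(n)))
}

# Brute-force complete-linkage agglomeration: merge the closest cluster
# pair (ties broken by lexicographically smallest member indices, which the
# scan order realizes) while the complete-linkage distance stays at or
# below the cut height. Returns memberships renumbered by first appearance.
oracle_complete_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    bestd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < bestd - 1e-12) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  mem <- integer(n)
  for (g in seq_along(clusters)) mem[clusters[[g]]] <- g
  match(mem, unique(mem))
}

# Single-sample regression-tree prediction driven by ranger::treeInfo,
# independent of the package's flattened-tree C++ traversal.
treeinfo_predict <- function(info, x) {
  node <- 1L
  repeat {
    row <- info[node, ]
    if (row$terminal) {
      return(row$prediction)
    }
    nxt <- if (x[[row$splitvarName]] <= row$splitval) row$leftChild else row$rightChild
    node <- which(info$nodeID == nxt)
  }
}

# Small deterministic 2-tree forest on <= 8 samples with hand-enumerable
# OOB sets, used by the Eq.-oracle tests.
toy_forest <- function() {
  set.seed(3)
  n <- 8L
  X <- toy_alterations(matrix(rbinom(n * 3L, 1L, 0.5), n, 3L))
  y <- round(runif(n), 3)
  list(X = X, y = y, fit = fit_forest(X, y, num_trees = 2, min_node_size = 2, seed = 9))
}

# Catalog label of the driver prototype alteration nearest a target
# prevalence (used to plant effects).
nearest_label <- function(config, target, exclude = character()) {
  cat_df <- alteration_catalog(config)
  pool <- cat_df[cat_df$prototype & cat_df$driver & !cat_df$label %in% exclude, ]
  pool$label[which.min(abs(pool$prevalence - target))]
}

null_effects <- function() {
  data.frame(
    drug = character(), alteration = character(), effect = numeric(),
    stringsAsFactors = FALSE
  )
}

# Minimal stand-in for a per-drug pipeline result, for report tests.
fake_drug_result <- function(compound, ccc, lo, hi, mean_auc = 0.9,
                             n = 100L, importance = NULL) {
  if (is.null(importance)) importance <- fake_importance(character())
  list(
    compound = compound,
    ccc = structure(
      list(
        ccc = ccc, ci_lower = lo, ci_upper = hi, n = n,
        label = classify_ccc(ccc), at_least_fair = lo > 20
      ),
      class = "ccc_result"
    ),
    mean_auc = mean_auc, sample_size = n, importance = importance
  )
}

# Importance table with the named alterations significant, in the given
# (decreasing-importance) order; extra non-significant filler rows appended.
fake_importance <- function(significant, filler = c("ZZZ_MUT")) {
  labs <- c(significant, setdiff(filler, significant))
  k <- length(significant)
  out <- data.frame(
    alteration = labs,
    imp = rev(seq_along(labs)) * 0.01,
    sd = 0.001, z = 5, p = 0, p_adj = 0,
    significant = c(rep(TRUE, k), rep(FALSE, length(labs) - k)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("importance_table", "data.frame")
  out
}
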