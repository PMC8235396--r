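# Synthetic pharmacogenomic studies with known ground truth: binary
# alterations over a wide prevalence spectrum (including sub-threshold and
# near-duplicate columns), logit-scale AUC responses with planted
# alteration effects and drug-pair differential effects, and per-drug
# missing-at-random screening gaps. Everything the pipeline consumes can be
# generated here, so every stage is testable without external downloads.

#' Configuration of a synthetic study
#'
#' Defaults describe the package's demo study: 400 cell lines, 60
#' independent alterations with prevalences evenly spaced over
#' \[0.02, 0.5\] (so the variance filter has work to do), three
#' near-duplicate column pairs (flip probability 0.005, hence realized
#' |r| >= 0.95), six drugs with baseline logit-AUC 1.5 (mean AUC around
#' 0.82, as in real screens), logit-scale noise sd 0.1 and 20% per-drug
#' missingness. Two drugs carry a -1-logit effect on distinct
#' prevalence-0.3 alterations (near-identical mean AUCs, different top
#' alterations: the planted interaction pair), one drug a milder
#' -0.5-logit effect at prevalence 0.2, and three drugs are pure noise.
#'
#' @param n_cell_lines Number of cell lines.
#' @param n_alterations Number of independent (prototype) alterations;
#'   redundant copies are appended on top.
#' @param prevalence_range Range of alteration prevalences, spread evenly
#'   (deterministically) across the prototypes.
#' @param n_redundant_groups Number of near-duplicate groups; prototypes
#'   are the highest-prevalence driver alterations.
#' @param redundant_group_size Total group size (prototype + copies).
#' @param flip_prob Per-entry flip probability when copying a prototype;
#'   tunes the realized within-group |r|.
#' @param n_drugs Number of compounds.
#' @param missing_fraction Per-drug probability that a cell line's AUC is
#'   missing (scalar or length-`n_drugs`), missing completely at random.
#' @param baseline_logit Baseline logit-AUC per drug (scalar or vector).
#' @param noise_sd Gaussian noise sd on the logit scale.
#' @param effects Data frame (drug, alteration, effect): additive main
#'   effects on the logit-AUC scale. `NULL` installs the demo effects
#'   described above; use a zero-row data frame for a global null.
#' @param interactions Data frame (drug_a, drug_b, alteration, effect):
#'   `drug_b` receives an additional `effect` x alteration term that
#'   `drug_a` does not — a planted differential (interaction) effect for
#'   the pair. Default: none (the demo pair's interaction arises from its
#'   crossed main effects).
#' @param driver_fraction Fraction of prototype genes included in the
#'   generated driver list (every fifth gene is held out, deterministically).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cell_lines = 400, n_alterations = 60,
                             prevalence_range = c(0.02, 0.5),
                             n_redundant_groups = 3, redundant_group_size = 2,
                             flip_prob = 0.005,
                             n_drugs = 6, missing_fraction = 0.2,
                             baseline_logit = 1.5, noise_sd = 0.1,
                             effects = NULL, interactions = NULL,
                             driver_fraction = 0.8) {
  stopifnot(
    n_cell_lines >= 10, n_alterations >= 1,
    length(prevalence_range) == 2,
    prevalence_range[1] > 0, prevalence_range[2] < 1,
    prevalence_range[1] <= prevalence_range[2],
    n_redundant_groups >= 0, redundant_group_size >= 2,
    flip_prob >= 0, flip_prob <= 1,
    all(missing_fraction >= 0), all(missing_fraction < 1),
    noise_sd >= 0
  )
  if (n_drugs < 1) stop("config needs at least one drug")
  if (n_redundant_groups > n_alterations) {
    stop("infeasible config: more redundant groups than prototype alterations")
  }
  cfg <- structure(
    list(
      n_cell_lines = as.integer(n_cell_lines),
      n_alterations = as.integer(n_alterations),
      prevalence_range = prevalence_range,
      n_redundant_groups = as.integer(n_redundant_groups),
      redundant_group_size = as.integer(redundant_group_size),
      flip_prob = flip_prob,
      n_drugs = as.integer(n_drugs),
      missing_fraction = rep_len(missing_fraction, n_drugs),
      baseline_logit = rep_len(baseline_logit, n_drugs),
      noise_sd = noise_sd,
      driver_fraction = driver_fraction
    ),
    class = "synthetic_config"
  )
  cfg$effects <- if (is.null(effects)) default_demo_effects(cfg) else effects
  cfg$interactions <- if (is.null(interactions)) {
    data.frame(
      drug_a = character(), drug_b = character(),
      alteration = character(), effect = numeric(),
      stringsAsFactors = FALSE
    )
  } else {
    interactions
  }
  validate_effect_tables(cfg)
  cfg
}

#' Catalog of the alterations a configuration generates
#'
#' The label, gene, prevalence, driver status and redundancy group of every
#' column [generate_alterations()] will produce. Prevalences and labels are
#' deterministic given the configuration (only the realized 0/1 draws
#' depend on the seed), so planted effects can target a label by
#' prevalence.
#'
#' @param config A `synthetic_config`.
#' @return Data frame: label, gene, prevalence, driver, group (`NA` for
#'   independent columns), prototype (logical).
#' @export
alteration_catalog <- function(config) {
  n <- config$n_alterations
  idx <- seq_len(n)
  gene <- sprintf("G%03d", idx)
  suffix <- c("MUT", "DEL", "AMP")[(idx - 1L) %% 3L + 1L]
  prevalence <- if (n == 1L) {
    mean(config$prevalence_range)
  } else {
    seq(config$prevalence_range[1], config$prevalence_range[2], length.out = n)
  }
  driver <- idx %% 5L != 0L | config$driver_fraction >= 1
  cat_df <- data.frame(
    label = paste0(gene, "_", suffix), gene = gene,
    prevalence = prevalence, driver = driver,
    group = NA_integer_, prototype = TRUE,
    stringsAsFactors = FALSE
  )
  if (config$n_redundant_groups > 0L) {
    # prototypes: highest-prevalence driver alterations
    proto <- rev(idx[driver])
    proto <- proto[seq_len(config$n_redundant_groups)]
    cat_df$group[proto] <- seq_along(proto)
    copies <- do.call(rbind, lapply(seq_along(proto), function(g) {
      i <- proto[g]
      k <- seq_len(config$redundant_group_size - 1L)
      data.frame(
        label = sprintf("%s.R%d_%s", gene[i], k, suffix[i]),
        gene = gene[i], prevalence = prevalence[i], driver = driver[i],
        group = g, prototype = FALSE, stringsAsFactors = FALSE
      )
    }))
    cat_df <- rbind(cat_df, copies)
  }
  cat_df
}

# Demo effect table: two strongly determined drugs with distinct top
# alterations and near-identical mean AUC, one moderate drug, rest null.
default_demo_effects <- function(config) {
  cat_df <- alteration_catalog(config)
  usable <- cat_df[cat_df$prototype & cat_df$driver & cat_df$prevalence >= 0.1, ]
  n_eff <- min(3L, config$n_drugs, nrow(usable))
  if (n_eff == 0L) {
    return(data.frame(
      drug = character(), alteration = character(), effect = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  pick <- function(target, exclude) {
    pool <- usable[!usable$label %in% exclude, ]
    pool$label[which.min(abs(pool$prevalence - target))]
  }
  # adjacent prevalences for the paired drugs keep their mean AUCs within
  # the candidate screen's tolerance across sampling noise; -1-logit
  # effects keep that noise small while still dominating the 0.1 noise sd
  a <- pick(0.30, character())
  b <- pick(0.31, a)
  c <- pick(0.20, c(a, b))
  drugs <- paste0("drug_", seq_len(config$n_drugs))
  data.frame(
    drug = drugs[seq_len(n_eff)],
    alteration = c(a, b, c)[seq_len(n_eff)],
    effect = c(-1, -1, -0.5)[seq_len(n_eff)],
    stringsAsFactors = FALSE
  )
}

validate_effect_tables <- function(config) {
  cat_df <- alteration_catalog(config)
  drugs <- paste0("drug_", seq_len(config$n_drugs))
  eff <- config$effects
  if (nrow(eff)) {
    stopifnot(all(c("drug", "alteration", "effect") %in% names(eff)))
    if (!all(eff$drug %in% drugs)) stop("effect table references unknown drug")
    if (!all(eff$alteration %in% cat_df$label)) {
      stop("effect table references unknown alteration")
    }
    if (!all(is.finite(eff$effect))) stop("non-finite effect")
  }
  ia <- config$interactions
  if (nrow(ia)) {
    stopifnot(all(c("drug_a", "drug_b", "alteration", "effect") %in% names(ia)))
    if (!all(c(ia$drug_a, ia$drug_b) %in% drugs)) {
      stop("interaction table references unknown drug")
    }
    if (!all(ia$alteration %in% cat_df$label)) {
      stop("interaction table references unknown alteration")
    }
    if (!all(is.finite(ia$effect))) stop("non-finite interaction effect")
  }
  invisible(config)
}

#' Generate the binary alteration matrix of a synthetic study
#'
#' Independent prototype columns are drawn at the catalog prevalences;
#' redundant-group members copy their prototype and flip each entry with
#' the configured probability. Cell lines get CCLE-style
#' `SAMPLE_TISSUE` names. Realized within-group correlations are attached
#' as the `redundant_groups` attribute.
#'
#' @param config A `synthetic_config`.
#' @param seed RNG seed (mandatory).
#' @return Alteration matrix (cell lines x alterations) with a
#'   `redundant_groups` attribute (prototype, member, realized_r).
#' @export
generate_alterations <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cat_df <- alteration_catalog(config)
  n <- config$n_cell_lines
  tissues <- c("LUNG", "SKIN", "BREAST", "OVARY", "PANCREAS")
  cells <- sprintf("CL%04d_%s", seq_len(n), sample(tissues, n, replace = TRUE))
  X <- matrix(0L, n, nrow(cat_df), dimnames = list(cells, cat_df$label))
  for (i in which(cat_df$prototype)) {
    X[, i] <- rbinom(n, 1L, cat_df$prevalence[i])
  }
  groups <- NULL
  for (i in which(!cat_df$prototype)) {
    proto_label <- cat_df$label[cat_df$prototype & cat_df$group %in% cat_df$group[i]]
    flips <- rbinom(n, 1L, config$flip_prob)
    X[, i] <- as.integer(xor(X[, proto_label], flips))
    r <- if (var(X[, i]) > 0 && var(X[, proto_label]) > 0) {
      cor(X[, i], X[, proto_label])
    } else {
      NA_real_
    }
    groups <- rbind(groups, data.frame(
      prototype = proto_label, member = cat_df$label[i], realized_r = r,
      stringsAsFactors = FALSE
    ))
  }
  attr(X, "redundant_groups") <- groups
  assert_alteration_matrix(X)
  X
}

#' Generate AUC responses for a synthetic study
#'
#' For each drug and cell line, logit-AUC = baseline + sum of main effects
#' x alteration + sum of differential (interaction) effects x alteration +
#' Gaussian noise; the AUC is the inverse logit. A per-drug MCAR mask is
#' then applied.
#'
#' @param alterations Matrix from [generate_alterations()].
#' @param config The same `synthetic_config`.
#' @param seed RNG seed (mandatory).
#' @return List with `responses` (compounds x cell lines, plain uppercase
#'   cell names, `NA` where unscreened) and `truth` (per-drug effect
#'   matrix, influential table, interacting pairs).
#' @export
generate_responses <- function(alterations, config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nrow(alterations)
  drugs <- paste0("drug_", seq_len(config$n_drugs))
  labels <- colnames(alterations)
  # per-drug total effect vectors (main + differential)
  E <- matrix(0, config$n_drugs, length(labels), dimnames = list(drugs, labels))
  eff <- config$effects
  for (k in seq_len(nrow(eff))) {
    E[eff$drug[k], eff$alteration[k]] <- E[eff$drug[k], eff$alteration[k]] + eff$effect[k]
  }
  ia <- config$interactions
  for (k in seq_len(nrow(ia))) {
    E[ia$drug_b[k], ia$alteration[k]] <- E[ia$drug_b[k], ia$alteration[k]] + ia$effect[k]
  }
  A <- alterations
  storage.mode(A) <- "double"
  lin <- sweep(A %*% t(E), 2L, config$baseline_logit, "+") # n x drugs
  lin <- lin + matrix(rnorm(n * config$n_drugs, sd = config$noise_sd), n)
  auc <- t(plogis(lin))
  rownames(auc) <- drugs
  colnames(auc) <- normalize_cell_line_names(rownames(alterations),
    strip_tissue_suffix = TRUE
  )
  for (d in seq_len(config$n_drugs)) {
    auc[d, rbinom(n, 1L, config$missing_fraction[d]) == 1L] <- NA_real_
  }
  # pairs whose per-drug effect vectors differ: true drug x gene interactions
  pairs <- NULL
  if (config$n_drugs >= 2L) {
    idx <- utils::combn(config$n_drugs, 2L)
    differ <- apply(idx, 2L, function(ij) any(E[ij[1], ] != E[ij[2], ]))
    if (any(differ)) {
      pairs <- data.frame(
        drug_a = drugs[idx[1, differ]], drug_b = drugs[idx[2, differ]],
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    responses = auc,
    truth = list(
      effect_matrix = E,
      influential = config$effects,
      differential = config$interactions,
      interacting_pairs = pairs
    )
  )
}

#' Generate a complete matched synthetic study
#'
#' Composes [generate_alterations()] and [generate_responses()], writes
#' nothing, and returns the matched study (the generated alteration and
#' response matrices are pushed through [match_cell_lines()], dog-fooding
#' the normalization), the ground truth, and the generated driver-gene
#' list.
#'
#' @param config A `synthetic_config`.
#' @param seed RNG seed (mandatory); the response generator uses
#'   `seed + 1`.
#' @return A `synthetic_study`: list with `study` (a `matched_study`),
#'   `truth`, `drivers`, `config`, `seed`.
#' @export
make_study <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is mandatory")
  alt <- generate_alterations(config, seed)
  resp <- generate_responses(alt, config, seed + 1L)
  study <- match_cell_lines(alt, resp$responses, strip_tissue_suffix = TRUE)
  cat_df <- alteration_catalog(config)
  truth <- resp$truth
  truth$redundant_groups <- attr(alt, "redundant_groups")
  truth$catalog <- cat_df
  structure(
    list(
      study = study,
      truth = truth,
      drivers = unique(cat_df$gene[cat_df$driver]),
      config = config, seed = seed
    ),
    class = "synthetic_study"
  )
}

#' Write a synthetic study in the pipeline's input formats
#'
#' Dog-foods the parsers: the alteration matrix goes out as GCT, the
#' responses as CSV, the driver genes as a one-per-line list and the truth
#' as JSON.
#'
#' @param x A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    alterations = file.path(dir, "alterations.gct"),
    responses = file.path(dir, "responses.csv"),
    drivers = file.path(dir, "driver_genes.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_alteration_gct(x$study$alterations, paths["alterations"])
  write_response_table(x$study$responses, paths["responses"])
  writeLines(x$drivers, paths["drivers"])
  jsonlite::write_json(
    list(
      seed = x$seed,
      effects = x$truth$influential,
      differential = x$truth$differential,
      interacting_pairs = x$truth$interacting_pairs,
      redundant_groups = x$truth$redundant_groups
    ),
    paths["truth"],
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}
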