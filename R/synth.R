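#' Describe one planted ceRNA axis
#'
#' A planted axis is a (lncRNA, miRNA, mRNA) triple inserted into the
#' synthetic data with known log2 fold changes, a known survival effect and
#' a known diagnostic effect, so that recovery by the pipeline can be
#' scored against ground truth. The sponge sign pattern is enforced:
#' an oncogenic axis is up-lncRNA / down-miRNA / up-mRNA, a suppressive
#' axis is the mirror image, and the lncRNA fold change must reach the
#' two-fold gate (|lfc_lnc| >= 1 on the log2 scale) so the axis is
#' recoverable at all.
#'
#' @param lncrna_id,mirna_id,mrna_id Feature identifiers.
#' @param polarity `"oncogenic"` or `"suppressive"`.
#' @param lfc_lnc,lfc_mir,lfc_mrna Planted log2 fold changes
#'   (case minus control). Signs must match `polarity`.
#' @param hazard_coef Log hazard ratio of the above-median expression group
#'   for the axis mRNA in the simulated survival cohort. Positive values
#'   make high expression risky.
#' @param auc_effect Standardized mean shift (Cohen's d) of tumor versus
#'   normal expression scores; the expected AUC under the equal-variance
#'   binormal model is `pnorm(auc_effect / sqrt(2))`.
#' @return A one-row tibble; bind rows of these to form the
#'   `planted_axes` field of [simulation_config()].
#' @export
planted_axis <- function(lncrna_id, mirna_id, mrna_id,
                         polarity = c("oncogenic", "suppressive"),
                         lfc_lnc, lfc_mir, lfc_mrna,
                         hazard_coef = 0, auc_effect = 0) {
  polarity <- match.arg(polarity)
  signs <- if (polarity == "oncogenic") c(1, -1, 1) else c(-1, 1, -1)
  lfc <- c(lfc_lnc, lfc_mir, lfc_mrna)
  if (any(sign(lfc) != signs)) {
    abort(sprintf(
      "%s axis requires log2FC signs (%s); got (%s).",
      polarity, paste(c("+", "-", "+")[match(signs, c(1, -1, 1))], collapse = ","),
      paste(ifelse(lfc >= 0, "+", "-"), collapse = ",")
    ))
  }
  if (abs(lfc_lnc) < 1) {
    abort("|lfc_lnc| must be >= 1 (log2) so the linear two-fold lncRNA gate is satisfiable.")
  }
  tibble::tibble(
    lncrna_id = as.character(lncrna_id),
    mirna_id = as.character(mirna_id),
    mrna_id = as.character(mrna_id),
    polarity = polarity,
    lfc_lnc = lfc_lnc, lfc_mir = lfc_mir, lfc_mrna = lfc_mrna,
    hazard_coef = hazard_coef, auc_effect = auc_effect
  )
}

#' Default planted axes: three oncogenic and three suppressive
#'
#' Mirrors the design of a study discovering three axes per polarity.
#' Effect sizes are chosen as typical of a strong microarray hit: planted
#' |log2FC| of 1.5-2.5 (3- to 6-fold), a survival log hazard of +/-0.7
#' (hazard ratio around 2, as commonly reported for prognostic lncRNAs in
#' lung cancer) and a diagnostic shift d = 1.19, whose binormal AUC
#' pnorm(1.19/sqrt(2)) ~= 0.80 sits in the middle of the 0.71-0.92 range
#' typical of single-gene lung cancer biomarkers.
#'
#' @return A six-row planted-axes tibble.
#' @export
default_planted_axes <- function() {
  dplyr::bind_rows(
    planted_axis("lnc_ax1", "mir_ax1", "gene_ax1", "oncogenic", 2.0, -2.0, 2.0, 0.7, 1.19),
    planted_axis("lnc_ax2", "mir_ax2", "gene_ax2", "oncogenic", 2.5, -1.5, 1.8, 0.7, 1.19),
    planted_axis("lnc_ax3", "mir_ax3", "gene_ax3", "oncogenic", 1.5, -2.5, 2.2, 0.7, 1.19),
    planted_axis("lnc_ax4", "mir_ax4", "gene_ax4", "suppressive", -2.0, 2.0, -2.0, -0.7, 1.19),
    planted_axis("lnc_ax5", "mir_ax5", "gene_ax5", "suppressive", -1.8, 1.6, -2.4, -0.7, 1.19),
    planted_axis("lnc_ax6", "mir_ax6", "gene_ax6", "suppressive", -2.2, 2.4, -1.6, -0.7, 1.19)
  )
}

#' Configuration for the synthetic tri-omics generator
#'
#' Encodes the study conditions the generator emulates: a two-group
#' (control versus transformed) microarray design with per-feature
#' independent Gaussian noise on log2 intensities, planted ceRNA axes
#' with the sponge sign structure, and interaction tables mixing the
#' planted edges with decoys.
#'
#' @param n_lncrna,n_mirna,n_mrna Features per RNA class (>= number of
#'   planted members of that class).
#' @param n_samples_per_group Arrays per group; 3 per group is a typical
#'   two-group microarray design and is the default.
#' @param planted_axes Tibble of [planted_axis()] rows (default
#'   [default_planted_axes()]).
#' @param noise_sd Standard deviation of the log2-intensity noise; 0 is
#'   accepted as the noiseless limit used for exact recovery checks.
#' @param background_fc_sd Spread of the (mean-zero) log2 fold changes of
#'   non-planted features.
#' @param decoy_edge_count Number of non-axis interaction edges added to
#'   each interaction table.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_lncrna = 50, n_mirna = 50, n_mrna = 50,
                              n_samples_per_group = 3,
                              planted_axes = default_planted_axes(),
                              noise_sd = 0.5,
                              background_fc_sd = 0.25,
                              decoy_edge_count = 100,
                              seed = 1L) {
  n_lncrna <- assert_count(n_lncrna, "n_lncrna")
  n_mirna <- assert_count(n_mirna, "n_mirna")
  n_mrna <- assert_count(n_mrna, "n_mrna")
  n_samples_per_group <- assert_count(n_samples_per_group, "n_samples_per_group")
  decoy_edge_count <- assert_count(decoy_edge_count, "decoy_edge_count", min = 0L)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.numeric(background_fc_sd) || background_fc_sd < 0) {
    abort("`background_fc_sd` must be >= 0.")
  }
  stopifnot(is.data.frame(planted_axes))
  for (col in c("lncrna_id", "mirna_id", "mrna_id")) {
    ids <- planted_axes[[col]]
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicate planted feature IDs in `%s`: %s", col,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
  }
  n_ax <- nrow(planted_axes)
  if (n_lncrna < n_ax || n_mirna < n_ax || n_mrna < n_ax) {
    abort("each class must have at least as many features as planted axes.")
  }
  structure(
    list(
      n_lncrna = n_lncrna, n_mirna = n_mirna, n_mrna = n_mrna,
      n_samples_per_group = n_samples_per_group,
      planted_axes = planted_axes,
      noise_sd = noise_sd, background_fc_sd = background_fc_sd,
      decoy_edge_count = decoy_edge_count,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

class_sizes <- function(config) {
  c(lncRNA = config$n_lncrna, miRNA = config$n_mirna, mRNA = config$n_mrna)
}

planted_ids_for <- function(config, class) {
  switch(class,
    lncRNA = config$planted_axes$lncrna_id,
    miRNA = config$planted_axes$mirna_id,
    mRNA = config$planted_axes$mrna_id
  )
}

planted_lfc_for <- function(config, class) {
  switch(class,
    lncRNA = config$planted_axes$lfc_lnc,
    miRNA = config$planted_axes$lfc_mir,
    mRNA = config$planted_axes$lfc_mrna
  )
}

id_prefix <- c(lncRNA = "lnc", miRNA = "mir", mRNA = "gene")

#' Simulate tri-omics expression matrices with planted ceRNA axes
#'
#' Draws, for each RNA class, a features-by-samples matrix of log2
#' intensities under a two-group design. Each feature has a baseline
#' intensity, a log2 fold change (the planted value for axis members,
#' N(0, background_fc_sd) otherwise) split symmetrically between the two
#' group means, and independent N(0, noise_sd) noise per observation.
#' With `noise_sd = 0` the empirical group-mean difference equals the
#' planted log2FC exactly.
#'
#' @param config A [simulation_config()].
#' @return A `cerna_sim` list with elements `expression` (named list of
#'   three wide tibbles: `feature_id` column then one column per sample),
#'   `groups` (tibble `sample_id`, `group` in control/case), and `truth`
#'   (per-feature truth, the planted axes and their interaction edges).
#' @examples
#' sim <- simulate_expression(simulation_config(seed = 7))
#' sim$expression$miRNA
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  k <- config$n_samples_per_group
  samples <- c(paste0("control_", seq_len(k)), paste0("case_", seq_len(k)))
  groups <- tibble::tibble(
    sample_id = samples,
    group = rep(c("control", "case"), each = k)
  )

  sizes <- class_sizes(config)
  expression <- list()
  feature_truth <- list()
  for (class in names(sizes)) {
    n <- sizes[[class]]
    planted <- planted_ids_for(config, class)
    ids <- c(planted, setdiff(
      sprintf("%s_%04d", id_prefix[[class]], seq_len(n)), planted
    ))[seq_len(n)]
    lfc <- c(planted_lfc_for(config, class),
             rnorm(n - length(planted), 0, config$background_fc_sd))
    base <- rnorm(n, 8, 1.5)
    mu <- cbind(
      matrix(base - lfc / 2, n, k),
      matrix(base + lfc / 2, n, k)
    )
    mat <- mu + matrix(rnorm(n * 2 * k, 0, config$noise_sd), n, 2 * k)
    colnames(mat) <- samples
    expression[[class]] <- dplyr::bind_cols(
      tibble::tibble(feature_id = ids),
      tibble::as_tibble(mat)
    )
    feature_truth[[class]] <- tibble::tibble(
      feature_id = ids, rna_class = class, true_lfc = lfc,
      planted = ids %in% planted,
      axis_id = ifelse(ids %in% planted,
                       paste0("axis_", match(ids, planted)), NA_character_)
    )
  }

  axes <- dplyr::mutate(config$planted_axes,
                        axis_id = paste0("axis_", dplyr::row_number()),
                        .before = 1)
  edges <- dplyr::bind_rows(
    dplyr::transmute(axes, mirna_id = .data$mirna_id,
                     partner_id = .data$lncrna_id, partner_class = "lncRNA",
                     axis_id = .data$axis_id),
    dplyr::transmute(axes, mirna_id = .data$mirna_id,
                     partner_id = .data$mrna_id, partner_class = "mRNA",
                     axis_id = .data$axis_id)
  )
  truth <- structure(
    list(features = dplyr::bind_rows(feature_truth), axes = axes,
         axis_edges = edges, seed = config$seed),
    class = "cerna_truth"
  )
  structure(
    list(expression = expression, groups = groups, truth = truth,
         config = config),
    class = "cerna_sim"
  )
}

#' Simulate miRNA-lncRNA and miRNA-mRNA interaction tables
#'
#' Emulates the union of target-prediction databases: every planted-axis
#' edge is present, plus `decoy_edge_count` decoy edges per table sampled
#' uniformly without replacement from the non-axis (miRNA, partner) pairs.
#' `decoy_scope = "non_de"` restricts decoys to pairs of non-planted
#' features, the regime in which planted-axis recovery is exact; the
#' default `"non_axis"` allows decoys to touch planted features, so a
#' decoy can legitimately complete an extra (true-by-the-rule) triple.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` element of [simulate_expression()] output.
#' @param decoy_scope `"non_axis"` (default) or `"non_de"`.
#' @return Named list of two interaction tibbles (`lncRNA`, `mRNA`), each
#'   with columns `mirna_id`, `partner_id`, `partner_class`, `source`.
#' @export
simulate_interactions <- function(config, truth,
                                  decoy_scope = c("non_axis", "non_de")) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "cerna_truth"))
  decoy_scope <- match.arg(decoy_scope)
  set.seed(config$seed + 1L)

  feats <- truth$features
  mir_ids <- feats$feature_id[feats$rna_class == "miRNA"]
  out <- list()
  for (class in c("lncRNA", "mRNA")) {
    partner_ids <- feats$feature_id[feats$rna_class == class]
    axis_edges <- truth$axis_edges[truth$axis_edges$partner_class == class, ]
    mir_pool <- mir_ids
    partner_pool <- partner_ids
    if (decoy_scope == "non_de") {
      planted <- feats$feature_id[feats$planted]
      mir_pool <- setdiff(mir_pool, planted)
      partner_pool <- setdiff(partner_pool, planted)
    }
    all_pairs <- tidyr::expand_grid(mirna_id = mir_pool, partner_id = partner_pool)
    candidates <- dplyr::anti_join(
      all_pairs, axis_edges[, c("mirna_id", "partner_id")],
      by = c("mirna_id", "partner_id")
    )
    if (config$decoy_edge_count > nrow(candidates)) {
      abort(sprintf(
        "decoy_edge_count (%d) exceeds the %d available non-axis %s pairs.",
        config$decoy_edge_count, nrow(candidates), class
      ))
    }
    decoys <- candidates[sample.int(nrow(candidates), config$decoy_edge_count), ]
    out[[class]] <- dplyr::bind_rows(
      dplyr::transmute(axis_edges, mirna_id = .data$mirna_id,
                       partner_id = .data$partner_id,
                       partner_class = class, source = "planted"),
      dplyr::mutate(decoys, partner_class = class, source = "decoy")
    ) |>
      dplyr::arrange(.data$mirna_id, .data$partner_id)
  }
  out
}

#' Simulate a clinical cohort with planted survival and diagnostic effects
#'
#' Builds a cohort carrying one expression column per planted-axis
#' component plus overall-survival and tumor/normal diagnosis fields.
#' Within each axis the three component expressions share a standard
#' normal latent factor (signed by the component's direction) plus
#' independent N(0, expr_noise_sd) noise, so they are strongly
#' inter-correlated as sponge partners are. Tumor subjects are shifted by
#' `auc_effect` common-SD units along each component's direction, giving
#' an expected AUC of `pnorm(auc_effect/sqrt(2))` under the equal-variance
#' binormal model. Survival times are exponential with log hazard equal to
#' the sum over axes of `hazard_coef` times the indicator of above-median
#' expression of the axis mRNA; censoring is independent exponential
#' calibrated to the requested overall rate.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` element of [simulate_expression()] output.
#' @param n_subjects Cohort size (balanced normal/tumor labels).
#' @param censoring_rate Target fraction censored, in [0, 1).
#' @param baseline_hazard Events per month in the reference group.
#' @param expr_noise_sd Component-specific expression noise SD.
#' @param seed Seed for this generator (defaults to `config$seed + 2`).
#' @return A `cerna_clinical` tibble: `subject_id`, `time` (months),
#'   `event` (1 = death), `label` (normal/tumor), one column per gene.
#' @export
simulate_clinical <- function(config, truth, n_subjects = 200,
                              censoring_rate = 0.2, baseline_hazard = 0.05,
                              expr_noise_sd = 0.5, seed = config$seed + 2L) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "cerna_truth"))
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 2L)
  if (!is.numeric(censoring_rate) || censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must lie in [0, 1).")
  }
  set.seed(seed)

  axes <- truth$axes
  label <- rep(c("normal", "tumor"), length.out = n_subjects)
  is_tumor <- label == "tumor"
  sigma_total <- sqrt(1 + expr_noise_sd^2)

  expr_cols <- list()
  loghaz <- numeric(n_subjects)
  for (i in seq_len(nrow(axes))) {
    ax <- axes[i, ]
    signs <- if (ax$polarity == "oncogenic") c(1, -1, 1) else c(-1, 1, -1)
    comp_ids <- c(ax$lncrna_id, ax$mirna_id, ax$mrna_id)
    u <- rnorm(n_subjects)
    for (j in 1:3) {
      expr_cols[[comp_ids[j]]] <- 8 + signs[j] * u +
        rnorm(n_subjects, 0, expr_noise_sd) +
        signs[j] * ax$auc_effect * sigma_total * is_tumor
    }
    high <- expr_cols[[ax$mrna_id]] > median(expr_cols[[ax$mrna_id]])
    loghaz <- loghaz + ax$hazard_coef * high
  }

  rate <- baseline_hazard * exp(loghaz)
  t_event <- rexp(n_subjects, rate)
  if (censoring_rate > 0) {
    cens_rate <- mean(rate) * censoring_rate / (1 - censoring_rate)
    t_cens <- rexp(n_subjects, cens_rate)
  } else {
    t_cens <- rep(Inf, n_subjects)
  }

  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("subj_%04d", seq_len(n_subjects)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      label = label
    ),
    tibble::as_tibble(expr_cols)
  )
  class(out) <- c("cerna_clinical", class(out))
  attr(out, "seed") <- seed
  out
}

#' Write a simulated dataset to TSV files
#'
#' Emits the expression matrix per class, the sample-group map, the two
#' interaction tables, the clinical cohort and a YAML ground-truth record
#' (including the seed, for provenance) into `outdir`.
#'
#' @param sim A `cerna_sim` from [simulate_expression()].
#' @param interactions Output of [simulate_interactions()] (optional).
#' @param clinical Output of [simulate_clinical()] (optional).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, interactions = NULL, clinical = NULL, outdir) {
  stopifnot(inherits(sim, "cerna_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (class in names(sim$expression)) {
    p <- file.path(outdir, paste0("expression_", class, ".tsv"))
    write_tsv_quiet(sim$expression[[class]], p)
    paths[paste0("expression_", class)] <- p
  }
  paths["groups"] <- write_tsv_quiet(sim$groups, file.path(outdir, "groups.tsv"))
  if (!is.null(interactions)) {
    for (class in names(interactions)) {
      p <- file.path(outdir, paste0("interactions_", class, ".tsv"))
      write_tsv_quiet(interactions[[class]], p)
      paths[paste0("interactions_", class)] <- p
    }
  }
  if (!is.null(clinical)) {
    paths["clinical"] <- write_tsv_quiet(
      tibble::as_tibble(clinical), file.path(outdir, "clinical.tsv")
    )
  }
  truth_path <- file.path(outdir, "ground_truth.yaml")
  yaml::write_yaml(
    list(
      seed = sim$truth$seed,
      axes = lapply(seq_len(nrow(sim$truth$axes)), function(i) {
        as.list(sim$truth$axes[i, ])
      }),
      features = lapply(seq_len(nrow(sim$truth$features)), function(i) {
        as.list(sim$truth$features[i, ])
      })
    ),
    truth_path
  )
  paths["ground_truth"] <- truth_path
  invisible(paths)
}
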