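#' Configuration of an end-to-end ceRNA analysis run
#'
#' Bundles the inputs and options of [run_pipeline()]. Data come either
#' from the synthetic generator (`simulation`) or from TSV files on disk
#' (`expression_paths`/`groups_path`/`interaction_paths`/`clinical_path`);
#' the enrichment and clinical stages are optional and run only when
#' their inputs are present.
#'
#' @param simulation A [simulation_config()] (default) or `NULL` when
#'   reading files.
#' @param expression_paths Named list/vector of TSVs for `lncRNA`,
#'   `miRNA`, `mRNA` (wide: `feature_id` + sample columns).
#' @param groups_path Two-column TSV `sample_id`, `group`.
#' @param interaction_paths Named list/vector of TSVs `lncRNA`, `mRNA`
#'   (columns `mirna_id`, `partner_id`, optional `source`).
#' @param clinical_path Clinical cohort TSV, or `NULL`. With a
#'   `simulation`, `clinical = TRUE` simulates the cohort instead.
#' @param clinical Logical: run the clinical stage (with a simulation,
#'   generates the cohort).
#' @param annotation_path Optional GMT file for the enrichment stage.
#' @param thresholds A [de_thresholds()].
#' @param polarities Polarities to mine (default both).
#' @param top_k Axes retained per polarity (default 3).
#' @param partner_min_fc,lnc_min_fc Linear fold-change gates, as in
#'   [match_candidate_mirnas()] and [rank_axes()].
#' @param decoy_scope Passed to [simulate_interactions()].
#' @param n_subjects,censoring_rate Clinical-simulation options.
#' @param outdir Optional directory; when set, every stage writes its
#'   table there and a run manifest is emitted.
#' @param seed Seed for the synthetic stages (overrides the simulation
#'   config's seed so one knob controls the run).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            expression_paths = NULL, groups_path = NULL,
                            interaction_paths = NULL, clinical_path = NULL,
                            clinical = TRUE, annotation_path = NULL,
                            thresholds = de_thresholds(),
                            polarities = c("oncogenic", "suppressive"),
                            top_k = 3, partner_min_fc = 2, lnc_min_fc = 2,
                            decoy_scope = "non_axis",
                            n_subjects = 200, censoring_rate = 0.2,
                            outdir = NULL, seed = NULL) {
  if (is.null(simulation)) {
    for (p in c(unlist(expression_paths), groups_path,
                unlist(interaction_paths), clinical_path, annotation_path)) {
      if (!is.null(p) && !file.exists(p)) abort(sprintf("input not found: %s", p))
    }
  } else {
    stopifnot(inherits(simulation, "simulation_config"))
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
  }
  structure(
    list(simulation = simulation, expression_paths = expression_paths,
         groups_path = groups_path, interaction_paths = interaction_paths,
         clinical_path = clinical_path, clinical = clinical,
         annotation_path = annotation_path, thresholds = thresholds,
         polarities = match.arg(polarities, several.ok = TRUE),
         top_k = top_k, partner_min_fc = partner_min_fc,
         lnc_min_fc = lnc_min_fc, decoy_scope = decoy_scope,
         n_subjects = n_subjects, censoring_rate = censoring_rate,
         outdir = outdir,
         seed = if (is.null(simulation)) seed else simulation$seed),
    class = "pipeline_config"
  )
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full ceRNA discovery pipeline
#'
#' Executes, in order: data acquisition (simulation or TSV input),
#' differential expression per RNA class, candidate-miRNA matching and
#' axis assembly/ranking per polarity, optional term enrichment of the
#' DE mRNAs, and optional per-axis clinical validation. Stage progress is
#' logged to standard error; tables are written to `outdir` when set,
#' together with a YAML run manifest recording the seed, thresholds and
#' per-stage counts. A failing stage aborts with the stage named; outputs
#' already written are retained.
#'
#' @param config A [pipeline_config()], or the path to a YAML file of
#'   its fields (with `simulation` given as a list of
#'   [simulation_config()] arguments).
#' @return A `cerna_pipeline` list: `sim` (when simulated), `de` (named
#'   list of `de_table`s), `axes` (named list per polarity, ranked),
#'   `enrichment`, `clinical_reports` (list per axis), `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(
#'   simulation = simulation_config(noise_sd = 0.3, seed = 11)
#' ))
#' res$axes$oncogenic
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$simulation)) {
      if (!is.null(raw$simulation$planted_axes)) {
        raw$simulation$planted_axes <-
          purrr::map_dfr(raw$simulation$planted_axes,
                         ~ do.call(planted_axis, .x))
      }
      raw$simulation <- do.call(simulation_config, raw$simulation)
    }
    if (!is.null(raw$thresholds)) {
      raw$thresholds <- do.call(de_thresholds, raw$thresholds)
    }
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, name) {
    if (!is.null(outdir)) write_tsv_quiet(tibble::as_tibble(tbl),
                                          file.path(outdir, name))
  }
  counts <- list()

  # data stage
  sim <- NULL; clinical_tbl <- NULL
  if (!is.null(config$simulation)) {
    data <- run_stage("simulate", {
      sim <- simulate_expression(config$simulation)
      inter <- simulate_interactions(config$simulation, sim$truth,
                                     decoy_scope = config$decoy_scope)
      if (isTRUE(config$clinical)) {
        clinical_tbl <- simulate_clinical(
          config$simulation, sim$truth,
          n_subjects = config$n_subjects,
          censoring_rate = config$censoring_rate
        )
      }
      list(expression = sim$expression, groups = sim$groups,
           interactions = inter, clinical = clinical_tbl)
    })
    sim <- sim
  } else {
    data <- run_stage("read-input", {
      expression <- lapply(config$expression_paths, function(p) {
        readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
      })
      interactions <- purrr::imap(config$interaction_paths, function(p, cls) {
        read_interactions(p, partner_class = cls)
      })
      clinical <- if (!is.null(config$clinical_path)) {
        readr::read_tsv(config$clinical_path, show_col_types = FALSE,
                        progress = FALSE)
      }
      list(expression = expression,
           groups = readr::read_tsv(config$groups_path, show_col_types = FALSE,
                                    progress = FALSE),
           interactions = interactions, clinical = clinical)
    })
    clinical_tbl <- data$clinical
  }
  stage_log("data", "expression: %s",
            paste(sprintf("%s x %d features", names(data$expression),
                          vapply(data$expression, nrow, 1L)), collapse = ", "))

  # differential expression
  de <- run_stage("diffexpr", {
    purrr::imap(data$expression, function(expr, class) {
      call_de(expr, data$groups, rna_class = class,
              thresholds = config$thresholds)
    })
  })
  for (class in names(de)) {
    cnt <- de_counts(de[[class]])
    counts[[paste0("de_", class)]] <-
      list(up = cnt$n_up, down = cnt$n_down, total = cnt$n_de)
    stage_log("diffexpr", "%s: %d up, %d down of %d features",
              class, cnt$n_up, cnt$n_down, cnt$n_features)
    emit(tidy(de[[class]]), paste0("de_", class, ".tsv"))
    emit(volcano_table(de[[class]]), paste0("volcano_", class, ".tsv"))
  }

  # axis assembly and ranking
  axes <- run_stage("axes", {
    purrr::set_names(config$polarities) |>
      purrr::map(function(pol) {
        cand <- match_candidate_mirnas(
          de$miRNA, de$lncRNA, de$mRNA,
          data$interactions$lncRNA, data$interactions$mRNA,
          polarity = pol, partner_min_fc = config$partner_min_fc
        )
        ranked <- rank_axes(assemble_axes(cand), top_k = config$top_k,
                            lnc_min_fc = config$lnc_min_fc)
        list(candidates = cand, ranked = ranked)
      })
  })
  for (pol in names(axes)) {
    ranked <- axes[[pol]]$ranked
    counts[[paste0("axes_", pol)]] <-
      list(candidates = nrow(axes[[pol]]$candidates), axes = nrow(ranked))
    stage_log("axes", "%s: %d candidate miRNAs, %d ranked axes",
              pol, nrow(axes[[pol]]$candidates), nrow(ranked))
    emit(ranked, paste0("axes_", pol, ".tsv"))
    if (!is.null(outdir) && nrow(ranked) > 0) {
      export_network(ranked,
                     sif = file.path(outdir, paste0("network_", pol, ".sif")),
                     graphml = file.path(outdir, paste0("network_", pol, ".graphml")))
    }
  }

  # enrichment (optional)
  enrichment <- NULL
  if (!is.null(config$annotation_path)) {
    enrichment <- run_stage("enrich", {
      annot <- read_gmt(config$annotation_path)
      universe <- data$expression$mRNA$feature_id
      query <- de$mRNA$feature_id[de$mRNA$direction != "ns"]
      hypergeom_enrich(query, annot, universe = universe)
    })
    counts$enrich <- list(terms = nrow(enrichment),
                          significant = sum(enrichment$p_value < 0.05))
    stage_log("enrich", "%d terms, %d at p < 0.05",
              nrow(enrichment), sum(enrichment$p_value < 0.05))
    emit(enrichment, "enrichment.tsv")
  }

  # clinical validation (optional)
  clinical_reports <- NULL
  if (!is.null(clinical_tbl)) {
    clinical_reports <- run_stage("clinical", {
      purrr::imap(axes, function(ax, pol) {
        ranked <- ax$ranked
        purrr::map_dfr(seq_len(nrow(ranked)), function(i) {
          ids <- c(ranked$lncrna_id[i], ranked$mirna_id[i], ranked$mrna_id[i])
          if (!all(ids %in% names(clinical_tbl))) return(tibble::tibble())
          dplyr::mutate(module_report(ranked[i, ], clinical_tbl),
                        polarity = pol, rank = ranked$rank[i], .before = 1)
        })
      })
    })
    n_rows <- sum(vapply(clinical_reports, nrow, 1L))
    counts$clinical <- list(component_rows = n_rows)
    stage_log("clinical", "%d component validation rows", n_rows)
    for (pol in names(clinical_reports)) {
      if (nrow(clinical_reports[[pol]]) > 0) {
        emit(clinical_reports[[pol]], paste0("clinical_", pol, ".tsv"))
      }
    }
  }

  manifest <- list(
    package = "ceRNAxis",
    version = as.character(utils::packageVersion("ceRNAxis")),
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    top_k = config$top_k,
    partner_min_fc = config$partner_min_fc,
    lnc_min_fc = config$lnc_min_fc,
    stage_counts = counts
  )
  if (!is.null(outdir)) {
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  structure(
    list(sim = sim, de = de, axes = purrr::map(axes, "ranked"),
         candidates = purrr::map(axes, "candidates"),
         enrichment = enrichment, clinical_reports = clinical_reports,
         manifest = manifest),
    class = "cerna_pipeline"
  )
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("ceRNA discovery pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  for (class in names(x$de)) {
    cnt <- de_counts(x$de[[class]])
    cat(sprintf("  DE %s: %d up, %d down\n", class, cnt$n_up, cnt$n_down))
  }
  for (pol in names(x$axes)) {
    cat(sprintf("  %s axes (top %d): %d\n", pol,
                x$manifest$top_k, nrow(x$axes[[pol]])))
  }
  invisible(x)
}
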