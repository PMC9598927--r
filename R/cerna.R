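#' Read and validate a miRNA interaction table
#'
#' @param path TSV with columns `mirna_id`, `partner_id` and optionally
#'   `partner_class`, `source`.
#' @param partner_class Class to assign when the file lacks the column.
#' @return Interaction tibble with all four columns.
#' @export
read_interactions <- function(path, partner_class = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("mirna_id", "partner_id") %in% names(tbl)))
  if (!"partner_class" %in% names(tbl)) {
    if (is.null(partner_class)) abort("supply `partner_class` for a two-column table.")
    tbl$partner_class <- partner_class
  }
  if (!"source" %in% names(tbl)) tbl$source <- "user"
  validate_interactions(tbl)
}

validate_interactions <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!"source" %in% names(edges)) edges$source <- "user"
  cls <- dplyr::distinct(edges, .data$partner_id, .data$partner_class)
  if (anyDuplicated(cls$partner_id)) {
    abort("`partner_class` is inconsistent for at least one partner_id.")
  }
  edges
}

# collapse duplicate (miRNA, partner) rows across source databases,
# keeping the number and identity of distinct supporting sources
collapse_edges <- function(edges, min_sources = 1) {
  edges |>
    dplyr::mutate(mirna_key = normalize_mirna_id(.data$mirna_id)) |>
    dplyr::group_by(.data$mirna_key, .data$partner_id) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source),
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_sources >= min_sources)
}

required_directions <- function(polarity) {
  if (polarity == "oncogenic") {
    c(mirna = "down", partner = "up")
  } else {
    c(mirna = "up", partner = "down")
  }
}

partner_records <- function(de_partners, edges, partner_dir, min_abs_fc) {
  de_partners |>
    dplyr::filter(.data$direction == partner_dir,
                  abs(.data$fold_change) >= min_abs_fc) |>
    dplyr::select("feature_id", "log2fc", "fold_change", "p_value", "fdr") |>
    dplyr::inner_join(edges, by = c(feature_id = "partner_id")) |>
    dplyr::rename(partner_id = "feature_id")
}

#' Match differentially expressed miRNAs to inversely regulated partners
#'
#' The first step of ceRNA-axis mining: select miRNAs whose differential
#' expression opposes that of both an interacting lncRNA and an
#' interacting mRNA. For the oncogenic polarity the miRNA must be
#' down-regulated with at least one up-regulated lncRNA partner AND one
#' up-regulated mRNA partner; the suppressive polarity is the mirror
#' image. Partners must additionally reach a linear fold change of
#' `partner_min_fc` (default 2). miRNA identifiers are matched after
#' [normalize_mirna_id()], and duplicate edges across source databases are
#' unioned (require agreement of at least `min_sources` databases to
#' intersect instead).
#'
#' @param de_mirnas,de_lncrnas,de_mrnas Direction-classified `de_table`s
#'   (from [call_de()] or any table with `feature_id`, `log2fc`,
#'   `fold_change`, `p_value`, `fdr`, `direction`).
#' @param lnc_edges,mrna_edges Interaction tibbles (`mirna_id`,
#'   `partner_id`, optional `source`).
#' @param polarity `"oncogenic"` or `"suppressive"`.
#' @param partner_min_fc Minimum linear |fold change| for partners.
#' @param min_sources Minimum distinct databases supporting an edge.
#' @return A `cerna_candidates` tibble: one row per candidate miRNA with
#'   its DE statistics and two list-columns `lnc_partners`,
#'   `mrna_partners` of partner records.
#' @export
match_candidate_mirnas <- function(de_mirnas, de_lncrnas, de_mrnas,
                                   lnc_edges, mrna_edges,
                                   polarity = c("oncogenic", "suppressive"),
                                   partner_min_fc = 2, min_sources = 1) {
  polarity <- match.arg(polarity)
  dirs <- required_directions(polarity)
  empty <- tibble::tibble(
    mirna_id = character(), mir_log2fc = numeric(), mir_fold_change = numeric(),
    mir_p_value = numeric(), mir_fdr = numeric(),
    lnc_partners = list(), mrna_partners = list()
  )
  if (nrow(lnc_edges) == 0 || nrow(mrna_edges) == 0) {
    warn("empty interaction table: no candidates can be matched.")
    return(structure(empty, polarity = polarity,
                     class = c("cerna_candidates", class(empty))))
  }
  lnc_edges <- collapse_edges(validate_interactions(lnc_edges), min_sources)
  mrna_edges <- collapse_edges(validate_interactions(mrna_edges), min_sources)

  mirs <- de_mirnas |>
    dplyr::filter(.data$direction == dirs[["mirna"]]) |>
    dplyr::mutate(mirna_key = normalize_mirna_id(.data$feature_id))

  lnc_part <- partner_records(de_lncrnas, lnc_edges, dirs[["partner"]], partner_min_fc)
  mrna_part <- partner_records(de_mrnas, mrna_edges, dirs[["partner"]], partner_min_fc)

  out <- mirs |>
    dplyr::transmute(
      mirna_id = .data$feature_id, mirna_key = .data$mirna_key,
      mir_log2fc = .data$log2fc, mir_fold_change = .data$fold_change,
      mir_p_value = .data$p_value, mir_fdr = .data$fdr
    ) |>
    dplyr::mutate(
      lnc_partners = purrr::map(.data$mirna_key, function(k) {
        dplyr::select(dplyr::filter(lnc_part, .data$mirna_key == k), -"mirna_key")
      }),
      mrna_partners = purrr::map(.data$mirna_key, function(k) {
        dplyr::select(dplyr::filter(mrna_part, .data$mirna_key == k), -"mirna_key")
      })
    ) |>
    dplyr::filter(purrr::map_int(.data$lnc_partners, nrow) > 0,
                  purrr::map_int(.data$mrna_partners, nrow) > 0) |>
    dplyr::select(-"mirna_key") |>
    dplyr::arrange(.data$mirna_id)
  structure(out, polarity = polarity,
            class = c("cerna_candidates", class(out)))
}

#' Assemble lncRNA-miRNA-mRNA axes from candidate miRNAs
#'
#' Expands each candidate miRNA's (lncRNA partner x mRNA partner) pairs
#' into individual axes. Every axis inherits the per-component DE
#' statistics, satisfies the polarity sign pattern by construction, and
#' carries the supporting edge provenance.
#'
#' @param candidates A `cerna_candidates` from [match_candidate_mirnas()].
#' @return A `cerna_axes` tibble, one row per (lncRNA, miRNA, mRNA)
#'   triple, with `lnc_*`, `mir_*`, `mrna_*` statistic columns.
#' @export
assemble_axes <- function(candidates) {
  stopifnot(inherits(candidates, "cerna_candidates"))
  polarity <- attr(candidates, "polarity")
  empty <- tibble::tibble(
    lncrna_id = character(), mirna_id = character(), mrna_id = character(),
    polarity = character(),
    lnc_log2fc = numeric(), lnc_fold_change = numeric(),
    lnc_p_value = numeric(), lnc_fdr = numeric(),
    mir_log2fc = numeric(), mir_fold_change = numeric(),
    mir_p_value = numeric(), mir_fdr = numeric(),
    mrna_log2fc = numeric(), mrna_fold_change = numeric(),
    mrna_p_value = numeric(), mrna_fdr = numeric(),
    lnc_edge_sources = character(), mrna_edge_sources = character()
  )
  if (nrow(candidates) == 0) {
    return(structure(empty, class = c("cerna_axes", class(empty))))
  }
  out <- purrr::pmap_dfr(
    list(candidates$mirna_id, candidates$mir_log2fc, candidates$mir_fold_change,
         candidates$mir_p_value, candidates$mir_fdr,
         candidates$lnc_partners, candidates$mrna_partners),
    function(mid, mlfc, mfc, mp, mq, lncs, mrnas) {
      tidyr::expand_grid(l = seq_len(nrow(lncs)), g = seq_len(nrow(mrnas))) |>
        purrr::pmap_dfr(function(l, g) {
          tibble::tibble(
            lncrna_id = lncs$partner_id[l], mirna_id = mid,
            mrna_id = mrnas$partner_id[g], polarity = polarity,
            lnc_log2fc = lncs$log2fc[l], lnc_fold_change = lncs$fold_change[l],
            lnc_p_value = lncs$p_value[l], lnc_fdr = lncs$fdr[l],
            mir_log2fc = mlfc, mir_fold_change = mfc,
            mir_p_value = mp, mir_fdr = mq,
            mrna_log2fc = mrnas$log2fc[g], mrna_fold_change = mrnas$fold_change[g],
            mrna_p_value = mrnas$p_value[g], mrna_fdr = mrnas$fdr[g],
            lnc_edge_sources = lncs$sources[l],
            mrna_edge_sources = mrnas$sources[g]
          )
        })
    }
  )
  structure(out, class = c("cerna_axes", class(out)))
}

#' Filter and rank assembled axes
#'
#' Re-asserts the lncRNA gate (linear |fold change| >= `lnc_min_fc`,
#' default 2) and ranks the survivors by `rank_score`, the mean of the
#' three components' -log10 p values (larger = jointly more significant).
#' Ties break by |log2FC| of the lncRNA, then lexicographically on the
#' three identifiers, so the ranking is fully deterministic. This numeric
#' score replaces literature-based relevance judgements with a
#' reproducible criterion.
#'
#' @param axes A `cerna_axes` tibble.
#' @param top_k Number of axes to keep (default 3 per polarity).
#' @param lnc_min_fc Minimum linear |fold change| of the lncRNA.
#' @return The top `top_k` axes with `rank_score` and `rank` columns.
#' @export
rank_axes <- function(axes, top_k = 3, lnc_min_fc = 2) {
  stopifnot(inherits(axes, "cerna_axes"))
  if (!is.numeric(top_k) || top_k < 1) abort("`top_k` must be >= 1.")
  out <- axes |>
    dplyr::filter(abs(.data$lnc_fold_change) >= lnc_min_fc) |>
    dplyr::mutate(
      rank_score = (-log10(.data$lnc_p_value) - log10(.data$mir_p_value) -
                      log10(.data$mrna_p_value)) / 3
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$rank_score), dplyr::desc(abs(.data$lnc_log2fc)),
      .data$lncrna_id, .data$mirna_id, .data$mrna_id
    ) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = top_k)
  structure(out, class = c("cerna_axes", class(dplyr::as_tibble(out))))
}

axis_nodes <- function(axes) {
  dplyr::bind_rows(
    tibble::tibble(id = axes$lncrna_id, type = "lncRNA",
                   direction = ifelse(axes$lnc_log2fc > 0, "up", "down")),
    tibble::tibble(id = axes$mirna_id, type = "miRNA",
                   direction = ifelse(axes$mir_log2fc > 0, "up", "down")),
    tibble::tibble(id = axes$mrna_id, type = "mRNA",
                   direction = ifelse(axes$mrna_log2fc > 0, "up", "down"))
  ) |> dplyr::distinct(.data$id, .keep_all = TRUE)
}

axis_edges_tbl <- function(axes) {
  dplyr::bind_rows(
    tibble::tibble(source = axes$lncrna_id, relation = "sponges",
                   target = axes$mirna_id),
    tibble::tibble(source = axes$mirna_id, relation = "targets",
                   target = axes$mrna_id)
  ) |> dplyr::distinct()
}

#' Export a ceRNA network for Cytoscape
#'
#' Builds the bipartite-style triple network (nodes typed
#' lncRNA/miRNA/mRNA with their direction, lncRNA-miRNA "sponges" edges
#' and miRNA-mRNA "targets" edges) and optionally writes it as SIF and/or
#' GraphML, both of which Cytoscape imports directly.
#'
#' @param axes A non-empty `cerna_axes` tibble.
#' @param sif,graphml Optional output paths.
#' @return Invisibly, the igraph graph object.
#' @export
export_network <- function(axes, sif = NULL, graphml = NULL) {
  stopifnot(inherits(axes, "cerna_axes"))
  if (nrow(axes) == 0) abort("cannot export an empty axis list.")
  nodes <- axis_nodes(axes)
  edges <- axis_edges_tbl(axes)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "relation")],
    directed = FALSE, vertices = nodes
  )
  if (!is.null(sif)) {
    ok <- try(writeLines(paste(edges$source, edges$relation, edges$target,
                               sep = "\t"), sif), silent = TRUE)
    if (inherits(ok, "try-error")) abort(sprintf("failed to write SIF to %s", sif))
  }
  if (!is.null(graphml)) {
    ok <- try(igraph::write_graph(g, graphml, format = "graphml"), silent = TRUE)
    if (inherits(ok, "try-error")) {
      abort(sprintf("failed to write GraphML to %s", graphml))
    }
  }
  invisible(g)
}

#' Read a SIF network file
#'
#' @param path SIF path (tab-separated `source relation target` lines).
#' @return Tibble with columns `source`, `relation`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t")
  tibble::tibble(
    source = purrr::map_chr(parts, 1),
    relation = purrr::map_chr(parts, 2),
    target = purrr::map_chr(parts, 3)
  )
}
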