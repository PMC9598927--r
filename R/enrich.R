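#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @param namespace Namespace tag stored on every term (default "custom").
#' @return Annotation tibble: `term_id`, `term_name`, `namespace`,
#'   `gene_id` (one row per term-gene pair, duplicates removed).
#' @export
read_gmt <- function(path, namespace = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(strsplit(lines, "\t"), function(f) {
    tibble::tibble(
      term_id = f[1], term_name = f[2], namespace = namespace,
      gene_id = unique(f[-(1:2)])
    )
  })
}

#' Hypergeometric over-representation analysis
#'
#' For every term, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query set and the term's
#' members, given the universe: `P(X >= k | N, K, n)` with N the universe
#' size, K the term size, n the query size and k the overlap. FDR is
#' controlled by Benjamini-Hochberg separately within each annotation
#' namespace (GO branches and pathways are distinct multiple-testing
#' families). Terms are returned sorted by ascending p.
#'
#' @param query Character vector of query gene IDs.
#' @param annotation Annotation tibble (`term_id`, `gene_id`, optional
#'   `term_name`, `namespace`), e.g. from [read_gmt()].
#' @param universe Character vector of all assayable genes. Defaults to
#'   the union of annotation members and the query. Query genes outside
#'   the universe are dropped with a warning (set
#'   `outside_query = "error"` to reject instead).
#' @param outside_query `"drop"` (default) or `"error"`.
#' @return Enrichment tibble: `term_id`, `term_name`, `namespace`, `k`,
#'   `n`, `K`, `N`, `p_value`, `fdr`, sorted by `p_value`.
#' @export
hypergeom_enrich <- function(query, annotation, universe = NULL,
                             outside_query = c("drop", "error")) {
  outside_query <- match.arg(outside_query)
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("term_id", "gene_id") %in% names(annotation)))
  if (!"term_name" %in% names(annotation)) annotation$term_name <- annotation$term_id
  if (!"namespace" %in% names(annotation)) annotation$namespace <- "custom"
  if (is.null(universe)) universe <- union(annotation$gene_id, query)
  universe <- unique(universe)
  annotation <- dplyr::filter(annotation, .data$gene_id %in% universe)

  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    if (outside_query == "error") {
      abort(sprintf("query genes outside the universe: %s",
                    paste(outside, collapse = ", ")))
    }
    warn(sprintf("dropping %d query gene(s) not in the universe.", length(outside)))
    query <- setdiff(query, outside)
  }

  n <- length(query); N <- length(universe)
  out <- annotation |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$namespace) |>
    dplyr::summarise(
      k = sum(unique(.data$gene_id) %in% query),
      K = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      # P(X >= k): phyper counts strictly greater, so shift by one
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    ) |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "namespace",
                  "k", "n", "K", "N", "p_value", "fdr")
  out
}

#' Venn region counts for two or three gene sets
#'
#' Classifies every element of the union by its membership pattern and
#' counts each Venn region. The intersection of all sets is reported as
#' the `shared` attribute (and row).
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble `region` (e.g. "A", "A&B", "A&B&C"), `n`, `members`
#'   (list-column), with attribute `shared` = size of the all-sets
#'   intersection.
#' @export
multiset_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    abort("`sets` must be a named list of 2 or 3 gene sets.")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every set must be named.")
  }
  sets <- lapply(sets, unique)
  all_elems <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_elems %in% s,
                       logical(length(all_elems)))
  membership <- matrix(membership, nrow = length(all_elems),
                       dimnames = list(all_elems, names(sets)))
  pattern <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  region_names <- unname(apply(regions, 1, function(row) {
    paste(names(sets)[as.logical(row)], collapse = "&")
  }))
  out <- tibble::tibble(
    region = region_names,
    n = vapply(region_names, function(r) sum(pattern == r), integer(1),
               USE.NAMES = FALSE),
    members = lapply(region_names, function(r) all_elems[pattern == r])
  )
  attr(out, "shared") <- sum(pattern == paste(names(sets), collapse = "&"))
  out
}

#' Stemness interaction profile of one gene
#'
#' Counts, for a ceRNA component, its physical and regulatory interaction
#' partners in a catalog (gene, partner, mode) and how many of those fall
#' in a stemness-related gene list and a stemness transcription-factor
#' list — the computable core of a stemness-signature lookup.
#'
#' @param gene_id Gene to profile.
#' @param catalog Interaction tibble: `gene_id`, `partner_id`,
#'   `mode` in physical/regulatory.
#' @param stemness_genes,stemness_tfs Character vectors of stemness gene
#'   and stemness TF identifiers.
#' @return List with `counts` (tibble: `mode`, `n_partners`,
#'   `n_stemness_genes`, `n_stemness_tfs`) and `partners` (tibble of the
#'   gene's partner records with membership flags).
#' @export
stemness_profile <- function(gene_id, catalog, stemness_genes = character(),
                             stemness_tfs = character()) {
  catalog <- tibble::as_tibble(catalog)
  stopifnot(all(c("gene_id", "partner_id", "mode") %in% names(catalog)))
  if (!all(catalog$mode %in% c("physical", "regulatory"))) {
    abort("`mode` must be 'physical' or 'regulatory'.")
  }
  partners <- dplyr::filter(catalog, .data$gene_id == !!gene_id) |>
    dplyr::distinct(.data$partner_id, .data$mode) |>
    dplyr::mutate(
      in_stemness_genes = .data$partner_id %in% stemness_genes,
      in_stemness_tfs = .data$partner_id %in% stemness_tfs
    )
  if (nrow(partners) == 0) {
    warn(sprintf("gene '%s' not found in the interaction catalog.", gene_id))
  }
  counts <- tibble::tibble(mode = c("physical", "regulatory")) |>
    dplyr::left_join(
      partners |>
        dplyr::group_by(.data$mode) |>
        dplyr::summarise(
          n_partners = dplyr::n(),
          n_stemness_genes = sum(.data$in_stemness_genes),
          n_stemness_tfs = sum(.data$in_stemness_tfs),
          .groups = "drop"
        ),
      by = "mode"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0L)))
  list(counts = counts, partners = partners)
}
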