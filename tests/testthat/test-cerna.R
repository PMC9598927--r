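de_record <- function(id, log2fc, p = 0.01, direction = NULL) {
  if (is.null(direction)) {
    direction <- dplyr::case_when(log2fc >= 1 ~ "up",
                                  log2fc <= -1 ~ "down",
                                  .default = "ns")
  }
  tibble::tibble(feature_id = id, log2fc = log2fc,
                 fold_change = sign(log2fc) * 2^abs(log2fc),
                 p_value = p, fdr = p, direction = direction)
}

edges_tbl <- function(mirna, partner, class) {
  tibble::tibble(mirna_id = mirna, partner_id = partner,
                 partner_class = class, source = "db1")
}

test_that("candidate matching requires both inverse partners above the FC gate", {
  de_mir <- dplyr::bind_rows(de_record("m1", -2), de_record("m2", -2))
  de_lnc <- dplyr::bind_rows(de_record("lnc1", 2), de_record("lnc2", -2))
  de_mrna <- de_record("g1", log2(3) * sign(1))
  lnc_edges <- edges_tbl(c("m1", "m2"), c("lnc1", "lnc2"), "lncRNA")
  mrna_edges <- edges_tbl("m1", "g1", "mRNA")

  cand <- match_candidate_mirnas(de_mir, de_lnc, de_mrna,
                                 lnc_edges, mrna_edges, "oncogenic")
  # m1: up lnc1 (FC 4) and up g1 (FC 3); m2 only touches a down lncRNA
  expect_equal(cand$mirna_id, "m1")
  expect_equal(cand$lnc_partners[[1]]$partner_id, "lnc1")
  expect_equal(cand$mrna_partners[[1]]$partner_id, "g1")
})

test_that("no DE miRNAs or empty edge tables give empty candidate sets", {
  de_mir <- de_record("m1", 0.1)
  de_lnc <- de_record("lnc1", 2)
  de_mrna <- de_record("g1", 2)
  lnc_edges <- edges_tbl("m1", "lnc1", "lncRNA")
  mrna_edges <- edges_tbl("m1", "g1", "mRNA")
  expect_equal(nrow(match_candidate_mirnas(de_mir, de_lnc, de_mrna,
                                           lnc_edges, mrna_edges, "oncogenic")), 0)
  expect_warning(
    empty <- match_candidate_mirnas(de_record("m1", -2), de_lnc, de_mrna,
                                    lnc_edges[0, ], mrna_edges, "oncogenic"),
    "empty interaction table"
  )
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(assemble_axes(empty)), 0)
})

test_that("miRNA identifier dialects are matched case-insensitively without hsa prefix", {
  de_mir <- de_record("hsa-miR-182-5p", -2)
  de_lnc <- de_record("HOTAIRM1", 2)
  de_mrna <- de_record("ERO1A", 2)
  lnc_edges <- edges_tbl("MIR-182-5P", "HOTAIRM1", "lncRNA")
  mrna_edges <- edges_tbl("mir-182-5p", "ERO1A", "mRNA")
  cand <- match_candidate_mirnas(de_mir, de_lnc, de_mrna,
                                 lnc_edges, mrna_edges, "oncogenic")
  expect_equal(cand$mirna_id, "hsa-miR-182-5p")
  ax <- assemble_axes(cand)
  expect_equal(ax$lncrna_id, "HOTAIRM1")
  expect_equal(ax$mrna_id, "ERO1A")
  # arm suffix must be preserved: a 3p edge does not match a 5p miRNA
  expect_equal(normalize_mirna_id("hsa-miR-182-5p"), "mir-182-5p")
  expect_false(normalize_mirna_id("miR-182-3p") == normalize_mirna_id("miR-182-5p"))
})

test_that("axis assembly is the Cartesian product of partner sets", {
  de_mir <- de_record("m1", -2)
  de_lnc <- de_record("L1", 2)
  de_mrna <- dplyr::bind_rows(de_record("G1", 2), de_record("G2", 1.5))
  cand <- match_candidate_mirnas(
    de_mir, de_lnc, de_mrna,
    edges_tbl("m1", "L1", "lncRNA"),
    edges_tbl(c("m1", "m1"), c("G1", "G2"), "mRNA"),
    "oncogenic"
  )
  ax <- assemble_axes(cand)
  expect_equal(nrow(ax), 2)
  expect_setequal(ax$mrna_id, c("G1", "G2"))
  expect_equal(unique(ax$lncrna_id), "L1")
  expect_equal(anyDuplicated(ax[, c("lncrna_id", "mirna_id", "mrna_id")]), 0L)
})

test_that("ranking filters the lncRNA two-fold gate and sorts by joint significance", {
  de_mir <- de_record("m1", -2)
  de_lnc <- dplyr::bind_rows(
    de_record("Lweak", log2(1.5)),  # linear FC 1.5: below the gate
    de_record("Lstrong", 2, p = 1e-4),
    de_record("Lmid", 2.5, p = 1e-2)
  )
  de_lnc$direction <- "up"
  de_mrna <- dplyr::bind_rows(de_record("G1", 2, p = 1e-4),
                              de_record("G2", 2, p = 1e-2))
  cand <- match_candidate_mirnas(
    de_mir, de_lnc, de_mrna,
    edges_tbl(rep("m1", 3), c("Lweak", "Lstrong", "Lmid"), "lncRNA"),
    edges_tbl(rep("m1", 2), c("G1", "G2"), "mRNA"),
    "oncogenic", partner_min_fc = 1  # let the weak lncRNA through to ranking
  )
  ax <- assemble_axes(cand)
  expect_true("Lweak" %in% ax$lncrna_id)
  ranked <- rank_axes(ax, top_k = 10)
  expect_false("Lweak" %in% ranked$lncrna_id)

  # mean -log10 p: (Lstrong, m1 @1e-2, G1) = (4 + 2 + 4)/3 beats (Lmid, ., G2)
  de_mir2 <- de_record("m1", -2, p = 1e-2)
  cand2 <- match_candidate_mirnas(
    de_mir2, de_lnc, de_mrna,
    edges_tbl(rep("m1", 2), c("Lstrong", "Lmid"), "lncRNA"),
    edges_tbl(rep("m1", 2), c("G1", "G2"), "mRNA"), "oncogenic"
  )
  ranked2 <- rank_axes(assemble_axes(cand2), top_k = 4)
  expect_equal(ranked2$lncrna_id[1], "Lstrong")
  expect_equal(ranked2$mrna_id[1], "G1")
  expect_equal(ranked2$rank_score[1], (4 + 2 + 4) / 3)
  expect_equal(ranked2$rank, 1:4)
  expect_error(rank_axes(assemble_axes(cand2), top_k = 0), "top_k")

  single <- rank_axes(assemble_axes(cand2), top_k = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$rank, 1)
})

test_that("requiring multiple source databases intersects the edge union", {
  de_mir <- de_record("m1", -2)
  de_lnc <- de_record("L1", 2)
  de_mrna <- de_record("G1", 2)
  lnc_edges <- dplyr::bind_rows(
    edges_tbl("m1", "L1", "lncRNA"),
    dplyr::mutate(edges_tbl("m1", "L1", "lncRNA"), source = "db2")
  )
  mrna_edges <- edges_tbl("m1", "G1", "mRNA")  # one source only
  cand2 <- match_candidate_mirnas(de_mir, de_lnc, de_mrna, lnc_edges,
                                  mrna_edges, "oncogenic", min_sources = 2)
  expect_equal(nrow(cand2), 0)  # the mRNA edge has a single source
  cand1 <- match_candidate_mirnas(de_mir, de_lnc, de_mrna, lnc_edges,
                                  mrna_edges, "oncogenic", min_sources = 1)
  expect_equal(nrow(cand1), 1)
  expect_equal(cand1$lnc_partners[[1]]$sources, "db1;db2")
})

test_that("every emitted axis satisfies its polarity sign pattern", {
  set.seed(20)
  for (rep in 1:25) {
    de_lnc <- random_de_table(paste0("L", 1:6))
    de_mir <- random_de_table(paste0("m", 1:6))
    de_mrna <- random_de_table(paste0("G", 1:6))
    lnc_edges <- edges_tbl(sample(de_mir$feature_id, 10, TRUE),
                           sample(de_lnc$feature_id, 10, TRUE), "lncRNA") |>
      dplyr::distinct(mirna_id, partner_id, .keep_all = TRUE)
    mrna_edges <- edges_tbl(sample(de_mir$feature_id, 10, TRUE),
                            sample(de_mrna$feature_id, 10, TRUE), "mRNA") |>
      dplyr::distinct(mirna_id, partner_id, .keep_all = TRUE)
    for (pol in c("oncogenic", "suppressive")) {
      ax <- assemble_axes(match_candidate_mirnas(
        de_mir, de_lnc, de_mrna, lnc_edges, mrna_edges, pol
      ))
      if (nrow(ax) == 0) next
      if (pol == "oncogenic") {
        expect_true(all(ax$lnc_log2fc > 0 & ax$mir_log2fc < 0 & ax$mrna_log2fc > 0))
      } else {
        expect_true(all(ax$lnc_log2fc < 0 & ax$mir_log2fc > 0 & ax$mrna_log2fc < 0))
      }
      expect_true(all(abs(ax$lnc_fold_change) >= 2))
    }
  }
})

test_that("mirror symmetry: negating fold changes swaps the polarities exactly", {
  set.seed(21)
  for (rep in 1:10) {
    de_lnc <- random_de_table(paste0("L", 1:5))
    de_mir <- random_de_table(paste0("m", 1:5))
    de_mrna <- random_de_table(paste0("G", 1:5))
    lnc_edges <- edges_tbl(sample(de_mir$feature_id, 8, TRUE),
                           sample(de_lnc$feature_id, 8, TRUE), "lncRNA") |>
      dplyr::distinct(mirna_id, partner_id, .keep_all = TRUE)
    mrna_edges <- edges_tbl(sample(de_mir$feature_id, 8, TRUE),
                            sample(de_mrna$feature_id, 8, TRUE), "mRNA") |>
      dplyr::distinct(mirna_id, partner_id, .keep_all = TRUE)
    flip <- function(de) dplyr::mutate(
      de, log2fc = -log2fc, fold_change = -fold_change,
      direction = dplyr::case_when(direction == "up" ~ "down",
                                   direction == "down" ~ "up",
                                   .default = "ns")
    )
    onc <- assemble_axes(match_candidate_mirnas(
      de_mir, de_lnc, de_mrna, lnc_edges, mrna_edges, "oncogenic"))
    sup_flipped <- assemble_axes(match_candidate_mirnas(
      flip(de_mir), flip(de_lnc), flip(de_mrna),
      lnc_edges, mrna_edges, "suppressive"))
    key <- function(ax) sort(paste(ax$lncrna_id, ax$mirna_id, ax$mrna_id))
    expect_equal(key(onc), key(sup_flipped))
  }
})

test_that("axis output matches the brute-force triple loop on small instances", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    de_lnc <- random_de_table(paste0("L", 1:n))
    de_mir <- random_de_table(paste0("m", 1:n))
    de_mrna <- random_de_table(paste0("G", 1:n))
    ne <- sample(5:15, 1)
    lnc_edges <- edges_tbl(sample(de_mir$feature_id, ne, TRUE),
                           sample(de_lnc$feature_id, ne, TRUE), "lncRNA") |>
      dplyr::distinct(mirna_id, partner_id, .keep_all = TRUE)
    mrna_edges <- edges_tbl(sample(de_mir$feature_id, ne, TRUE),
                            sample(de_mrna$feature_id, ne, TRUE), "mRNA") |>
      dplyr::distinct(mirna_id, partner_id, .keep_all = TRUE)
    for (pol in c("oncogenic", "suppressive")) {
      ranked <- rank_axes(assemble_axes(match_candidate_mirnas(
        de_mir, de_lnc, de_mrna, lnc_edges, mrna_edges, pol
      )), top_k = 1000)
      got <- sort(paste(ranked$lncrna_id, ranked$mirna_id, ranked$mrna_id))
      want <- brute_force_axes(de_lnc, de_mir, de_mrna, lnc_edges, mrna_edges, pol)
      expect_equal(got, want)
    }
  }
})

test_that("planted axes are recovered exactly from noiseless synthetic data", {
  cfg <- simulation_config(n_samples_per_group = 6, noise_sd = 0,
                           decoy_edge_count = 100, seed = 17)
  sim <- simulate_expression(cfg)
  inter <- simulate_interactions(cfg, sim$truth, decoy_scope = "non_de")
  de <- purrr::imap(sim$expression, ~ call_de(.x, sim$groups, rna_class = .y))
  truth <- sim$truth$axes
  for (pol in c("oncogenic", "suppressive")) {
    ranked <- rank_axes(assemble_axes(match_candidate_mirnas(
      de$miRNA, de$lncRNA, de$mRNA, inter$lncRNA, inter$mRNA, pol
    )), top_k = 100)
    got <- sort(paste(ranked$lncrna_id, ranked$mirna_id, ranked$mrna_id))
    tp <- truth[truth$polarity == pol, ]
    expect_equal(got, sort(paste(tp$lncrna_id, tp$mirna_id, tp$mrna_id)))
  }
})

test_that("network export counts nodes and edges correctly and round-trips", {
  de_mir <- dplyr::bind_rows(de_record("m1", -2), de_record("m2", -2), de_record("m3", -2))
  de_lnc <- dplyr::bind_rows(de_record("L1", 2), de_record("L2", 2), de_record("L3", 2))
  de_mrna <- dplyr::bind_rows(de_record("G1", 2), de_record("G2", 2), de_record("G3", 2))
  disjoint <- match_candidate_mirnas(
    de_mir, de_lnc, de_mrna,
    edges_tbl(c("m1", "m2", "m3"), c("L1", "L2", "L3"), "lncRNA"),
    edges_tbl(c("m1", "m2", "m3"), c("G1", "G2", "G3"), "mRNA"), "oncogenic"
  )
  ax3 <- assemble_axes(disjoint)
  g <- export_network(ax3)
  expect_equal(igraph::vcount(g), 9)
  expect_equal(igraph::ecount(g), 6)

  one <- ax3[1, ]; class(one) <- class(ax3)
  g1 <- export_network(one)
  expect_equal(igraph::vcount(g1), 3)
  expect_equal(igraph::ecount(g1), 2)

  # k axes sharing one miRNA: 1 + distinct lnc + distinct mRNA nodes
  shared <- match_candidate_mirnas(
    de_mir[1, ], de_lnc, de_mrna,
    edges_tbl(c("m1", "m1"), c("L1", "L2"), "lncRNA"),
    edges_tbl(c("m1", "m1"), c("G1", "G2"), "mRNA"), "oncogenic"
  )
  axs <- assemble_axes(shared)
  expect_equal(igraph::vcount(export_network(axs)), 1 + 2 + 2)

  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif"); gml <- file.path(dir, "net.graphml")
  export_network(ax3, sif = sif, graphml = gml)
  back <- read_sif(sif)
  expect_equal(nrow(back), 6)
  expect_setequal(unique(back$relation), c("sponges", "targets"))
  g_back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g_back), 9)
  expect_setequal(igraph::vertex_attr(g_back, "type"),
                  c("lncRNA", "miRNA", "mRNA"))
  doc <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(doc), "graphml")

  expect_error(export_network(ax3[0, ]), "empty")
})
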