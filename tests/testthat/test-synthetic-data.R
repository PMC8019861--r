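test_that("preferential-attachment interactome has forced size and is connected", {
  cases <- list(list(n = 100L, m = 2L, seed = 1L),
                list(n = 3L, m = 1L, seed = 7L),
                list(n = 1358L, m = 3L, seed = 42L))
  for (cs in cases) {
    g <- generate_interactome(cs$n, cs$m, cs$seed)
    expect_equal(igraph::vcount(g), cs$n)
    expect_equal(igraph::ecount(g), (cs$n - cs$m) * cs$m)
    expect_true(igraph::is_connected(g))
    expect_true(igraph::is_simple(g))
  }
  # edge/node ratio of the largest case is of the order seen in real
  # disease QQPPI networks (3505/1358 ~ 2.6)
  g <- generate_interactome(1358L, 3L, 42L)
  expect_equal(igraph::ecount(g) / igraph::vcount(g), 4065 / 1358)
  expect_error(generate_interactome(3, 3, 1), "attachment")
})

test_that("generator output is deterministic for a fixed seed", {
  g1 <- generate_interactome(200, 2, 5)
  g2 <- generate_interactome(200, 2, 5)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  cfg <- synth_config(n_genes = 100, interactome_nodes = 100,
                      n_planted_hubs = 2, hub_extra_degree = 10,
                      n_drugs = 5, seed = 9)
  s1 <- run_synthetic_study(cfg)
  s2 <- run_synthetic_study(cfg)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$drug_table, s2$drug_table)
  expect_false(anyNA(s1$expression$values))
})

test_that("hub planting raises each hub's degree by exactly extra_degree", {
  g <- generate_interactome(500, 2, 3)
  before <- igraph::degree(g)
  planted <- plant_hubs(g, n_hubs = 5, extra_degree = 40, seed = 3)
  after <- igraph::degree(planted$graph)
  expect_length(planted$hubs, 5)
  expect_equal(unname(after[planted$hubs] - before[planted$hubs]),
               rep(40, 5))
  expect_true(igraph::is_simple(planted$graph))
  # identity case
  same <- plant_hubs(g, n_hubs = 0, extra_degree = 40, seed = 1)
  expect_identical(igraph::as_edgelist(same$graph),
                   igraph::as_edgelist(g))
  expect_length(same$hubs, 0)
})

test_that("hub planting on a path graph links an endpoint across", {
  p3 <- igraph::make_graph(~ a - b, b - c)
  planted <- plant_hubs(p3, n_hubs = 1, extra_degree = 1, seed = 2)
  # the middle node has no non-neighbor, so a or c is picked and the
  # only possible new edge is a-c
  expect_true(planted$hubs %in% c("a", "c"))
  expect_true(igraph::are_adjacent(planted$graph, "a", "c"))
  expect_equal(unname(igraph::degree(planted$graph)[planted$hubs]), 2)
  expect_error(plant_hubs(p3, n_hubs = 3, extra_degree = 2, seed = 1),
               "non-neighbors")
})

test_that("planted expression yields recoverable DEGs with matching directions", {
  cfg <- synth_config(n_genes = 2000, deg_fraction = 0.1,
                      effect_size = 2, noise_sd = 1, seed = 5)
  out <- generate_expression(cfg, gene_symbols(2000))
  expect_equal(dim(out$expression$values), c(2000L, 67L))
  expect_length(out$truth$true_deg_genes, 200)
  expect_setequal(names(out$truth$true_directions),
                  out$truth$true_deg_genes)
  degs <- call_degs(out$expression, alpha = 0.05, route = "anova")
  recovered <- intersect(degs$gene, out$truth$true_deg_genes)
  expect_gte(length(recovered) / 200, 0.95)
  dir_called <- degs$direction[match(recovered, degs$gene)]
  expect_identical(dir_called,
                   unname(out$truth$true_directions[recovered]))
})

test_that("null expression keeps the DEG call rate at the type-I level", {
  cfg <- synth_config(n_genes = 2000, deg_fraction = 0.1,
                      effect_size = 0, noise_sd = 1, seed = 17)
  out <- generate_expression(cfg, gene_symbols(2000))
  degs <- call_degs(out$expression, alpha = 0.05, route = "anova")
  rate <- nrow(degs) / 2000
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("hub bias steers drug targets toward high-degree genes", {
  g <- generate_interactome(200, 2, 9)
  mean_deg <- mean(igraph::degree(g))
  drugged_means <- vapply(1:20, function(r) {
    dt <- generate_drug_table(g, n_drugs = 20, hub_bias = 2,
                              seed = 9 + r)
    mean(igraph::degree(g)[unique(dt$drug_table$gene)])
  }, numeric(1))
  expect_gt(mean(drugged_means), mean_deg)
  # schema and determinism
  dt <- generate_drug_table(g, n_drugs = 7, hub_bias = 0, seed = 4)
  expect_named(dt$drug_table,
               c("gene", "drug_id", "drug_name", "action", "groups"))
  expect_true(all(dt$drug_table$gene %in% igraph::V(g)$name))
  expect_identical(dt$drug_table,
                   generate_drug_table(g, 7, 0, 4)$drug_table)
})

test_that("a strongly biased single drug targets the star center", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("HUB", "L1", "L2", "L3", "L4")
  hits <- vapply(1:25, function(s) {
    dt <- generate_drug_table(star, n_drugs = 1, hub_bias = 50,
                              seed = s)
    "HUB" %in% dt$drug_table$gene
  }, logical(1))
  expect_true(all(hits))
})

test_that("synthetic study files round-trip through the TSV writers", {
  cfg <- synth_config(n_genes = 120, interactome_nodes = 100,
                      n_planted_hubs = 1, hub_extra_degree = 10,
                      n_drugs = 4, seed = 2)
  s <- run_synthetic_study(cfg)
  td <- withr::local_tempdir()
  write_expression(s$expression, file.path(td, "e.tsv"),
                   file.path(td, "g.tsv"))
  back <- read_expression(file.path(td, "e.tsv"),
                          file.path(td, "g.tsv"))
  expect_equal(back$values, s$expression$values, tolerance = 1e-9)
  expect_identical(back$sample_groups, s$expression$sample_groups)
  write_edge_tsv(s$interactome, file.path(td, "edges.tsv"))
  g2 <- read_edge_tsv(file.path(td, "edges.tsv"))
  expect_equal(igraph::ecount(g2), igraph::ecount(s$interactome))
  expect_setequal(igraph::V(g2)$name, igraph::V(s$interactome)$name)
})
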