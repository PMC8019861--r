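#' Synthetic study configuration
#'
#' Bundles every parameter of the synthetic-study generator. Defaults
#' describe the emulated study design: 43 cases vs 24 controls, a 10%
#' differentially-expressed fraction with a 2-unit log-expression shift
#' at unit noise, a 1000-node scale-free interactome with 2 attachment
#' edges per node (edge/node ratio close to 2, the order observed in
#' disease QQPPI networks), 5 planted hub genes and a 20-drug table
#' biased toward high-degree targets.
#'
#' One integer `seed` governs all sub-generators through a fixed
#' derivation rule: the interactome uses `seed`, hub planting `seed + 1`,
#' the expression matrix `seed + 2` and the drug table `seed + 3`, so any
#' stage can be regenerated independently.
#'
#' @param n_genes number of genes in the expression matrix.
#' @param n_case,n_control group sizes (cases first).
#' @param deg_fraction fraction of genes planted as true DEGs, in (0,1).
#' @param effect_size mean log-expression shift added to case samples for
#'   planted DEGs (up-shifted for "up" genes, down-shifted for "down").
#' @param noise_sd per-observation Gaussian noise standard deviation.
#' @param interactome_nodes,attachment_edges size and preferential-
#'   attachment parameter of the synthetic interactome.
#' @param n_planted_hubs number of hub genes planted into the interactome.
#' @param hub_extra_degree edges added to each planted hub.
#' @param n_drugs rows of the synthetic drug-target generator.
#' @param hub_bias exponent of the degree-proportional target sampling
#'   weight (`degree^hub_bias`); 0 gives uniform sampling.
#' @param seed master integer seed.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000L, n_case = 43L, n_control = 24L,
                         deg_fraction = 0.1, effect_size = 2,
                         noise_sd = 1, interactome_nodes = 1000L,
                         attachment_edges = 2L, n_planted_hubs = 5L,
                         hub_extra_degree = 40L, n_drugs = 20L,
                         hub_bias = 2, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_case = as.integer(n_case),
    n_control = as.integer(n_control), deg_fraction = deg_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    interactome_nodes = as.integer(interactome_nodes),
    attachment_edges = as.integer(attachment_edges),
    n_planted_hubs = as.integer(n_planted_hubs),
    hub_extra_degree = as.integer(hub_extra_degree),
    n_drugs = as.integer(n_drugs), hub_bias = hub_bias,
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_case", "n_control", "interactome_nodes",
              "attachment_edges", "n_drugs")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0L) {
      stop(sprintf("'%s' must be a positive count", f), call. = FALSE)
    }
  }
  if (cfg$n_planted_hubs < 0L || cfg$hub_extra_degree < 0L) {
    stop("hub counts must be non-negative", call. = FALSE)
  }
  if (cfg$deg_fraction <= 0 || cfg$deg_fraction >= 1) {
    stop("'deg_fraction' must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  if (cfg$n_case < 2L || cfg$n_control < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  if (cfg$interactome_nodes <= cfg$attachment_edges) {
    stop("'interactome_nodes' must exceed 'attachment_edges'",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Synthetic gene symbols
#'
#' Zero-padded labels (`G0001`, ...) so lexicographic and numeric order
#' coincide and tie-breaking is deterministic.
#'
#' @param n number of symbols.
#' @return character vector of length `n`.
#' @export
gene_symbols <- function(n) {
  sprintf("G%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}

#' Generate a scale-free synthetic interactome
#'
#' Preferential attachment: the first of the `n_nodes - attachment_edges`
#' added nodes links to all `attachment_edges` founder nodes, and each
#' later node attaches `attachment_edges` edges to distinct existing
#' nodes sampled with probability proportional to current degree. The
#' result is a connected simple undirected graph with exactly
#' `(n_nodes - attachment_edges) * attachment_edges` edges, a structure
#' whose heavy-tailed degree distribution mimics real PPI networks.
#'
#' @param n_nodes node count; must exceed `attachment_edges`.
#' @param attachment_edges edges attached by each incoming node (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return an [igraph::graph] with vertex names from [gene_symbols()].
#' @export
generate_interactome <- function(n_nodes, attachment_edges, seed) {
  n <- as.integer(n_nodes)
  m <- as.integer(attachment_edges)
  if (m < 1L || n <= m) {
    stop("need n_nodes > attachment_edges >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  deg <- integer(n)
  n_edges <- (n - m) * m
  from <- integer(n_edges)
  to <- integer(n_edges)
  k <- 0L
  for (v in seq.int(m + 1L, n)) {
    existing <- seq_len(v - 1L)
    targets <- if (v == m + 1L) existing
               else sample_vec(existing, m, prob = deg[existing])
    idx <- k + seq_along(targets)
    from[idx] <- v
    to[idx] <- targets
    k <- k + length(targets)
    deg[v] <- deg[v] + length(targets)
    deg[targets] <- deg[targets] + 1L
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$name <- gene_symbols(n)
  g
}

#' Plant high-degree hub nodes into a graph
#'
#' Picks `n_hubs` nodes uniformly among those with at least
#' `extra_degree` non-neighbors and connects each to `extra_degree`
#' randomly chosen non-neighbors outside the hub set, so every hub's
#' degree rises by exactly `extra_degree`. Gives downstream centrality
#' stages a known recovery target.
#'
#' @param graph an igraph graph with named vertices.
#' @param n_hubs number of hubs to plant (0 returns the graph unchanged).
#' @param extra_degree edges added per hub.
#' @param seed integer seed.
#' @return list with `graph` (modified copy) and `hubs` (character).
#' @export
plant_hubs <- function(graph, n_hubs, extra_degree, seed) {
  n_hubs <- as.integer(n_hubs)
  extra_degree <- as.integer(extra_degree)
  n <- igraph::vcount(graph)
  if (n_hubs == 0L) return(list(graph = graph, hubs = character(0)))
  if (n_hubs > n) stop("more hubs than nodes", call. = FALSE)
  if (extra_degree > n - 1L) {
    stop("'extra_degree' exceeds the number of other nodes",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  all_names <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  eligible <- all_names[n - 1L - deg >= extra_degree]
  if (length(eligible) < n_hubs) {
    stop("cannot plant hubs: too few nodes with enough non-neighbors",
         call. = FALSE)
  }
  hubs <- sort(sample_vec(eligible, n_hubs))
  new_edges <- character(0)
  for (h in hubs) {
    nbrs <- names(igraph::neighbors(graph, h))
    candidates <- setdiff(all_names, c(h, nbrs, hubs))
    if (length(candidates) < extra_degree) {
      stop(sprintf("cannot add %d edges to hub %s", extra_degree, h),
           call. = FALSE)
    }
    picked <- sample_vec(candidates, extra_degree)
    new_edges <- c(new_edges, rbind(h, picked))
  }
  list(graph = igraph::add_edges(graph, new_edges), hubs = hubs)
}

#' Generate a two-group expression matrix with planted DEGs
#'
#' Entries are gene baseline (Normal(7, 1), a typical log2 microarray
#' intensity scale) plus Gaussian noise; a `deg_fraction` subset of genes
#' is planted as truly differential, half shifted up and half down in
#' the case group by `effect_size`. Genes in `always_deg` are forced
#' into the planted set (used to make planted interactome hubs
#' recoverable through the expression stage).
#'
#' @param config a [synth_config()]; the expression stage uses
#'   `config$seed + 2`.
#' @param gene_symbols_ genes to simulate (rows of the matrix).
#' @param always_deg genes guaranteed to be planted as DEGs.
#' @return list with `expression` (a [expression_matrix()]) and `truth`
#'   (`true_deg_genes`, `true_directions`).
#' @export
generate_expression <- function(config, gene_symbols_,
                                always_deg = character(0)) {
  stopifnot(inherits(config, "synth_config"))
  if (length(gene_symbols_) == 0L) {
    stop("'gene_symbols_' must be non-empty", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  genes <- gene_symbols_
  n_genes <- length(genes)
  n_samp <- config$n_case + config$n_control
  always_deg <- intersect(always_deg, genes)
  n_deg <- max(round(config$deg_fraction * n_genes), length(always_deg))
  extra <- setdiff(genes, always_deg)
  deg_genes <- c(always_deg,
                 sample_vec(extra, n_deg - length(always_deg)))
  n_up <- ceiling(n_deg / 2)
  dirs <- rep(c("up", "down"), c(n_up, n_deg - n_up))
  names(dirs) <- deg_genes

  baseline <- rnorm(n_genes, mean = 7, sd = 1)
  values <- baseline +
    matrix(rnorm(n_genes * n_samp, sd = config$noise_sd),
           nrow = n_genes)
  rownames(values) <- genes
  colnames(values) <- c(sprintf("case_%02d", seq_len(config$n_case)),
                        sprintf("control_%02d",
                                seq_len(config$n_control)))
  case_cols <- seq_len(config$n_case)
  shift <- ifelse(dirs == "up", config$effect_size, -config$effect_size)
  values[deg_genes, case_cols] <-
    values[deg_genes, case_cols, drop = FALSE] + shift
  groups <- rep(c("case", "control"),
                c(config$n_case, config$n_control))
  names(groups) <- colnames(values)
  list(
    expression = expression_matrix(values, groups,
                                   platform = "synthetic"),
    truth = list(true_deg_genes = deg_genes, true_directions = dirs)
  )
}

#' Generate a drug-target table biased toward hub genes
#'
#' Each drug receives 1-4 target genes sampled without replacement with
#' probability proportional to `degree^hub_bias`, an action label, and a
#' development-group set drawn from the approved / experimental /
#' investigational combinations seen in curated drug databases.
#'
#' @param graph interactome whose node degrees drive target sampling.
#' @param n_drugs number of drugs.
#' @param hub_bias degree exponent; 0 means uniform target sampling.
#' @param seed integer seed.
#' @return list with `drug_table` (a drug-target data.frame with columns
#'   gene, drug_id, drug_name, action, groups) and `truth`
#'   (`planted_drug_links`, a drug_name/gene pair table).
#' @export
generate_drug_table <- function(graph, n_drugs, hub_bias, seed) {
  n_drugs <- as.integer(n_drugs)
  if (n_drugs < 1L) stop("'n_drugs' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  genes <- igraph::V(graph)$name
  w <- igraph::degree(graph)^hub_bias
  group_combos <- list(
    "approved", "experimental", "investigational",
    c("approved", "investigational"),
    c("experimental", "investigational"),
    c("approved", "experimental", "investigational")
  )
  combo_w <- c(5, 1, 1, 4, 2, 1)
  actions <- c("inhibitor", "antagonist", "agonist", "")
  action_w <- c(4, 2, 1, 2)
  rows <- vector("list", n_drugs)
  for (d in seq_len(n_drugs)) {
    k <- sample.int(4L, 1L)
    targets <- sample_vec(genes, min(k, length(genes)), prob = w)
    grp <- paste(group_combos[[sample.int(length(group_combos), 1L,
                                          prob = combo_w)]],
                 collapse = ",")
    act <- actions[sample.int(length(actions), 1L, prob = action_w)]
    rows[[d]] <- data.frame(
      gene = targets,
      drug_id = sprintf("DBS%05d", d),
      drug_name = sprintf("Drug%03d", d),
      action = act,
      groups = grp,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(
    drug_table = tab,
    truth = list(planted_drug_links = tab[, c("drug_name", "gene")])
  )
}

#' Generate a complete synthetic study
#'
#' Runs the four sub-generators under the seed-derivation rule of
#' [synth_config()]: scale-free interactome, planted hubs, two-group
#' expression over a gene universe of `max(n_genes, interactome_nodes)`
#' symbols (so expression genes missing from the interactome exercise
#' the query-mapping stage), and a degree-biased drug table. Planted
#' hubs are always members of the true-DEG set.
#'
#' @param config a [synth_config()].
#' @return list with `interactome`, `hubs`, `expression`, `truth`
#'   (merged DEG/hub/drug truth) and `drug_table`.
#' @export
run_synthetic_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  net <- generate_interactome(config$interactome_nodes,
                              config$attachment_edges, config$seed)
  # one symbol width across stages, whichever count is larger
  universe_all <- gene_symbols(max(config$n_genes,
                                   config$interactome_nodes))
  igraph::V(net)$name <- universe_all[seq_len(config$interactome_nodes)]
  planted <- plant_hubs(net, config$n_planted_hubs,
                        config$hub_extra_degree, config$seed + 1L)
  universe <- universe_all[seq_len(config$n_genes)]
  expr <- generate_expression(config, universe,
                              always_deg = planted$hubs)
  drugs <- generate_drug_table(planted$graph, config$n_drugs,
                               config$hub_bias, config$seed + 3L)
  list(
    interactome = planted$graph,
    hubs = planted$hubs,
    expression = expr$expression,
    truth = c(expr$truth,
              list(planted_hub_genes = planted$hubs,
                   planted_drug_links = drugs$truth$planted_drug_links)),
    drug_table = drugs$drug_table
  )
}
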