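#' Pipeline configuration
#'
#' Exactly one input mode must be set: `synth` (a [synth_config()],
#' generating the study) or the real-data trio of `expression_file` /
#' `groups_file` plus an interactome source (`mitab_files` or
#' `edge_file`). `drug_table_file` defaults to the packaged curated
#' drug-target table; in synthetic mode the generated drug table is
#' used unless a file is given.
#'
#' @param synth optional [synth_config()].
#' @param expression_file,groups_file expression TSV pair
#'   (see [read_expression()]).
#' @param mitab_files character vector of PSI-MITAB files (unioned).
#' @param edge_file 2-column edge TSV alternative.
#' @param drug_table_file drug-target TSV (see [read_drug_table()]).
#' @param de_route `"anova"` or `"fisher_bh"`.
#' @param alpha DEG significance threshold.
#' @param use_lcc compute centralities on the largest connected
#'   component (required by the distance-based measures; disable only
#'   for graphs known to be connected).
#' @param k,min_measures consensus parameters (top-k lists, minimum
#'   supporting measures).
#' @param allowed_groups drug development-status filter.
#' @param seed master seed (overrides `synth$seed` when given).
#' @param out_dir output directory for all stage tables.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, expression_file = NULL,
                            groups_file = NULL, mitab_files = NULL,
                            edge_file = NULL, drug_table_file = NULL,
                            de_route = "anova", alpha = 0.05,
                            use_lcc = TRUE, k = 30L, min_measures = 2L,
                            allowed_groups = c("approved",
                                               "experimental",
                                               "investigational"),
                            seed = NULL, out_dir = "netprio_out") {
  real <- !is.null(expression_file)
  if (is.null(synth) == !real) {
    stop("set exactly one of 'synth' or real expression inputs",
         call. = FALSE)
  }
  if (real && is.null(groups_file)) {
    stop("real mode needs 'groups_file'", call. = FALSE)
  }
  if (real && is.null(mitab_files) && is.null(edge_file)) {
    stop("real mode needs an interactome ('mitab_files' or 'edge_file')",
         call. = FALSE)
  }
  if (!is.null(synth)) {
    stopifnot(inherits(synth, "synth_config"))
    if (!is.null(seed)) synth$seed <- as.integer(seed)
    seed <- synth$seed
  }
  de_route <- match.arg(de_route, c("anova", "fisher_bh"))
  structure(list(
    synth = synth, expression_file = expression_file,
    groups_file = groups_file, mitab_files = mitab_files,
    edge_file = edge_file, drug_table_file = drug_table_file,
    de_route = de_route, alpha = alpha, use_lcc = isTRUE(use_lcc),
    k = as.integer(k), min_measures = as.integer(min_measures),
    allowed_groups = tolower(allowed_groups),
    seed = as.integer(seed %||% 1L), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirroring the [pipeline_config()] arguments; a `synth`
#' block mirrors [synth_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  do.call(pipeline_config, y)
}

#' Run the prioritization pipeline end-to-end
#'
#' Stages: (synthetic study) -> differential expression -> interactome
#' -> QQPPI extraction -> largest component -> five centralities ->
#' top-k / consensus -> drug mapping. Every stage writes a fixed-format
#' TSV under `config$out_dir`, and identical config + seed gives
#' byte-identical output trees. A failing stage aborts with the stage
#' named and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return a `RunReport` list of per-stage counts and the parameter
#'   echo (invisibly written to `report.tsv` as well).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(failed_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  drug_records <- NULL
  if (!is.null(config$synth)) {
    study <- stage("synthetic", {
      s <- run_synthetic_study(config$synth)
      write_expression(s$expression, file.path(out, "expression.tsv"),
                       file.path(out, "sample_groups.tsv"))
      write_edge_tsv(s$interactome,
                     file.path(out, "interactome_edges.tsv"))
      write_psimitab(s$interactome,
                     file.path(out, "interactome.mitab"))
      write_tsv(data.frame(gene = s$truth$true_deg_genes,
                           direction = unname(s$truth$true_directions),
                           is_planted_hub = s$truth$true_deg_genes %in%
                             s$hubs,
                           stringsAsFactors = FALSE),
                file.path(out, "truth_degs.tsv"))
      write_tsv(s$drug_table, file.path(out, "drug_table.tsv"))
      s
    })
    expression <- study$expression
    interactome <- study$interactome
    drug_records <- study$drug_table
    say("synthetic: %d genes, interactome %d nodes / %d edges, %d hubs",
        nrow(expression$values), igraph::vcount(interactome),
        igraph::ecount(interactome), length(study$hubs))
  } else {
    expression <- stage("load_expression",
                        read_expression(config$expression_file,
                                        config$groups_file))
    interactome <- stage("load_interactome", {
      if (!is.null(config$mitab_files)) {
        recs <- do.call(rbind, lapply(config$mitab_files,
                                      read_psimitab))
        build_graph(recs)
      } else {
        read_edge_tsv(config$edge_file)
      }
    })
    say("loaded: %d genes x %d samples; interactome %d nodes / %d edges",
        nrow(expression$values), ncol(expression$values),
        igraph::vcount(interactome), igraph::ecount(interactome))
  }
  if (!is.null(config$drug_table_file)) {
    drug_records <- stage("load_drug_table",
                          read_drug_table(config$drug_table_file))
  }
  if (is.null(drug_records)) {
    drug_records <- read_drug_table(
      system.file("extdata", "table2_drug_targets.tsv",
                  package = "netprio"))
  }

  degs <- stage("differential_expression", {
    d <- call_degs(expression, alpha = config$alpha,
                   route = config$de_route)
    write_tsv(d, file.path(out, "degs.tsv"))
    d
  })
  say("differential expression (%s): %d DEGs (%d up / %d down)",
      config$de_route, nrow(degs), sum(degs$direction == "up"),
      sum(degs$direction == "down"))

  qq <- stage("qqppi", extract_qqppi(interactome, degs))
  qq_nodes <- igraph::vcount(qq$graph)
  qq_edges <- igraph::ecount(qq$graph)
  analysis <- if (config$use_lcc) largest_component(qq) else qq
  stage("qqppi", write_qqppi(qq, file.path(out, "qqppi_edges.tsv"),
                             file.path(out, "qqppi_nodes.tsv")))
  say("QQPPI: %d nodes / %d edges; analysis component %d nodes",
      qq_nodes, qq_edges, igraph::vcount(analysis$graph))

  cent <- stage("centrality", {
    tb <- compute_all(analysis$graph)
    write_centrality(tb, file.path(out, "centrality.tsv"))
    tb
  })

  selection <- stage("prioritize", {
    sel <- consensus_central(top_k_per_measure(cent, k = config$k),
                             min_measures = config$min_measures)
    write_consensus(sel, file.path(out, "top_sets.tsv"),
                    file.path(out, "consensus.tsv"))
    sel
  })
  say("consensus: %d central node(s)", nrow(selection$consensus))

  mapped <- stage("drug_mapping", {
    m <- map_drugs(selection, drug_records,
                   allowed_groups = config$allowed_groups)
    write_tsv(m, file.path(out, "prioritized_drugs.tsv"))
    m
  })
  say("drug mapping: %d drug-target pair(s) over %d target(s)",
      nrow(mapped), length(unique(mapped$gene)))

  report <- list(
    n_genes_tested = nrow(expression$values),
    n_degs = nrow(degs),
    n_degs_up = sum(degs$direction == "up"),
    n_degs_down = sum(degs$direction == "down"),
    n_queries_unmapped = qq$n_queries_unmapped,
    qqppi_nodes = qq_nodes,
    qqppi_edges = qq_edges,
    lcc_nodes = igraph::vcount(analysis$graph),
    consensus_size = nrow(selection$consensus),
    n_targets_with_drugs = length(unique(mapped$gene)),
    n_drug_target_pairs = nrow(mapped),
    de_route = config$de_route,
    alpha = config$alpha,
    use_lcc = config$use_lcc,
    k = config$k,
    min_measures = config$min_measures,
    allowed_groups = paste(config$allowed_groups, collapse = ","),
    seed = config$seed,
    netprio_version = as.character(utils::packageVersion("netprio"))
  )
  fmt <- function(v) if (is.numeric(v)) sprintf("%.10g", v)
                     else as.character(v)
  write_tsv(data.frame(key = names(report),
                       value = vapply(report, fmt, character(1)),
                       stringsAsFactors = FALSE),
            file.path(out, "report.tsv"))
  invisible(report)
}
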