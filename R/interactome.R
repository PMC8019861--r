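#' Read PSI-MITAB 2.5 interaction records
#'
#' Minimal-dialect reader for the tab-separated interchange format used
#' by the IMEx-consortium interaction databases. Only the identifier
#' columns (1, 2), the alias columns (5, 6) and the source-database
#' column (13) are interpreted; gene symbols are taken from alias
#' entries tagged `(gene name)` when present, otherwise from the
#' identifier column, and uppercased. Lines with fewer than 15 columns
#' are skipped and counted; a leading line starting with `#` is treated
#' as a header.
#'
#' @param path a file path, or a character vector of MITAB lines.
#' @return data.frame of interaction records (interactor_a,
#'   interactor_b, source_db, detection_method, publication) with
#'   attribute `n_skipped`; errors if no line parses.
#' @export
read_psimitab <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path)
  } else {
    as.character(path)
  }
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(sprintf("read_psimitab: skipped %d line(s) with < 15 columns",
                    n_skipped))
  }
  fields <- fields[ok]
  if (length(fields) == 0L) {
    stop("no parseable PSI-MITAB records", call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  a <- mitab_symbol(get(5), get(1))
  b <- mitab_symbol(get(6), get(2))
  rec <- data.frame(
    interactor_a = a,
    interactor_b = b,
    source_db = mitab_paren(get(13)),
    detection_method = mitab_paren(get(7)),
    publication = get(9),
    stringsAsFactors = FALSE
  )
  keep <- nzchar(rec$interactor_a) & nzchar(rec$interactor_b)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf(
      "read_psimitab: dropped %d record(s) without a usable symbol",
      dropped))
  }
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no parseable PSI-MITAB records",
                            call. = FALSE)
  rownames(rec) <- NULL
  attr(rec, "n_skipped") <- n_skipped + dropped
  rec
}

# alias column entries look like db:VALUE(type)|db:VALUE(type)...;
# prefer the entry typed "gene name", else fall back to the id column.
mitab_symbol <- function(alias_col, id_col) {
  pick <- function(alias, id) {
    if (alias != "-" && nzchar(alias)) {
      parts <- strsplit(alias, "|", fixed = TRUE)[[1]]
      tagged <- grep("\\(gene name\\)\\s*$", parts, value = TRUE)
      if (length(tagged) > 0L) {
        return(sub("\\(.*$", "", sub("^[^:]*:", "", tagged[1])))
      }
    }
    if (id != "-" && nzchar(id)) {
      return(sub("\\(.*$", "", sub("^[^:]*:", "", id)))
    }
    ""
  }
  toupper(trimws(gsub('"', "", mapply(pick, alias_col, id_col,
                                      USE.NAMES = FALSE))))
}

# text inside the first parentheses, else the raw field
mitab_paren <- function(x) {
  has <- grepl("\\(", x)
  out <- x
  out[has] <- sub("^[^(]*\\(([^)]*)\\).*$", "\\1", x[has])
  out[out == "-"] <- ""
  out
}

#' Build an interactome graph from interaction records
#'
#' Undirected simple graph keyed by gene symbol: duplicate edges (in
#' either orientation) are collapsed with merged source-database
#' provenance, and self-interactions are dropped — the centrality
#' definitions downstream assume simple graphs. Symbols seen only in
#' self-interactions are retained as isolated nodes when
#' `keep_isolated = TRUE`.
#'
#' @param records data.frame with columns interactor_a, interactor_b
#'   and optionally source_db (from [read_psimitab()] or built by hand).
#'   Several record sets (one per source database) can be concatenated
#'   with `rbind` before this call; provenance is kept per database.
#' @param keep_isolated keep self-interaction-only symbols as isolated
#'   nodes.
#' @return an igraph graph with edge attribute `sources`.
#' @export
build_graph <- function(records, keep_isolated = FALSE) {
  if (nrow(records) == 0L) stop("no interaction records", call. = FALSE)
  a0 <- toupper(records$interactor_a)
  b0 <- toupper(records$interactor_b)
  src <- if ("source_db" %in% names(records)) records$source_db
         else rep("", nrow(records))
  self <- a0 == b0
  a <- pmin(a0[!self], b0[!self])
  b <- pmax(a0[!self], b0[!self])
  key <- paste(a, b, sep = "\r")
  sources <- vapply(split(src[!self], key), function(s) {
    paste(sort(unique(s[nzchar(s)])), collapse = ",")
  }, character(1))
  uniq <- !duplicated(key)
  ed <- data.frame(a = a[uniq], b = b[uniq],
                   stringsAsFactors = FALSE)
  ed$sources <- unname(sources[paste(ed$a, ed$b, sep = "\r")])
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  vertices <- sort(unique(c(ed$a, ed$b)))
  if (keep_isolated) {
    lonely <- setdiff(unique(a0[self]), vertices)
    vertices <- sort(c(vertices, lonely))
  }
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = vertices)
}

#' Translate record identifiers through a user symbol map
#'
#' Applies an accession-to-symbol map (e.g. UniProt accession to HGNC
#' symbol) to both interactor columns; records with an unmapped side
#' are dropped and counted in attribute `n_unmapped`.
#'
#' @param records interaction-record data.frame.
#' @param id_map data.frame with columns `from`, `to`.
#' @return remapped records.
#' @export
apply_id_map <- function(records, id_map) {
  lut <- toupper(id_map$to)
  names(lut) <- toupper(id_map$from)
  a <- unname(lut[toupper(records$interactor_a)])
  b <- unname(lut[toupper(records$interactor_b)])
  keep <- !is.na(a) & !is.na(b)
  out <- records[keep, , drop = FALSE]
  out$interactor_a <- a[keep]
  out$interactor_b <- b[keep]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(!keep)
  out
}

#' Read / write the normalized edge TSV
#'
#' Two mandatory columns (`symbol_a`, `symbol_b`) and an optional
#' `sources` provenance column; the plain-text alternative to PSI-MITAB.
#'
#' @param path TSV file path.
#' @return for the reader, an igraph graph (via [build_graph()]).
#' @export
read_edge_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  rec <- data.frame(interactor_a = tab$symbol_a,
                    interactor_b = tab$symbol_b,
                    source_db = tab$sources %||% "",
                    stringsAsFactors = FALSE)
  build_graph(rec)
}

#' @rdname read_edge_tsv
#' @param graph igraph graph to write.
#' @export
write_edge_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  src <- igraph::edge_attr(graph, "sources") %||%
    rep("", nrow(el))
  df <- data.frame(symbol_a = a, symbol_b = b, sources = src,
                   stringsAsFactors = FALSE)
  df <- df[order(df$symbol_a, df$symbol_b), , drop = FALSE]
  write_tsv(df, path)
}

#' Write a graph as minimal PSI-MITAB 2.5
#'
#' Fifteen-column dialect: synthetic identifiers in columns 1-2, gene
#' names in the alias columns, source database (edge `sources`
#' attribute) in column 13, `-` elsewhere.
#'
#' @param graph igraph graph with named vertices.
#' @param path output file path.
#' @export
write_psimitab <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  src <- igraph::edge_attr(graph, "sources") %||%
    rep("synthetic", nrow(el))
  src[!nzchar(src)] <- "synthetic"
  header <- paste0("#ID(s) interactor A\tID(s) interactor B\t",
                   "Alt. ID(s) interactor A\tAlt. ID(s) interactor B\t",
                   "Alias(es) interactor A\tAlias(es) interactor B\t",
                   "Interaction detection method(s)\t",
                   "Publication 1st author(s)\t",
                   "Publication Identifier(s)\t",
                   "Taxid interactor A\tTaxid interactor B\t",
                   "Interaction type(s)\tSource database(s)\t",
                   "Interaction identifier(s)\tConfidence value(s)")
  lines <- sprintf(
    paste0("synthetic:%s\tsynthetic:%s\t-\t-\t",
           "synthetic:%s(gene name)\tsynthetic:%s(gene name)\t",
           "-\t-\t-\ttaxid:9606(human)\ttaxid:9606(human)\t-\t",
           "psi-mi:\"MI:0000\"(%s)\t-\t-"),
    el[, 1], el[, 2], el[, 1], el[, 2], src)
  writeLines(c(header, lines), path)
  invisible(path)
}
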