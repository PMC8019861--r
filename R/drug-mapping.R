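#' Read a drug-target table
#'
#' TSV with header columns `gene`, `drug_id`, `drug_name`, `action`,
#' `groups` (development-status tokens, comma-separated). Gene symbols
#' are uppercased, group tokens lowercased and sorted; `-` or empty
#' action means no annotated action. Rows missing a gene, drug name or
#' group set are skipped and counted in attribute `n_skipped`.
#'
#' The curated drug-target table shipped with the package
#' (`system.file("extdata", "table2_drug_targets.tsv",
#' package = "netprio")`) follows this schema.
#'
#' @param path TSV file path.
#' @return data.frame of validated records.
#' @export
read_drug_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("gene", "drug_id", "drug_name", "action", "groups")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("drug table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, needed]
  tab$gene <- toupper(trimws(tab$gene))
  tab$drug_name <- trimws(tab$drug_name)
  tab$action <- trimws(tab$action)
  tab$action[tab$action == "-"] <- ""
  tab$groups <- vapply(strsplit(tab$groups, ","), function(g) {
    paste(sort(unique(tolower(trimws(g[nzchar(trimws(g))])))),
          collapse = ",")
  }, character(1))
  ok <- nzchar(tab$gene) & nzchar(tab$drug_name) & nzchar(tab$groups)
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

group_sets <- function(groups) {
  strsplit(groups, ",", fixed = TRUE)
}

#' Map consensus central proteins to candidate drugs
#'
#' Joins the consensus set against a drug-target table, keeping records
#' whose development-group set intersects `allowed_groups`; consensus
#' genes with no surviving drug are omitted. Drugs are keyed by
#' normalized drug name (curated tables repeat accession numbers
#' across target rows).
#'
#' @param consensus a `consensus_selection` (or a data.frame with
#'   columns node, n_measures).
#' @param records drug-target data.frame from [read_drug_table()] or
#'   [generate_drug_table()].
#' @param allowed_groups development-status filter.
#' @return data.frame (gene, n_measures, drug_id, drug_name, action,
#'   groups), one row per drug-target pair, sorted by n_measures
#'   descending, then gene, then drug name.
#' @export
map_drugs <- function(consensus, records,
                      allowed_groups = c("approved", "experimental",
                                         "investigational")) {
  cons <- if (inherits(consensus, "consensus_selection")) {
    consensus$consensus
  } else {
    consensus
  }
  if (nrow(cons) == 0L) stop("empty consensus set", call. = FALSE)
  allowed_groups <- tolower(allowed_groups)
  grp <- group_sets(records$groups)
  grp_ok <- vapply(grp, function(g) any(g %in% allowed_groups),
                   logical(1))
  hits <- records[grp_ok & records$gene %in% cons$node, , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("gene", "drug_name")]), ,
               drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(gene = character(0), n_measures = integer(0),
                      drug_id = character(0), drug_name = character(0),
                      action = character(0), groups = character(0),
                      stringsAsFactors = FALSE))
  }
  nm_lut <- cons$n_measures
  names(nm_lut) <- cons$node
  out <- data.frame(
    gene = hits$gene,
    n_measures = as.integer(nm_lut[hits$gene]),
    drug_id = hits$drug_id,
    drug_name = hits$drug_name,
    action = hits$action,
    groups = hits$groups,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_measures, out$gene, out$drug_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a drug-target table
#'
#' @param records drug-target data.frame.
#' @return list with `n_unique_drugs`, `n_unique_targets` and
#'   `per_drug_targets` (named integer vector of distinct target genes
#'   per drug, sorted by drug name).
#' @export
drug_summary <- function(records) {
  if (nrow(records) == 0L) stop("empty drug table", call. = FALSE)
  key <- tolower(records$drug_name)
  per <- vapply(split(records$gene, key),
                function(g) length(unique(g)), integer(1))
  # report under the first-seen display name for each normalized key
  display <- records$drug_name[!duplicated(key)]
  names(display) <- key[!duplicated(key)]
  names(per) <- unname(display[names(per)])
  per <- per[order(names(per))]
  list(n_unique_drugs = length(per),
       n_unique_targets = length(unique(records$gene)),
       per_drug_targets = per)
}
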