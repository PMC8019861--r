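#' Two-group gene expression matrix
#'
#' Container for a normalized (log-scale) expression matrix with a
#' case/control label per sample. Missing values are rejected here: the
#' pipeline treats missing-data handling as a pre-filter the user must
#' apply before loading, never as silent imputation.
#'
#' @param values numeric gene x sample matrix with row and column names.
#' @param sample_groups named character vector (`"case"`/`"control"`),
#'   one entry per column of `values`.
#' @param platform free-text platform label.
#' @return object of class `gene_expression_matrix`.
#' @export
expression_matrix <- function(values, sample_groups,
                              platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values; filter or impute ",
         "before loading", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs gene rownames and sample colnames",
         call. = FALSE)
  }
  sample_groups <- sample_groups[colnames(values)]
  if (anyNA(sample_groups) ||
      !all(sample_groups %in% c("case", "control"))) {
    stop("every sample needs a 'case' or 'control' group label",
         call. = FALSE)
  }
  if (!all(c("case", "control") %in% sample_groups)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  structure(list(values = values, sample_groups = sample_groups,
                 platform = platform),
            class = "gene_expression_matrix")
}

#' @export
print.gene_expression_matrix <- function(x, ...) {
  cat(sprintf(
    "gene_expression_matrix: %d genes x %d samples (%d case / %d control), platform %s\n",
    nrow(x$values), ncol(x$values), sum(x$sample_groups == "case"),
    sum(x$sample_groups == "control"), x$platform))
  invisible(x)
}

#' One-way two-group ANOVA
#'
#' Fixed-effects one-way ANOVA for two groups: F = SSB / MSW on
#' (1, n - 2) degrees of freedom, with the upper-tail p-value. For two
#' groups this F is identically the square of the pooled-variance t
#' statistic. Degenerate inputs where both groups are constant return
#' p = 1 (equal constants) or p = 0 (different constants), each with a
#' warning.
#'
#' @param case_values,control_values numeric vectors, >= 2 values each.
#' @return named vector `c(F = ..., p = ...)`.
#' @export
anova_pvalue <- function(case_values, control_values) {
  if (length(case_values) < 2L || length(control_values) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  n1 <- length(case_values)
  n2 <- length(control_values)
  n <- n1 + n2
  m1 <- mean(case_values)
  m2 <- mean(control_values)
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((case_values - m1)^2) + sum((control_values - m2)^2)
  if (ssw == 0) {
    if (ssb == 0) {
      warning("both groups constant and equal; F undefined, p = 1")
      return(c(F = 0, p = 1))
    }
    warning("both groups constant and different; p = 0 limit")
    return(c(F = Inf, p = 0))
  }
  f <- ssb / (ssw / (n - 2))
  c(F = f, p = pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the observed
#' table's probability (with the conventional relative tolerance on the
#' comparison, as implemented by [stats::fisher.test()]).
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all-zero table", call. = FALSE)
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, scale the
#' i-th smallest p by m/i, enforce monotonicity by a cumulative minimum
#' from the largest rank, cap at 1, and return values in the original
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Per-gene minimum p across platforms
#'
#' For studies measuring genes on several array platforms, keeps for
#' every gene the smallest p-value over the platforms that measured it.
#'
#' @param tables list of named numeric vectors (gene -> p).
#' @return named numeric vector over the union of genes, sorted by name.
#' @export
min_p_across_platforms <- function(tables) {
  if (length(tables) == 0L) stop("need at least one table",
                                 call. = FALSE)
  genes <- sort(unique(unlist(lapply(tables, names))))
  out <- rep(Inf, length(genes))
  names(out) <- genes
  for (tab in tables) {
    out[names(tab)] <- pmin(out[names(tab)], tab)
  }
  out
}

# Row-wise two-group F statistics (vectorized one-way ANOVA).
row_anova <- function(values, case_idx, control_idx) {
  n1 <- length(case_idx)
  n2 <- length(control_idx)
  n <- n1 + n2
  m1 <- rowMeans(values[, case_idx, drop = FALSE])
  m2 <- rowMeans(values[, control_idx, drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((values[, case_idx, drop = FALSE] - m1)^2) +
    rowSums((values[, control_idx, drop = FALSE] - m2)^2)
  f <- ssb / (ssw / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  list(F = f, p = p, ssw = ssw, case_mean = m1, control_mean = m2)
}

# Median-split 2x2 Fisher p per gene: group x (above / below-or-equal
# the gene's overall median); ties go to the below-or-equal cell.
row_fisher_median_split <- function(values, case_idx, control_idx) {
  apply_one <- function(row) {
    med <- median(row)
    above <- row > med
    a <- sum(above[case_idx])
    b <- length(case_idx) - a
    cc <- sum(above[control_idx])
    d <- length(control_idx) - cc
    stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2,
                              byrow = TRUE))$p.value
  }
  apply(values, 1, apply_one)
}

#' Call differentially expressed genes
#'
#' Two statistical routes over a two-group expression matrix:
#' \describe{
#'   \item{`anova`}{per-gene one-way ANOVA; genes with raw p below
#'     `alpha` are called (BH-adjusted p is still reported).}
#'   \item{`fisher_bh`}{each gene is dichotomized at its overall median
#'     (ties to the below-or-equal cell), the 2x2 group-by-level table
#'     is tested by the two-sided Fisher exact test, and genes with
#'     BH-adjusted p below `alpha` are called. The median-split table
#'     construction is this package's interpretation of a
#'     count-based route; per-gene tables can be supplied directly via
#'     [call_degs_from_tables()].}
#' }
#' Direction is `up` when the case mean exceeds the control mean (both
#' routes). Genes constant across all samples are reported as
#' non-significant and counted in a warning.
#'
#' @param mat a [expression_matrix()].
#' @param alpha significance threshold on the route's p-value.
#' @param route `"anova"` or `"fisher_bh"`.
#' @return `DEGTable` data.frame with columns gene, direction, p_value,
#'   p_adjusted, source — significant genes only, sorted by p then gene.
#' @export
call_degs <- function(mat, alpha = 0.05,
                      route = c("anova", "fisher_bh")) {
  stopifnot(inherits(mat, "gene_expression_matrix"))
  route <- match.arg(route)
  values <- mat$values
  case_idx <- which(mat$sample_groups == "case")
  control_idx <- which(mat$sample_groups == "control")
  an <- row_anova(values, case_idx, control_idx)
  constant <- apply(values, 1, function(r) all(r == r[1]))
  if (any(constant)) {
    warning(sprintf("%d gene(s) constant across all samples; %s",
                    sum(constant), "reported as non-significant"))
  }
  if (route == "anova") {
    p <- an$p
    p[constant] <- 1
    p_adj <- bh_adjust(pmax(p, .Machine$double.xmin))
    keep <- p < alpha & !constant
    source_lab <- "anova"
  } else {
    p <- row_fisher_median_split(values, case_idx, control_idx)
    p[constant] <- 1
    p_adj <- bh_adjust(p)
    keep <- p_adj < alpha & !constant
    source_lab <- "fisher"
  }
  direction <- ifelse(an$case_mean > an$control_mean, "up", "down")
  out <- data.frame(
    gene = rownames(values)[keep],
    direction = direction[keep],
    p_value = p[keep],
    p_adjusted = p_adj[keep],
    source = rep(source_lab, sum(keep)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call DEGs from user-supplied 2x2 tables
#'
#' Pluggable variant of the Fisher route: the caller provides one 2x2
#' count table per gene (e.g. present/absent calls by group) plus a
#' direction flag, and the BH-corrected Fisher p decides significance.
#'
#' @param tables named list of 2x2 integer matrices (gene -> table).
#' @param directions named character vector (`"up"`/`"down"`) per gene.
#' @param alpha threshold on the BH-adjusted p-value.
#' @return `DEGTable` data.frame as in [call_degs()].
#' @export
call_degs_from_tables <- function(tables, directions, alpha = 0.05) {
  if (length(tables) == 0L) stop("empty table list", call. = FALSE)
  p <- vapply(tables, function(tb) {
    fisher_exact_two_sided(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
  }, numeric(1))
  p_adj <- bh_adjust(p)
  keep <- p_adj < alpha
  out <- data.frame(
    gene = names(tables)[keep],
    direction = unname(directions[names(tables)[keep]]),
    p_value = unname(p[keep]),
    p_adjusted = unname(p_adj[keep]),
    source = "fisher",
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write the expression TSV pair
#'
#' The on-disk form is a genes x samples TSV (first column `gene`,
#' header row of sample IDs) plus a sidecar TSV mapping `sample` to
#' `group`. The same schema serves synthetic and real data.
#'
#' @param values_path path of the expression TSV.
#' @param groups_path path of the sample-group sidecar TSV.
#' @param platform platform label to attach.
#' @return a [expression_matrix()].
#' @export
read_expression <- function(values_path, groups_path,
                            platform = "unknown") {
  tab <- read.delim(values_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  grp <- read.delim(groups_path, stringsAsFactors = FALSE)
  groups <- grp$group
  names(groups) <- grp$sample
  expression_matrix(values, groups, platform = platform)
}

#' @rdname read_expression
#' @param mat a [expression_matrix()] to write.
#' @export
write_expression <- function(mat, values_path, groups_path) {
  stopifnot(inherits(mat, "gene_expression_matrix"))
  out <- data.frame(gene = rownames(mat$values), mat$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(out, values_path)
  write_tsv(data.frame(sample = names(mat$sample_groups),
                       group = unname(mat$sample_groups),
                       stringsAsFactors = FALSE),
            groups_path)
  invisible(c(values_path, groups_path))
}

# fixed-format TSV writer shared by all stages (byte-determinism)
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
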