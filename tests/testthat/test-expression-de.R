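test_that("two-group ANOVA matches hand-computed and t-test oracles", {
  expect_equal(unname(anova_pvalue(c(1, 2, 3), c(1, 2, 3))),
               c(0, 1))
  res <- anova_pvalue(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res["F"]), 13.5)  # SSB = 13.5, MSW = 1
  expect_equal(unname(res["p"]),
               pf(13.5, 1, 4, lower.tail = FALSE))
  # F is the squared pooled-variance t statistic, p identical
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    res <- anova_pvalue(x, y)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(unname(res["F"]), unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(unname(res["p"]), tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA is invariant to group exchange and constant shifts", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(6)
    y <- rnorm(8, 0.5)
    expect_equal(anova_pvalue(x, y)["F"], anova_pvalue(y, x)["F"])
    expect_equal(anova_pvalue(x, y)["p"],
                 anova_pvalue(x + 3.7, y + 3.7)["p"])
  }
})

test_that("ANOVA flags degenerate constant inputs", {
  expect_warning(res <- anova_pvalue(c(2, 2, 2), c(2, 2)), "equal")
  expect_equal(unname(res["p"]), 1)
  expect_warning(res <- anova_pvalue(c(2, 2, 2), c(5, 5)), "different")
  expect_equal(unname(res["p"]), 0)
  expect_error(anova_pvalue(1, c(1, 2)), "at least 2")
})

test_that("Fisher two-sided p equals hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact_two_sided(0, 5, 5, 0), 2 / 252)
  expect_equal(fisher_exact_two_sided(2, 2, 2, 2), 1)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "all-zero")
  # random spot check against the enumeration oracle
  set.seed(11)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(4:20, 1), rep(1 / 4, 4)))
    if (sum(cells) == 0) next
    expect_equal(do.call(fisher_exact_two_sided, as.list(cells)),
                 do.call(fisher_enum, as.list(cells)),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.02, 0.02, 0.02)), c(0.02, 0.02, 0.02))
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  # permutation equivariance
  set.seed(3)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # adjusted never below raw
  expect_true(all(bh_adjust(p) >= p))
})

test_that("cross-platform merge keeps the per-gene minimum p", {
  tabs <- list(c(X = 0.03, Y = 0.5, Z = 0.2),
               c(X = 0.2, Y = 0.01, W = 0.7))
  merged <- min_p_across_platforms(tabs)
  expect_equal(merged[["X"]], 0.03)
  expect_equal(merged[["Y"]], 0.01)
  expect_equal(merged[["W"]], 0.7)  # single-platform gene kept as-is
  expect_equal(min_p_across_platforms(list(tabs[[1]])),
               tabs[[1]][order(names(tabs[[1]]))])
})

test_that("DEG calling respects route, threshold and degeneracy rules", {
  cfg <- synth_config(n_genes = 300, deg_fraction = 0.2,
                      effect_size = 3, noise_sd = 1, n_case = 10,
                      n_control = 10, seed = 21)
  out <- generate_expression(cfg, gene_symbols(300))
  mat <- out$expression
  # alpha = 0 calls nothing
  expect_equal(nrow(call_degs(mat, alpha = 0, route = "anova")), 0)
  degs_a <- call_degs(mat, alpha = 0.05, route = "anova")
  expect_true(all(degs_a$p_value < 0.05))
  expect_true(all(degs_a$p_adjusted >= degs_a$p_value))
  expect_true(all(degs_a$source == "anova"))
  degs_f <- call_degs(mat, alpha = 0.05, route = "fisher_bh")
  expect_true(all(degs_f$p_adjusted < 0.05))
  expect_true(all(degs_f$source == "fisher"))
  # both routes recover most strong planted effects
  expect_gte(length(intersect(degs_f$gene, out$truth$true_deg_genes)),
             0.8 * length(out$truth$true_deg_genes))
  # a constant gene is reported as non-significant with a warning
  mat$values[5, ] <- 3
  expect_warning(degs_c <- call_degs(mat, 0.05, "anova"), "constant")
  expect_false(rownames(mat$values)[5] %in% degs_c$gene)
})

test_that("user-supplied 2x2 tables drive the pluggable fisher route", {
  tables <- list(
    GA = matrix(c(9, 1, 1, 9), 2, byrow = TRUE),
    GB = matrix(c(5, 5, 5, 5), 2, byrow = TRUE),
    GC = matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  )
  dirs <- c(GA = "up", GB = "down", GC = "down")
  degs <- call_degs_from_tables(tables, dirs, alpha = 0.05)
  expect_setequal(degs$gene, c("GA", "GC"))
  expect_identical(degs$direction[degs$gene == "GC"], "down")
})

test_that("expression container rejects malformed input", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  grp <- c(s1 = "case", s2 = "case", s3 = "control", s4 = "control")
  expect_s3_class(expression_matrix(v, grp), "gene_expression_matrix")
  v_na <- v
  v_na[1, 1] <- NA
  expect_error(expression_matrix(v_na, grp), "missing values")
  expect_error(expression_matrix(v, grp[-1]), "group label")
  expect_error(expression_matrix(v, setNames(rep("case", 4),
                                             colnames(v))),
               "both groups")
})
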