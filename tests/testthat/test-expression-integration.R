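mk_matrices <- function(n_genes = 5, n_samples = 20, seed = 1) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  samples <- paste0("s", seq_len(n_samples))
  cn <- matrix(sample(0:5, n_genes * n_samples, replace = TRUE),
               n_genes, dimnames = list(genes, samples))
  list(cn = cn, samples = samples, genes = genes)
}

test_that("perfectly linear expression gives r = 1 and constant CN is excluded", {
  m <- mk_matrices()
  expr <- 2 + 0.5 * m$cn
  m$cn["G3", ] <- 2L  # constant copy number
  res <- cn_expression_correlation(m$cn, expr)
  tested <- res[res$gene_symbol != "G3", ]
  expect_true(all(abs(tested$r - 1) < 1e-12))
  g3 <- res[res$gene_symbol == "G3", ]
  expect_true(is.na(g3$r))
  expect_identical(g3$reason, "zero CN variance")
  expect_error(cn_expression_correlation(m$cn[, 1:2], expr[, 1:2]),
               "3 shared samples")
})

test_that("a planted moderate correlation is estimated within +/- 0.1", {
  set.seed(52)
  n <- 200
  cn <- matrix(sample(0:6, n, replace = TRUE), 1,
               dimnames = list("G1", paste0("s", 1:n)))
  sd_cn <- sd(cn[1, ])
  r_target <- 0.4
  noise_sd <- sd_cn * sqrt(1 / r_target^2 - 1)  # slope 1 => r = 0.4
  expr <- cn + matrix(rnorm(n, 0, noise_sd), 1,
                      dimnames = dimnames(cn))
  res <- cn_expression_correlation(cn, expr)
  expect_lt(abs(res$r - r_target), 0.1)
})

test_that("correlation is invariant to sample order and per-gene affine rescaling", {
  m <- mk_matrices(seed = 3)
  set.seed(53)
  expr <- 1 + 0.3 * m$cn + matrix(rnorm(length(m$cn)), nrow(m$cn),
                                  dimnames = dimnames(m$cn))
  base <- cn_expression_correlation(m$cn, expr)
  perm <- sample(m$samples)
  shuf <- cn_expression_correlation(m$cn[, perm], expr)
  expect_equal(shuf$r, base$r)
  scaled <- cn_expression_correlation(m$cn, 7 + 3 * expr)
  expect_equal(scaled$r, base$r)
  expect_equal(scaled$p_value, base$p_value)
})

test_that("correlated-gene selection applies strict thresholds", {
  res <- data.frame(gene_symbol = c("a", "b", "c", "d"),
                    r = c(0.4, 0.9, 0.41, NA),
                    q_value = c(0.01, 0.5, 0.049, NA))
  expect_identical(select_correlated(res), "c")
  expect_identical(select_correlated(res[0, ]), character())
})

test_that("differential expression recovers a planted 2-log2 shift", {
  set.seed(54)
  n_genes <- 1000
  n_per <- 50
  expr <- matrix(rnorm(n_genes * 2 * n_per, 8, 1), n_genes,
                 dimnames = list(paste0("G", 1:n_genes),
                                 paste0("s", 1:(2 * n_per))))
  groups <- setNames(rep(c(TRUE, FALSE), each = n_per), colnames(expr))
  planted <- paste0("G", 1:10)
  expr[planted, groups] <- expr[planted, groups] + 2
  de <- differential_expression(expr, groups)
  hits <- de$gene_symbol[de$q_value < 0.05]
  expect_gte(sum(planted %in% hits), 9)
  expect_lte(length(setdiff(hits, planted)), 25)
  expect_true(all(de$effect[match(planted, de$gene_symbol)] > 0))
})

test_that("swapping group labels flips effects and keeps p-values", {
  m <- mk_matrices(n_genes = 30, seed = 5)
  set.seed(55)
  expr <- matrix(rnorm(30 * 20, 6, 1), 30,
                 dimnames = list(m$genes <- paste0("G", 1:30), m$samples))
  g <- setNames(rep(c(TRUE, FALSE), 10), m$samples)
  a <- differential_expression(expr, g)
  b <- differential_expression(expr, !g)
  expect_equal(a$effect, -b$effect)
  expect_equal(a$p_value, b$p_value)
  expect_error(differential_expression(expr, setNames(c(TRUE, rep(FALSE, 19)),
                                                      m$samples)),
               "two samples")
})

test_that("identical group means leave no gene significant", {
  set.seed(56)
  expr <- matrix(rnorm(200 * 40, 5, 1), 200,
                 dimnames = list(paste0("G", 1:200), paste0("s", 1:40)))
  g <- setNames(rep(c(TRUE, FALSE), 20), colnames(expr))
  de <- differential_expression(expr, g)
  expect_identical(sum(de$q_value < 0.05), 0L)
})

test_that("cross-cohort DE intersection is plain set intersection", {
  expect_identical(intersect_cohort_de(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_identical(intersect_cohort_de(c("a"), c("b")), character())
  expect_identical(intersect_cohort_de(c("a", "b"), c("a", "b")),
                   c("a", "b"))
})

test_that("two generated cohorts recover the shared planted DE genes", {
  spec_a <- cohort_spec(n_samples = 120, seed = 101)
  spec_b <- cohort_spec(n_samples = 120, seed = 202)
  hit_genes <- function(spec) {
    co <- generate_cohort(spec)
    bg <- grep("^BG", rownames(co$expression), value = TRUE)
    g <- setNames(co$truth$samples$kras_loh, co$truth$samples$sample)
    de <- differential_expression(co$expression[bg, ], g)
    list(hits = de$gene_symbol[de$q_value < 0.05], truth = co$truth$de_genes)
  }
  a <- hit_genes(spec_a)
  b <- hit_genes(spec_b)
  expect_identical(a$truth, b$truth)
  common <- intersect_cohort_de(a$hits, b$hits)
  expect_gte(mean(a$truth %in% common), 0.9)
})

mk_centroids <- function(n_genes = 40, seed = 57) {
  set.seed(seed)
  matrix(rnorm(n_genes * 3), n_genes,
         dimnames = list(paste0("SIG", 1:n_genes), c("TRU", "PP", "PI")))
}

test_that("a sample equal to a centroid is assigned to it", {
  cen <- mk_centroids()
  expr <- cbind(cen[, "TRU"], cen[, "PI"])
  colnames(expr) <- c("s1", "s2")
  got <- assign_subtypes(expr, cen)
  expect_identical(got$subtype, c("TRU", "PI"))
  expect_false(any(got$ambiguous))
})

test_that("exact centroid ties break by column order and are flagged", {
  cen <- matrix(c(1, 0, 1, 0, 0, 1), 2,
                dimnames = list(c("g1", "g2"), c("TRU", "PP", "PI")))
  expr <- matrix(c(1, 0, 1, 0, 1, 0), 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  got <- assign_subtypes(expr, cen, method = "euclidean")
  expect_identical(got$subtype, rep("TRU", 3))  # tied with PP, TRU first
  expect_true(all(got$ambiguous))
})

test_that("noisy centroid draws are recovered at 95%+ and labels resist affine shifts", {
  cen <- mk_centroids()
  set.seed(58)
  n <- 300
  truth <- sample(colnames(cen), n, replace = TRUE)
  expr <- cen[, truth] + matrix(rnorm(nrow(cen) * n, 0, 0.4), nrow(cen))
  colnames(expr) <- paste0("s", 1:n)
  got <- assign_subtypes(expr, cen)
  expect_gte(mean(got$subtype == truth), 0.95)
  shifted <- assign_subtypes(2 * expr + 5, cen)
  expect_identical(shifted$subtype, got$subtype)
})

test_that("missing centroid genes below the floor raise an informative error", {
  cen <- mk_centroids(n_genes = 10)
  expr <- matrix(rnorm(8), 4, 2,
                 dimnames = list(rownames(cen)[1:4], c("s1", "s2")))
  expect_error(assign_subtypes(expr, cen), "4/10")
  expect_silent(assign_subtypes(expr, cen, min_gene_frac = 0.3))
})
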