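#' Per-gene copy number versus expression correlation
#'
#' Pearson correlation between a gene's copy-number values and its
#' normalized log2 expression across the samples shared by both
#' matrices, with two-sided p-values and Benjamini-Hochberg q-values
#' across all tested genes. Genes with zero copy-number variance are
#' reported but excluded from testing with a reason code.
#'
#' @param cn_matrix Numeric matrix, genes x samples, of per-gene copy
#'   number values (e.g. total or ploidy-adjusted copy number).
#' @param expr Numeric expression matrix, genes x samples.
#' @return data.frame per shared gene: `gene_symbol`, `r`, `p_value`,
#'   `q_value`, `n_samples`, `reason` (`NA` when tested).
#' @export
cn_expression_correlation <- function(cn_matrix, expr) {
  genes <- intersect(rownames(cn_matrix), rownames(expr))
  samples <- intersect(colnames(cn_matrix), colnames(expr))
  if (length(samples) < 3L)
    stop("need at least 3 shared samples; found ", length(samples))
  if (length(genes) == 0L)
    return(data.frame(gene_symbol = character(), r = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      n_samples = integer(), reason = character()))
  x <- cn_matrix[genes, samples, drop = FALSE]
  y <- expr[genes, samples, drop = FALSE]
  n <- length(samples)
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  testable <- sx > 0 & sy > 0
  r[!testable] <- NA_real_
  # two-sided p from the t transform of r on n - 2 df
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!testable] <- NA_real_
  q <- rep(NA_real_, length(genes))
  q[testable] <- bh_adjust(pmin(pmax(p[testable],
                                     .Machine$double.xmin), 1))
  data.frame(
    gene_symbol = genes, r = r, p_value = p, q_value = q, n_samples = n,
    reason = ifelse(testable, NA_character_,
                    ifelse(sx > 0, "zero expression variance",
                           "zero CN variance")),
    row.names = NULL)
}

#' Select genes with high, significant CN-expression correlation
#'
#' Strict thresholds: `r > r_min` and `q < q_max`.
#'
#' @param results Output of [cn_expression_correlation()].
#' @param r_min Minimum Pearson r (exclusive; default 0.4).
#' @param q_max Maximum BH q (exclusive; default 0.05).
#' @return Character vector of gene symbols.
#' @export
select_correlated <- function(results, r_min = 0.4, q_max = 0.05) {
  keep <- !is.na(results$r) & results$r > r_min &
    !is.na(results$q_value) & results$q_value < q_max
  results$gene_symbol[keep]
}

#' Differential expression between LOH groups
#'
#' Per-gene Welch t-test on log2 expression between samples with and
#' without the LOH flag, with BH adjustment across genes. The effect is
#' `mean(loh) - mean(no_loh)` in log2 units.
#'
#' @param expr Numeric expression matrix, genes x samples.
#' @param groups Named logical vector (TRUE = LOH) or factor/character
#'   with levels `loh` / `no_loh`, aligned to `colnames(expr)` by name.
#' @return data.frame per gene: `gene_symbol`, `effect`, `statistic`,
#'   `p_value`, `q_value`.
#' @export
differential_expression <- function(expr, groups) {
  if (is.character(groups) || is.factor(groups)) {
    g <- as.character(groups)
    if (!all(g %in% c("loh", "no_loh")))
      stop("group labels must be 'loh' or 'no_loh'")
    groups <- setNames(g == "loh", names(groups))
  }
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(expr), names(groups))
    if (length(miss)) stop("no group label for sample(s): ",
                           paste(head(miss, 3L), collapse = ", "))
    groups <- groups[colnames(expr)]
  } else if (length(groups) != ncol(expr)) {
    stop("groups must match the expression columns")
  }
  n1 <- sum(groups)
  n2 <- sum(!groups)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least two samples")
  x1 <- expr[, groups, drop = FALSE]
  x2 <- expr[, !groups, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df = df)
  p[se2 == 0 & m1 == m2] <- 1  # constant, identical groups
  data.frame(gene_symbol = rownames(expr), effect = m1 - m2,
             statistic = tstat, p_value = p,
             q_value = bh_adjust(pmin(pmax(p, .Machine$double.xmin), 1)),
             row.names = NULL)
}

#' Genes differentially expressed in both of two cohorts
#'
#' @param de_a,de_b Character vectors of significant gene symbols.
#' @return Their intersection.
#' @export
intersect_cohort_de <- function(de_a, de_b) intersect(de_a, de_b)

#' Nearest-centroid molecular subtype assignment
#'
#' Assigns each sample to the expression subtype (e.g. TRU / PP / PI)
#' whose signature-gene centroid it is closest to. Expression rows are
#' median-centered across samples before comparison. With the default
#' Pearson metric, "closest" means the highest correlation between the
#' sample's signature-gene vector and the centroid. Exact ties are
#' broken by centroid column order and flagged ambiguous.
#'
#' @param expr Numeric expression matrix, genes x samples.
#' @param centroids Numeric matrix, signature genes x subtypes, with
#'   gene rownames and subtype colnames (column order = tie-break
#'   order).
#' @param min_gene_frac Minimum fraction of centroid genes that must be
#'   present in `expr` (default 0.5).
#' @param method Distance flavor: `"pearson"` (default), `"spearman"`,
#'   or `"euclidean"`.
#' @return data.frame per sample: `sample_id`, `subtype`, `score`
#'   (correlation, or negative distance for euclidean), `ambiguous`.
#' @export
assign_subtypes <- function(expr, centroids, min_gene_frac = 0.5,
                            method = c("pearson", "spearman", "euclidean")) {
  method <- match.arg(method)
  if (ncol(centroids) < 2L) stop("need at least two subtype centroids")
  shared <- intersect(rownames(centroids), rownames(expr))
  if (length(shared) < min_gene_frac * nrow(centroids)) {
    missing <- setdiff(rownames(centroids), rownames(expr))
    stop("only ", length(shared), "/", nrow(centroids),
         " centroid genes present in the expression matrix; missing: ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  }
  x <- expr[shared, , drop = FALSE]
  x <- x - apply(x, 1L, median)
  cen <- as.matrix(centroids)[shared, , drop = FALSE]
  score <- switch(
    method,
    pearson = cor(x, cen),
    spearman = cor(x, cen, method = "spearman"),
    euclidean = -sqrt(pmax(outer(colSums(x^2), colSums(cen^2), `+`) -
                             2 * crossprod(x, cen), 0)))
  best <- apply(score, 1L, which.max)  # first max = column-order tie-break
  top2 <- apply(score, 1L, function(s) sort(s, decreasing = TRUE)[1:2])
  data.frame(sample_id = colnames(expr),
             subtype = colnames(cen)[best],
             score = score[cbind(seq_len(ncol(x)), best)],
             ambiguous = top2[1L, ] == top2[2L, ],
             row.names = NULL)
}
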