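#' Cross-tabulate two per-sample category vectors
#'
#' Samples with a missing label in either vector are dropped pairwise.
#'
#' @param labels_a,labels_b Equal-length vectors (factor-coercible).
#' @return Integer contingency matrix (rows = levels of `labels_a`).
#' @export
build_contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- factor(labels_a[keep])
  b <- factor(labels_b[keep])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("need at least two observed levels in each label vector")
  tab <- table(a, b)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

check_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (sum(counts) < 1) stop("contingency table is empty")
  counts
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic `sum((O-E)^2/E)` with upper-tail chi-square
#' p-value on `(r-1)(c-1)` degrees of freedom; for 2x2 tables a Yates
#' continuity correction may be applied.
#'
#' @param counts r x c matrix of non-negative integer counts.
#' @param correct Apply the continuity correction (2x2 only).
#' @return List (`statistic`, `df`, `p_value`, `method`).
#' @export
chi_square <- function(counts, correct = FALSE) {
  counts <- check_contingency(counts)
  if (correct && !all(dim(counts) == 2L))
    stop("continuity correction is defined for 2x2 tables only")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0))
    stop("chi-square undefined: expected count of zero (empty margin)")
  ht <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       method = if (correct) "chi-square (Yates)" else "chi-square")
}

#' Fisher's exact test on a 2x2 table, with sample odds ratio
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger
#' than that of the observed table. The reported estimate is the plain
#' sample odds ratio `ad/bc` (not the conditional maximum-likelihood
#' odds ratio).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return List (`p_value`, `estimate`, `method`).
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- check_contingency(counts)
  if (!all(dim(counts) == 2L)) stop("fisher_exact_2x2 needs a 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("Fisher test undefined: zero margin")
  p <- fisher.test(counts)$p.value
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  list(p_value = p, estimate = or, method = "Fisher exact")
}

#' Default 2x2 / r x c association test policy
#'
#' The per-row test used for clinicopathological association tables:
#' 2x2 tables get the continuity-corrected chi-square unless any
#' expected count is below 5 (then Fisher's exact test); larger tables
#' get the uncorrected Pearson chi-square.
#'
#' @param counts r x c matrix of non-negative integer counts.
#' @return List (`p_value`, `method`, and `statistic`/`df` or
#'   `estimate` depending on the test used).
#' @export
table2_association <- function(counts) {
  counts <- check_contingency(counts)
  if (all(dim(counts) == 2L)) {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(expected < 5)) fisher_exact_2x2(counts)
    else chi_square(counts, correct = TRUE)
  } else {
    chi_square(counts, correct = FALSE)
  }
}

#' Welch two-sample t-test
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @return List (`statistic`, `df`, `p_value`, `estimate` = mean
#'   difference a - b).
#' @export
two_sample_t <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least two values")
  diff <- mean(values_a) - mean(values_b)
  if (var(values_a) == 0 && var(values_b) == 0) {
    # degenerate: both groups constant
    if (diff == 0)
      return(list(statistic = 0, df = NA_real_, p_value = 1, estimate = 0))
    stop("both groups constant with different means: t undefined")
  }
  ht <- t.test(values_a, values_b)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), estimate = diff)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `p_(i) -> min_{j >= i} p_(j) * m / j`, capped at
#' 1 and returned in input order.
#'
#' @param p_values Numeric vector with values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}
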