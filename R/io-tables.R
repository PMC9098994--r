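#' Read a normalized log2 expression matrix
#'
#' TSV with gene symbols in the first column and one column per sample.
#' Rows sharing a gene symbol (a gene measured by several probes) are
#' averaged into a single row.
#'
#' @param path Input TSV.
#' @return Numeric matrix, genes x samples, unique rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2L) stop("expression file needs >= 1 sample column")
  genes <- as.character(df[[1L]])
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(!is.na(v) & is.na(vn)))
        stop("non-numeric expression value in column '",
             names(vals)[j], "'")
      v <- vn
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (anyDuplicated(genes)) {
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(m) <- unique(genes)
  } else {
    rownames(m) <- genes
  }
  m
}

#' Write an expression matrix
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output TSV path.
#' @return Invisibly, `expr`.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr)
}

CLINICAL_COLUMNS <- c("sample", "age", "sex", "stage", "ecog", "smoker",
                      "kras_mut", "egfr_mut", "os_time", "os_event",
                      "rfs_time", "rfs_event")

#' Read a clinical table
#'
#' Typed clinical records: demographics, stage, ECOG, smoking, KRAS and
#' EGFR mutation status, and overall/relapse-free survival time-event
#' pairs (months from surgery). Missing values are preserved as `NA`,
#' never imputed; downstream analyses drop them pairwise.
#'
#' @param path TSV with the columns `sample`, `age`, `sex`
#'   (female/male), `stage` (I/II/III), `ecog` (0-3), `smoker`
#'   (TRUE/FALSE), `kras_mut`, `egfr_mut` (mutated/wild-type),
#'   `os_time`, `os_event`, `rfs_time`, `rfs_event`.
#' @param na_token Token encoding a missing value (default `"NA"`).
#' @return data.frame with typed columns; times numeric months, events
#'   0/1 integers.
#' @export
read_clinical <- function(path, na_token = "NA") {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = na_token)
  miss <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(miss))
    stop("clinical file lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[CLINICAL_COLUMNS]
  df$sample <- as.character(df$sample)
  df$age <- as.numeric(df$age)
  chk_lvl <- function(x, lv, what) {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) stop("invalid ", what, " value: '", x[bad][1L], "'")
    factor(x, levels = lv)
  }
  df$sex <- chk_lvl(df$sex, c("female", "male"), "sex")
  df$stage <- chk_lvl(df$stage, c("I", "II", "III"), "stage")
  df$ecog <- as.integer(df$ecog)
  if (any(!is.na(df$ecog) & (df$ecog < 0L | df$ecog > 3L)))
    stop("ECOG outside 0..3")
  df$smoker <- as.logical(df$smoker)
  df$kras_mut <- chk_lvl(df$kras_mut, c("wild-type", "mutated"), "kras_mut")
  df$egfr_mut <- chk_lvl(df$egfr_mut, c("wild-type", "mutated"), "egfr_mut")
  for (col in c("os_time", "rfs_time")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.na(df[[col]]) & df[[col]] < 0))
      stop("negative survival time in ", col)
  }
  for (col in c("os_event", "rfs_event")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(!is.na(df[[col]]) & !(df[[col]] %in% 0:1)))
      stop("event flag in ", col, " must be 0 or 1")
  }
  df
}

#' Write a clinical table
#' @param clinical data.frame as returned by [read_clinical()].
#' @param path Output TSV path.
#' @param na_token Token used for missing values.
#' @return Invisibly, `clinical`.
#' @export
write_clinical <- function(clinical, path, na_token = "NA") {
  write.table(clinical, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = na_token)
  invisible(clinical)
}
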