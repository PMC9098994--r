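#' Read a refFlat gene annotation
#'
#' Parses refFlat (tab-separated, headerless: geneName, name, chrom,
#' strand, txStart, txEnd, ...). refFlat transcript starts are 0-based;
#' they are shifted to the package-wide 1-based inclusive convention on
#' read. Multiple transcripts of one gene symbol on the same chromosome
#' are collapsed to their union span. Strand is read but ignored (copy
#' number is strand-agnostic). Gene symbols whose transcripts sit on
#' more than one chromosome are dropped with a warning rather than
#' assigned an arbitrary locus.
#'
#' @param path refFlat file.
#' @return data.frame with columns `gene_symbol`, `chrom`, `tx_start`,
#'   `tx_end` (1-based inclusive), one row per gene symbol.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(gene_symbol = character(), chrom = character(),
                      tx_start = integer(), tx_end = integer())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed refFlat line ", which(nf < 6L)[1L],
         ": fewer than 6 tab-separated fields")
  tx_start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  tx_end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
  if (anyNA(tx_start) || anyNA(tx_end))
    stop("malformed refFlat line ",
         which(is.na(tx_start) | is.na(tx_end))[1L],
         ": non-numeric transcript coordinates")
  ann <- data.frame(
    gene_symbol = vapply(fields, `[`, "", 1L),
    chrom = vapply(fields, `[`, "", 3L),
    tx_start = tx_start + 1L,  # 0-based -> 1-based
    tx_end = tx_end)
  bad <- which(ann$tx_start > ann$tx_end)
  if (length(bad))
    stop("malformed refFlat line ", bad[1L], ": txStart > txEnd")
  multi <- tapply(ann$chrom, ann$gene_symbol,
                  function(ch) length(unique(ch)) > 1L)
  if (any(multi)) {
    warning("dropping gene(s) annotated on multiple chromosomes: ",
            paste(names(multi)[multi], collapse = ", "))
    ann <- ann[!(ann$gene_symbol %in% names(multi)[multi]), , drop = FALSE]
  }
  if (nrow(ann) == 0L) return(empty)
  out <- do.call(rbind, lapply(split(ann, ann$gene_symbol), function(g) {
    data.frame(gene_symbol = g$gene_symbol[1L], chrom = g$chrom[1L],
               tx_start = min(g$tx_start), tx_end = max(g$tx_end))
  }))
  out <- out[order(out$chrom, out$tx_start, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene annotation in refFlat dialect
#'
#' Inverse of [read_gene_annotation()] for the fields this package uses.
#' Coordinates are converted back to refFlat's 0-based transcript starts.
#'
#' @param genes data.frame with `gene_symbol`, `chrom`, `tx_start`, `tx_end`.
#' @param path Output file.
#' @return Invisibly, `genes`.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- sprintf("%s\t%s\t%s\t+\t%d\t%d\t%d\t%d\t1\t%d,\t%d,",
                   genes$gene_symbol, paste0(genes$gene_symbol, "_t1"),
                   genes$chrom, genes$tx_start - 1L, genes$tx_end,
                   genes$tx_start - 1L, genes$tx_end,
                   genes$tx_start - 1L, genes$tx_end)
  writeLines(lines, path)
  invisible(genes)
}

#' Read a probe position map
#'
#' @param path TSV with header columns `chrom`, `position` (1-based).
#' @return A `probe_map`: named list of strictly increasing integer
#'   position vectors, one per chromosome.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "position"), names(df))
  if (length(miss))
    stop("probe map lacks column(s): ", paste(miss, collapse = ", "))
  probe_map(split(as.integer(df$position), df$chrom))
}

#' Construct a probe map from per-chromosome positions
#'
#' @param positions Named list of integer probe positions per chromosome.
#' @return Validated `probe_map` (positions sorted, duplicates rejected).
#' @export
probe_map <- function(positions) {
  if (is.null(names(positions)) || any(!nzchar(names(positions))))
    stop("probe positions must be a named list (chromosome names)")
  out <- lapply(positions, function(p) {
    p <- sort(as.integer(p))
    if (anyDuplicated(p)) stop("duplicated probe position")
    p
  })
  structure(out, class = "probe_map")
}

#' Write a probe map
#' @param probes A `probe_map`.
#' @param path Output TSV path.
#' @return Invisibly, `probes`.
#' @export
write_probe_map <- function(probes, path) {
  df <- data.frame(
    chrom = rep(names(probes), lengths(probes)),
    position = unlist(probes, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(probes)
}
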