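#' Construct an allele-specific segment profile
#'
#' A segment profile is one tumor's allele-specific copy-number
#' segmentation (ASCAT-style) together with its estimated ploidy
#' (average tumor copy number) and cellularity (tumor cell fraction).
#'
#' @param sample_id Sample identifier.
#' @param ploidy Positive real; average tumor copy number.
#' @param cellularity Tumor cell fraction in (0, 1].
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `n_major`, `n_minor` (non-negative integer
#'   allele copy numbers, `n_major >= n_minor`). Segments on one
#'   chromosome must be non-overlapping; they are sorted on construction.
#'
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(sample_id, ploidy, cellularity, segments) {
  stopifnot(length(sample_id) == 1L, length(ploidy) == 1L,
            length(cellularity) == 1L)
  if (!is.finite(ploidy) || ploidy <= 0)
    stop("ploidy must be a positive real for sample '", sample_id, "'")
  if (!is.finite(cellularity) || cellularity <= 0 || cellularity > 1)
    stop("cellularity must lie in (0, 1] for sample '", sample_id, "'")
  segments <- validate_segments(segments, sample_id)
  structure(
    list(sample_id = as.character(sample_id), ploidy = as.numeric(ploidy),
         cellularity = as.numeric(cellularity), segments = segments),
    class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile '%s': %d segments on %d chromosome(s), ploidy %.3g, cellularity %.3g\n",
              x$sample_id, nrow(x$segments),
              length(unique(x$segments$chrom)), x$ploidy, x$cellularity))
  invisible(x)
}

# Enforce the segment invariants: integer non-negative allele counts,
# n_major >= n_minor, start <= end, and per-chromosome disjointness.
# Returns the segments sorted by (chrom, start).
validate_segments <- function(segments, sample_id = "<unknown>") {
  req <- c("chrom", "start", "end", "n_major", "n_minor")
  miss <- setdiff(req, names(segments))
  if (length(miss))
    stop("segment table for sample '", sample_id,
         "' lacks column(s): ", paste(miss, collapse = ", "))
  segments <- as.data.frame(segments)[req]
  segments$chrom <- as.character(segments$chrom)
  for (col in c("start", "end", "n_major", "n_minor"))
    segments[[col]] <- as.integer(segments[[col]])
  if (nrow(segments) == 0L) return(segments)
  if (anyNA(segments))
    stop("NA in segment table for sample '", sample_id, "'")
  bad <- which(segments$start > segments$end)
  if (length(bad))
    stop("segment ", bad[1L], " of sample '", sample_id, "' has start > end")
  bad <- which(segments$n_major < segments$n_minor | segments$n_minor < 0L)
  if (length(bad))
    stop("segment ", bad[1L], " of sample '", sample_id,
         "' violates n_major >= n_minor >= 0")
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", ch, " in sample '", sample_id, "'")
  }
  segments
}

#' Read allele-specific segment profiles
#'
#' Reads a long segment table plus a per-sample metadata table and
#' assembles one [segment_profile] per sample.
#'
#' @param seg_path TSV with header columns `sample`, `chrom`, `start`,
#'   `end`, `nMajor`, `nMinor`.
#' @param meta_path TSV with header columns `sample`, `ploidy`,
#'   `cellularity`.
#'
#' @return Named list of `segment_profile` objects (name = sample id),
#'   in the order samples appear in the metadata table.
#' @export
read_segment_profiles <- function(seg_path, meta_path) {
  seg <- read.delim(seg_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    stop("segment file lacks column(s): ", paste(miss, collapse = ", "))
  meta <- read.delim(meta_path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "ploidy", "cellularity"), names(meta))
  if (length(miss))
    stop("metadata file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stop("duplicated sample id in metadata: ",
         meta$sample[duplicated(meta$sample)][1L])
  orphan <- setdiff(seg$sample, meta$sample)
  if (length(orphan))
    stop("segments present for sample(s) absent from metadata: ",
         paste(head(orphan, 3L), collapse = ", "))
  out <- lapply(seq_len(nrow(meta)), function(i) {
    s <- seg[seg$sample == meta$sample[i], , drop = FALSE]
    segment_profile(
      sample_id = meta$sample[i], ploidy = meta$ploidy[i],
      cellularity = meta$cellularity[i],
      segments = data.frame(chrom = s$chrom, start = s$start, end = s$end,
                            n_major = s$nMajor, n_minor = s$nMinor))
  })
  names(out) <- meta$sample
  out
}

#' Write segment profiles
#'
#' Inverse of [read_segment_profiles()]; writes the long segment table
#' and the per-sample ploidy/cellularity table.
#'
#' @param profiles Named list of [segment_profile] objects.
#' @param seg_path,meta_path Output TSV paths.
#' @return Invisibly, `profiles`.
#' @export
write_segment_profiles <- function(profiles, seg_path, meta_path) {
  seg <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$segments) == 0L) return(NULL)
    data.frame(sample = p$sample_id, chrom = p$segments$chrom,
               start = p$segments$start, end = p$segments$end,
               nMajor = p$segments$n_major, nMinor = p$segments$n_minor)
  }))
  if (is.null(seg))
    seg <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      nMajor = integer(), nMinor = integer())
  meta <- data.frame(
    sample = vapply(profiles, `[[`, "", "sample_id"),
    ploidy = vapply(profiles, `[[`, 0, "ploidy"),
    cellularity = vapply(profiles, `[[`, 0, "cellularity"))
  write.table(seg, seg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profiles)
}

#' Retain samples above a tumor-cell-fraction threshold
#'
#' Cohort QC filter: keeps profiles whose cellularity is *strictly*
#' greater than `min_fraction` (default 0.20, i.e. tumor cell fraction
#' greater than 20%).
#'
#' @param profiles List of [segment_profile] objects.
#' @param min_fraction Threshold in \[0, 1).
#' @return The retained profiles, input order preserved.
#' @export
filter_by_cellularity <- function(profiles, min_fraction = 0.20) {
  stopifnot(length(min_fraction) == 1L, min_fraction >= 0, min_fraction < 1)
  keep <- vapply(profiles, function(p) p$cellularity > min_fraction, NA)
  profiles[keep]
}
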