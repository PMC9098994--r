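#' Ploidy-adjusted total copy number
#'
#' Subtracts the tumor ploidy (a real-valued average tumor copy number,
#' used unrounded) from the total copy number of a region and rounds the
#' difference to the nearest integer. Ties at exactly .5 are rounded
#' half away from zero, so gains and losses are treated symmetrically.
#'
#' @param total_cn Non-negative integer total copy number (vectorized).
#' @param ploidy Positive real tumor ploidy.
#' @return Integer vector of ploidy-adjusted copy numbers.
#' @export
ploidy_adjusted_cn <- function(total_cn, ploidy) {
  if (any(!is.finite(ploidy)) || any(ploidy <= 0))
    stop("ploidy must be positive")
  if (any(total_cn < 0)) stop("total_cn must be non-negative")
  round_half_away(total_cn - ploidy)
}

# round half away from zero (round() would round half to even)
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Classify a ploidy-adjusted copy number as gain, neutral or loss
#'
#' Adjusted copy number >= 1 is a gain, <= -1 a loss, 0 neutral.
#'
#' @param adjusted_cn Integer vector.
#' @return Character vector in `c("gain", "neutral", "loss")`.
#' @export
classify_state <- function(adjusted_cn) {
  ifelse(adjusted_cn >= 1, "gain", ifelse(adjusted_cn <= -1, "loss", "neutral"))
}

#' Loss of heterozygosity of a segment
#'
#' A region has LOH when only one allele remains: minor allele copy
#' number zero with at least one major copy. A homozygous deletion
#' (0, 0) has no remaining allele and is *not* LOH; it is flagged
#' separately by [call_segment()].
#'
#' @param n_major,n_minor Non-negative integer allele copy numbers,
#'   `n_major >= n_minor` (vectorized).
#' @return Logical vector.
#' @export
segment_loh <- function(n_major, n_minor) {
  if (any(n_major < n_minor)) stop("n_major must be >= n_minor")
  if (any(n_minor < 0)) stop("allele copy numbers must be non-negative")
  n_minor == 0 & n_major >= 1
}

#' Call one segment against tumor ploidy
#'
#' Composes the three calling rules: ploidy-adjusted total copy number,
#' gain/neutral/loss state, and LOH. Copy-neutral LOH is LOH whose
#' total copy number equals tumor ploidy after adjustment (one allele
#' lost, the other duplicated); homozygous deletion is total copy
#' number zero (state loss, LOH false).
#'
#' @param segment One-row data.frame or list with `n_major`, `n_minor`.
#' @param ploidy Positive real tumor ploidy.
#' @return List with `adjusted_cn`, `state`, `loh`, `copy_neutral_loh`,
#'   `homozygous_deletion`.
#' @export
call_segment <- function(segment, ploidy) {
  total <- segment$n_major + segment$n_minor
  adj <- ploidy_adjusted_cn(total, ploidy)
  loh <- segment_loh(segment$n_major, segment$n_minor)
  list(adjusted_cn = adj,
       state = ifelse(total == 0, "loss", classify_state(adj)),
       loh = loh,
       copy_neutral_loh = loh & adj == 0L,
       homozygous_deletion = total == 0)
}

#' Call every segment of a profile
#'
#' @param profile A [segment_profile].
#' @return The profile with its `segments` data.frame augmented by
#'   `total_cn`, `adjusted_cn`, `state`, `loh`, `copy_neutral_loh`,
#'   `homozygous_deletion` columns.
#' @export
call_profile <- function(profile) {
  seg <- profile$segments
  calls <- call_segment(seg, profile$ploidy)
  seg$total_cn <- seg$n_major + seg$n_minor
  seg$adjusted_cn <- calls$adjusted_cn
  seg$state <- calls$state
  seg$loh <- calls$loh
  seg$copy_neutral_loh <- calls$copy_neutral_loh
  seg$homozygous_deletion <- calls$homozygous_deletion
  profile$segments <- seg
  profile
}

#' Call every profile of a cohort
#' @param profiles List of [segment_profile] objects.
#' @return List of called profiles (see [call_profile()]).
#' @export
call_profiles <- function(profiles) lapply(profiles, call_profile)

# Index of the segment containing each position, NA when uncovered.
# `seg` must be the sorted, disjoint segment table of one chromosome.
segment_index_at <- function(positions, seg) {
  if (nrow(seg) == 0L) return(rep(NA_integer_, length(positions)))
  idx <- findInterval(positions, seg$start)
  inside <- idx >= 1L & positions <= seg$end[pmax(idx, 1L)]
  ifelse(inside, idx, NA_integer_)
}

#' Genome instability index
#'
#' Fraction of the genome altered, computed in practice as the fraction
#' of probes lying within segments called gain or loss. Probes outside
#' every segment carry no call and are excluded from numerator and
#' denominator alike.
#'
#' @param profile A called [segment_profile] (see [call_profile()]);
#'   an uncalled profile is called on the fly.
#' @param probes A [probe_map()].
#' @return List with `value` (fraction in \[0,1\]), `n_probes_aberrant`,
#'   `n_probes_total`.
#' @export
genome_instability_index <- function(profile, probes) {
  if (is.null(profile$segments$state)) profile <- call_profile(profile)
  n_ab <- 0L
  n_tot <- 0L
  for (ch in intersect(unique(profile$segments$chrom), names(probes))) {
    seg <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    idx <- segment_index_at(probes[[ch]], seg)
    covered <- !is.na(idx)
    n_tot <- n_tot + sum(covered)
    n_ab <- n_ab + sum(seg$state[idx[covered]] != "neutral")
  }
  if (n_tot == 0L)
    stop("GII undefined: no probe falls within any segment of sample '",
         profile$sample_id, "'")
  list(value = n_ab / n_tot, n_probes_aberrant = n_ab, n_probes_total = n_tot)
}

#' Split genome instability indices into high and low
#'
#' High means strictly above the cutoff (default: the cohort median, so
#' values tied with the median are low).
#'
#' @param values Named numeric vector of per-sample GII values (>= 2).
#' @param cutoff Numeric cutoff; defaults to `median(values)`.
#' @return Character vector (`"high"`/`"low"`) with the input names.
#' @export
dichotomize_gii <- function(values, cutoff = NULL) {
  if (length(values) < 2L) stop("need at least two samples")
  if (is.null(cutoff)) cutoff <- median(values)
  setNames(ifelse(values > cutoff, "high", "low"), names(values))
}
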