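#' Tile chromosomes into fixed-width genomic intervals
#'
#' Consecutive 1-based inclusive intervals `[1, w], [w+1, 2w], ...`;
#' the last interval of a chromosome is truncated at the chromosome
#' end.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Interval width in bp (default 15000, i.e. 15-kb
#'   intervals).
#' @return data.frame `chrom`, `start`, `end`, ordered by chromosome
#'   then start.
#' @export
tile_genome <- function(chrom_sizes, width = 15000L) {
  stopifnot(width >= 1)
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(1, len, by = width)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width - 1, len)))
  })
  do.call(rbind, out)
}

#' Per-interval gain/loss frequencies across a cohort
#'
#' A sample counts as gained (lost) in an interval iff the segment
#' containing the interval midpoint is called gain (loss); samples
#' with no segment at the midpoint are excluded from that interval's
#' denominator. Intervals covered by no sample get `NA` frequencies.
#'
#' @param profiles List of called profiles (see [call_profiles()]).
#' @param intervals Interval tiling from [tile_genome()].
#' @return data.frame: intervals plus `n_gain`, `n_loss`, `n_total`,
#'   `gain_freq`, `loss_freq`.
#' @export
aberration_frequency <- function(profiles, intervals) {
  mid <- (intervals$start + intervals$end) %/% 2
  n_gain <- n_loss <- n_total <- integer(nrow(intervals))
  for (p in profiles) {
    if (is.null(p$segments$state)) p <- call_profile(p)
    for (ch in unique(intervals$chrom)) {
      ii <- which(intervals$chrom == ch)
      seg <- p$segments[p$segments$chrom == ch, , drop = FALSE]
      idx <- segment_index_at(mid[ii], seg)
      covered <- !is.na(idx)
      n_total[ii] <- n_total[ii] + covered
      st <- seg$state[idx[covered]]
      n_gain[ii[covered]] <- n_gain[ii[covered]] + (st == "gain")
      n_loss[ii[covered]] <- n_loss[ii[covered]] + (st == "loss")
    }
  }
  intervals$n_gain <- n_gain
  intervals$n_loss <- n_loss
  intervals$n_total <- n_total
  intervals$gain_freq <- ifelse(n_total > 0, n_gain / n_total, NA_real_)
  intervals$loss_freq <- ifelse(n_total > 0, n_loss / n_total, NA_real_)
  intervals
}

#' Per-interval two-group comparison of aberration frequencies
#'
#' For every interval, a two-sample proportion test (two-proportion
#' z-test, equivalently the chi-square test on the 2x2 table, with
#' continuity correction by default) comparing the gain (or loss)
#' proportion between two frequency tracks. Intervals with a zero
#' denominator in either group get a missing p-value; intervals with
#' equal, degenerate proportions (0% or 100% in both groups) get p = 1.
#'
#' @param track_a,track_b Frequency tracks from
#'   [aberration_frequency()], computed on the same interval tiling.
#' @param aberration `"gain"` or `"loss"`.
#' @param correct Continuity correction (default TRUE, matching
#'   `prop.test`).
#' @return Numeric vector of two-sided p-values, one per interval.
#' @export
compare_group_frequencies <- function(track_a, track_b,
                                      aberration = c("gain", "loss"),
                                      correct = TRUE) {
  aberration <- match.arg(aberration)
  if (!identical(track_a[c("chrom", "start", "end")],
                 track_b[c("chrom", "start", "end")]))
    stop("tracks were computed on different interval tilings")
  xcol <- paste0("n_", aberration)
  xa <- track_a[[xcol]]
  xb <- track_b[[xcol]]
  na <- track_a$n_total
  nb <- track_b$n_total
  vapply(seq_len(nrow(track_a)), function(i) {
    if (na[i] == 0L || nb[i] == 0L) return(NA_real_)
    p <- suppressWarnings(
      prop.test(c(xa[i], xb[i]), c(na[i], nb[i]), correct = correct)$p.value)
    if (is.nan(p)) {
      # zero-variance table (both 0% or both 100%): no difference
      if (xa[i] / na[i] == xb[i] / nb[i]) 1 else NA_real_
    } else p
  }, numeric(1))
}

#' Plot-ready genome-wide frequency table
#'
#' One row per interval with gain frequencies on a positive scale and
#' loss frequencies negated for plotting below the axis, per group.
#'
#' @param tracks Named list of frequency tracks sharing one tiling.
#' @return data.frame: `chrom`, `start`, `end`, then per group
#'   `<name>_gain` and `<name>_loss` (the latter negated).
#' @export
export_frequency_plot_data <- function(tracks) {
  base <- tracks[[1L]][c("chrom", "start", "end")]
  for (nm in names(tracks)) {
    base[[paste0(nm, "_gain")]] <- tracks[[nm]]$gain_freq
    base[[paste0(nm, "_loss")]] <- -tracks[[nm]]$loss_freq
  }
  base[order(base$chrom, base$start), , drop = FALSE]
}

#' Write a two-group frequency comparison as a BED-like table
#'
#' 0-based half-open coordinates on write (BED convention); internal
#' coordinates stay 1-based inclusive.
#'
#' @param track_a,track_b Frequency tracks on one tiling.
#' @param path Output TSV path.
#' @param correct Continuity correction for the per-interval tests.
#' @return Invisibly, the written data.frame.
#' @export
write_frequency_comparison <- function(track_a, track_b, path,
                                       correct = TRUE) {
  df <- data.frame(
    chrom = track_a$chrom, start0 = track_a$start - 1L, end = track_a$end,
    gain_freq_a = track_a$gain_freq, loss_freq_a = track_a$loss_freq,
    gain_freq_b = track_b$gain_freq, loss_freq_b = track_b$loss_freq,
    p_gain = compare_group_frequencies(track_a, track_b, "gain", correct),
    p_loss = compare_group_frequencies(track_a, track_b, "loss", correct))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
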