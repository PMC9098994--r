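# Independent oracles used across the suite. Each one recomputes its
# quantity from first principles with different machinery than the
# package (per-probe loops, exhaustive enumeration, closed forms), so a
# shared bug cannot hide.

# GII by looping probe by probe and segment by segment; aberration
# decided by re-deriving the ploidy-adjusted CN with trunc-based
# half-away-from-zero rounding.
brute_force_gii <- function(profile, probes) {
  n_ab <- 0L
  n_tot <- 0L
  for (ch in names(probes)) {
    seg <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    for (pos in probes[[ch]]) {
      for (k in seq_len(nrow(seg))) {
        if (pos >= seg$start[k] && pos <= seg$end[k]) {
          n_tot <- n_tot + 1L
          d <- seg$n_major[k] + seg$n_minor[k] - profile$ploidy
          adj <- trunc(d + 0.5 * sign(d))
          if (adj != 0) n_ab <- n_ab + 1L
          break
        }
      }
    }
  }
  list(value = if (n_tot > 0) n_ab / n_tot else NA_real_,
       n_probes_aberrant = n_ab, n_probes_total = n_tot)
}

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing hypergeometric probabilities no larger
# than the observed one (with the customary 1 + 1e-7 slack on ties).
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up written out directly from its definition.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-group log-rank chi-square for fully observed (uncensored),
# untied event times; vectorized so a permutation null is cheap.
# `g` is a logical group indicator.
uncensored_logrank_stat <- function(time, g) {
  z <- g[order(time)]
  n <- length(z)
  n_at_risk <- n:1
  n1 <- rev(cumsum(rev(z)))
  e <- n1 / n_at_risk
  v <- e * (1 - e)
  (sum(z - e))^2 / sum(v)
}

# A small random segment profile on 1-2 chromosomes with gaps between
# segments; guaranteed to put at least one probe inside a segment.
random_small_profile <- function(id = "R1") {
  repeat {
    chroms <- sample(c("cA", "cB"), sample(1:2, 1))
    segs <- do.call(rbind, lapply(chroms, function(ch) {
      n_seg <- sample(1:4, 1)
      bounds <- sort(sample(1:200, 2 * n_seg))
      minor <- sample(0:2, n_seg, replace = TRUE)
      data.frame(chrom = ch,
                 start = bounds[seq(1, by = 2, length.out = n_seg)],
                 end = bounds[seq(2, by = 2, length.out = n_seg)],
                 n_major = minor + sample(0:3, n_seg, replace = TRUE),
                 n_minor = minor)
    }))
    probes <- lapply(setNames(nm = chroms),
                     function(ch) sort(sample(1:200, sample(5:40, 1))))
    prof <- segment_profile(id, ploidy = runif(1, 0.8, 4.2),
                            cellularity = 0.8, segments = segs)
    oracle <- brute_force_gii(prof, probes)
    if (oracle$n_probes_total > 0)
      return(list(profile = prof, probes = probe_map(probes)))
  }
}
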