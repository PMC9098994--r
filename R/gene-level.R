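#' Project a profile's segment calls onto genes
#'
#' Each gene takes the call of the overlapping segment with the largest
#' base-pair overlap. Ties are broken by the more extreme
#' `|adjusted_cn|`, then by LOH = TRUE, then by the leftmost segment.
#' Genes overlapping no segment are reported with `covered = FALSE`.
#'
#' @param profile A called [segment_profile] (see [call_profile()]).
#' @param genes Gene annotation data.frame (`gene_symbol`, `chrom`,
#'   `tx_start`, `tx_end`), as from [read_gene_annotation()].
#' @return data.frame with one row per gene: `gene_symbol`, `sample_id`,
#'   `covered`, `adjusted_cn`, `state`, `loh`, `copy_neutral_loh`,
#'   `covered_fraction` (fraction of gene bases covered by the
#'   assigning segment; NA when uncovered).
#' @export
gene_calls <- function(profile, genes) {
  if (is.null(profile$segments$state))
    stop("profile has no segment calls; run call_profile() first")
  seg <- profile$segments
  out <- data.frame(
    gene_symbol = genes$gene_symbol,
    sample_id = rep(profile$sample_id, nrow(genes)),
    covered = FALSE, adjusted_cn = NA_integer_,
    state = NA_character_, loh = NA, copy_neutral_loh = NA,
    covered_fraction = NA_real_)
  if (nrow(genes) == 0L || nrow(seg) == 0L) return(out)
  g_gr <- GRanges(genes$chrom, IRanges(genes$tx_start, genes$tx_end))
  s_gr <- GRanges(seg$chrom, IRanges(seg$start, seg$end))
  hits <- findOverlaps(g_gr, s_gr)
  if (length(hits) == 0L) return(out)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  ov_bp <- width(pintersect(g_gr[qh], s_gr[sh]))
  # tie-break chain encoded as lexicographic ordering
  ord <- order(qh, -ov_bp, -abs(seg$adjusted_cn[sh]), !seg$loh[sh],
               seg$start[sh])
  best <- ord[!duplicated(qh[ord])]
  gi <- qh[best]
  si <- sh[best]
  out$covered[gi] <- TRUE
  out$adjusted_cn[gi] <- seg$adjusted_cn[si]
  out$state[gi] <- seg$state[si]
  out$loh[gi] <- seg$loh[si]
  out$copy_neutral_loh[gi] <- seg$copy_neutral_loh[si]
  out$covered_fraction[gi] <- ov_bp[best] /
    (genes$tx_end[gi] - genes$tx_start[gi] + 1)
  out
}

#' Gene-by-sample aberration call matrix for a cohort
#'
#' Batched [gene_calls()] over all profiles.
#'
#' @param profiles List of called profiles ([call_profiles()]); uncalled
#'   profiles are called on the fly.
#' @param genes Gene annotation data.frame.
#' @return Long data.frame, one row per (gene, sample), columns as in
#'   [gene_calls()].
#' @export
cohort_gene_matrix <- function(profiles, genes) {
  if (length(profiles) == 0L || nrow(genes) == 0L)
    return(data.frame(gene_symbol = character(), sample_id = character(),
                      covered = logical(), adjusted_cn = integer(),
                      state = character(), loh = logical(),
                      copy_neutral_loh = logical(),
                      covered_fraction = numeric()))
  profiles <- lapply(profiles, function(p)
    if (is.null(p$segments$state)) call_profile(p) else p)
  sample_ids <- vapply(profiles, `[[`, "", "sample_id")
  n_genes <- nrow(genes)
  out <- data.frame(
    gene_symbol = rep(genes$gene_symbol, times = length(profiles)),
    sample_id = rep(sample_ids, each = n_genes),
    covered = FALSE, adjusted_cn = NA_integer_,
    state = NA_character_, loh = NA, copy_neutral_loh = NA,
    covered_fraction = NA_real_)
  seg <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    s <- profiles[[i]]$segments
    if (nrow(s)) s$.sample <- i
    s
  }))
  if (is.null(seg) || nrow(seg) == 0L) return(out)
  # one overlap query for the whole cohort
  g_gr <- GRanges(genes$chrom, IRanges(genes$tx_start, genes$tx_end))
  s_gr <- GRanges(seg$chrom, IRanges(seg$start, seg$end))
  hits <- findOverlaps(g_gr, s_gr)
  if (length(hits) == 0L) return(out)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  ov_bp <- width(pintersect(g_gr[qh], s_gr[sh]))
  key <- (seg$.sample[sh] - 1) * n_genes + qh  # row in `out`
  ord <- order(key, -ov_bp, -abs(seg$adjusted_cn[sh]), !seg$loh[sh],
               seg$start[sh])
  best <- ord[!duplicated(key[ord])]
  ki <- key[best]
  si <- sh[best]
  out$covered[ki] <- TRUE
  out$adjusted_cn[ki] <- seg$adjusted_cn[si]
  out$state[ki] <- seg$state[si]
  out$loh[ki] <- seg$loh[si]
  out$copy_neutral_loh[ki] <- seg$copy_neutral_loh[si]
  out$covered_fraction[ki] <- ov_bp[best] /
    (genes$tx_end[qh[best]] - genes$tx_start[qh[best]] + 1)
  rownames(out) <- NULL
  out
}

#' Extract a per-sample flag for one gene from a call matrix
#'
#' @param matrix Call matrix from [cohort_gene_matrix()].
#' @param gene Gene symbol.
#' @param what One of `"loh"`, `"gain"`, `"loss"`, `"copy_neutral_loh"`.
#' @return Named logical vector over samples (NA where uncovered).
#' @export
gene_flag <- function(matrix, gene,
                      what = c("loh", "gain", "loss", "copy_neutral_loh")) {
  what <- match.arg(what)
  m <- matrix[matrix$gene_symbol == gene, , drop = FALSE]
  if (nrow(m) == 0L) stop("gene '", gene, "' absent from call matrix")
  v <- switch(what,
              loh = m$loh,
              copy_neutral_loh = m$copy_neutral_loh,
              gain = m$state == "gain",
              loss = m$state == "loss")
  setNames(ifelse(m$covered, v, NA), m$sample_id)
}

#' Hotspot panel copy-number/LOH summary
#'
#' Cohort-wide percentages of samples with gain, loss and LOH per panel
#' gene, plus the LOH percentage restricted to the KRAS-LOH-positive
#' subgroup. Uncovered (gene, sample) entries count as non-aberrant.
#'
#' @param matrix Call matrix from [cohort_gene_matrix()].
#' @param panel Character vector of gene symbols
#'   (default [default_hotspot_panel()]).
#' @param kras_loh Named logical vector: per-sample KRAS LOH status.
#' @return data.frame per gene: `gene_symbol`, `gain_pct`, `loss_pct`,
#'   `loh_pct`, `loh_pct_within_kras_loh`.
#' @export
hotspot_summary <- function(matrix, panel = default_hotspot_panel(),
                            kras_loh) {
  absent <- setdiff(panel, unique(matrix$gene_symbol))
  if (length(absent))
    stop("panel gene(s) absent from call matrix: ",
         paste(absent, collapse = ", "))
  pct <- function(flag) 100 * mean(flag, na.rm = FALSE)
  out <- do.call(rbind, lapply(panel, function(g) {
    loh <- gene_flag(matrix, g, "loh")
    loh[is.na(loh)] <- FALSE
    gain <- gene_flag(matrix, g, "gain")
    gain[is.na(gain)] <- FALSE
    loss <- gene_flag(matrix, g, "loss")
    loss[is.na(loss)] <- FALSE
    in_kras <- kras_loh[names(loh)]
    data.frame(gene_symbol = g, gain_pct = pct(gain), loss_pct = pct(loss),
               loh_pct = pct(loh),
               loh_pct_within_kras_loh =
                 if (any(in_kras, na.rm = TRUE))
                   pct(loh[!is.na(in_kras) & in_kras]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Association of panel-gene LOH with KRAS LOH
#'
#' For every panel gene except KRAS itself, cross-tabulates the gene's
#' LOH status against KRAS LOH, tests the association (chi-square,
#' continuity-corrected for 2x2 unless an expected count is below 5, in
#' which case Fisher's exact test), and adjusts the raw p-values by
#' Benjamini-Hochberg across the non-KRAS panel family.
#'
#' @inheritParams hotspot_summary
#' @return data.frame per non-KRAS gene: `gene_symbol`, `p_value`,
#'   `q_value`, `method`.
#' @export
hotspot_association <- function(matrix, panel = default_hotspot_panel(),
                                kras_loh) {
  genes <- setdiff(panel, "KRAS")
  res <- lapply(genes, function(g) {
    loh <- gene_flag(matrix, g, "loh")
    loh[is.na(loh)] <- FALSE
    tab <- build_contingency(loh[names(kras_loh)], kras_loh)
    tr <- table2_association(tab)
    data.frame(gene_symbol = g, p_value = tr$p_value, method = tr$method)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out[, c("gene_symbol", "p_value", "q_value", "method")]
}
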