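#' Specify a synthetic tumor cohort
#'
#' Parameters of the synthetic-cohort generator. The defaults encode
#' the study conditions the pipeline targets: an early-stage lung
#' adenocarcinoma cohort of 233 tumors with KRAS LOH in about 27% of
#' cases, KRAS hotspot mutation in 36.5%, mean genome instability index
#' 0.57 in LOH vs 0.46 in non-LOH tumors, copy-neutral LOH in about
#' 19% of the LOH tumors, an overall-survival hazard ratio of 0.65 for
#' KRAS LOH, and expression linearly coupled to gene copy number.
#'
#' @param n_samples Number of tumors (default 233).
#' @param seed Integer RNG seed (keep below 2^31 - 2).
#' @param kras_loh_prevalence Fraction of tumors with KRAS LOH.
#' @param kras_mut_prevalence Fraction with KRAS hotspot mutation.
#' @param gii_mean_loh,gii_mean_noloh Target mean aberrant-genome
#'   fraction per LOH group.
#' @param gii_sd Between-tumor sd of the aberrant fraction.
#' @param loh_hr Proportional-hazards multiplier for KRAS-LOH tumors
#'   (< 1 means protective).
#' @param cn_expr_slope Log2 expression units per copy.
#' @param cn_expr_noise_sd Residual expression noise sd (log2).
#' @param censoring_rate Approximate fraction of censored tumors.
#' @param cnloh_fraction Fraction of KRAS-LOH tumors whose KRAS LOH is
#'   copy-neutral.
#' @param median_os_months Baseline (no-LOH) median overall survival.
#' @param n_background_genes,n_signature_genes Background (CN-coupled)
#'   and subtype-signature gene counts.
#' @param n_de_genes Genes with a planted LOH expression shift.
#' @param de_log2_effect Planted differential-expression shift (log2).
#' @param subtype_probs Named subtype mixing proportions (TRU/PP/PI).
#' @param subtype_noise_sd Noise sd around signature centroids.
#' @param probe_spacing Probe spacing in bp.
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param seg_per_chrom_mean Mean segments per chromosome.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 233L, seed = 1L,
                        kras_loh_prevalence = 0.27,
                        kras_mut_prevalence = 0.365,
                        gii_mean_loh = 0.57, gii_mean_noloh = 0.46,
                        gii_sd = 0.10, loh_hr = 0.65,
                        cn_expr_slope = 0.6, cn_expr_noise_sd = 0.6,
                        censoring_rate = 0.30,
                        cnloh_fraction = 12 / 62,
                        median_os_months = 60,
                        n_background_genes = 300L,
                        n_signature_genes = 60L,
                        n_de_genes = 10L, de_log2_effect = 2,
                        subtype_probs = c(TRU = 0.55, PP = 0.26, PI = 0.19),
                        subtype_noise_sd = 0.3,
                        probe_spacing = 20000L,
                        chrom_sizes = c(chr1 = 50e6, chr3 = 40e6,
                                        chr7 = 35e6, chr12 = 30e6,
                                        chr17 = 25e6),
                        seg_per_chrom_mean = 5) {
  spec <- as.list(environment())
  for (f in c("kras_loh_prevalence", "kras_mut_prevalence", "gii_mean_loh",
              "gii_mean_noloh", "censoring_rate", "cnloh_fraction"))
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  if (loh_hr <= 0) stop("loh_hr must be positive")
  if (gii_mean_loh < 0.02 && kras_loh_prevalence > 0)
    stop("infeasible spec: near-zero aberrant fraction with a mandatory ",
         "LOH segment")
  if (abs(sum(subtype_probs) - 1) > 1e-8)
    stop("subtype_probs must sum to 1")
  structure(spec, class = "cohort_spec")
}

# Hotspot panel placement on the synthetic genome: chromosome and
# relative arm position. KRAS sits on the short arm of the chr12
# analogue, mirroring 12p12.1.
panel_layout <- function() {
  data.frame(
    gene_symbol = c("KRAS", "RET", "EGFR", "BRAF", "MET", "TP53",
                    "ERBB2", "NTRK3", "NTRK1", "STK11", "ALK", "ROS1",
                    "NTRK2", "PIK3CA"),
    chrom = c("chr12", "chr12", "chr7", "chr7", "chr7", "chr17",
              "chr17", "chr17", "chr1", "chr1", "chr3", "chr3",
              "chr3", "chr3"),
    rel_pos = c(0.25, 0.65, 0.20, 0.60, 0.75, 0.10,
                0.45, 0.80, 0.60, 0.15, 0.10, 0.45, 0.70, 0.85))
}

#' Generate the synthetic genome
#'
#' Deterministic under the spec seed: probe map (regular spacing),
#' hotspot panel genes at fixed positions (KRAS on the 12p analogue),
#' randomly placed background and subtype-signature genes.
#'
#' @param spec A [cohort_spec()].
#' @return List: `genes` (annotation data.frame with a `role` column:
#'   panel/background/signature), `probes` ([probe_map]),
#'   `chrom_sizes`.
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  sizes <- spec$chrom_sizes
  probes <- probe_map(lapply(sizes, function(L)
    seq(spec$probe_spacing, L, by = spec$probe_spacing)))
  lay <- panel_layout()
  if (!all(lay$chrom %in% names(sizes))) {
    # custom chromosome model: map the layout chromosomes onto the
    # available ones in order (KRAS keeps a dedicated placement)
    orig <- unique(lay$chrom)
    chmap <- setNames(rep(names(sizes), length.out = length(orig)), orig)
    lay$chrom <- unname(chmap[lay$chrom])
  }
  panel <- data.frame(
    gene_symbol = lay$gene_symbol, chrom = lay$chrom,
    tx_start = pmax(1L, as.integer(round(lay$rel_pos * sizes[lay$chrom]))),
    role = "panel")
  panel$tx_end <- pmin(panel$tx_start + 99999L,
                       as.integer(sizes[panel$chrom]))
  rand_genes <- function(n, prefix, role) {
    ch <- sample(names(sizes), n, replace = TRUE,
                 prob = sizes / sum(sizes))
    w <- pmin(as.integer(round(runif(n, 2e4, 2e5))),
              as.integer(sizes[ch] %/% 3))
    st <- as.integer(floor(runif(n, 1, sizes[ch] - w)))
    data.frame(gene_symbol = sprintf("%s%04d", prefix, seq_len(n)),
               chrom = ch, tx_start = st, tx_end = st + w, role = role)
  }
  genes <- rbind(panel[c("gene_symbol", "chrom", "tx_start", "tx_end", "role")],
                 rand_genes(spec$n_background_genes, "BG", "background"),
                 rand_genes(spec$n_signature_genes, "SIG", "signature"))
  genes <- genes[order(genes$chrom, genes$tx_start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, probes = probes, chrom_sizes = sizes)
}

# Allele-specific copy numbers for one segment given its state and the
# rounded ploidy. Returns c(n_major, n_minor).
draw_segment_alleles <- function(state, roundp) {
  if (state == "neutral") {
    total <- roundp
    minor <- max(1L, total %/% 2L)
  } else if (state == "gain") {
    total <- roundp + sample(1:2, 1L, prob = c(0.7, 0.3))
    minor <- if (runif(1) < 0.2) 0L else sample(seq_len(total %/% 2L), 1L)
  } else {
    total <- max(1L, roundp - if (roundp >= 3L)
      sample(1:2, 1L, prob = c(0.8, 0.2)) else 1L)
    minor <- if (total == 1L || runif(1) < 0.7) 0L
    else sample(seq_len(total %/% 2L), 1L)
  }
  c(total - minor, minor)
}

# Split segments of one chromosome at the [lo, hi] boundaries so every
# resulting segment lies entirely inside or outside the window.
carve_segments <- function(seg, chrom, lo, hi) {
  hit <- which(seg$chrom == chrom & seg$start <= hi & seg$end >= lo)
  if (length(hit) == 0L) return(seg)
  pieces <- lapply(hit, function(k) {
    row <- seg[k, , drop = FALSE]
    cuts <- rbind(
      if (row$start < lo) data.frame(start = row$start, end = lo - 1L),
      data.frame(start = max(row$start, lo), end = min(row$end, hi)),
      if (row$end > hi) data.frame(start = hi + 1L, end = row$end))
    piece <- row[rep(1L, nrow(cuts)), , drop = FALSE]
    piece$start <- cuts$start
    piece$end <- cuts$end
    piece
  })
  out <- rbind(seg[-hit, , drop = FALSE], do.call(rbind, pieces))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Segment one chromosome into a full partition with per-segment states
# drawn at the sample's target aberrant fraction.
draw_chromosome_segments <- function(chrom, len, ab_frac, roundp, mean_seg) {
  n_break <- rpois(1L, max(mean_seg - 1, 0))
  bounds <- sort(unique(c(1, sample.int(len - 1L, n_break) + 1L, len + 1L)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L] - 1L
  n <- length(starts)
  aberrant <- runif(n) < ab_frac
  state <- ifelse(aberrant, ifelse(runif(n) < 0.5, "gain", "loss"),
                  "neutral")
  alle <- t(vapply(state, draw_segment_alleles, integer(2L),
                   roundp = roundp))
  data.frame(chrom = chrom, start = starts, end = ends,
             n_major = alle[, 1L], n_minor = alle[, 2L], state = state)
}

# Probes (regular spacing, first at `spacing`) falling in [start, end].
probes_in_span <- function(start, end, spacing) {
  floor(end / spacing) - floor((start - 1) / spacing)
}

#' Generate a complete synthetic cohort with recorded ground truth
#'
#' Emits everything the pipeline consumes — allele-specific segment
#' profiles with a planted KRAS-LOH status per tumor, probe map and
#' gene annotation, a log2 expression matrix linearly coupled to gene
#' copy number (plus a planted LOH expression shift in a few genes and
#' subtype-signature structure), and a clinical table with exponential
#' survival times whose hazard is multiplied by `loh_hr` for KRAS-LOH
#' tumors — together with the ground truth needed to score recovery.
#'
#' @param spec A [cohort_spec()].
#' @param cohort_id Optional label appended to sample ids (for
#'   two-cohort designs); the planted differentially expressed genes
#'   are identical across cohorts generated from specs that share
#'   `n_de_genes` and the genome, so cross-cohort intersection tests
#'   have a common truth.
#' @return Object of class `synthetic_cohort`: list with `spec`,
#'   `genome`, `profiles` (named list of [segment_profile]),
#'   `expression`, `centroids`, `clinical`, `truth`.
#' @export
generate_cohort <- function(spec, cohort_id = NULL) {
  genome <- generate_genome(spec)
  set.seed(spec$seed + 1L)
  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  if (!is.null(cohort_id)) ids <- paste0(cohort_id, "_", ids)
  genes <- genome$genes

  kras_loh <- runif(n) < spec$kras_loh_prevalence
  kras_cnloh <- kras_loh & runif(n) < spec$cnloh_fraction
  kras_mut <- runif(n) < spec$kras_mut_prevalence
  egfr_mut <- !kras_mut & runif(n) < 0.146 / (1 - spec$kras_mut_prevalence)
  ploidy <- pmin(pmax(rnorm(n, 2.6, 0.45), 1.6), 4.5)
  cellularity <- runif(n, 0.30, 0.95)
  ab_frac <- pmin(pmax(
    rnorm(n, ifelse(kras_loh, spec$gii_mean_loh, spec$gii_mean_noloh),
          spec$gii_sd), 0.02), 0.95)
  subtype <- sample(names(spec$subtype_probs), n, replace = TRUE,
                    prob = spec$subtype_probs)

  kras <- genes[genes$gene_symbol == "KRAS", ]
  profiles <- vector("list", n)
  realized_gii <- numeric(n)
  for (i in seq_len(n)) {
    roundp <- max(2L, round_half_away(ploidy[i]))
    seg <- do.call(rbind, lapply(names(genome$chrom_sizes), function(ch)
      draw_chromosome_segments(ch, genome$chrom_sizes[[ch]], ab_frac[i],
                               roundp, spec$seg_per_chrom_mean)))
    # carve segment boundaries at the KRAS gene and plant its state on
    # the pieces inside the gene (the rest of the genome keeps the
    # drawn aberrant fraction, so planting barely perturbs GII)
    seg <- carve_segments(seg, kras$chrom, kras$tx_start, kras$tx_end)
    at_kras <- seg$chrom == kras$chrom & seg$start >= kras$tx_start &
      seg$end <= kras$tx_end
    if (kras_loh[i]) {
      total <- if (kras_cnloh[i]) roundp
      else if (runif(1) < 0.75) roundp - 1L else roundp + 1L
      seg$n_major[at_kras] <- total
      seg$n_minor[at_kras] <- 0L
      seg$state[at_kras] <- if (total == roundp) "neutral"
      else if (total < roundp) "loss" else "gain"
    } else {
      minor <- max(1L, roundp %/% 2L)
      seg$n_major[at_kras] <- roundp - minor
      seg$n_minor[at_kras] <- minor
      seg$state[at_kras] <- "neutral"
    }
    np <- probes_in_span(seg$start, seg$end, spec$probe_spacing)
    realized_gii[i] <- sum(np[seg$state != "neutral"]) / sum(np)
    profiles[[i]] <- segment_profile(ids[i], ploidy[i], cellularity[i], seg)
  }
  names(profiles) <- ids

  # gene-level total CN (segment containing the gene midpoint)
  cn_genes <- genes[genes$role != "signature", , drop = FALSE]
  gmid <- (cn_genes$tx_start + cn_genes$tx_end) %/% 2
  cn <- matrix(NA_real_, nrow(cn_genes), n,
               dimnames = list(cn_genes$gene_symbol, ids))
  for (i in seq_len(n)) {
    segs <- profiles[[i]]$segments
    for (ch in unique(cn_genes$chrom)) {
      gi <- which(cn_genes$chrom == ch)
      seg <- segs[segs$chrom == ch, , drop = FALSE]
      idx <- segment_index_at(gmid[gi], seg)
      cn[gi, i] <- (seg$n_major + seg$n_minor)[idx]
    }
  }

  # expression: baseline + slope * CN + noise; planted DE shift;
  # signature genes follow their subtype centroid
  # stable symbols, so independently seeded cohorts share the planted set
  de_genes <- sprintf("BG%04d",
                      seq_len(min(spec$n_de_genes, spec$n_background_genes)))
  baseline <- rnorm(nrow(cn_genes), 8, 1.5)
  expr_cn <- baseline + spec$cn_expr_slope * cn +
    matrix(rnorm(length(cn), 0, spec$cn_expr_noise_sd), nrow(cn))
  expr_cn[de_genes, kras_loh] <- expr_cn[de_genes, kras_loh] +
    spec$de_log2_effect
  sig_genes <- genes$gene_symbol[genes$role == "signature"]
  centroids <- matrix(rnorm(length(sig_genes) * 3), length(sig_genes), 3,
                      dimnames = list(sig_genes, c("TRU", "PP", "PI")))
  expr_sig <- 6 + centroids[, subtype, drop = FALSE] +
    matrix(rnorm(length(sig_genes) * n, 0, spec$subtype_noise_sd),
           length(sig_genes))
  colnames(expr_sig) <- ids
  expression <- rbind(expr_cn, expr_sig)

  # survival: exponential baseline, proportional LOH effect,
  # independent exponential censoring
  lambda0 <- log(2) / spec$median_os_months
  hazard_mult <- ifelse(kras_loh, spec$loh_hr, 1)
  cens_rate <- lambda0 * spec$censoring_rate /
    max(1 - spec$censoring_rate, 1e-8)
  draw_surv <- function(rate_scale) {
    t_ev <- rexp(n, lambda0 * hazard_mult * rate_scale)
    t_cn <- if (cens_rate > 0) rexp(n, cens_rate * rate_scale)
    else rep(Inf, n)
    data.frame(time = round(pmin(t_ev, t_cn), 2),
               event = as.integer(t_ev <= t_cn))
  }
  os <- draw_surv(1)
  rfs <- draw_surv(1.3)  # relapses accrue faster than deaths

  clinical <- data.frame(
    sample = ids,
    age = round(pmin(pmax(rnorm(n, 64.5, 8.5), 39), 84)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.56, 0.44)),
    stage = sample(c("I", "II", "III"), n, TRUE,
                   prob = c(0.63, 0.22, 0.15)),
    ecog = sample(0:3, n, TRUE, prob = c(0.55, 0.30, 0.10, 0.05)),
    smoker = runif(n) < 0.88,
    kras_mut = ifelse(kras_mut, "mutated", "wild-type"),
    egfr_mut = ifelse(egfr_mut, "mutated", "wild-type"),
    os_time = os$time, os_event = os$event,
    rfs_time = rfs$time, rfs_event = rfs$event)

  truth <- list(
    samples = data.frame(
      sample = ids, kras_loh = kras_loh, kras_cnloh = kras_cnloh,
      kras_mut = kras_mut, subtype = subtype,
      target_aberrant_fraction = ab_frac, realized_gii = realized_gii,
      hazard_multiplier = hazard_mult),
    de_genes = de_genes, cn_expr_slope = spec$cn_expr_slope,
    loh_hr = spec$loh_hr)

  structure(list(spec = spec, genome = genome, profiles = profiles,
                 expression = expression, centroids = centroids,
                 clinical = clinical, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples, %d genes, ",
                     "%d planted KRAS-LOH (%d copy-neutral)\n"),
              length(x$profiles), nrow(x$genome$genes),
              sum(x$truth$samples$kras_loh),
              sum(x$truth$samples$kras_cnloh)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(segments = file.path(dir, "segments.tsv"),
             meta = file.path(dir, "sample_meta.tsv"),
             probes = file.path(dir, "probes.tsv"),
             annotation = file.path(dir, "annotation.refflat"),
             expression = file.path(dir, "expression.tsv"),
             centroids = file.path(dir, "centroids.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_segment_profiles(cohort$profiles, paths["segments"], paths["meta"])
  write_probe_map(cohort$genome$probes, paths["probes"])
  write_gene_annotation(cohort$genome$genes, paths["annotation"])
  write_expression_matrix(cohort$expression, paths["expression"])
  write.table(data.frame(gene = rownames(cohort$centroids),
                         cohort$centroids),
              paths["centroids"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_clinical(cohort$clinical, paths["clinical"])
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Score pipeline recovery of planted ground truth
#'
#' Compares pipeline outputs against the generator's recorded truth.
#' All observed arguments are optional; supply whichever stage you ran.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param kras_loh_calls Named logical vector of per-sample KRAS LOH
#'   calls from the gene-level matrix.
#' @param gii Named numeric vector of per-sample GII values.
#' @param hr_estimate Estimated hazard ratio for KRAS LOH.
#' @param de_genes Character vector of genes called differentially
#'   expressed.
#' @param subtypes Named character vector of assigned subtype labels.
#' @return List of recovery metrics (`loh_concordance`, `gii_mae`,
#'   `gii_group_difference`, `hr_planted`, `hr_estimated`,
#'   `de_sensitivity`, `subtype_accuracy`; missing stages are NA).
#' @export
truth_report <- function(truth, kras_loh_calls = NULL, gii = NULL,
                         hr_estimate = NULL, de_genes = NULL,
                         subtypes = NULL) {
  ts <- truth$samples
  need_ids <- function(x, what) {
    if (!all(ts$sample %in% names(x)))
      stop("sample ids in ", what, " do not match the ground truth")
    x[ts$sample]
  }
  out <- list(loh_concordance = NA_real_, gii_mae = NA_real_,
              gii_group_difference = NA_real_,
              hr_planted = truth$loh_hr, hr_estimated = NA_real_,
              de_sensitivity = NA_real_, subtype_accuracy = NA_real_)
  if (!is.null(kras_loh_calls)) {
    calls <- need_ids(kras_loh_calls, "kras_loh_calls")
    out$loh_concordance <- mean(calls == ts$kras_loh)
  }
  if (!is.null(gii)) {
    g <- need_ids(gii, "gii")
    out$gii_mae <- mean(abs(g - ts$realized_gii))
    out$gii_group_difference <-
      mean(g[ts$kras_loh]) - mean(g[!ts$kras_loh])
  }
  if (!is.null(hr_estimate)) out$hr_estimated <- hr_estimate
  if (!is.null(de_genes))
    out$de_sensitivity <- mean(truth$de_genes %in% de_genes)
  if (!is.null(subtypes)) {
    s <- need_ids(subtypes, "subtypes")
    out$subtype_accuracy <- mean(s == ts$subtype)
  }
  out
}
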