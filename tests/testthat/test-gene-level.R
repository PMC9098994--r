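mk_called_profile <- function(seg, ploidy = 2.0, id = "S1") {
  call_profile(segment_profile(id, ploidy, 0.8, seg))
}

test_that("a gene inside one segment takes that segment's call in full", {
  prof <- mk_called_profile(data.frame(
    chrom = "chr1", start = 1L, end = 10000L, n_major = 2L, n_minor = 1L))
  genes <- data.frame(gene_symbol = "G", chrom = "chr1",
                      tx_start = 2000L, tx_end = 3000L)
  call <- gene_calls(prof, genes)
  expect_true(call$covered)
  expect_identical(call$state, "gain")
  expect_equal(call$covered_fraction, 1)
})

test_that("largest base-pair overlap wins for boundary-spanning genes", {
  prof <- mk_called_profile(data.frame(
    chrom = "chr1", start = c(1L, 1701L), end = c(1700L, 5000L),
    n_major = c(1L, 1L), n_minor = c(1L, 0L)))
  genes <- data.frame(gene_symbol = "G", chrom = "chr1",
                      tx_start = 1001L, tx_end = 2000L)
  # 700 bp of the neutral segment vs 300 bp of the loss/LOH segment
  call <- gene_calls(prof, genes)
  expect_identical(call$state, "neutral")
  expect_false(call$loh)
  expect_equal(call$covered_fraction, 0.7)
})

test_that("overlap ties break by |adjusted CN|, then LOH, then position", {
  genes <- data.frame(gene_symbol = "G", chrom = "chr1",
                      tx_start = 1001L, tx_end = 2000L)
  # equal 500 bp overlaps; the right segment is a deeper aberration
  prof <- mk_called_profile(data.frame(
    chrom = "chr1", start = c(1L, 1501L), end = c(1500L, 4000L),
    n_major = c(3L, 4L), n_minor = c(0L, 1L)))
  expect_identical(gene_calls(prof, genes)$adjusted_cn, 3L)
  # equal overlap, equal |adjusted|: LOH wins
  prof <- mk_called_profile(data.frame(
    chrom = "chr1", start = c(1L, 1501L), end = c(1500L, 4000L),
    n_major = c(2L, 3L), n_minor = c(1L, 0L)))
  expect_true(gene_calls(prof, genes)$loh)
  # fully tied calls: leftmost segment assigns (same resulting call)
  prof <- mk_called_profile(data.frame(
    chrom = "chr1", start = c(1L, 1501L), end = c(1500L, 4000L),
    n_major = c(3L, 3L), n_minor = c(0L, 0L)))
  expect_equal(gene_calls(prof, genes)$covered_fraction, 0.5)
})

test_that("genes with no overlapping segment are marked uncovered", {
  prof <- mk_called_profile(data.frame(
    chrom = "chr1", start = 1L, end = 1000L, n_major = 1L, n_minor = 1L))
  genes <- data.frame(gene_symbol = c("G1", "G2"),
                      chrom = c("chr2", "chr1"),
                      tx_start = c(1L, 5000L), tx_end = c(100L, 6000L))
  calls <- gene_calls(prof, genes)
  expect_identical(calls$covered, c(FALSE, FALSE))
  expect_true(all(is.na(calls$state)))
})

test_that("gene calls ignore segment input order", {
  seg <- data.frame(chrom = "chr1", start = c(1L, 1001L, 3001L),
                    end = c(1000L, 3000L, 7000L),
                    n_major = c(3L, 1L, 2L), n_minor = c(1L, 0L, 2L))
  genes <- data.frame(gene_symbol = c("A", "B"), chrom = "chr1",
                      tx_start = c(500L, 2500L), tx_end = c(1500L, 3500L))
  a <- gene_calls(mk_called_profile(seg), genes)
  b <- gene_calls(mk_called_profile(seg[c(3, 1, 2), ]), genes)
  expect_equal(a, b)
})

test_that("cohort matrix equals elementwise per-profile calls", {
  set.seed(77)
  co <- generate_cohort(cohort_spec(n_samples = 8, seed = 5))
  called <- call_profiles(co$profiles)
  genes <- co$genome$genes
  mat <- cohort_gene_matrix(called, genes)
  expect_identical(nrow(mat), nrow(genes) * length(called))
  for (p in called[c(1, 4, 8)]) {
    sub <- mat[mat$sample_id == p$sample_id, ]
    rownames(sub) <- NULL
    expect_equal(sub, gene_calls(p, genes))
  }
})

test_that("cohort matrix handles empty inputs", {
  genes <- data.frame(gene_symbol = character(), chrom = character(),
                      tx_start = integer(), tx_end = integer())
  expect_identical(nrow(cohort_gene_matrix(list(), genes)), 0L)
  co <- generate_cohort(cohort_spec(n_samples = 2, seed = 5))
  expect_identical(nrow(cohort_gene_matrix(call_profiles(co$profiles),
                                           genes)), 0L)
})

test_that("hotspot summary percentages agree with direct recounting", {
  profs <- list(
    mk_called_profile(data.frame(chrom = "chr1", start = 1L, end = 1000L,
                                 n_major = 3L, n_minor = 1L), id = "s1"),
    mk_called_profile(data.frame(chrom = "chr1", start = 1L, end = 1000L,
                                 n_major = 1L, n_minor = 0L), id = "s2"),
    mk_called_profile(data.frame(chrom = "chr1", start = 1L, end = 1000L,
                                 n_major = 1L, n_minor = 0L), id = "s3"),
    mk_called_profile(data.frame(chrom = "chr1", start = 1L, end = 1000L,
                                 n_major = 1L, n_minor = 1L), id = "s4"))
  genes <- data.frame(gene_symbol = "TP53", chrom = "chr1",
                      tx_start = 100L, tx_end = 200L)
  mat <- cohort_gene_matrix(profs, genes)
  kras_loh <- c(s1 = TRUE, s2 = TRUE, s3 = FALSE, s4 = FALSE)
  hs <- hotspot_summary(mat, panel = "TP53", kras_loh = kras_loh)
  expect_equal(hs$gain_pct, 25)
  expect_equal(hs$loss_pct, 50)
  expect_equal(hs$loh_pct, 50)
  # within the two KRAS-LOH samples, only s2 has TP53 LOH
  expect_equal(hs$loh_pct_within_kras_loh, 50)
  expect_error(hotspot_summary(mat, panel = c("TP53", "NOPE"), kras_loh),
               "NOPE")
})

test_that("an all-neutral cohort yields zero hotspot percentages", {
  profs <- lapply(1:3, function(i) mk_called_profile(
    data.frame(chrom = "chr1", start = 1L, end = 1000L,
               n_major = 1L, n_minor = 1L), id = paste0("s", i)))
  genes <- data.frame(gene_symbol = "EGFR", chrom = "chr1",
                      tx_start = 10L, tx_end = 20L)
  mat <- cohort_gene_matrix(profs, genes)
  hs <- hotspot_summary(mat, panel = "EGFR",
                        kras_loh = c(s1 = FALSE, s2 = FALSE, s3 = FALSE))
  expect_equal(unlist(hs[c("gain_pct", "loss_pct", "loh_pct")]),
               c(gain_pct = 0, loss_pct = 0, loh_pct = 0))
  expect_true(is.na(hs$loh_pct_within_kras_loh))
})

test_that("hotspot association excludes KRAS and adjusts over the panel family", {
  co <- generate_cohort(cohort_spec(n_samples = 60, seed = 9))
  mat <- cohort_gene_matrix(call_profiles(co$profiles), co$genome$genes)
  kras_loh <- gene_flag(mat, "KRAS", "loh")
  kras_loh[is.na(kras_loh)] <- FALSE
  assoc <- hotspot_association(mat, kras_loh = kras_loh)
  expect_false("KRAS" %in% assoc$gene_symbol)
  expect_identical(nrow(assoc), 13L)
  expect_equal(assoc$q_value, bh_step_up(assoc$p_value))
})
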