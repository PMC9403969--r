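test_that("per-transcript metrics aggregate windows arithmetically", {
  sc <- fake_scan(start = c(1L, 2L), z = c(-1, -3), w = 4L, L = 5L,
                  dg = c(-10, -20), ed = c(2, 4))
  tm <- transcript_metrics(sc)
  expect_equal(tm$mean_windowed_z, -2)
  expect_equal(tm$mean_windowed_dg, -15)
  expect_equal(tm$mean_windowed_ed, 3)
  expect_equal(tm$pct_windows_z_le_m1, 100)   # cutoff inclusive
  expect_equal(tm$pct_windows_z_le_m2, 50)
  expect_equal(tm$n_windows, 2L)
  empty <- sc[0, , drop = FALSE]
  attr(empty, "transcript_id") <- "FAKE.1"; attr(empty, "transcript_length") <- 5L
  expect_error(transcript_metrics(empty), "skipped")
})

test_that("metrics invariants: pct and motif-count ordering", {
  set.seed(66)
  for (rep in 1:10) {
    z <- rnorm(sample(5:50, 1), mean = -1)
    sc <- fake_scan(start = seq_along(z), z = z, w = 4L,
                    L = length(z) + 3L)
    tm <- transcript_metrics(sc)
    expect_lte(tm$pct_windows_z_le_m2, tm$pct_windows_z_le_m1)
    expect_true(tm$pct_windows_z_le_m1 >= 0 && tm$pct_windows_z_le_m1 <= 100)
  }
})

test_that("aggregation is linear under window-set concatenation", {
  set.seed(8)
  z1 <- rnorm(10); z2 <- rnorm(15)
  s1 <- fake_scan(start = 1:10, z = z1, w = 4L, L = 30L)
  s2 <- fake_scan(start = 1:15, z = z2, w = 4L, L = 30L)
  both <- fake_scan(start = c(1:10, 1:15), z = c(z1, z2), w = 4L, L = 30L)
  t1 <- transcript_metrics(s1); t2 <- transcript_metrics(s2)
  tb <- transcript_metrics(both)
  expect_equal(tb$mean_windowed_z,
               (10 * t1$mean_windowed_z + 15 * t2$mean_windowed_z) / 25)
  expect_equal(tb$pct_windows_z_le_m1,
               (10 * t1$pct_windows_z_le_m1 + 15 * t2$pct_windows_z_le_m1) / 25)
})

test_that("regional z-averages equal direct slice means", {
  tx <- transcript("R30.1", strrep("ACGUA", 6), utr5 = c(1, 10),
                   cds = c(11, 20), utr3 = c(21, 30))
  ramp <- seq(-3, 0, length.out = 30)
  rz <- regional_zavg(ramp, tx)
  expect_equal(rz$utr5_mean_z, mean(ramp[1:10]))
  expect_equal(rz$cds_mean_z, mean(ramp[11:20]))
  expect_equal(rz$utr3_mean_z, mean(ramp[21:30]))
  expect_equal(c(rz$utr5_n, rz$cds_n, rz$utr3_n), c(10, 10, 10))
  # uniform values give uniform means
  rzu <- regional_zavg(rep(-1, 30), tx)
  expect_equal(c(rzu$utr5_mean_z, rzu$cds_mean_z, rzu$utr3_mean_z),
               rep(-1, 3))
  # uncovered (NA) positions are excluded; empty regions give NA
  v <- ramp; v[1:10] <- NA
  rzn <- regional_zavg(v, tx)
  expect_true(is.na(rzn$utr5_mean_z))
  expect_equal(rzn$utr5_n, 0)
  # transcripts without a region annotation return NA for it
  tx2 <- transcript("R30.2", strrep("ACGUA", 6), cds = c(11, 20))
  rz2 <- regional_zavg(ramp, tx2)
  expect_true(is.na(rz2$utr5_mean_z) && is.na(rz2$utr3_mean_z))
})

test_that("whole-transcript mean is the length-weighted mean of region means", {
  tx <- transcript("T.1", strrep("A", 50), utr5 = c(1, 12), cds = c(13, 37),
                   utr3 = c(38, 50))
  set.seed(10)
  v <- rnorm(50)
  rz <- regional_zavg(v, tx)
  weighted <- (12 * rz$utr5_mean_z + 25 * rz$cds_mean_z + 13 * rz$utr3_mean_z) / 50
  expect_equal(weighted, mean(v))
})

test_that("expression-group summaries are transcript-weighted with unmatched count", {
  mt <- data.frame(
    transcript_id = c("T1.1", "T2.1", "T3.1", "T4.1", "T5.1"),
    gene_name = c("A", "A", "B", "C", "ZZZ"),
    mean_windowed_dg = c(-30, -40, -20, -10, -99),
    mean_windowed_z = c(-1, -2, -0.5, 0, -9),
    stringsAsFactors = FALSE)
  groups <- data.frame(gene = c("A", "B", "C"),
                       group = c("hk", "hk", "tissue"),
                       stringsAsFactors = FALSE)
  res <- expression_group_summary(mt, groups)
  expect_equal(res$n_unmatched, 1L)
  hk <- res$summary[res$summary$group == "hk", ]
  expect_equal(hk$n_transcripts, 3L)
  expect_equal(hk$n_genes, 2L)
  expect_equal(hk$mean_windowed_dg, mean(c(-30, -40, -20)))
  expect_equal(hk$mean_windowed_z, mean(c(-1, -2, -0.5)))
  ts <- res$summary[res$summary$group == "tissue", ]
  expect_equal(ts$mean_windowed_z, 0)
})

test_that("power binning is lower-inclusive and total-preserving", {
  rec <- data.frame(i = 1:4, j = 5:8, power = c(0.05, 0.1, 0.25, 0.9))
  expect_equal(unname(bin_power(rec)), c(1L, 1L, 2L))
  expect_equal(unname(bin_power(data.frame(power = numeric(0)))), c(0L, 0L, 0L))
  set.seed(12)
  p <- runif(1000)
  bins <- bin_power(data.frame(power = p))
  expect_equal(sum(bins), 1000L)
  expect_equal(unname(bins),
               c(sum(p < 0.1), sum(p >= 0.1 & p < 0.25), sum(p >= 0.25)))
})

test_that("power tables parse with comments and trailing power column", {
  f <- tempfile(fileext = ".power")
  writeLines(c("# left_pos right_pos substitutions power",
               "12  45   7   0.31",
               "13  44   2   0.08",
               "",
               "14  43   4   0.10"), f)
  rec <- read_power_table(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$i, c(12L, 13L, 14L))
  expect_equal(rec$power, c(0.31, 0.08, 0.10))
  expect_equal(unname(bin_power(rec)), c(1L, 1L, 1L))
})

test_that("gene-group tables require the documented columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tgroup", "A\thk"), f)
  expect_equal(read_gene_groups(f)$gene, "A")
  writeLines(c("symbol\tclass", "A\thk"), f)
  expect_error(read_gene_groups(f))
})
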