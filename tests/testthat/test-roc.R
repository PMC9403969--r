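test_that("percentile pairing calls hit the forced endpoints", {
  prof <- reactivity_profile(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(call_paired_at_percentile(prof, 0)), 0L)
  expect_equal(sum(call_paired_at_percentile(prof, 100)), 4L)
  expect_equal(which(call_paired_at_percentile(prof, 50)), c(1L, 2L))
  # missing positions are excluded
  prof2 <- reactivity_profile(c(0.1, NA, 0.3, 0.4))
  expect_equal(which(call_paired_at_percentile(prof2, 100)), c(1L, 3L, 4L))
})

test_that("confusion counts partition paired and unpaired positions", {
  prof <- reactivity_profile(c(0.1, 0.4, 0.2, 0.3))
  paired <- c(TRUE, TRUE, FALSE, FALSE)
  calls <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(confusion(paired, calls, prof),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  expect_error(confusion(paired[1:3], calls, prof), "length")
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    prof <- reactivity_profile(runif(n))
    s <- sample(c(TRUE, FALSE), n, TRUE)
    cc <- confusion(s, call_paired_at_percentile(prof, sample(0:100, 1)), prof)
    expect_equal(cc[["tp"]] + cc[["fn"]], sum(s))
    expect_equal(cc[["fp"]] + cc[["tn"]], sum(!s))
  }
})

test_that("ROC sweep runs (0,0) to (1,1), is monotone, AUC = 1 when separable", {
  set.seed(31)
  db <- "((((....))))"
  paired <- !is.na(pairs_from_dotbracket(db))
  prof <- make_reactivity(db, noise_sd = 0, seed = 5)
  roc <- roc_curve(paired, prof)
  sw <- roc$sweep
  expect_equal(nrow(sw), 101L)
  expect_equal(c(sw$tpr[1], sw$fpr[1]), c(0, 0))
  expect_equal(c(sw$tpr[101], sw$fpr[101]), c(1, 1))
  expect_true(all(diff(sw$tpr) >= 0))
  expect_true(all(diff(sw$fpr) >= 0))
  expect_equal(roc$auc, 1.0)
})

test_that("AUC is invariant under monotone transforms and flips under reversal", {
  set.seed(41)
  n <- 80L
  paired <- sample(c(TRUE, FALSE), n, TRUE)
  r <- runif(n)
  p1 <- reactivity_profile(r)
  a1 <- roc_curve(paired, p1)$auc
  # strictly increasing transform: identical AUC
  p2 <- reactivity_profile(exp(3 * r))
  expect_equal(roc_curve(paired, p2)$auc, a1, tolerance = 1e-12)
  # order reversal maps AUC -> 1 - AUC (up to discrete-sweep granularity)
  p3 <- reactivity_profile(max(r) + 1 - r)
  expect_equal(roc_curve(paired, p3)$auc, 1 - a1, tolerance = 0.03)
})

test_that("degenerate structures yield NA AUC with a warning", {
  prof <- reactivity_profile(runif(10))
  expect_warning(r <- roc_curve(rep(TRUE, 10), prof), "degenerate")
  expect_true(is.na(r$auc))
})

test_that("top-fraction mask picks the largest reactivities deterministically", {
  prof <- reactivity_profile(c(5, 1, 9, 3, 7, 2, 8, 4, 6, 0) / 10)
  expect_equal(top_fraction_mask(prof, 0.2), c(3L, 7L))
  # all-equal: ties broken by position index
  profeq <- reactivity_profile(rep(0.5, 10))
  expect_equal(top_fraction_mask(profeq, 0.3), 1:3)
  # perfectly informative profile on a hairpin: all masked single-stranded
  db <- "(((((....)))))"
  paired <- !is.na(pairs_from_dotbracket(db))
  prof2 <- make_reactivity(db, noise_sd = 0, seed = 2)
  mask <- top_fraction_mask(prof2, 4 / 14)
  expect_equal(single_stranded_share(mask, paired), 1.0)
})

test_that("CT and reactivity readers handle standard conventions", {
  st <- "((((....))))"
  sc <- fake_scan(start = 1L, z = -2.5, structure = st, w = 12L, L = 12L,
                  sequence = "GGGGAAAACCCC")
  m <- extract_motifs(final_partners(sc), -2)[[1]]
  ctf <- tempfile(fileext = ".ct")
  write_ct(m, ctf)
  ct <- read_ct(ctf)
  expect_equal(ct$paired, !is.na(pairs_from_dotbracket(st)))

  rf <- tempfile(fileext = ".react")
  writeLines(c("1\t0.5", "2\t-999", "3\tNA", "4\t1.25"), rf)
  prof <- read_reactivity(rf, length = 5)
  expect_equal(prof$reactivity, c(0.5, NA, NA, 1.25, NA))
  # DMS A/C-only masking
  prof2 <- read_reactivity(rf, length = 5, ac_only = TRUE, sequence = "ACGUA")
  expect_equal(prof2$mask, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("ROC tables round-trip through the writer", {
  set.seed(51)
  paired <- sample(c(TRUE, FALSE), 40, TRUE)
  roc <- roc_curve(paired, reactivity_profile(runif(40)))
  f <- tempfile(fileext = ".tsv")
  write_roc_table(roc, f)
  lines <- readLines(f)
  expect_equal(length(lines), 103L)  # header + 101 rows + auc comment
  expect_match(lines[103], "^# auc\t")
  back <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$tpr, roc$sweep$tpr, tolerance = 1e-6)
})
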