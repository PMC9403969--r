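test_that("pair accumulation sums z over the windows containing each pair", {
  # windows at starts 1..3, each pairing local (1,8) -> transcript (s, s+7)
  sc <- fake_scan(start = 1:3, z = c(-2, -2, -2), structure = "(......)",
                  w = 8L, L = 10L)
  ps <- accumulate_pairs(sc)
  expect_equal(nrow(ps), 3L)
  row <- ps[ps$i == 2 & ps$j == 9, ]
  expect_equal(row$n_windows, 1L)
  # same pair recurring across windows accumulates
  sc2 <- fake_scan(start = c(1L, 1L, 1L), z = c(-2, -2, -2),
                   structure = "(......)", w = 8L, L = 8L)
  ps2 <- accumulate_pairs(sc2)
  expect_equal(ps2$n_windows, 3L)
  expect_equal(ps2$zsum, -6)
  expect_equal(add_znorm(ps2)$znorm, -2)
})

test_that("two-window pair table equals brute-force enumeration", {
  st <- c("((....))..", ".((....))2")
  st[2] <- ".((....))."
  sc <- fake_scan(start = c(1L, 3L), z = c(-1.5, -0.5), structure = st,
                  w = 10L, L = 12L)
  ps <- accumulate_pairs(sc)
  # oracle: enumerate pairs of each structure directly
  want <- list()
  for (k in 1:2) {
    pr <- pairs_from_dotbracket(st[k])
    off <- sc$start[k] - 1L
    for (i in which(!is.na(pr) & pr > seq_along(pr))) {
      key <- paste(i + off, pr[i] + off)
      if (is.null(want[[key]])) want[[key]] <- c(0L, 0)
      want[[key]] <- want[[key]] + c(1L, sc$z[k])
    }
  }
  expect_equal(nrow(ps), length(want))
  for (r in seq_len(nrow(ps))) {
    key <- paste(ps$i[r], ps$j[r])
    expect_false(is.null(want[[key]]))
    expect_equal(ps$n_windows[r], want[[key]][1])
    expect_equal(ps$zsum[r], want[[key]][2])
  }
  # unbalanced window structure is a structural error naming the window
  bad <- fake_scan(start = 5L, z = -1, structure = "((...)", w = 6L, L = 10L)
  expect_error(accumulate_pairs(bad), "window starting at 5")
})

test_that("znorm denominator readings differ as documented on a 3-window fixture", {
  # windows all contain pair (2,9); endpoint 2 also pairs elsewhere in win 3
  st <- c("((....))..", "((....))..", "(.....)...")
  sc <- fake_scan(start = c(1L, 1L, 1L), z = c(-3, -1, -2), structure = st,
                  w = 10L, L = 10L)
  ps <- accumulate_pairs(sc)
  per_pair <- add_znorm(ps, denominator = "pair")
  per_nt <- add_znorm(ps, sc, denominator = "nucleotide")
  r <- per_pair[per_pair$i == 2 & per_pair$j == 7, ]
  expect_equal(r$zsum, -4)       # windows 1 and 2
  expect_equal(r$znorm, -2)      # zsum / n_windows(pair) = -4 / 2
  r2 <- per_nt[per_nt$i == 2 & per_nt$j == 7, ]
  # endpoint 2 paired in 2 windows; endpoint 7 paired in 3 (window 3 pairs 1-7)
  expect_equal(r2$znorm, -4 / mean(c(2, 3)))
})

test_that("competition resolution follows lowest-znorm-first with one partner", {
  ps <- data.frame(i = c(1L, 1L), j = c(10L, 12L), n_windows = c(1L, 1L),
                   zsum = c(-2, -1), znorm = c(-2, -1))
  rc <- resolve_competition(ps, 12L)
  expect_equal(rc$partner[1], 10L)
  expect_equal(rc$partner[10], 1L)
  expect_true(is.na(rc$partner[12]))
  # chain conflict: (1,10) accepted first blocks (10,20)
  ps2 <- data.frame(i = c(1L, 10L), j = c(10L, 20L), n_windows = 1L,
                    zsum = 0, znorm = c(-2, -1.5))
  rc2 <- resolve_competition(ps2, 20L)
  expect_equal(rc2$partner[1], 10L)
  expect_true(is.na(rc2$partner[20]))
})

test_that("final partners satisfy involution and maximality on random instances", {
  set.seed(55)
  for (rep in 1:25) {
    n <- 12L
    m <- sample(1:10, 1)
    i <- sample(1:(n - 1), m, replace = TRUE)
    j <- pmin(n, i + sample(1:6, m, replace = TRUE))
    df <- unique(data.frame(i = i, j = j))
    df <- df[df$i < df$j, , drop = FALSE]
    if (!nrow(df)) next
    df$znorm <- round(runif(nrow(df), -3, 0), 3)
    rc <- resolve_competition(df, n)
    p <- rc$partner
    idx <- which(!is.na(p))
    expect_equal(p[p[idx]], idx)                 # involution
    expect_lte(max(table(p[idx])), 1L)           # competition of 1
    # maximality: every rejected pair conflicts with an accepted one
    acc_key <- paste(rc$accepted$i, rc$accepted$j)
    for (r in seq_len(nrow(df))) {
      key <- paste(df$i[r], df$j[r])
      if (key %in% acc_key) next
      expect_true(!is.na(p[df$i[r]]) || !is.na(p[df$j[r]]))
    }
  }
})

test_that("pair classes use inclusive boundaries", {
  expect_equal(as.character(classify_pairs(c(-2.0, -1.5, -1.0, -0.2, 0, 0.5))),
               c("le_m2", "le_m1", "le_m1", "lt_0", "ge_0", "ge_0"))
})

test_that("crossing pairs are resolved by discarding the higher znorm", {
  acc <- data.frame(i = c(1L, 5L), j = c(10L, 15L), n_windows = 1L,
                    zsum = 0, znorm = c(-2, -1))
  out <- foldscan:::remove_crossings(acc)
  expect_equal(nrow(out), 1L)
  expect_equal(out$i, 1L)  # the lower (more negative) znorm survives
})

test_that("motif extraction delimits maximal nested components and thresholds", {
  # one hairpin; all pairs z = -2.5
  st <- "((((....))))"
  sc <- fake_scan(start = 1L, z = -2.5, structure = st, w = 12L, L = 12L,
                  sequence = "GGGGAAAACCCC")
  fp <- final_partners(sc)
  m2 <- extract_motifs(fp, -2)
  expect_length(m2, 1L)
  expect_equal(m2[[1]]$start, 1L)
  expect_equal(m2[[1]]$end, 12L)
  expect_equal(m2[[1]]$structure, st)
  expect_equal(m2[[1]]$min_pair_z, -2.5)

  # same hairpin at z = -1.5: motif at -1, none at -2
  sc2 <- fake_scan(start = 1L, z = -1.5, structure = st, w = 12L, L = 12L,
                   sequence = "GGGGAAAACCCC")
  fp2 <- final_partners(sc2)
  expect_length(extract_motifs(fp2, -2), 0L)
  expect_length(extract_motifs(fp2, -1), 1L)

  # two separate hairpins are two motifs; spans disjoint and sorted
  st3 <- "((....))..((....))"
  sc3 <- fake_scan(start = 1L, z = -2.5, structure = st3, w = 18L, L = 18L)
  m3 <- extract_motifs(final_partners(sc3), -2)
  expect_length(m3, 2L)
  expect_lt(m3[[1]]$end, m3[[2]]$start)
})

test_that("motif sets are monotone across thresholds on folded fixtures", {
  for (seed in 1:3) {
    ft <- make_transcript(n_motifs = 1L, stem_len = 10L,
                          region_layout = c(utr5 = 0L, cds = 30L, utr3 = 30L),
                          seed = seed)
    sc <- scan_transcript(ft$tx, tiny_params(window = 40L, n_shuffle = 20L,
                                             seed = seed))
    fp <- final_partners(sc)
    key <- function(m) sprintf("%d-%d", m$start, m$end)
    k1 <- vapply(extract_motifs(fp, -1), key, "")
    k2 <- vapply(extract_motifs(fp, -2), key, "")
    expect_true(all(k2 %in% k1))
    # involution on the full final pairing
    p <- fp$partner; idx <- which(!is.na(p))
    if (length(idx)) expect_equal(p[p[idx]], idx)
    # paired positions annotated with pair znorm, unpaired with z-average
    zavg <- per_nt_zavg(sc)
    unp <- which(is.na(p))
    expect_equal(fp$z_annot[unp], zavg[unp])
  }
})

test_that("consensus writers emit readable CT, dbn, GFF3 and arcs", {
  st <- "((((....))))"
  sc <- fake_scan(start = 1L, z = -2.5, structure = st, w = 12L, L = 12L,
                  sequence = "GGGGAAAACCCC")
  fp <- final_partners(sc)
  m <- extract_motifs(fp, -2)
  ct <- tempfile(fileext = ".ct")
  write_ct(m[[1]], ct)
  back <- read_ct(ct)
  expect_equal(back$length, 12L)
  expect_equal(back$partner, c(12L, 11L, 10L, 9L, 0L, 0L, 0L, 0L, 4L, 3L, 2L, 1L))
  expect_equal(paste(back$bases, collapse = ""), "GGGGAAAACCCC")

  dbn <- tempfile(fileext = ".dbn")
  write_dbn(m[[1]], dbn)
  expect_equal(readLines(dbn)[2:3], c("GGGGAAAACCCC", st))

  gff <- tempfile(fileext = ".gff3")
  write_motifs_gff3(m, gff, -2)
  g <- read_motifs_gff3(gff)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 1L); expect_equal(g$end, 12L)
  expect_equal(g$min_pair_z, -2.5, tolerance = 1e-4)

  fpf <- tempfile(fileext = ".tsv")
  write_final_partners(fp, fpf)
  tab <- read.table(fpf, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$partner[1], 12L)

  arcs <- tempfile(fileext = ".tsv")
  write_arcs(fp, arcs)
  a <- read.table(arcs, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(a), 4L)
  expect_equal(a$class, rep("le_m2", 4L))
})
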