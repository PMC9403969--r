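#' Accumulate base-pair statistics across scan windows
#'
#' Every base pair occurring in any window's MFE structure is recorded in
#' transcript coordinates with the number of windows containing it and the
#' sum of those windows' z-scores (Zsum). Recurring pairs in low z-score
#' windows accumulate strongly negative Zsum.
#'
#' @param windows a `foldscan_scan` data.frame (see [scan_transcript()])
#' @return data.frame with columns i, j (1-based, i < j), n_windows, zsum
#' @export
accumulate_pairs <- function(windows) {
  keys <- character(0); zs <- numeric(0)
  ilist <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    pr <- tryCatch(pairs_from_dotbracket(windows$structure[k]),
                   error = function(e)
                     stop(sprintf("window starting at %d: %s",
                                  windows$start[k], conditionMessage(e)),
                          call. = FALSE))
    idx <- which(!is.na(pr) & pr > seq_along(pr))
    if (!length(idx)) { ilist[[k]] <- NULL; next }
    off <- windows$start[k] - 1L
    ilist[[k]] <- data.frame(i = idx + off, j = pr[idx] + off,
                             z = windows$z[k])
  }
  all <- do.call(rbind, ilist)
  if (is.null(all) || !nrow(all))
    return(data.frame(i = integer(0), j = integer(0),
                      n_windows = integer(0), zsum = numeric(0)))
  key <- paste(all$i, all$j)
  agg <- rowsum(cbind(n = 1, zsum = all$z), key)
  ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    n_windows = as.integer(agg[, "n"]), zsum = agg[, "zsum"])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage-normalized pair score (Znorm)
#'
#' Zsum divided by a window-exposure denominator, giving a score in standard
#' deviation units that weights pairings appearing consistently in low
#' z-score windows and is comparable between well-covered interior positions
#' and sparsely covered transcript ends. Two denominator readings exist:
#'
#' * `"pair"` (default): the number of windows containing that exact pair, so
#'   Znorm is the mean z of the windows supporting the pair; symmetric in i
#'   and j.
#' * `"nucleotide"`: the mean over the two endpoints of the number of windows
#'   in which the endpoint is paired to *any* partner, penalizing pairs whose
#'   endpoints frequently pair elsewhere.
#'
#' @param pair_stats data.frame from [accumulate_pairs()]
#' @param windows the originating `foldscan_scan` (needed for the
#'   `"nucleotide"` denominator)
#' @param denominator `"pair"` or `"nucleotide"`
#' @return `pair_stats` with a `znorm` column
#' @export
add_znorm <- function(pair_stats, windows = NULL,
                      denominator = c("pair", "nucleotide")) {
  denominator <- match.arg(denominator)
  if (!nrow(pair_stats)) {
    pair_stats$znorm <- numeric(0)
    return(pair_stats)
  }
  if (denominator == "pair") {
    pair_stats$znorm <- pair_stats$zsum / pair_stats$n_windows
  } else {
    if (is.null(windows))
      stop("denominator = 'nucleotide' needs the scan windows")
    L <- attr(windows, "transcript_length")
    paired_cnt <- integer(L)
    for (k in seq_len(nrow(windows))) {
      pr <- pairs_from_dotbracket(windows$structure[k])
      pos <- which(!is.na(pr)) + windows$start[k] - 1L
      paired_cnt[pos] <- paired_cnt[pos] + 1L
    }
    denom <- (paired_cnt[pair_stats$i] + paired_cnt[pair_stats$j]) / 2
    pair_stats$znorm <- pair_stats$zsum / denom
  }
  pair_stats
}

#' Resolve pairing competition into final partners
#'
#' Greedy global selection in ascending Znorm (most negative first; ties
#' broken by smaller i, then smaller j): a pair is accepted iff both
#' endpoints are still unpartnered, enforcing "competition of 1" -- at most
#' one partner per nucleotide. The result is an involution.
#'
#' @param pair_stats data.frame with `znorm` (see [add_znorm()])
#' @param transcript_length transcript length, nt
#' @return list with `partner` (integer vector, NA = unpaired), `pair_z`
#'   (znorm of the accepted pair at each paired position, NA elsewhere) and
#'   `accepted` (the accepted subset of `pair_stats`)
#' @export
resolve_competition <- function(pair_stats, transcript_length) {
  partner <- rep(NA_integer_, transcript_length)
  pair_z <- rep(NA_real_, transcript_length)
  if (!nrow(pair_stats)) {
    return(list(partner = partner, pair_z = pair_z,
                accepted = pair_stats[0, , drop = FALSE]))
  }
  ord <- order(pair_stats$znorm, pair_stats$i, pair_stats$j)
  taken <- logical(transcript_length)
  keep <- logical(nrow(pair_stats))
  for (r in ord) {
    i <- pair_stats$i[r]; j <- pair_stats$j[r]
    if (taken[i] || taken[j]) next
    taken[i] <- taken[j] <- TRUE
    keep[r] <- TRUE
    partner[i] <- j; partner[j] <- i
    pair_z[i] <- pair_z[j] <- pair_stats$znorm[r]
  }
  acc <- pair_stats[keep, , drop = FALSE]
  acc <- acc[order(acc$i), , drop = FALSE]
  rownames(acc) <- NULL
  list(partner = partner, pair_z = pair_z, accepted = acc)
}

#' Z-score class of consensus pairs
#'
#' Boundary-inclusive classes matching the arc-track convention: `le_m2`
#' (z <= -2), `le_m1` (-2 < z <= -1), `lt_0` (-1 < z < 0) and `ge_0`
#' (z >= 0; excluded from motif extraction).
#'
#' @param znorm numeric vector of pair Znorm values
#' @return factor with levels le_m2, le_m1, lt_0, ge_0
#' @export
classify_pairs <- function(znorm) {
  cls <- ifelse(znorm <= -2, "le_m2",
         ifelse(znorm <= -1, "le_m1",
         ifelse(znorm < 0, "lt_0", "ge_0")))
  factor(cls, levels = c("le_m2", "le_m1", "lt_0", "ge_0"))
}

# Discard the higher-znorm pair of every crossing so the surviving set is
# nested (required for CT/dot-bracket emission). Pairs (i,j) and (k,l) cross
# iff i < k < j < l.
remove_crossings <- function(accepted) {
  if (nrow(accepted) < 2L) return(accepted)
  ord <- order(accepted$znorm, accepted$i, accepted$j)
  keep <- logical(nrow(accepted))
  for (r in ord) {
    i <- accepted$i[r]; j <- accepted$j[r]
    sel <- which(keep)
    crosses <- any((accepted$i[sel] < i & i < accepted$j[sel] & accepted$j[sel] < j) |
                   (i < accepted$i[sel] & accepted$i[sel] < j & j < accepted$j[sel]))
    if (!crosses) keep[r] <- TRUE
  }
  out <- accepted[keep, , drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

#' Consensus structure (final partners) for a scanned transcript
#'
#' Runs the full consensus stage: accumulate recurring pairs over windows,
#' normalize (Znorm), resolve competition, classify, and annotate every
#' position -- paired positions carry their pair's Znorm, unpaired positions
#' the per-nucleotide windowed z-average, so every position has a value for
#' track export. Crossing pairs surviving competition are retained in
#' `accepted` but flagged; [extract_motifs()] works on the nested subset.
#'
#' @param windows a `foldscan_scan`
#' @param denominator Znorm denominator, see [add_znorm()]
#' @return object of class `final_partners`: list with `partner`, `z_annot`,
#'   `pair_z`, `accepted` (with `z_class` and `crossing` columns), `nested`
#'   (crossing-free subset), `transcript_id`, `length`, `sequence`
#' @export
final_partners <- function(windows, denominator = c("pair", "nucleotide")) {
  denominator <- match.arg(denominator)
  L <- attr(windows, "transcript_length")
  id <- attr(windows, "transcript_id")
  ps <- add_znorm(accumulate_pairs(windows), windows, denominator)
  rc <- resolve_competition(ps, L)
  acc <- rc$accepted
  nested <- remove_crossings(acc)
  acc$crossing <- !(paste(acc$i, acc$j) %in% paste(nested$i, nested$j))
  acc$z_class <- classify_pairs(acc$znorm)
  nested$z_class <- classify_pairs(nested$znorm)
  zavg <- per_nt_zavg(windows, L)
  z_annot <- ifelse(is.na(rc$pair_z), zavg, rc$pair_z)
  seqfull <- transcript_sequence_from_scan(windows)
  structure(list(partner = rc$partner, z_annot = z_annot, pair_z = rc$pair_z,
                 accepted = acc, nested = nested, transcript_id = id,
                 length = L, sequence = seqfull),
            class = "final_partners")
}

# Reassemble the transcript sequence from overlapping window sequences.
transcript_sequence_from_scan <- function(windows) {
  L <- attr(windows, "transcript_length")
  out <- rep(NA_character_, L)
  for (k in seq_len(nrow(windows))) {
    rng <- windows$start[k]:windows$end[k]
    out[rng] <- strsplit(windows$sequence[k], "", fixed = TRUE)[[1]]
  }
  paste(ifelse(is.na(out), "N", out), collapse = "")
}

#' @export
print.final_partners <- function(x, ...) {
  cat(sprintf("<final_partners %s: %d nt, %d pairs (%d z<=-1, %d z<=-2)>\n",
              x$transcript_id, x$length, nrow(x$accepted),
              sum(x$accepted$znorm <= -1), sum(x$accepted$znorm <= -2)))
  invisible(x)
}

#' Extract structural motifs at a z-score threshold
#'
#' Motifs are maximal nested components of the consensus pairing: everything
#' enclosed by an outermost accepted pair, internal unpaired stretches
#' included; isolated pairs form one-pair motifs. A motif is emitted iff its
#' most negative pair Znorm is at or below `threshold_z`. The motif set at
#' threshold -2 is therefore a subset of the set at -1.
#'
#' @param fp a [final_partners()] object
#' @param threshold_z emit motifs whose minimum pair z is <= this (typical:
#'   -1 or -2); pairs with znorm >= 0 never count toward emission
#' @return list of `foldscan_motif` objects sorted by start, each with
#'   `start`, `end`, `pairs` (local data.frame i, j, znorm, z_class),
#'   `min_pair_z`, `sequence`, `structure`
#' @export
extract_motifs <- function(fp, threshold_z = -2) {
  stopifnot(inherits(fp, "final_partners"))
  prs <- fp$nested
  if (!nrow(prs)) return(list())
  # group pairs into maximal nested components via outermost pairs
  ord <- order(prs$i)
  prs <- prs[ord, , drop = FALSE]
  comp <- integer(nrow(prs))
  cur_end <- -1L; cid <- 0L
  for (r in seq_len(nrow(prs))) {
    if (prs$i[r] > cur_end) { cid <- cid + 1L; cur_end <- prs$j[r] }
    comp[r] <- cid
  }
  motifs <- lapply(split(seq_len(nrow(prs)), comp), function(rows) {
    sub <- prs[rows, , drop = FALSE]
    start <- min(sub$i); end <- max(sub$j)
    minz <- min(sub$znorm)
    if (minz > threshold_z) return(NULL)
    local <- data.frame(i = sub$i - start + 1L, j = sub$j - start + 1L,
                        znorm = sub$znorm, z_class = sub$z_class,
                        tx_i = sub$i, tx_j = sub$j)
    pairs_vec <- rep(NA_integer_, end - start + 1L)
    pairs_vec[local$i] <- local$j; pairs_vec[local$j] <- local$i
    structure(list(start = start, end = end, pairs = local,
                   min_pair_z = minz,
                   sequence = substr(fp$sequence, start, end),
                   structure = dotbracket_from_pairs(pairs_vec),
                   transcript_id = fp$transcript_id),
              class = "foldscan_motif")
  })
  motifs <- Filter(Negate(is.null), motifs)
  motifs[order(vapply(motifs, `[[`, 1L, "start"))]
}

#' @export
print.foldscan_motif <- function(x, ...) {
  cat(sprintf("<motif %s:%d-%d, %d pairs, min pair z %.2f>\n",
              x$transcript_id, x$start, x$end, nrow(x$pairs), x$min_pair_z))
  invisible(x)
}

# ---------------------------------------------------------------- writers --

#' Write the final-partners table
#'
#' TSV: position, nucleotide, partner (0 = unpaired), z annotation (pair
#' Znorm for paired positions, per-nt windowed z-average otherwise), class.
#'
#' @param fp a [final_partners()]
#' @param path output path
#' @export
write_final_partners <- function(fp, path) {
  n <- fp$length
  cls <- rep(NA_character_, n)
  paired <- !is.na(fp$partner)
  cls[paired] <- as.character(classify_pairs(fp$pair_z[paired]))
  df <- data.frame(position = seq_len(n),
                   nucleotide = strsplit(fp$sequence, "")[[1]],
                   partner = ifelse(paired, fp$partner, 0L),
                   z = fp$z_annot, class = ifelse(paired, cls, "."))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# foldscan final partners: transcript=%s", fp$transcript_id), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Write extracted motifs as GFF3
#' @param motifs list from [extract_motifs()]
#' @param path output path
#' @param threshold_z the extraction threshold (recorded in attributes)
#' @export
write_motifs_gff3 <- function(motifs, path, threshold_z = -2) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    writeLines(sprintf(
      "%s\tfoldscan\tsequence_secondary_structure\t%d\t%d\t.\t+\t.\tID=motif_%d;min_pair_z=%.4f;z_class=%s;threshold=%g",
      m$transcript_id, m$start, m$end, k, m$min_pair_z,
      as.character(classify_pairs(m$min_pair_z)), threshold_z), con)
  }
  invisible(path)
}

#' Read a motif GFF3 written by [write_motifs_gff3()]
#' @param path GFF3 file
#' @return data.frame with transcript_id, start, end, min_pair_z
#' @export
read_motifs_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), min_pair_z = numeric(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    transcript_id = vapply(f, `[[`, "", 1),
    start = as.integer(vapply(f, `[[`, "", 4)),
    end = as.integer(vapply(f, `[[`, "", 5)),
    min_pair_z = as.numeric(sub(".*min_pair_z=([-0-9.]+).*", "\\1",
                                vapply(f, `[[`, "", 9))))
}

#' Write a motif as a standard 6-column CT file
#'
#' Columns: index, base, index-1, index+1, partner (0 if unpaired), and the
#' original transcript position (historical numbering column).
#'
#' @param motif a `foldscan_motif`
#' @param path output path
#' @export
write_ct <- function(motif, path) {
  n <- motif$end - motif$start + 1L
  partner <- rep(0L, n)
  partner[motif$pairs$i] <- motif$pairs$j
  partner[motif$pairs$j] <- motif$pairs$i
  bases <- strsplit(motif$sequence, "")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d  %s:%d-%d min_pair_z=%.4f", n, motif$transcript_id,
                     motif$start, motif$end, motif$min_pair_z), con)
  writeLines(sprintf("%d\t%s\t%d\t%d\t%d\t%d", seq_len(n), bases,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L), partner,
                     motif$start:motif$end), con)
  invisible(path)
}

#' Write a motif as dot-bracket (dbn)
#' @inheritParams write_ct
#' @export
write_dbn <- function(motif, path) {
  writeLines(c(sprintf(">%s:%d-%d min_pair_z=%.4f", motif$transcript_id,
                       motif$start, motif$end, motif$min_pair_z),
               motif$sequence, motif$structure), path)
  invisible(path)
}

#' Write the base-pair arc track
#'
#' One row per accepted pair (crossing pairs included): position_i,
#' position_j, znorm, class -- suitable for genome-browser arc rendering.
#'
#' @param fp a [final_partners()]
#' @param path output path
#' @export
write_arcs <- function(fp, path) {
  df <- data.frame(position_i = fp$accepted$i, position_j = fp$accepted$j,
                   znorm = fp$accepted$znorm,
                   class = as.character(fp$accepted$z_class))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# foldscan arcs: transcript=%s", fp$transcript_id), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
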