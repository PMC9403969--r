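#' Scan parameters
#'
#' Defaults mirror the transcriptome-scale scanning protocol: 120 nt window,
#' 1 nt step, 100 mononucleotide shuffles per window, 37 C.
#'
#' @param window window size, nt
#' @param step step size, nt (1 <= step <= window)
#' @param shuffle a [shuffle_config()]
#' @param temperature_c folding temperature
#' @param seed global integer seed; per-window shuffle streams are derived
#'   from (seed, transcript id, window start) so results do not depend on
#'   evaluation order
#' @param compute_ed compute ensemble diversity for each native window
#'   (default TRUE; the partition function is the costliest part of a window
#'   and z-score-only analyses may skip it)
#' @export
scan_params <- function(window = 120L, step = 1L,
                        shuffle = shuffle_config(), temperature_c = 37,
                        seed = NULL, compute_ed = TRUE) {
  window <- as.integer(window); step <- as.integer(step)
  stopifnot(step >= 1L, step <= window, inherits(shuffle, "shuffle_config"))
  structure(list(window = window, step = step, shuffle = shuffle,
                 temperature_c = temperature_c, seed = seed,
                 compute_ed = isTRUE(compute_ed)),
            class = "scan_params")
}

#' Thermodynamic z-score
#'
#' `(native - mean(shuffled)) / sd(shuffled)`; each negative unit is one
#' standard deviation more stable than composition-matched random sequence.
#' The sample (n-1) standard deviation is used. Windows whose shuffled
#' energies are all identical (sd = 0, e.g. homopolymers) return z = 0 by
#' convention rather than poisoning downstream averages; callers can detect
#' them via [pvalue()] = 1 plus the scan table's `degenerate` flag.
#'
#' @param native_dg native window MFE, kcal/mol
#' @param shuffled_dgs numeric vector of >= 2 shuffled-window MFEs
#' @return z-score (standard deviations)
#' @export
zscore <- function(native_dg, shuffled_dgs) {
  if (length(shuffled_dgs) < 2L) stop("zscore requires >= 2 shuffled energies")
  s <- sd(shuffled_dgs)
  if (s == 0) return(0)
  (native_dg - mean(shuffled_dgs)) / s
}

#' Empirical p-value of a native window energy
#'
#' Fraction of shuffled energies at or below the native energy (ties count).
#' A quality-control companion to the z-score.
#'
#' @inheritParams zscore
#' @export
pvalue <- function(native_dg, shuffled_dgs) {
  if (length(shuffled_dgs) < 1L) stop("pvalue requires >= 1 shuffled energy")
  sum(shuffled_dgs <= native_dg) / length(shuffled_dgs)
}

#' Scan a transcript with a sliding thermodynamic window
#'
#' Each full window is folded natively (structure, MFE, ensemble diversity),
#' then shuffled `n_randomizations` times; the shuffled MFEs give the window
#' z-score and p-value. Only full windows are scanned: a transcript of length
#' L yields `floor((L - window)/step) + 1` windows. Transcripts shorter than
#' the window raise an error (filter first with [filter_by_length()]).
#'
#' @param tx a [transcript()]
#' @param params a [scan_params()]
#' @param backend a [fold_backend()]
#' @return data.frame of class `foldscan_scan` with columns start, end,
#'   native_dg, z, p, ed, degenerate, sequence, structure; attributes
#'   `transcript_id`, `transcript_length`, `params`, `backend`
#' @export
scan_transcript <- function(tx, params = scan_params(),
                            backend = fold_backend()) {
  stopifnot(inherits(tx, "transcript"), inherits(params, "scan_params"))
  L <- nchar(tx$sequence)
  w <- params$window
  if (L < w)
    stop(sprintf("transcript '%s' (%d nt) is shorter than the %d nt window",
                 tx$transcript_id, L, w))
  starts <- seq.int(1L, L - w + 1L, by = params$step)
  n <- length(starts)
  res <- data.frame(start = starts, end = starts + w - 1L,
                    native_dg = NA_real_, z = NA_real_, p = NA_real_,
                    ed = NA_real_, degenerate = FALSE,
                    sequence = NA_character_, structure = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    s <- starts[k]
    wseq <- substr(tx$sequence, s, s + w - 1L)
    nat <- backend$fold(wseq, params$temperature_c)
    ed <- if (params$compute_ed) backend$ed(wseq, params$temperature_c) else NA_real_
    stream <- if (is.null(params$seed)) NULL else
      derive_stream_seed(params$seed, tx$transcript_id, s)
    shufs <- with_stream_seed(stream, draw_shuffles(wseq, params$shuffle))
    dgs <- backend$energies(shufs, params$temperature_c)
    sdev <- sd(dgs)
    res$native_dg[k] <- nat$delta_g
    res$degenerate[k] <- sdev == 0
    res$z[k] <- if (sdev == 0) 0 else (nat$delta_g - mean(dgs)) / sdev
    res$p[k] <- if (sdev == 0) 1 else pvalue(nat$delta_g, dgs)
    res$ed[k] <- ed
    res$sequence[k] <- wseq
    res$structure[k] <- nat$structure
  }
  structure(res, class = c("foldscan_scan", "data.frame"),
            transcript_id = tx$transcript_id, transcript_length = L,
            params = params, backend = paste0(backend$name, "/", backend$version))
}

#' Per-nucleotide z-average
#'
#' For each transcript position, the mean z over all windows containing it;
#' positions covered by no window are `NA`. With step 1 every internal
#' position (window <= i <= L - window + 1) is covered by exactly `window`
#' windows.
#'
#' @param windows a `foldscan_scan` data.frame
#' @param transcript_length transcript length in nt (defaults to the scan
#'   attribute)
#' @return numeric vector of length `transcript_length`
#' @export
per_nt_zavg <- function(windows,
                        transcript_length = attr(windows, "transcript_length")) {
  stopifnot(!is.null(transcript_length))
  zsum <- numeric(transcript_length)
  cnt <- integer(transcript_length)
  for (k in seq_len(nrow(windows))) {
    rng <- windows$start[k]:windows$end[k]
    zsum[rng] <- zsum[rng] + windows$z[k]
    cnt[rng] <- cnt[rng] + 1L
  }
  out <- ifelse(cnt > 0L, zsum / cnt, NA_real_)
  out
}

#' Write / read a scan table
#'
#' Tab-separated, one row per window, with a commented header recording the
#' transcript, parameters and folding backend.
#'
#' @param windows a `foldscan_scan`
#' @param path output path
#' @export
write_scan_table <- function(windows, path) {
  p <- attr(windows, "params")
  hdr <- c(
    sprintf("# foldscan scan: transcript=%s length=%d", attr(windows, "transcript_id"),
            attr(windows, "transcript_length")),
    sprintf("# window=%d step=%d shuffle=%s randomizations=%d temperature_c=%s seed=%s",
            p$window, p$step, p$shuffle$mode, p$shuffle$n_randomizations,
            p$temperature_c, if (is.null(p$seed)) "NA" else p$seed),
    sprintf("# backend=%s", attr(windows, "backend")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(windows, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  tab <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  id <- sub(".*transcript=(\\S+).*", "\\1", meta[1])
  len <- as.integer(sub(".*length=(\\d+).*", "\\1", meta[1]))
  wdw <- as.integer(sub(".*window=(\\d+).*", "\\1", meta[2]))
  stp <- as.integer(sub(".* step=(\\d+).*", "\\1", meta[2]))
  structure(tab, class = c("foldscan_scan", "data.frame"),
            transcript_id = id, transcript_length = len,
            params = scan_params(window = wdw, step = stp),
            backend = sub("# backend=", "", meta[3], fixed = TRUE))
}

#' Write a fixedStep wig track
#'
#' One value per nucleotide in transcript-local coordinates (start=1, step=1);
#' `NA` values are written as `NA`.
#'
#' @param values numeric vector, one value per position
#' @param path output path
#' @param chrom track sequence name (transcript id)
#' @param name track name
#' @export
write_wig <- function(values, path, chrom, name = "foldscan") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
  writeLines(ifelse(is.na(values), "NA", formatC(values, format = "g", digits = 8)), con)
  invisible(path)
}

#' Read a fixedStep wig track written by [write_wig()]
#' @param path wig file
#' @return list with `chrom` and `values`
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  fs <- grep("^fixedStep", lines)
  if (!length(fs)) stop("not a fixedStep wig file: ", path)
  chrom <- sub(".*chrom=(\\S+).*", "\\1", lines[fs[1]])
  vals <- suppressWarnings(as.numeric(lines[(fs[1] + 1L):length(lines)]))
  list(chrom = chrom, values = vals)
}
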