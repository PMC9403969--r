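#' Transcript objects
#'
#' A transcript is a sequence in the RNA alphabet plus optional 1-based,
#' inclusive region spans for the 5'UTR, CDS and 3'UTR (transcript-local
#' coordinates, as in CT/wig/GFF3 conventions). Spans, when all present, must
#' be ordered 5'UTR < CDS < 3'UTR and non-overlapping.
#'
#' @param transcript_id accession string (e.g. an ENST id with version)
#' @param sequence nucleotide string; T is transliterated to U, ambiguity
#'   codes are preserved (they never base-pair in the folding engine)
#' @param gene_name gene symbol or `""`
#' @param utr5,cds,utr3 integer length-2 vectors `c(start, end)` or `NULL`
#' @return an object of class `transcript`
#' @export
transcript <- function(transcript_id, sequence, gene_name = "",
                       utr5 = NULL, cds = NULL, utr3 = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  sequence <- toupper(chartr("Tt", "Uu", sequence))
  len <- nchar(sequence)
  check_span <- function(span, what) {
    if (is.null(span)) return(NULL)
    span <- as.integer(span)
    if (length(span) != 2L || anyNA(span) || span[1] > span[2] ||
        span[1] < 1L || span[2] > len)
      stop(sprintf("transcript '%s': invalid %s span", transcript_id, what),
           call. = FALSE)
    span
  }
  utr5 <- check_span(utr5, "UTR5"); cds <- check_span(cds, "CDS")
  utr3 <- check_span(utr3, "UTR3")
  spans <- Filter(Negate(is.null), list(utr5 = utr5, cds = cds, utr3 = utr3))
  if (length(spans) > 1L) {
    m <- do.call(rbind, spans)
    ord <- order(m[, 1])
    if (any(diff(ord) < 0) || any(m[ord[-1], 1] <= m[ord[-length(ord)], 2]))
      stop(sprintf("transcript '%s': region spans overlap or are misordered",
                   transcript_id), call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, gene_name = gene_name,
                 sequence = sequence, utr5 = utr5, cds = cds, utr3 = utr3),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  fmt <- function(s) if (is.null(s)) "-" else sprintf("%d-%d", s[1], s[2])
  cat(sprintf("<transcript %s (%s), %d nt; UTR5 %s, CDS %s, UTR3 %s>\n",
              x$transcript_id, if (nzchar(x$gene_name)) x$gene_name else "?",
              nchar(x$sequence), fmt(x$utr5), fmt(x$cds), fmt(x$utr3)))
  invisible(x)
}

#' @export
length.transcript <- function(x) nchar(x$sequence)

parse_gencode_header <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  id <- fields[1]
  gene <- ""
  # GENCODE pc_transcripts: ENST|ENSG|OTTHUMG|OTTHUMT|name-201|name|len|UTR5:|CDS:|UTR3:|
  if (length(fields) >= 6L && grepl("^ENS", fields[1])) gene <- fields[6]
  spans <- list(utr5 = NULL, cds = NULL, utr3 = NULL)
  keys <- c(utr5 = "UTR5:", cds = "CDS:", utr3 = "UTR3:")
  for (k in names(keys)) {
    hit <- fields[startsWith(fields, keys[[k]])]
    if (length(hit)) {
      body <- sub(keys[[k]], "", hit[1], fixed = TRUE)
      parts <- strsplit(body, "-", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.integer(parts))
      if (length(val) != 2L || anyNA(val) || val[1] > val[2])
        stop(sprintf("record '%s': malformed %s span '%s'", id, keys[[k]], body),
             call. = FALSE)
      spans[[k]] <- val
    }
  }
  list(id = id, gene = gene, spans = spans)
}

#' Read transcripts from FASTA
#'
#' Accepts plain FASTA headers as well as the GENCODE protein-coding
#' transcript dialect with pipe-delimited `UTR5:a-b|CDS:c-d|UTR3:e-f` fields.
#' DNA is transliterated to RNA; record order is preserved. Unknown pipe
#' fields are ignored and absent region fields leave spans unset.
#'
#' @param path FASTA file
#' @return list of [transcript()] objects
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("no FASTA records in ", path)
    return(list())
  }
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    h <- parse_gencode_header(names(seqs)[k])
    out[[k]] <- transcript(h$id, as.character(seqs[[k]]), gene_name = h$gene,
                           utr5 = h$spans$utr5, cds = h$spans$cds,
                           utr3 = h$spans$utr3)
  }
  out
}

#' Write transcripts to FASTA
#'
#' Region spans, when present, are emitted in GENCODE-style pipe fields so a
#' write/read round trip is lossless.
#'
#' @param transcripts list of [transcript()] objects
#' @param path output file
#' @export
write_transcripts <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    hdr <- tx$transcript_id
    if (nzchar(tx$gene_name)) hdr <- paste0(hdr, "|", tx$gene_name)
    for (k in c("utr5", "cds", "utr3")) {
      if (!is.null(tx[[k]]))
        hdr <- paste0(hdr, "|", toupper(sub("utr", "UTR", k)), ":",
                      tx[[k]][1], "-", tx[[k]][2])
    }
    c(paste0(">", hdr), tx$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Partition transcripts by a minimum-length filter
#'
#' Transcripts shorter than the scan window cannot produce a single full
#' window and are set aside, mirroring the short-transcript exclusion applied
#' to transcriptome-scale scans.
#'
#' @param transcripts list of [transcript()] objects
#' @param min_length minimum length in nt (default 120, one scan window)
#' @return list with `kept` (transcripts) and `skipped`
#'   (data.frame: transcript_id, length)
#' @export
filter_by_length <- function(transcripts, min_length = 120L) {
  stopifnot(min_length >= 1L)
  lens <- vapply(transcripts, function(tx) nchar(tx$sequence), integer(1))
  keep <- lens >= min_length
  skipped <- data.frame(
    transcript_id = vapply(transcripts[!keep], `[[`, "", "transcript_id"),
    length = lens[!keep], stringsAsFactors = FALSE)
  list(kept = transcripts[keep], skipped = skipped)
}

#' Write the skipped-transcript report
#' @param skipped data.frame from [filter_by_length()]
#' @param path output TSV
#' @export
write_skipped_report <- function(skipped, path) {
  write.table(skipped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
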