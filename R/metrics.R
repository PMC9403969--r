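#' Per-transcript summary metrics
#'
#' Arithmetic means over all scan windows of MFE, z and ED, the percentage
#' of windows at or below the z <= -1 and z <= -2 cutoffs (inclusive), and
#' motif counts at both thresholds.
#'
#' @param windows a `foldscan_scan` (non-empty)
#' @param motifs_m1,motifs_m2 motif lists from [extract_motifs()] at
#'   thresholds -1 and -2
#' @param tx the scanned [transcript()] (for length and gene name); optional
#' @return one-row data.frame
#' @export
transcript_metrics <- function(windows, motifs_m1 = list(),
                               motifs_m2 = list(), tx = NULL) {
  if (!nrow(windows))
    stop("transcript_metrics: no windows (transcript should be in the skipped set)")
  n <- nrow(windows)
  data.frame(
    transcript_id = attr(windows, "transcript_id"),
    gene_name = if (!is.null(tx)) tx$gene_name else "",
    length = attr(windows, "transcript_length"),
    n_windows = n,
    mean_windowed_dg = mean(windows$native_dg),
    mean_windowed_z = mean(windows$z),
    mean_windowed_ed = mean(windows$ed),
    pct_windows_z_le_m1 = 100 * sum(windows$z <= -1) / n,
    pct_windows_z_le_m2 = 100 * sum(windows$z <= -2) / n,
    n_motifs_le_m1 = length(motifs_m1),
    n_motifs_le_m2 = length(motifs_m2),
    stringsAsFactors = FALSE)
}

#' Regional per-nucleotide z-averages
#'
#' Mean of the per-nucleotide windowed z-average over each annotated region
#' (5'UTR, CDS, 3'UTR). Positions not covered by any window are excluded;
#' transcripts lacking an annotation for a region return `NA` for it.
#'
#' @param per_nt_z vector from [per_nt_zavg()]
#' @param tx the [transcript()] carrying region spans
#' @return one-row data.frame: utr5_mean_z, cds_mean_z, utr3_mean_z and the
#'   per-region counts of covered nucleotides
#' @export
regional_zavg <- function(per_nt_z, tx) {
  stopifnot(inherits(tx, "transcript"))
  one <- function(span) {
    if (is.null(span)) return(c(NA_real_, 0))
    v <- per_nt_z[span[1]:span[2]]
    v <- v[!is.na(v)]
    c(if (length(v)) mean(v) else NA_real_, length(v))
  }
  u5 <- one(tx$utr5); cd <- one(tx$cds); u3 <- one(tx$utr3)
  data.frame(transcript_id = tx$transcript_id,
             utr5_mean_z = u5[1], utr5_n = u5[2],
             cds_mean_z = cd[1], cds_n = cd[2],
             utr3_mean_z = u3[1], utr3_n = u3[2],
             stringsAsFactors = FALSE)
}

#' Expression-class summary of scan metrics
#'
#' Joins a per-transcript metrics table against a gene -> group table and
#' reports per-group means of the average windowed MFE and z-score. Genes
#' with several analyzed transcripts contribute each transcript
#' (transcript-weighted means). Metrics rows whose gene has no group label
#' are counted as unmatched and excluded.
#'
#' @param metrics_table data.frame from [transcript_metrics()] rows
#' @param gene_to_group data.frame with columns `gene` and `group`
#' @return list with `summary` (group, n_transcripts, n_genes,
#'   mean_windowed_dg, mean_windowed_z) and `n_unmatched`
#' @export
expression_group_summary <- function(metrics_table, gene_to_group) {
  stopifnot(all(c("gene", "group") %in% names(gene_to_group)))
  idx <- match(metrics_table$gene_name, gene_to_group$gene)
  unmatched <- sum(is.na(idx))
  m <- metrics_table[!is.na(idx), , drop = FALSE]
  grp <- gene_to_group$group[idx[!is.na(idx)]]
  if (!nrow(m)) {
    return(list(summary = data.frame(group = character(0),
                                     n_transcripts = integer(0),
                                     n_genes = integer(0),
                                     mean_windowed_dg = numeric(0),
                                     mean_windowed_z = numeric(0)),
                n_unmatched = unmatched))
  }
  sp <- split(seq_len(nrow(m)), grp)
  summary <- do.call(rbind, lapply(names(sp), function(g) {
    rows <- sp[[g]]
    data.frame(group = g, n_transcripts = length(rows),
               n_genes = length(unique(m$gene_name[rows])),
               mean_windowed_dg = mean(m$mean_windowed_dg[rows]),
               mean_windowed_z = mean(m$mean_windowed_z[rows]),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, n_unmatched = unmatched)
}

#' Read a gene-list table (gene, group)
#' @param path TSV with header columns gene, group
#' @export
read_gene_groups <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "group") %in% names(df)))
  df
}

#' Bin covariation power values
#'
#' Counts covarying base pairs with power in \[0, 0.1), \[0.1, 0.25) and
#' \[0.25, Inf) -- lower-inclusive, so 0.1 falls in the middle bin and 0.25
#' in the top bin. Bin counts always sum to the number of records.
#'
#' @param power_records data.frame with a `power` column (values in \[0,1\])
#' @return named integer vector `c(low, mid, high)`
#' @export
bin_power <- function(power_records) {
  p <- power_records$power
  c(low = sum(p < 0.1), mid = sum(p >= 0.1 & p < 0.25), high = sum(p >= 0.25))
}

#' Read an R-scape-style base-pair power table
#'
#' Whitespace-delimited rows of `left_pos right_pos [substitutions] power`
#' with `#` comment lines; power is taken from the last numeric column.
#'
#' @param path power file
#' @return data.frame with i, j, power
#' @export
read_power_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(i = integer(0), j = integer(0), power = numeric(0)))
  f <- strsplit(lines, "\\s+")
  data.frame(i = as.integer(vapply(f, `[[`, "", 1)),
             j = as.integer(vapply(f, `[[`, "", 2)),
             power = as.numeric(vapply(f, function(x) x[length(x)], "")))
}
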