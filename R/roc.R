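#' Reactivity profile
#'
#' Per-position chemical probing reactivities (DMS or SHAPE). High
#' reactivity indicates single-strandedness. Missing values (`NA` or the
#' -999 sentinel) are excluded from all percentile computations; DMS
#' profiles can optionally be restricted to A/C nucleotides via the mask.
#'
#' @param reactivity numeric vector (non-negative where present)
#' @param probe label, e.g. "DMS" or "SHAPE"
#' @param mask logical vector of applicable positions (default: all)
#' @export
reactivity_profile <- function(reactivity, probe = "SHAPE", mask = NULL) {
  reactivity[!is.na(reactivity) & reactivity <= -500] <- NA
  if (is.null(mask)) mask <- rep(TRUE, length(reactivity))
  stopifnot(length(mask) == length(reactivity))
  structure(list(reactivity = reactivity, probe = probe, mask = mask),
            class = "reactivity_profile")
}

#' Read a two-column reactivity file
#'
#' Lines of `position value`; `NA` and `-999` mark missing values. Positions
#' absent from the file are missing.
#'
#' @param path reactivity file (.react/.shape style)
#' @param length profile length; defaults to the maximum position present
#' @param probe probe label
#' @param ac_only restrict applicability to A/C positions (DMS convention);
#'   requires `sequence`
#' @param sequence transcript sequence (needed for `ac_only`)
#' @export
read_reactivity <- function(path, length = NULL, probe = "SHAPE",
                            ac_only = FALSE, sequence = NULL) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", "nan"))
  pos <- as.integer(df[[1]]); val <- suppressWarnings(as.numeric(df[[2]]))
  if (is.null(length)) length <- max(pos)
  r <- rep(NA_real_, length)
  r[pos] <- val
  mask <- rep(TRUE, length)
  if (ac_only) {
    if (is.null(sequence)) stop("ac_only = TRUE requires the sequence")
    ch <- strsplit(toupper(chartr("T", "U", sequence)), "")[[1]]
    mask <- ch %in% c("A", "C")
  }
  reactivity_profile(r, probe = probe, mask = mask)
}

#' Read a standard 6-column CT file
#'
#' @param path CT file (first line: length + title)
#' @return list with `length`, `bases`, `partner` (0 = unpaired) and
#'   `paired` (logical)
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- read.table(text = lines[2:(n + 1)], header = FALSE,
                     stringsAsFactors = FALSE)
  if (nrow(body) != n) stop("CT row count does not match header length")
  list(length = n, bases = as.character(body[[2]]),
       partner = as.integer(body[[5]]), paired = as.integer(body[[5]]) > 0L)
}

applicable_idx <- function(profile) {
  which(profile$mask & !is.na(profile$reactivity))
}

#' Pairing calls at a reactivity percentile
#'
#' The `x_percent` of applicable positions with the *lowest* reactivity are
#' called paired (low reactivity implies base pairing); ties are broken by
#' position index. At 0% no position is called paired; at 100% all
#' applicable positions are.
#'
#' @param profile a [reactivity_profile()]
#' @param x_percent threshold in \[0, 100\]
#' @return logical vector over all positions (FALSE where inapplicable)
#' @export
call_paired_at_percentile <- function(profile, x_percent) {
  stopifnot(x_percent >= 0, x_percent <= 100)
  idx <- applicable_idx(profile)
  k <- floor(x_percent / 100 * length(idx) + 1e-9)
  calls <- rep(FALSE, length(profile$reactivity))
  if (k > 0L) {
    ord <- idx[order(profile$reactivity[idx], idx)]
    calls[ord[seq_len(k)]] <- TRUE
  }
  calls
}

#' Confusion counts of reactivity pairing calls against a structure
#'
#' TP: paired in the structure and called paired; FN: paired, called
#' unpaired; FP: unpaired, called paired; TN: unpaired, called unpaired.
#' Counted over applicable, non-missing positions only.
#'
#' @param paired_ct logical vector: paired in the structure model
#' @param calls logical vector from [call_paired_at_percentile()]
#' @param profile the [reactivity_profile()] (for applicability)
#' @return named integer vector tp, fn, fp, tn
#' @export
confusion <- function(paired_ct, calls, profile) {
  if (length(paired_ct) != length(profile$reactivity))
    stop("structure and reactivity profile lengths differ")
  idx <- applicable_idx(profile)
  s <- paired_ct[idx]; c_ <- calls[idx]
  c(tp = sum(s & c_), fn = sum(s & !c_), fp = sum(!s & c_), tn = sum(!s & !c_))
}

#' ROC curve of a structure model against a reactivity profile
#'
#' Sweeps the pairing-call threshold from 0% to 100% in 1% steps; TPR =
#' TP/(TP+FN), FPR = FP/(FP+TN); AUC by the trapezoidal rule over the sweep.
#' The curve runs from (0,0) to (1,1) and both rates are non-decreasing in
#' the threshold. Structures with zero paired or zero unpaired applicable
#' positions have no defined AUC (returned as NA with a warning).
#'
#' @param paired_ct logical vector: paired in the structure model
#' @param profile a [reactivity_profile()] of the same length
#' @return object of class `roc_curve`: list with `sweep` (data.frame:
#'   threshold, tp, fn, fp, tn, tpr, fpr) and `auc`
#' @export
roc_curve <- function(paired_ct, profile) {
  thresholds <- 0:100
  rows <- t(vapply(thresholds, function(x) {
    confusion(paired_ct, call_paired_at_percentile(profile, x), profile)
  }, c(tp = 0, fn = 0, fp = 0, tn = 0)))
  sweep <- data.frame(threshold = thresholds, rows)
  npair <- sweep$tp + sweep$fn
  nunp <- sweep$fp + sweep$tn
  sweep$tpr <- ifelse(npair > 0, sweep$tp / npair, NA_real_)
  sweep$fpr <- ifelse(nunp > 0, sweep$fp / nunp, NA_real_)
  auc <- NA_real_
  if (all(npair > 0) && all(nunp > 0)) {
    ord <- order(sweep$fpr, sweep$tpr)
    fpr <- sweep$fpr[ord]; tpr <- sweep$tpr[ord]
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  } else {
    warning("degenerate structure (no paired or no unpaired positions); AUC undefined")
  }
  structure(list(sweep = sweep, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d sweep points, AUC = %s>\n", nrow(x$sweep),
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' Top-fraction reactivity mask
#'
#' The highest-reactivity fraction of applicable positions (ties broken by
#' position index), as overlaid on structure models to check that high
#' reactivities fall in single-stranded regions. The companion statistic
#' [single_stranded_share()] reports the share of masked positions that are
#' unpaired in a given structure.
#'
#' @param profile a [reactivity_profile()]
#' @param fraction fraction in (0, 1\]; default 0.20
#' @return integer vector of positions
#' @export
top_fraction_mask <- function(profile, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- applicable_idx(profile)
  k <- floor(fraction * length(idx) + 0.5)
  if (k == 0L) return(integer(0))
  ord <- idx[order(-profile$reactivity[idx], idx)]
  sort(ord[seq_len(k)])
}

#' Share of masked positions that are single-stranded in a structure
#' @param mask positions from [top_fraction_mask()]
#' @param paired_ct logical paired-in-structure vector
#' @return fraction in \[0, 1\]
#' @export
single_stranded_share <- function(mask, paired_ct) {
  if (!length(mask)) return(NA_real_)
  mean(!paired_ct[mask])
}

#' Write an ROC sweep table and AUC summary
#' @param roc a [roc_curve()]
#' @param path output TSV (the AUC goes in a trailing comment line)
#' @export
write_roc_table <- function(roc, path) {
  con <- file(path, "w"); on.exit(close(con))
  suppressWarnings(write.table(roc$sweep, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  writeLines(sprintf("# auc\t%s", if (is.na(roc$auc)) "NA"
                     else formatC(roc$auc, format = "f", digits = 6)), con)
  invisible(path)
}
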