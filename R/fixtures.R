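#' Synthetic transcript with planted hairpins
#'
#' Generates a transcript whose background is i.i.d. mononucleotide sequence
#' (matching the mononucleotide-shuffle null, so background windows have
#' z-scores centered near 0) with `n_motifs` GC-rich perfect hairpins planted
#' at recorded positions. Every planted pair is recorded in `planted`;
#' recovery tests are computed against this record, never re-derived.
#'
#' @param n_motifs number of hairpins to plant
#' @param stem_len stem length in base pairs (GC-rich stems of >= 8 bp fold
#'   robustly; default 12)
#' @param loop_len hairpin loop length, nt (>= 3; default 4)
#' @param region_layout named integer vector of region lengths in order
#'   utr5, cds, utr3; the transcript length is their sum
#' @param background_freqs mononucleotide probabilities (A, C, G, U)
#' @param seed integer seed; fixed seed gives a byte-identical transcript
#' @return list with `tx` (a [transcript()]), `planted` (list per motif:
#'   start, end, region, pairs data.frame i, j), `seed`
#' @export
make_transcript <- function(n_motifs = 1L, stem_len = 12L, loop_len = 4L,
                            region_layout = c(utr5 = 30L, cds = 60L, utr3 = 60L),
                            background_freqs = c(A = 0.25, C = 0.25,
                                                 G = 0.25, U = 0.25),
                            seed = 1L) {
  stopifnot(stem_len >= 1L, loop_len >= 3L, all(region_layout >= 0L))
  L <- sum(region_layout)
  motif_len <- 2L * stem_len + loop_len
  with_stream_seed(seed, {
    bases <- c("A", "C", "G", "U")
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    seq_ch <- sample(bases, L, replace = TRUE, prob = background_freqs)
    bounds <- cumsum(region_layout)
    region_span <- function(k) {
      lo <- if (k == 1L) 1L else bounds[k - 1L] + 1L
      c(lo, bounds[k])
    }
    planted <- list()
    occupied <- logical(L)
    for (m in seq_len(n_motifs)) {
      # choose a region that can hold the motif, then a free start within it
      ok_regions <- which(region_layout >= motif_len)
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        rk <- ok_regions[sample.int(length(ok_regions), 1L)]
        sp <- region_span(rk)
        start <- sp[1] + sample.int(sp[2] - sp[1] + 1L - motif_len + 1L, 1L) - 1L
        rng <- start:(start + motif_len - 1L)
        if (!any(occupied[rng])) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place planted motif ", m)
      stem <- sample(bases, stem_len, replace = TRUE,
                     prob = c(A = 0.1, C = 0.4, G = 0.4, U = 0.1))
      loop <- sample(bases, loop_len, replace = TRUE, prob = background_freqs)
      seq_ch[rng] <- c(stem, loop, rev(unname(comp[stem])))
      occupied[rng] <- TRUE
      pairs <- data.frame(i = start + seq_len(stem_len) - 1L,
                          j = start + motif_len - seq_len(stem_len))
      planted[[m]] <- list(start = start, end = start + motif_len - 1L,
                           region = names(region_layout)[rk], pairs = pairs)
    }
    tx <- transcript(sprintf("SYNTX%05d.1", seed),
                     paste(seq_ch, collapse = ""), gene_name = "SYNGENE",
                     utr5 = if (region_layout[1] > 0) region_span(1L) else NULL,
                     cds = if (region_layout[2] > 0) region_span(2L) else NULL,
                     utr3 = if (region_layout[3] > 0) region_span(3L) else NULL)
    list(tx = tx, planted = planted, seed = seed)
  })
}

#' Synthetic reactivity profile for a known structure
#'
#' Paired positions draw from a low-mean distribution, unpaired from a
#' high-mean one, with Gaussian noise of the stated sd, truncated at 0.
#' With `noise_sd = 0` the profile separates the generating structure
#' perfectly (ROC AUC = 1).
#'
#' @param structure dot-bracket string of the true structure
#' @param noise_sd Gaussian noise standard deviation (default 0.3)
#' @param seed integer seed
#' @param paired_mean,unpaired_mean distribution centers (defaults 0.2, 1.2)
#' @param probe probe label
#' @return a [reactivity_profile()]
#' @export
make_reactivity <- function(structure, noise_sd = 0.3, seed = 1L,
                            paired_mean = 0.2, unpaired_mean = 1.2,
                            probe = "SHAPE") {
  pr <- pairs_from_dotbracket(structure)
  n <- length(pr)
  with_stream_seed(seed, {
    mu <- ifelse(is.na(pr), unpaired_mean, paired_mean)
    vals <- pmax(0, rnorm(n, mean = mu, sd = noise_sd))
    reactivity_profile(vals, probe = probe)
  })
}

#' Write a reactivity profile as two-column text
#' @param profile a [reactivity_profile()]
#' @param path output file
#' @export
write_reactivity <- function(profile, path) {
  v <- profile$reactivity
  writeLines(sprintf("%d\t%s", seq_along(v),
                     ifelse(is.na(v), "NA", formatC(v, format = "f", digits = 4))),
             path)
  invisible(path)
}
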