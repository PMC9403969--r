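#' Shuffle configuration for the z-score null
#'
#' @param mode `"mononucleotide"` (permutation, preserves base composition) or
#'   `"dinucleotide"` (Euler-path shuffle, preserves all 16 dinucleotide
#'   counts and the terminal bases)
#' @param n_randomizations number of shuffled sequences per window
#' @param seed integer global seed, or `NULL` to use the current RNG state
#' @export
shuffle_config <- function(mode = c("mononucleotide", "dinucleotide"),
                           n_randomizations = 100L, seed = NULL) {
  mode <- match.arg(mode)
  n_randomizations <- as.integer(n_randomizations)
  stopifnot(n_randomizations >= 1L)
  structure(list(mode = mode, n_randomizations = n_randomizations, seed = seed),
            class = "shuffle_config")
}

#' Mononucleotide shuffle
#'
#' Random permutation of the sequence letters; the per-letter counts are
#' exactly preserved. Uses (and advances) the current R RNG stream.
#'
#' @param sequence nucleotide string
#' @return shuffled string
#' @export
shuffle_mononucleotide <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  stopifnot(length(ch) >= 1L)
  paste(ch[sample.int(length(ch))], collapse = "")
}

#' Dinucleotide shuffle (Altschul-Erickson)
#'
#' Random Euler path on the dinucleotide multigraph: every one of the 16
#' dinucleotide counts is preserved exactly, as are the first and last
#' letters. This is the field-standard realization of dinucleotide-preserving
#' randomization.
#'
#' @param sequence nucleotide string, length >= 2
#' @return shuffled string
#' @export
shuffle_dinucleotide <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2L) stop("dinucleotide shuffle requires length >= 2")
  letters_used <- unique(ch)
  last <- ch[n]
  # adjacency: out-edge target lists per vertex
  adj <- split(ch[-1], factor(ch[-n], levels = letters_used))
  verts <- names(adj)[vapply(adj, length, 1L) > 0L]
  if (length(letters_used) == 1L) return(sequence)

  repeat {
    # pick a random final out-edge for every vertex except the terminal one;
    # they must form an arborescence into `last`
    final_edge <- list()
    for (v in verts) {
      if (v == last) next
      final_edge[[v]] <- adj[[v]][sample.int(length(adj[[v]]), 1L)]
    }
    ok <- TRUE
    for (v in names(final_edge)) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.null(final_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- final_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle remaining out-edges; append the selected final edge last
  out_edges <- list()
  for (v in names(adj)) {
    e <- adj[[v]]
    if (!is.null(final_edge[[v]])) {
      drop_at <- match(final_edge[[v]], e)
      e <- e[-drop_at]
    }
    e <- if (length(e)) e[sample.int(length(e))] else character(0)
    if (!is.null(final_edge[[v]])) e <- c(e, final_edge[[v]])
    out_edges[[v]] <- e
  }
  # walk the Euler path from the first letter
  res <- character(n)
  res[1] <- ch[1]
  ptr <- setNames(rep(1L, length(out_edges)), names(out_edges))
  cur <- ch[1]
  for (k in 2:n) {
    nxt <- out_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[k] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Draw shuffled sequences under a configuration
#' @param sequence nucleotide string
#' @param config a [shuffle_config()]
#' @return character vector of `n_randomizations` shuffles
#' @export
draw_shuffles <- function(sequence, config) {
  fn <- switch(config$mode,
               mononucleotide = shuffle_mononucleotide,
               dinucleotide = shuffle_dinucleotide)
  vapply(seq_len(config$n_randomizations), function(i) fn(sequence), "")
}

# Deterministic per-window stream seed from (global seed, transcript id,
# window start), so scans are reproducible and order-independent. FNV-1a-like
# string hash folded into [0, 2^31 - 2].
derive_stream_seed <- function(seed, transcript_id, window_start) {
  h <- 104729
  mix <- function(h, x) {
    for (b in x) {
      h <- bitwXor(as.integer(h), as.integer(b))
      h <- (h * 48271) %% 2147483647  # MINSTD step; products stay below 2^53
    }
    h
  }
  h <- mix(h, utf8ToInt(as.character(transcript_id)))
  h <- mix(h, as.integer(seed) %% 256L + 1L)
  h <- mix(h, c(window_start %% 256L, window_start %/% 256L %% 256L,
                as.integer(seed) %% 65536L %/% 256L, as.integer(seed) %/% 65536L %% 256L))
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
# After seeding, a block of draws is discarded: the Mersenne-Twister state
# from small consecutive integer seeds is poorly scrambled in its first
# outputs, which measurably biases prob-weighted sampling (observed as a
# spurious positive thermodynamic z on "random" backgrounds). The warm-up
# restores i.i.d. behavior while keeping full determinism.
with_stream_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  invisible(stats::runif(257L))
  expr
}
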