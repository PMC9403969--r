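# shared helpers: random sequences, tiny scan fixtures, brute-force oracles

random_rna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

base_counts <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "U")))
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  table(factor(di, levels = lv))
}

# all strings reachable by a dinucleotide-preserving shuffle of s (brute force:
# permutations of the interior letters filtered on dinucleotide counts)
dinuc_reachable <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  mid <- ch[2:(n - 1)]
  perm_idx <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perm_idx(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
    out
  }
  cands <- unique(vapply(perm_idx(mid),
                         function(p) paste(c(ch[1], p, ch[n]), collapse = ""), ""))
  ref <- dinuc_counts(s)
  cands[vapply(cands, function(x) all(dinuc_counts(x) == ref), TRUE)]
}

# a fake scan object with given window rows (bypasses folding)
fake_scan <- function(start, z, structure = NULL, L = max(start) + w - 1L,
                      w = 120L, sequence = NULL, id = "FAKE.1",
                      dg = NULL, ed = NULL, p = NULL) {
  n <- length(start)
  if (is.null(structure)) structure <- strrep(".", w)
  if (length(structure) == 1L) structure <- rep(structure, n)
  if (is.null(sequence)) sequence <- rep(strrep("A", w), n)
  df <- data.frame(start = start, end = start + w - 1L,
                   native_dg = if (is.null(dg)) rep(-10, n) else dg,
                   z = z, p = if (is.null(p)) rep(0, n) else p,
                   ed = if (is.null(ed)) rep(1, n) else ed,
                   degenerate = FALSE, sequence = sequence,
                   structure = structure, stringsAsFactors = FALSE)
  structure(df, class = c("foldscan_scan", "data.frame"),
            transcript_id = id, transcript_length = L,
            params = scan_params(window = w, step = 1L), backend = "fake/0")
}

# small fast scan parameters for unit tests (not the stated scanning world;
# those live in the acceptance suite)
tiny_params <- function(window = 40L, n_shuffle = 10L, seed = 11L,
                        compute_ed = FALSE) {
  scan_params(window = window, step = 1L,
              shuffle = shuffle_config("mononucleotide", n_shuffle),
              seed = seed, compute_ed = compute_ed)
}

with_seed <- function(seed, expr) foldscan:::with_stream_seed(seed, expr)
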