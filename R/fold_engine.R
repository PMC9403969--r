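#' Folding backend adapter
#'
#' The scanning and consensus layers are backend-agnostic: any engine that
#' returns an MFE structure/energy and an ensemble diversity for windows of
#' ~200 nt or less can serve. Two adapters ship:
#'
#' * `"nn"` (default): the built-in reduced nearest-neighbor engine
#'   (Watson-Crick + wobble stacking, tabulated loop initiations, linear
#'   multibranch model, terminal AU/GU penalty; parameters at 37 C). MFE by a
#'   Zuker-style recursion; ensemble diversity from a matching McCaskill
#'   partition function. Deterministic, no external dependency.
#' * `"rnafold"`: shells out to an installed ViennaRNA `RNAfold` binary
#'   (Turner 2004 parameters). Selected explicitly; a configuration error
#'   naming the adapter is raised when the binary is absent.
#'
#' Backend name and version are recorded in all file-writer headers because
#' absolute MFE values depend on the energy parameter set.
#'
#' @param name backend name
#' @return an object of class `fold_backend` with elements `name`, `version`,
#'   and functions `fold(sequence, temperature_c)`,
#'   `energies(sequences, temperature_c)`, `ed(sequence, temperature_c)`,
#'   `energy_of(sequence, structure, temperature_c)`
#' @export
fold_backend <- function(name = getOption("foldscan.backend", "nn")) {
  switch(name,
    nn = structure(list(
      name = "nn",
      version = "foldscan-reduced-1",
      fold = function(sequence, temperature_c = 37) {
        r <- .fold_mfe_cpp(sequence)
        list(structure = r$structure, delta_g = r$dg, pairs = r$pairs)
      },
      energies = function(sequences, temperature_c = 37)
        .fold_energy_many_cpp(sequences),
      ed = function(sequence, temperature_c = 37)
        .partition_cpp(sequence, temperature_c)$ed,
      energy_of = function(sequence, structure, temperature_c = 37)
        .energy_of_structure_cpp(sequence, structure)
    ), class = "fold_backend"),
    rnafold = rnafold_backend(),
    stop("unknown folding backend: ", name)
  )
}

rnafold_backend <- function() {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin))
    stop("fold_backend('rnafold'): RNAfold binary not found on PATH; ",
         "install ViennaRNA or use the built-in 'nn' backend", call. = FALSE)
  ver <- tryCatch(system2(bin, "--version", stdout = TRUE)[1],
                  error = function(e) "RNAfold (unknown version)")
  run <- function(args, input) system2(bin, args, stdout = TRUE, input = input)
  parse_mfe <- function(out) {
    line <- out[2]
    db <- sub("^([.()]+).*", "\\1", line)
    dg <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
    list(structure = db, delta_g = dg)
  }
  structure(list(
    name = "rnafold",
    version = ver,
    fold = function(sequence, temperature_c = 37) {
      r <- parse_mfe(run(c("--noPS", "-T", temperature_c), sequence))
      r$pairs <- pairs_from_dotbracket(r$structure)
      r
    },
    energies = function(sequences, temperature_c = 37) {
      out <- run(c("--noPS", "-T", temperature_c), sequences)
      lines <- out[seq(2, length(out), by = 2)]
      as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", lines))
    },
    ed = function(sequence, temperature_c = 37) {
      out <- run(c("--noPS", "-p", "-T", temperature_c), sequence)
      line <- out[grepl("ensemble diversity", out)][1]
      as.numeric(sub(".*ensemble diversity\\s+([0-9.]+).*", "\\1", line))
    },
    energy_of = function(sequence, structure, temperature_c = 37) {
      out <- system2(Sys.which("RNAeval"), c("-T", temperature_c),
                     stdout = TRUE, input = c(sequence, structure))
      as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", out[2]))
    }
  ), class = "fold_backend")
}

#' @export
print.fold_backend <- function(x, ...) {
  cat(sprintf("<fold_backend %s (%s)>\n", x$name, x$version)); invisible(x)
}

#' Fold a sequence at its minimum free energy
#'
#' @param sequence RNA string (ambiguity codes allowed; they never pair)
#' @param temperature_c folding temperature; the built-in parameter set is
#'   defined at 37 C
#' @param backend a [fold_backend()]
#' @return list with `structure` (dot-bracket), `delta_g` (kcal/mol, <= 0)
#'   and `pairs` (1-based partner vector, NA when unpaired)
#' @export
mfe_fold <- function(sequence, temperature_c = 37, backend = fold_backend()) {
  stopifnot(nchar(sequence) >= 1L)
  backend$fold(sequence, temperature_c)
}

#' Ensemble diversity of a sequence
#'
#' Mean base-pair distance among Boltzmann-weighted conformations,
#' \eqn{2 \sum_{i<j} p_{ij} (1 - p_{ij})}. Low values indicate a single
#' dominant conformation.
#'
#' @inheritParams mfe_fold
#' @return non-negative scalar
#' @export
ensemble_diversity <- function(sequence, temperature_c = 37,
                               backend = fold_backend()) {
  backend$ed(sequence, temperature_c)
}

#' Free energy of a given structure
#' @inheritParams mfe_fold
#' @param structure dot-bracket string, same length as `sequence`
#' @export
structure_energy <- function(sequence, structure, temperature_c = 37,
                             backend = fold_backend()) {
  backend$energy_of(sequence, structure, temperature_c)
}

#' Partner vector from a dot-bracket string
#' @param structure dot-bracket string
#' @return integer vector; `pairs[i]` is the 1-based partner of i or NA
#' @export
pairs_from_dotbracket <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pairs <- rep(NA_integer_, n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stk <- c(stk, i)
    else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced dot-bracket")
      j <- stk[length(stk)]; stk <- stk[-length(stk)]
      pairs[i] <- j; pairs[j] <- i
    } else if (ch[i] != ".") stop("invalid dot-bracket character: ", ch[i])
  }
  if (length(stk)) stop("unbalanced dot-bracket")
  pairs
}

#' Dot-bracket string from a partner vector
#' @param pairs integer partner vector (NA = unpaired); crossing pairs are
#'   rejected
#' @return dot-bracket string
#' @export
dotbracket_from_pairs <- function(pairs) {
  n <- length(pairs)
  ch <- rep(".", n)
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (!is.na(j) && j > i) {
      if (pairs[j] != i) stop("partner vector is not an involution")
      ch[i] <- "("; ch[j] <- ")"
    }
  }
  db <- paste(ch, collapse = "")
  pb <- tryCatch(pairs_from_dotbracket(db), error = function(e) NULL)
  if (is.null(pb) || !identical(is.na(pb), is.na(pairs)) ||
      !all(pb[!is.na(pb)] == pairs[!is.na(pairs)]))
    stop("pair set contains crossing (pseudoknotted) pairs")
  db
}
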