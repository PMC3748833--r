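#' RNA sequence objects
#'
#' An `rna_sequence` is a validated nucleotide string over the alphabet
#' A/C/G/U with a 1-based indexing convention (`s_1 ... s_n`) used by every
#' part of the engine. `T` is accepted on input and normalized to `U`;
#' lowercase is accepted and upcased.
#'
#' @param x A single character string of nucleotides, or a character vector
#'   of single residues.
#' @param name Free-text identifier for the sequence.
#' @return An object of class `rna_sequence`: a list with elements
#'   `residues` (character vector of single bases), `codes` (integer codes
#'   A=1, C=2, G=3, U=4), `name`, and `n` (length).
#' @examples
#' rna_sequence("GGGAAAUCCC", name = "hp")
#' rna_sequence("acgt")   # normalized to ACGU
#' @export
rna_sequence <- function(x, name = "seq") {
  if (is.character(x) && length(x) == 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  }
  if (length(x) < 1L) {
    stop("an RNA sequence must have length n >= 1", call. = FALSE)
  }
  res <- toupper(x)
  res[res == "T"] <- "U"
  bad <- which(!res %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue '%s' at position %d (alphabet is A/C/G/U, T accepted)",
                 x[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(
    list(residues = res,
         codes = match(res, c("A", "C", "G", "U")),
         name = as.character(name)[1L],
         n = length(res)),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (n = %d)\n", x$name, x$n))
  s <- paste(x$residues, collapse = "")
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat(s, "\n")
  invisible(x)
}

#' @export
as.character.rna_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' @export
length.rna_sequence <- function(x) x$n

# Coerce strings transparently so every user-facing function accepts either
# an rna_sequence or a plain string.
as_rna_sequence <- function(x, name = "seq") {
  if (inherits(x, "rna_sequence")) return(x)
  rna_sequence(x, name = name)
}

#' Seeded random RNA sequence generation
#'
#' Draws i.i.d. residues with P(G) = P(C) = `gc_bias`/2 and
#' P(A) = P(U) = (1 - `gc_bias`)/2. Reproducible for a fixed seed; the
#' caller's random-number state is left untouched.
#'
#' @param count Number of sequences.
#' @param length Length of each sequence (recycled to `count`).
#' @param gc_bias Probability that a residue is G or C, in \[0, 1\].
#' @param seed Integer seed.
#' @return A list of [rna_sequence] objects named `rnd_<seed>_<k>`.
#' @examples
#' random_sequences(3, 12, seed = 1)
#' @export
random_sequences <- function(count, length, gc_bias = 0.5, seed = 1L) {
  stopifnot(count >= 1, all(length >= 1), gc_bias >= 0, gc_bias <= 1)
  len <- rep_len(as.integer(length), count)
  p <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lapply(seq_len(count), function(k) {
    rna_sequence(sample(c("A", "C", "G", "U"), len[k], replace = TRUE, prob = p),
                 name = sprintf("rnd_%d_%d", seed, k))
  })
}
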