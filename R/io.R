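#' Read RNA sequences from a FASTA file
#'
#' Reads single- or multi-record FASTA through Biostrings, then validates
#' and normalizes residues for the engine: lowercase is upcased, `T`
#' becomes `U`, anything outside A/C/G/U/T is a parse error naming the
#' record and position.
#'
#' @param path Path to a FASTA file.
#' @return A list of [rna_sequence] objects, named by FASTA headers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("%s: not a readable FASTA file (%s)",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) stop(path, ": empty FASTA file", call. = FALSE)
  out <- lapply(seq_along(set), function(k) {
    nm <- strsplit(names(set)[k], "[[:space:]]+")[[1L]][1L]
    chars <- strsplit(as.character(set[[k]]), "", fixed = TRUE)[[1L]]
    up <- toupper(chars)
    bad <- which(!up %in% c("A", "C", "G", "U", "T"))
    if (length(bad) > 0L) {
      stop(sprintf("%s: record '%s': illegal character '%s' at position %d",
                   path, nm, chars[bad[1L]], bad[1L]), call. = FALSE)
    }
    rna_sequence(chars, name = nm)
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Write a single FASTA record
#'
#' @param seq An [rna_sequence].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path, width = 60L) {
  s <- as_rna_sequence(seq)
  txt <- as.character(s)
  starts <- seq(1L, s$n, by = width)
  lines <- substring(txt, starts, pmin(starts + width - 1L, s$n))
  writeLines(c(paste0(">", s$name), lines), path)
  invisible(path)
}

#' Read and write CT (connect table) structure files
#'
#' The CT dialect written here is the classic 6-column layout. The header
#' line is `<length> ENERGY = <kcal> <name>` (the energy clause is omitted
#' when no energy is supplied); each of the following `n` rows is
#' `index base prev next partner index` where `prev`/`next` are the 5' and
#' 3' neighbor indices (0 at the ends) and `partner` is the pairing
#' partner or 0. Indices are 1-based and contiguous, and the partner
#' relation must be symmetric — a violation is a parse error naming the
#' row. `read_ct(write_ct(...))` reproduces the sequence and pair set
#' exactly.
#'
#' @param seq An [rna_sequence].
#' @param structure A [secondary_structure] valid for `seq`.
#' @param energy Optional energy in kcal/mol for the header.
#' @param path File path.
#' @return `write_ct()` returns `path` invisibly; `read_ct()` returns a
#'   list with elements `seq` and `structure` (and `energy`, `NA` if
#'   absent).
#' @export
write_ct <- function(seq, structure, path, energy = NULL) {
  s <- as_rna_sequence(seq)
  stopifnot(inherits(structure, "secondary_structure"), structure$n == s$n)
  partner <- integer(s$n)
  if (nrow(structure$pairs) > 0L) {
    partner[structure$pairs[, 1L]] <- structure$pairs[, 2L]
    partner[structure$pairs[, 2L]] <- structure$pairs[, 1L]
  }
  header <- if (is.null(energy)) {
    sprintf("%d %s", s$n, s$name)
  } else {
    sprintf("%d ENERGY = %.2f %s", s$n, energy, s$name)
  }
  rows <- sprintf("%d %s %d %d %d %d",
                  seq_len(s$n), s$residues,
                  seq_len(s$n) - 1L,
                  ifelse(seq_len(s$n) == s$n, 0L, seq_len(s$n) + 1L),
                  partner, seq_len(s$n))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @param path Path to a CT file.
#' @rdname write_ct
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("CT file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 1L) stop(path, ": empty CT file", call. = FALSE)
  head_toks <- strsplit(trimws(raw[1L]), "[[:space:]]+")[[1L]]
  n <- suppressWarnings(as.integer(head_toks[1L]))
  if (is.na(n) || n < 1L) stop(path, ":1: CT header must start with the length", call. = FALSE)
  energy <- NA_real_
  name <- "ct"
  if (length(head_toks) >= 4L && identical(head_toks[2L], "ENERGY") && identical(head_toks[3L], "=")) {
    energy <- suppressWarnings(as.numeric(head_toks[4L]))
    if (length(head_toks) >= 5L) name <- paste(head_toks[-(1:4)], collapse = " ")
  } else if (length(head_toks) >= 2L) {
    name <- paste(head_toks[-1L], collapse = " ")
  }
  if (length(raw) < n + 1L) {
    stop(sprintf("%s: CT file truncated: header says %d rows, found %d", path, n,
                 length(raw) - 1L), call. = FALSE)
  }
  bases <- character(n)
  partner <- integer(n)
  for (r in seq_len(n)) {
    toks <- strsplit(trimws(raw[r + 1L]), "[[:space:]]+")[[1L]]
    if (length(toks) < 6L) stop(sprintf("%s:%d: CT rows need 6 columns", path, r + 1L), call. = FALSE)
    idx <- suppressWarnings(as.integer(toks[1L]))
    if (is.na(idx) || idx != r) {
      stop(sprintf("%s:%d: CT indices must be contiguous (expected %d, found '%s')",
                   path, r + 1L, r, toks[1L]), call. = FALSE)
    }
    bases[r] <- toks[2L]
    pr <- suppressWarnings(as.integer(toks[5L]))
    if (is.na(pr) || pr < 0L || pr > n) {
      stop(sprintf("%s:%d: bad partner index '%s'", path, r + 1L, toks[5L]), call. = FALSE)
    }
    partner[r] <- pr
  }
  for (r in seq_len(n)) {
    if (partner[r] > 0L && partner[partner[r]] != r) {
      stop(sprintf("%s:%d: partner relation is not symmetric (%d -> %d -> %d)",
                   path, r + 1L, r, partner[r], partner[partner[r]]), call. = FALSE)
    }
    if (partner[r] == r) stop(sprintf("%s:%d: position paired with itself", path, r + 1L),
                              call. = FALSE)
  }
  i <- which(partner > seq_len(n))
  pairs <- cbind(i, partner[i])
  list(seq = rna_sequence(bases, name = name),
       structure = secondary_structure(pairs, n = n),
       energy = energy)
}
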