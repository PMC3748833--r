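#' RNA secondary structures
#'
#' A `secondary_structure` is a set of nested base pairs on a sequence of
#' length `n`: each position occurs in at most one pair and no two pairs
#' cross (pseudoknots are excluded by construction). Pairs are stored as a
#' two-column integer matrix with `i < j`, sorted by `i`.
#'
#' @param pairs A two-column matrix (or data frame) of pair positions, or
#'   `NULL`/empty for the open structure.
#' @param n Sequence length.
#' @return An object of class `secondary_structure`.
#' @examples
#' secondary_structure(rbind(c(1, 10), c(2, 9)), n = 10)
#' secondary_structure(NULL, n = 5)   # the empty structure
#' @export
secondary_structure <- function(pairs, n) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("pairs must have two columns (i, j)", call. = FALSE)
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L) || any(pairs > n)) {
      stop("pair positions must lie in 1..n", call. = FALSE)
    }
    if (any(pairs[, 1L] >= pairs[, 2L])) stop("pairs must satisfy i < j", call. = FALSE)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    pos <- c(pairs)
    if (anyDuplicated(pos)) {
      d <- pos[duplicated(pos)][1L]
      stop(sprintf("position %d occurs in more than one pair", d), call. = FALSE)
    }
    cr <- find_crossing(pairs)
    if (!is.null(cr)) {
      stop(sprintf("pairs (%d,%d) and (%d,%d) cross (pseudoknots are not allowed)",
                   cr[1L], cr[2L], cr[3L], cr[4L]), call. = FALSE)
    }
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(pairs = pairs, n = n), class = "secondary_structure")
}

# Returns c(i, j, k, l) for the first crossing pair of pairs, or NULL.
# pairs must be sorted by i.
find_crossing <- function(pairs) {
  m <- nrow(pairs)
  if (m < 2L) return(NULL)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      i <- pairs[a, 1L]; j <- pairs[a, 2L]
      k <- pairs[b, 1L]; l <- pairs[b, 2L]
      if (k > j) break              # sorted by i: no later pair can cross (i,j)
      if (k > i && k < j && l > j) return(c(i, j, k, l))
    }
  }
  NULL
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> n = %d, %d pair(s)\n", x$n, nrow(x$pairs)))
  if (x$n <= 120) cat(to_dotbracket(x), "\n")
  invisible(x)
}

#' @export
format.secondary_structure <- function(x, ...) to_dotbracket(x)

n_pairs <- function(structure) nrow(structure$pairs)

# Set-of-pairs equality irrespective of storage order.
same_pairs <- function(a, b) {
  identical(a$n, b$n) && nrow(a$pairs) == nrow(b$pairs) &&
    all(a$pairs == b$pairs)
}

#' Dot-bracket notation
#'
#' `to_dotbracket()` renders a nested structure with `(` at the 5' and `)`
#' at the 3' position of each pair and `.` elsewhere; only one bracket tier
#' is ever needed because structures are nested by construction.
#' `from_dotbracket()` parses a well-formed string back; an unbalanced
#' string is a parse error reporting the offending position.
#'
#' @param structure A [secondary_structure].
#' @param x A dot-bracket string.
#' @return A string, or a [secondary_structure].
#' @examples
#' to_dotbracket(secondary_structure(cbind(1, 5), 5))  # "(...)"
#' from_dotbracket("((...))")
#' @export
to_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  chars <- rep(".", structure$n)
  chars[structure$pairs[, 1L]] <- "("
  chars[structure$pairs[, 2L]] <- ")"
  paste(chars, collapse = "")
}

#' @rdname to_dotbracket
#' @export
from_dotbracket <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at position %d in dot-bracket string",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (length(open) == 0L) {
        stop(sprintf("unbalanced ')' at position %d", k), call. = FALSE)
      }
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) {
    stop(sprintf("unbalanced '(' at position %d (unclosed at end of string)",
                 open[length(open)]), call. = FALSE)
  }
  secondary_structure(pairs, n = length(chars))
}
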