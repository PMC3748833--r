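#' Folding constraints
#'
#' Hard constraints on the folding search space: `forced` pairs must appear
#' in every reported structure, `prohibited` pairs may never appear, and
#' `single` positions must stay unpaired. Forced pairs must be mutually
#' non-crossing and position-disjoint, disjoint from the prohibited set,
#' and must not touch a forced-single position. Satisfaction is hard:
#' conflicting DP cells are set to the forbidden sentinel, so every
#' returned structure satisfies the constraints structurally (never via
#' energy bonuses).
#'
#' @param forced Two-column matrix of pairs `(i, j)` that must be present.
#' @param prohibited Two-column matrix of pairs that must be absent.
#' @param single Integer vector of positions forced single-stranded.
#' @return An object of class `fold_constraints`.
#' @examples
#' fold_constraints(forced = cbind(2, 9), single = c(5))
#' @export
fold_constraints <- function(forced = NULL, prohibited = NULL, single = integer(0)) {
  as_pairs <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(integer(0), ncol = 2L))
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    if (ncol(x) != 2L) stop("constraint pairs must have two columns", call. = FALSE)
    if (any(x[, 1L] >= x[, 2L])) stop("constraint pairs must satisfy i < j", call. = FALSE)
    x[order(x[, 1L]), , drop = FALSE]
  }
  forced <- as_pairs(forced)
  prohibited <- as_pairs(prohibited)
  single <- sort(unique(as.integer(single)))
  if (nrow(forced) > 0L) {
    if (anyDuplicated(c(forced))) {
      stop("forced pairs must be position-disjoint", call. = FALSE)
    }
    cr <- find_crossing(forced)
    if (!is.null(cr)) {
      stop(sprintf("forced pairs (%d,%d) and (%d,%d) cross", cr[1L], cr[2L], cr[3L], cr[4L]),
           call. = FALSE)
    }
    if (any(c(forced) %in% single)) {
      stop("a forced-single position appears in a forced pair", call. = FALSE)
    }
    key <- function(m) paste(m[, 1L], m[, 2L])
    overlap <- intersect(key(forced), key(prohibited))
    if (length(overlap) > 0L) {
      stop("pair ", overlap[1L], " is both forced and prohibited", call. = FALSE)
    }
  }
  structure(list(forced = forced, prohibited = prohibited, single = single),
            class = "fold_constraints")
}

#' @export
print.fold_constraints <- function(x, ...) {
  cat(sprintf("<fold_constraints> %d forced pair(s), %d prohibited, %d forced single\n",
              nrow(x$forced), nrow(x$prohibited), length(x$single)))
  invisible(x)
}

empty_constraints <- function() fold_constraints()

#' Read a folding constraint file
#'
#' Plain-text dialect: one directive per line — `F i j` forces pair
#' `(i, j)`, `P i j` prohibits it, `S i` forces position `i`
#' single-stranded; `#` starts a comment.
#'
#' @param path Path to a constraint file.
#' @return A [fold_constraints] object.
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("constraint file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  forced <- prohibited <- matrix(integer(0), ncol = 2L)
  single <- integer(0)
  for (ln in seq_along(raw)) {
    txt <- sub("#.*$", "", raw[ln])
    toks <- strsplit(trimws(txt), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) next
    bad <- function() stop(sprintf("%s:%d: malformed constraint line '%s'", path, ln, trimws(txt)),
                           call. = FALSE)
    ints <- suppressWarnings(as.integer(toks[-1L]))
    if (anyNA(ints)) bad()
    if (toks[1L] == "F" && length(ints) == 2L) {
      forced <- rbind(forced, ints)
    } else if (toks[1L] == "P" && length(ints) == 2L) {
      prohibited <- rbind(prohibited, ints)
    } else if (toks[1L] == "S" && length(ints) == 1L) {
      single <- c(single, ints)
    } else bad()
  }
  fold_constraints(forced = forced, prohibited = prohibited, single = single)
}

#' SHAPE reactivity profiles
#'
#' Per-nucleotide SHAPE reactivities mapped to pseudo-energies
#' `m * ln(1 + r) + b` (kcal/mol), added once for each paired position at
#' pair-formation time during the minimization. Missing reactivities (`NA`,
#' or `-999` in files) contribute zero pseudo-energy.
#'
#' @param reactivity Numeric vector of non-negative reactivities, `NA` for
#'   missing.
#' @param slope,intercept The pseudo-energy map parameters `m` and `b`
#'   (kcal/mol); no defaults are assumed — both must be chosen by the user.
#' @return An object of class `shape_profile`.
#' @export
shape_profile <- function(reactivity, slope, intercept) {
  reactivity <- as.numeric(reactivity)
  if (any(reactivity < 0, na.rm = TRUE)) {
    stop("SHAPE reactivities must be non-negative (use NA or -999 for missing)",
         call. = FALSE)
  }
  structure(list(reactivity = reactivity,
                 slope = as.numeric(slope), intercept = as.numeric(intercept)),
            class = "shape_profile")
}

#' Read a SHAPE reactivity file
#'
#' Two whitespace-separated columns: 1-based position and reactivity;
#' `-999` denotes a missing value (a common convention). Unlisted positions
#' are missing.
#'
#' @param path Path to the file.
#' @param n Sequence length (profile length).
#' @inheritParams shape_profile
#' @return A [shape_profile] object.
#' @export
read_shape <- function(path, n, slope, intercept) {
  if (!file.exists(path)) stop("SHAPE file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  r <- rep(NA_real_, n)
  for (ln in seq_along(raw)) {
    txt <- sub("#.*$", "", raw[ln])
    toks <- strsplit(trimws(txt), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) next
    if (length(toks) != 2L) {
      stop(sprintf("%s:%d: SHAPE lines are: position reactivity", path, ln), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(toks[1L]))
    val <- suppressWarnings(as.numeric(toks[2L]))
    if (is.na(pos) || is.na(val) || pos < 1L || pos > n) {
      stop(sprintf("%s:%d: bad SHAPE entry '%s %s'", path, ln, toks[1L], toks[2L]),
           call. = FALSE)
    }
    r[pos] <- if (val == -999) NA_real_ else val
  }
  shape_profile(r, slope = slope, intercept = intercept)
}

#' Per-position SHAPE pseudo-energies
#'
#' Converts a reactivity profile into the per-position pseudo-energy vector
#' `m * ln(1 + r) + b` the engine adds for each paired position. Missing
#' reactivities map to zero.
#'
#' @param seq An [rna_sequence] (or string).
#' @param shape A [shape_profile] whose length matches the sequence.
#' @return Numeric vector of pseudo-energies in kcal/mol, length `n`.
#' @export
apply_shape <- function(seq, shape) {
  s <- as_rna_sequence(seq)
  if (is.null(shape)) return(numeric(s$n))
  stopifnot(inherits(shape, "shape_profile"))
  if (length(shape$reactivity) != s$n) {
    stop(sprintf("SHAPE profile length %d does not match sequence length %d",
                 length(shape$reactivity), s$n), call. = FALSE)
  }
  e <- shape$slope * log1p(shape$reactivity) + shape$intercept
  e[is.na(shape$reactivity)] <- 0
  e
}

shape_centi <- function(seq, shape) {
  to_centi(apply_shape(seq, shape))
}
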