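# Internal: candidate-pair logical matrix plus the must-pair vector
# implied by forced pairs. All constraint handling is hard (cells outside
# the candidate set are forbidden in the DP).
candidate_matrix <- function(seq, params, constraints = NULL, prefilter = FALSE) {
  s <- as_rna_sequence(seq)
  cons <- constraints %||% empty_constraints()
  n <- s$n
  adm <- pair_admissible_code(params)
  admissible <- matrix(FALSE, n, n)
  if (n >= 2L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    admissible[idx] <- adm[cbind(s$codes[idx[, 1L]], s$codes[idx[, 2L]])] > 0L
  }
  cand <- admissible
  if (n >= 2L) {
    loop_ok <- outer(seq_len(n), seq_len(n), function(i, j) j - i - 1L >= params$h)
    cand <- cand & loop_ok
  }
  # forced pairs must be admissible at sequence level and satisfy h
  if (nrow(cons$forced) > 0L) {
    for (r in seq_len(nrow(cons$forced))) {
      a <- cons$forced[r, 1L]; b <- cons$forced[r, 2L]
      if (b > n) stop(sprintf("forced pair (%d,%d) outside sequence of length %d", a, b, n),
                      call. = FALSE)
      if (adm[s$codes[a], s$codes[b]] == 0L || b - a - 1L < params$h) {
        stop(sprintf("forced pair (%d,%d) is not admissible for this sequence (%s-%s, loop %d, h = %d)",
                     a, b, s$residues[a], s$residues[b], b - a - 1L, params$h), call. = FALSE)
      }
    }
  }
  if (nrow(cons$prohibited) > 0L) {
    keep <- cons$prohibited[, 2L] <= n
    cand[cons$prohibited[keep, , drop = FALSE]] <- FALSE
  }
  if (length(cons$single) > 0L) {
    pos <- cons$single[cons$single <= n]
    cand[pos, ] <- FALSE
    cand[, pos] <- FALSE
  }
  if (prefilter && n >= 2L) {
    # keep (i,j) only if a stacked neighbor pair is admissible at sequence
    # level (before constraints): inner (i+1, j-1) or outer (i-1, j+1)
    inner <- matrix(FALSE, n, n)
    outer_ok <- matrix(FALSE, n, n)
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      ii <- idx[, 1L]; jj <- idx[, 2L]
      has_inner <- (jj - ii >= 3L) & adm[cbind(s$codes[pmin(ii + 1L, n)], s$codes[pmax(jj - 1L, 1L)])] > 0L
      has_outer <- (ii > 1L) & (jj < n)
      has_outer[has_outer] <- adm[cbind(s$codes[ii[has_outer] - 1L], s$codes[jj[has_outer] + 1L])] > 0L
      cand[idx[!(has_inner | has_outer), , drop = FALSE]] <- FALSE
    }
  }
  must_pair <- rep(FALSE, n)
  if (nrow(cons$forced) > 0L) {
    # forced pairs always retained; every conflicting cell is forbidden
    for (r in seq_len(nrow(cons$forced))) {
      a <- cons$forced[r, 1L]; b <- cons$forced[r, 2L]
      cand[a, ] <- FALSE; cand[, a] <- FALSE
      cand[b, ] <- FALSE; cand[, b] <- FALSE
      ij <- which(cand, arr.ind = TRUE)
      if (nrow(ij) > 0L) {
        i <- ij[, 1L]; j <- ij[, 2L]
        crosses <- (i < a & a < j & j < b) | (a < i & i < b & b < j)
        cand[ij[crosses, , drop = FALSE]] <- FALSE
      }
      cand[a, b] <- TRUE
      must_pair[c(a, b)] <- TRUE
    }
  }
  list(cand = cand, must_pair = must_pair, seq = s)
}

#' Candidate base pairs
#'
#' Enumerates the base pairs the engine will consider: admissible pair
#' types whose hairpin bound `j - i - 1 >= h` holds, minus prohibited
#' pairs and pairs touching forced-single positions. With
#' `prefilter = TRUE`, additionally drops any pair lacking at least one
#' admissible stacked neighbor pair — `(i+1, j-1)` or `(i-1, j+1)` at
#' sequence level, before constraints — while always retaining forced
#' pairs. This mirrors the lonely-pair prefilter that distinguishes
#' folding programs.
#'
#' @param seq An [rna_sequence] (or string).
#' @param params An `nntm_params` object.
#' @param constraints A [fold_constraints] object or `NULL`.
#' @param prefilter Apply the neighbor-pair prefilter?
#' @return A tibble with integer columns `i`, `j`, sorted by `(i, j)`.
#' @examples
#' candidate_pairs("ACGCGU", toy_parameters())
#' @export
candidate_pairs <- function(seq, params, constraints = NULL, prefilter = FALSE) {
  cm <- candidate_matrix(seq, params, constraints, prefilter)
  idx <- which(cm$cand, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
}

#' Bounded internal-loop enumeration window
#'
#' Iterates the inner pairs `(ip, jp)` considered for an internal loop or
#' bulge closed by `(i, j)`: all `i < ip < jp < j` with total unpaired
#' length `(ip - i - 1) + (j - jp - 1)` between 1 and `max_span`. The
#' both-sides-zero case (a stack) is excluded.
#'
#' @param i,j Closing pair positions.
#' @param max_span Maximum total unpaired length (default 30).
#' @return Integer matrix with columns `ip`, `jp`.
#' @export
internal_loop_window <- function(i, j, max_span = 30L) {
  i <- as.integer(i); j <- as.integer(j); max_span <- as.integer(max_span)
  stopifnot(max_span >= 0L, i < j)
  out <- list()
  for (ip in (i + 1L):max(i + 1L, j - 2L)) {
    if (ip > j - 2L) break
    l1 <- ip - i - 1L
    if (l1 > max_span) break
    for (jp in (j - 1L):(ip + 1L)) {
      if (jp <= ip) break
      l2 <- j - jp - 1L
      if (l1 + l2 > max_span) break
      if (l1 == 0L && l2 == 0L) next
      out[[length(out) + 1L]] <- c(ip, jp)
    }
  }
  m <- if (length(out) == 0L) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
  dimnames(m) <- list(NULL, c("ip", "jp"))
  m
}

#' Fill the dynamic-programming tables
#'
#' Computes the minimization tables of the free-energy recursion in
#' anti-diagonal order: all cells with subsequence length
#' `k = j - i + 1` are mutually independent, and diagonals are processed
#' from `k = 1` to `k = n`. `V(i, j)` is the minimum energy over structures
#' on `s_i..s_j` in which `(i, j)` pairs; `WM`/`WM1` hold multiloop
#' fragment scores; `W(j)` is the minimum energy over all structures on
#' `s_1..s_j`, so `W(n)` is the MFE. Cell values are exact fixed-decimal
#' integers (0.01 kcal/mol); the forbidden sentinel marks impossible
#' cells. Results are bit-identical for any `workers` value — the argument
#' only permutes the order in which the independent cells of one diagonal
#' are visited, emulating a wavefront schedule with that many workers.
#'
#' @inheritParams candidate_pairs
#' @param dangle Helix-end mode for multiloop and exterior branches:
#'   `"none"`, `"dangles"` or `"mismatch"`.
#' @param max_internal_span Internal-loop enumeration bound (total
#'   unpaired length).
#' @param shape A [shape_profile] or `NULL`.
#' @param workers Wavefront worker count (scheduling only; see above).
#' @return An object of class `dp_tables`: centi-kcal integer matrices
#'   `V`, `WM`, `WM1`, the vector `W` (length `n + 1`; `W[1]` is `W(0) = 0`
#'   for the empty prefix, so `W[n + 1]` is the MFE), plus the fold context
#'   needed for traceback.
#' @seealso [fold_traceback()], [rna_fold()]
#' @export
fill_tables <- function(seq, params, constraints = NULL,
                        dangle = c("none", "dangles", "mismatch"),
                        prefilter = FALSE, max_internal_span = 30L,
                        shape = NULL, workers = 1L) {
  dangle <- dangle_mode_code(dangle)
  mode_code <- match(dangle, c("none", "dangles", "mismatch")) - 1L
  cm <- candidate_matrix(seq, params, constraints, prefilter)
  s <- cm$seq
  sh <- shape_centi(s, shape)
  res <- cpp_fill(s$codes, cm$cand, cm$must_pair, sh,
                  params, pair_admissible_code(params), PAIR_CODE,
                  mode_code, as.integer(max_internal_span), as.integer(workers))
  structure(
    list(V = res$V, WM = res$WM, WM1 = res$WM1, W = res$W, n = s$n,
         seq = s, params = params,
         constraints = constraints %||% empty_constraints(),
         cand = cm$cand, must_pair = cm$must_pair, shape_centi = sh,
         dangle = dangle, mode_code = mode_code,
         prefilter = prefilter,
         max_internal_span = as.integer(max_internal_span),
         workers = as.integer(workers)),
    class = "dp_tables"
  )
}

#' @export
print.dp_tables <- function(x, ...) {
  cat(sprintf("<dp_tables> n = %d, dangle = %s, prefilter = %s, MFE = %s kcal/mol\n",
              x$n, x$dangle, x$prefilter, format(table_mfe(x))))
  invisible(x)
}

# W is returned with length n + 1: W[1] is W(0) = 0 for the empty prefix,
# W[j + 1] is W(j), so the MFE is W[n + 1].
table_mfe <- function(tables) {
  w <- tables$W[tables$n + 1L]
  if (w >= ENERGY_INF) Inf else from_centi(w)
}

#' Minimum free energy of a sequence
#'
#' Convenience wrapper: fills the tables and returns `W(n)` in kcal/mol.
#'
#' @inheritParams fill_tables
#' @return A single numeric energy.
#' @examples
#' mfe("GGGAAAUCCC", toy_parameters())
#' @export
mfe <- function(seq, params, constraints = NULL,
                dangle = c("none", "dangles", "mismatch"),
                prefilter = FALSE, max_internal_span = 30L,
                shape = NULL, workers = 1L) {
  table_mfe(fill_tables(seq, params, constraints, dangle, prefilter,
                        max_internal_span, shape, workers))
}

#' Deterministic traceback
#'
#' Recovers one optimal structure from filled tables by re-deriving the
#' minimizing case of each cell (no pointers are stored). Ties are broken
#' in a fixed documented order — hairpin, then stack, then internal/bulge
#' in lexicographic `(ip, jp)` order, then multiloop with the smallest
#' split point; in `W` and the multiloop fragments, "position unpaired"
#' is preferred before "pair here", and the smallest 5' partner wins — so
#' the output is a deterministic function of the fold inputs. The returned
#' structure's independently re-scored energy equals `W(n)` exactly; the
#' decomposition comes from [score_structure()], which never consults the
#' DP tables.
#'
#' @param tables A `dp_tables` object from [fill_tables()].
#' @return A list with elements `structure` (a [secondary_structure]) and
#'   `decomposition` (an energy decomposition; see [score_structure()]).
#' @export
fold_traceback <- function(tables) {
  stopifnot(inherits(tables, "dp_tables"))
  pairs <- cpp_traceback(tables$V, tables$WM, tables$WM1, tables$W,
                         tables$seq$codes, tables$cand, tables$must_pair,
                         tables$shape_centi, tables$params,
                         pair_admissible_code(tables$params), PAIR_CODE,
                         tables$mode_code, tables$max_internal_span)
  st <- secondary_structure(pairs, n = tables$n)
  dec <- score_structure(tables$seq, st, tables$params,
                         dangle = tables$dangle,
                         shape = NULL, shape_centi = tables$shape_centi)
  list(structure = st, decomposition = dec)
}

#' Fold an RNA sequence
#'
#' End-to-end minimum-free-energy prediction: candidate pairs, wavefront
#' table fill, deterministic traceback and an independent loop-by-loop
#' re-score of the returned structure.
#'
#' @inheritParams fill_tables
#' @param keep_tables Keep the DP tables in the result?
#' @return An object of class `rna_fold` with elements `seq`, `mfe`
#'   (kcal/mol), `structure`, `dotbracket`, `decomposition` and the mode
#'   flags; with `keep_tables = TRUE` also `tables`.
#' @examples
#' f <- rna_fold("GGGCGCAAAAGCGCCC", toy_parameters())
#' f$mfe
#' f$dotbracket
#' @export
rna_fold <- function(seq, params, constraints = NULL,
                     dangle = c("none", "dangles", "mismatch"),
                     prefilter = FALSE, max_internal_span = 30L,
                     shape = NULL, workers = 1L, keep_tables = FALSE) {
  tables <- fill_tables(seq, params, constraints, dangle, prefilter,
                        max_internal_span, shape, workers)
  tb <- fold_traceback(tables)
  out <- list(seq = tables$seq,
              mfe = table_mfe(tables),
              structure = tb$structure,
              dotbracket = to_dotbracket(tb$structure),
              decomposition = tb$decomposition,
              dangle = tables$dangle, prefilter = prefilter,
              max_internal_span = tables$max_internal_span,
              constraints = tables$constraints,
              workers = tables$workers)
  if (keep_tables) out$tables <- tables
  structure(out, class = "rna_fold")
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(sprintf("<rna_fold> %s (n = %d)\n", x$seq$name, x$seq$n))
  if (x$seq$n <= 120) {
    cat(as.character(x$seq), "\n")
    cat(x$dotbracket, "\n")
  }
  cat(sprintf("MFE = %.2f kcal/mol (%d pairs; dangle = %s)\n",
              x$mfe, n_pairs(x$structure), x$dangle))
  invisible(x)
}
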