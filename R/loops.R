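# Forbidden sentinel: 1e8 centi-kcal (1,000,000 kcal/mol), strictly larger
# than any achievable structure energy, saturating under addition.
ENERGY_INF <- 100000000L

sat_add <- function(a, b) {
  if (a >= ENERGY_INF || b >= ENERGY_INF) ENERGY_INF else a + b
}

# Logarithmic extrapolation beyond l_max, rounded to the nearest 0.01
# kcal/mol with floor(x + 0.5) so the R and C++ paths agree bit-for-bit.
init_lookup_centi <- function(tab, len, params) {
  if (len <= params$l_max) return(tab[len])
  tab[params$l_max] +
    as.integer(floor(params$extrapolation * log(len / params$l_max) + 0.5))
}

au_pen_centi <- function(pt, params) {
  if (pt == 3L || pt == 4L) 0L else params$terminal_au  # CG/GC exempt
}

dangle_mode_code <- function(mode) {
  match.arg(mode, c("none", "dangles", "mismatch"))
}

hairpin_centi <- function(codes, i, j, params, adm) {
  pt <- adm[codes[i], codes[j]]
  len <- j - i - 1L
  if (pt == 0L || len < params$h) return(ENERGY_INF)
  e <- init_lookup_centi(params$hairpin_init, len, params)
  if (len >= 2L) e <- e + params$tmismatch_h[pt, codes[i + 1L], codes[j - 1L]]
  e + au_pen_centi(pt, params)
}

stack_centi <- function(codes, i, j, params, adm) {
  if (j - i < 3L) return(ENERGY_INF)
  pt1 <- adm[codes[i], codes[j]]
  pt2 <- adm[codes[i + 1L], codes[j - 1L]]
  if (pt1 == 0L || pt2 == 0L) return(ENERGY_INF)
  params$stack[pt1, pt2]
}

internal_centi <- function(codes, i, j, ip, jp, params, adm) {
  pt1 <- adm[codes[i], codes[j]]
  pt2 <- adm[codes[ip], codes[jp]]
  if (pt1 == 0L || pt2 == 0L) return(ENERGY_INF)
  l1 <- ip - i - 1L
  l2 <- j - jp - 1L
  if (l1 == 0L && l2 == 0L) {
    stop("zero unpaired bases on both sides is a stack; use eval_stack", call. = FALSE)
  }
  ltot <- l1 + l2
  if (l1 == 0L || l2 == 0L) {
    e <- init_lookup_centi(params$bulge_init, ltot, params)
    if (ltot == 1L) {
      # helix effectively continues across a single-base bulge
      e <- e + params$stack[pt1, pt2]
    } else {
      e <- e + au_pen_centi(pt1, params) + au_pen_centi(pt2, params)
    }
    return(e)
  }
  e <- init_lookup_centi(params$internal_init, ltot, params)
  e <- e + min(params$asym_coeff * abs(l1 - l2), params$asym_max)
  e <- e + params$tmismatch_i[pt1, codes[i + 1L], codes[j - 1L]]
  ptr <- PAIR_CODE[codes[jp], codes[ip]]  # inner pair seen from the loop side
  e + params$tmismatch_i[ptr, codes[jp + 1L], codes[ip - 1L]]
}

multiloop_centi <- function(branches, unpaired, params) {
  params$ml_a + params$ml_b * branches + params$ml_c * unpaired
}

# End contribution of a branch pair (i, j) facing its enclosing multiloop
# or the exterior loop. Convention: the pair is viewed from outside as
# (s_j, s_i); in dangle mode the 5' flank s[i-1] and 3' flank s[j+1]
# contribute min(0, d5, d3, d5 + d3) over the flanks that exist in the
# sequence; in mismatch mode both flanks are required for the single
# tmismatch_i lookup, otherwise the term is omitted. Flank availability is
# by sequence bounds only — pairing status of the flank is ignored
# (per-branch independence).
end_branch_centi <- function(codes, n, i, j, mode_code, params) {
  if (mode_code == 0L) return(0L)
  rev <- PAIR_CODE[codes[j], codes[i]]
  if (rev == 0L) return(0L)
  if (mode_code == 1L) {
    best <- 0L
    d5 <- if (i > 1L) params$dangle5[rev, codes[i - 1L]] else NA_integer_
    d3 <- if (j < n) params$dangle3[rev, codes[j + 1L]] else NA_integer_
    if (!is.na(d5)) best <- min(best, d5)
    if (!is.na(d3)) best <- min(best, d3)
    if (!is.na(d5) && !is.na(d3)) best <- min(best, d5 + d3)
    return(best)
  }
  if (i > 1L && j < n) params$tmismatch_i[rev, codes[j + 1L], codes[i - 1L]] else 0L
}

# End contribution of a multiloop's closing pair (i, j), seen from inside
# the loop: 5' flank s[j-1], 3' flank s[i+1] (both always exist).
end_close_centi <- function(codes, i, j, mode_code, params) {
  if (mode_code == 0L) return(0L)
  pt <- PAIR_CODE[codes[i], codes[j]]
  if (pt == 0L) return(0L)
  if (mode_code == 1L) {
    d5 <- params$dangle5[pt, codes[j - 1L]]
    d3 <- params$dangle3[pt, codes[i + 1L]]
    return(min(0L, d5, d3, d5 + d3))
  }
  params$tmismatch_i[pt, codes[i + 1L], codes[j - 1L]]
}

centi_out <- function(e) if (e >= ENERGY_INF) Inf else from_centi(e)

#' Loop free-energy evaluators
#'
#' The elementary evaluators of the nearest-neighbor thermodynamic model.
#' Each returns an energy in kcal/mol, or `Inf` — the forbidden sentinel,
#' saturating under addition — when the requested loop cannot form
#' (inadmissible pair, hairpin shorter than `h`). Positions are 1-based.
#'
#' * `eval_hairpin(i, j)`: hairpin closed by `(i, j)`; initiation by loop
#'   length (log-extrapolated beyond `l_max`), terminal mismatch when at
#'   least two unpaired bases exist, and the terminal AU/GU penalty.
#' * `eval_stack(i, j)`: pair `(i+1, j-1)` stacked directly inside `(i, j)`.
#' * `eval_internal(i, j, ip, jp)`: internal loop or bulge closed by
#'   `(i, j)` and `(ip, jp)`. A one-sided loop is a bulge: length-1 bulges
#'   add the stacking term of the flanking pairs, longer bulges the AU/GU
#'   penalty for both closings. Two-sided loops add initiation by total
#'   length, the capped linear asymmetry penalty
#'   `min(asym_coeff * |l1 - l2|, asym_max)` and terminal mismatches at
#'   both closings. Both sides zero is a stack and raises an error.
#' * `multiloop_terms(branch_count, unpaired_count)`: the affine multiloop
#'   score `a + b * branch_count + c * unpaired_count` (the closing pair
#'   counts as a branch, so `branch_count >= 3` in a real multiloop).
#' * `end_contribution(pair, ...)`: helix-end energy for a pair bordering
#'   a multiloop or the exterior loop, under the selected `mode`: `"none"`
#'   gives 0; `"dangles"` gives the best (minimum, never positive) of the
#'   applicable 5'/3' dangling-end terms and their sum; `"mismatch"` gives
#'   a single terminal-mismatch lookup, omitted when a flanking base falls
#'   outside the sequence. `role = "closing"` applies the inside view used
#'   for a multiloop's closing pair.
#'
#' @param seq An [rna_sequence] (or string).
#' @param i,j,ip,jp 1-based positions with `i < ip < jp < j` where
#'   applicable.
#' @param params An `nntm_params` object.
#' @param branch_count,unpaired_count Multiloop branch and unpaired-base
#'   counts.
#' @param pair Length-2 integer vector `(i, j)`.
#' @param context `"external"` or `"multiloop"` (the energy rule is shared;
#'   the argument documents intent).
#' @param mode Helix-end mode: `"none"`, `"dangles"` or `"mismatch"`.
#' @param role `"branch"` or `"closing"`.
#' @return A numeric energy in kcal/mol (possibly `Inf`).
#' @examples
#' p <- toy_parameters()
#' eval_stack("CCGG", 1, 4, p)
#' eval_hairpin("GCGAAAGC", 2, 7, p)
#' multiloop_terms(3, 5, p)
#' @name loop_energies
NULL

#' @rdname loop_energies
#' @export
eval_hairpin <- function(seq, i, j, params) {
  s <- as_rna_sequence(seq)
  stopifnot(i >= 1, j <= s$n, i < j)
  centi_out(hairpin_centi(s$codes, as.integer(i), as.integer(j), params,
                          pair_admissible_code(params)))
}

#' @rdname loop_energies
#' @export
eval_stack <- function(seq, i, j, params) {
  s <- as_rna_sequence(seq)
  stopifnot(i >= 1, j <= s$n, i < j)
  centi_out(stack_centi(s$codes, as.integer(i), as.integer(j), params,
                        pair_admissible_code(params)))
}

#' @rdname loop_energies
#' @export
eval_internal <- function(seq, i, j, ip, jp, params) {
  s <- as_rna_sequence(seq)
  i <- as.integer(i); j <- as.integer(j); ip <- as.integer(ip); jp <- as.integer(jp)
  stopifnot(1 <= i, i < ip, ip < jp, jp < j, j <= s$n)
  centi_out(internal_centi(s$codes, i, j, ip, jp, params,
                           pair_admissible_code(params)))
}

#' @rdname loop_energies
#' @export
multiloop_terms <- function(branch_count, unpaired_count, params) {
  stopifnot(branch_count >= 0, unpaired_count >= 0)
  from_centi(multiloop_centi(as.integer(branch_count), as.integer(unpaired_count), params))
}

#' @rdname loop_energies
#' @export
end_contribution <- function(seq, pair, context = c("external", "multiloop"),
                             mode = c("none", "dangles", "mismatch"), params,
                             role = c("branch", "closing")) {
  s <- as_rna_sequence(seq)
  context <- match.arg(context)
  role <- match.arg(role)
  mode_code <- match(dangle_mode_code(mode), c("none", "dangles", "mismatch")) - 1L
  i <- as.integer(pair[1L]); j <- as.integer(pair[2L])
  stopifnot(1 <= i, i < j, j <= s$n)
  e <- if (role == "closing") {
    end_close_centi(s$codes, i, j, mode_code, params)
  } else {
    end_branch_centi(s$codes, s$n, i, j, mode_code, params)
  }
  from_centi(e)
}
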