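# Canonical orderings used by every table in the package.
PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
BASES <- c("A", "C", "G", "U")

# 4x4 map from (code_i, code_j) to pair type index 1..6, 0 where the two
# bases never form one of the six canonical pairs.
PAIR_CODE <- local({
  m <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  for (k in seq_along(PAIR_TYPES)) {
    p <- strsplit(PAIR_TYPES[k], "")[[1L]]
    m[p[1L], p[2L]] <- k
  }
  m
})

# Fixed-decimal representation: all energies are stored internally as
# integers in units of 0.01 kcal/mol so that ties and totals are exact.
to_centi <- function(x) as.integer(round(100 * x))
from_centi <- function(x) x / 100

#' Nearest-neighbor thermodynamic model parameters
#'
#' Container for every table and scalar of the nearest-neighbor
#' thermodynamic model (NNTM): stacking energies, loop initiation
#' penalties, terminal mismatches, dangling ends, the affine multiloop
#' score and assorted scalars. All energies are given in kcal/mol and are
#' stored internally in fixed decimal units of 0.01 kcal/mol, so every
#' energy the engine reports is exact to two decimals and ties are
#' reproducible.
#'
#' Tables are indexed by pair type in the fixed order AU, UA, CG, GC, GU,
#' UG and by base in the order A, C, G, U. `stack[p, q]` is the energy of
#' pair type `q` stacked directly inside pair type `p`. Mismatch arrays are
#' indexed `[closing pair, 5' unpaired base, 3' unpaired base]` where the
#' unpaired bases are the first inside position after `i` and the last
#' before `j` of the closing pair `(i, j)`.
#'
#' @param stack 6x6 numeric matrix of stacking energies (kcal/mol).
#' @param hairpin_init,bulge_init Numeric vectors of length `l_max`;
#'   initiation energy by loop length 1..`l_max`.
#' @param internal_init Numeric vector of length `l_max`; initiation by
#'   total unpaired length (entries below 2 are never consulted).
#' @param tmismatch_h,tmismatch_i 6x4x4 numeric arrays of terminal-mismatch
#'   energies for hairpin and internal contexts.
#' @param dangle5,dangle3 6x4 numeric matrices of dangling-end energies.
#' @param terminal_au Penalty for helix-terminal pairs other than CG/GC.
#' @param ml_a,ml_b,ml_c Affine multiloop score: offset, per-branch and
#'   per-unpaired-base terms (the closing pair counts as a branch).
#' @param h Minimum number of unpaired bases in a hairpin loop (default 3).
#' @param l_max Largest tabulated loop length; longer loops are
#'   extrapolated.
#' @param extrapolation Coefficient of the logarithmic long-loop
#'   extrapolation `init[l_max] + extrapolation * ln(len / l_max)`
#'   (kcal/mol); conventionally `1.75 * RT`.
#' @param rt Gas constant times temperature (kcal/mol), stored alongside
#'   the tables for reference.
#' @param asym_coeff,asym_max Internal-loop asymmetry penalty
#'   `min(asym_coeff * |l1 - l2|, asym_max)`.
#' @param allowed_pairs Character vector of admissible pair types, a subset
#'   of AU, UA, CG, GC, GU, UG.
#' @return An object of class `nntm_params`.
#' @seealso [toy_parameters()], [zero_parameters()], [read_parameters()]
#' @export
energy_parameters <- function(stack = matrix(0, 6, 6),
                              hairpin_init = numeric(30),
                              bulge_init = numeric(30),
                              internal_init = numeric(30),
                              tmismatch_h = array(0, c(6, 4, 4)),
                              tmismatch_i = array(0, c(6, 4, 4)),
                              dangle5 = matrix(0, 6, 4),
                              dangle3 = matrix(0, 6, 4),
                              terminal_au = 0,
                              ml_a = 0, ml_b = 0, ml_c = 0,
                              h = 3L,
                              l_max = 30L,
                              extrapolation = 0,
                              rt = 0.62,
                              asym_coeff = 0,
                              asym_max = 0,
                              allowed_pairs = PAIR_TYPES) {
  h <- as.integer(h); l_max <- as.integer(l_max)
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  if (l_max < max(h, 2L)) stop("l_max must be at least max(h, 2)", call. = FALSE)
  if (!all(allowed_pairs %in% PAIR_TYPES)) {
    stop("allowed_pairs must be a subset of ", paste(PAIR_TYPES, collapse = ", "), call. = FALSE)
  }
  chk <- function(x, dims, what) {
    if (!isTRUE(all.equal(dim(x) %||% length(x), dims, check.attributes = FALSE)) ||
        anyNA(x) || !all(is.finite(x))) {
      stop(sprintf("parameter table '%s' must be fully defined, finite, with dimensions %s",
                   what, paste(dims, collapse = "x")), call. = FALSE)
    }
  }
  chk(stack, c(6, 6), "stack")
  chk(hairpin_init, l_max, "hairpin_init")
  chk(bulge_init, l_max, "bulge_init")
  chk(internal_init, l_max, "internal_init")
  chk(tmismatch_h, c(6, 4, 4), "tmismatch_h")
  chk(tmismatch_i, c(6, 4, 4), "tmismatch_i")
  chk(dangle5, c(6, 4), "dangle5")
  chk(dangle3, c(6, 4), "dangle3")

  p <- list(
    stack = to_centi(stack),
    hairpin_init = to_centi(hairpin_init),
    bulge_init = to_centi(bulge_init),
    internal_init = to_centi(internal_init),
    tmismatch_h = to_centi(tmismatch_h),
    tmismatch_i = to_centi(tmismatch_i),
    dangle5 = to_centi(dangle5),
    dangle3 = to_centi(dangle3),
    terminal_au = to_centi(terminal_au),
    ml_a = to_centi(ml_a), ml_b = to_centi(ml_b), ml_c = to_centi(ml_c),
    h = h, l_max = l_max,
    extrapolation = to_centi(extrapolation),
    rt = to_centi(rt),
    asym_coeff = to_centi(asym_coeff),
    asym_max = to_centi(asym_max),
    allowed_pairs = allowed_pairs
  )
  dim(p$stack) <- c(6L, 6L)
  dim(p$tmismatch_h) <- c(6L, 4L, 4L)
  dim(p$tmismatch_i) <- c(6L, 4L, 4L)
  dim(p$dangle5) <- c(6L, 4L)
  dim(p$dangle3) <- c(6L, 4L)
  dimnames(p$stack) <- list(PAIR_TYPES, PAIR_TYPES)
  dimnames(p$tmismatch_h) <- dimnames(p$tmismatch_i) <- list(PAIR_TYPES, BASES, BASES)
  dimnames(p$dangle5) <- dimnames(p$dangle3) <- list(PAIR_TYPES, BASES)
  structure(p, class = "nntm_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nntm_params <- function(x, ...) {
  cat("<nntm_params>\n")
  cat(sprintf("  allowed pairs: %s\n", paste(x$allowed_pairs, collapse = " ")))
  cat(sprintf("  h = %d, l_max = %d, terminal AU/GU = %.2f kcal/mol\n",
              x$h, x$l_max, from_centi(x$terminal_au)))
  cat(sprintf("  multiloop a,b,c = %.2f, %.2f, %.2f; asymmetry %.2f (cap %.2f)\n",
              from_centi(x$ml_a), from_centi(x$ml_b), from_centi(x$ml_c),
              from_centi(x$asym_coeff), from_centi(x$asym_max)))
  invisible(x)
}

# 4x4 admissibility map restricted to the parameter set's allowed pairs.
pair_admissible_code <- function(params) {
  keep <- PAIR_CODE
  keep[!(PAIR_CODE %in% which(PAIR_TYPES %in% params$allowed_pairs))] <- 0L
  keep
}

#' All-zero null parameter set
#'
#' Every table and scalar is zero (with `h = 3`, `l_max = 30` retained), so
#' every admissible loop scores 0 and the MFE of any sequence is 0. Used to
#' exercise the engine's tie handling and termination.
#' @return An `nntm_params` object.
#' @export
zero_parameters <- function() energy_parameters()

#' Bundled toy parameter set
#'
#' A small hand-written parameter set with round numbers, designed for
#' worked examples and oracle-backed tests rather than biological realism:
#' stacking favours CG/GC-rich helices, loop initiations grow gently with
#' length, mismatches and dangles are small stabilizing bonuses. The same
#' set ships as a parameter file at
#' `system.file("extdata", "params_toy.txt", package = "wavefold")`.
#' @return An `nntm_params` object.
#' @examples
#' p <- toy_parameters()
#' p$stack["CG", "CG"]   # centi-kcal internal representation
#' @export
toy_parameters <- function() {
  w <- c(AU = 1.1, UA = 1.1, CG = 2.1, GC = 2.1, GU = 0.7, UG = 0.7)
  stack <- -outer(w, w, function(a, b) round((a + b) / 2, 2))
  l <- 1:30
  hairpin <- round(4.6 + 0.05 * pmax(l - 3, 0) + 0.4 * (l < 3), 2)
  bulge <- round(3.6 + 0.05 * (l - 1), 2)
  internal <- round(1.7 + 0.05 * pmax(l - 2, 0), 2)
  # deterministic small bonuses patterned on (pair, base) indices
  tm <- function(scale) {
    a <- array(0, c(6, 4, 4))
    for (p in 1:6) for (b1 in 1:4) for (b2 in 1:4)
      a[p, b1, b2] <- -round(scale * (1 + (p + b1 + 2 * b2) %% 4) / 10, 2)
    a
  }
  d5 <- matrix(0, 6, 4); d3 <- matrix(0, 6, 4)
  for (p in 1:6) for (b in 1:4) {
    d5[p, b] <- -round((1 + (p + b) %% 3) / 10, 2)
    d3[p, b] <- -round((1 + (p + 2 * b) %% 3) / 10, 2)
  }
  energy_parameters(
    stack = stack,
    hairpin_init = hairpin, bulge_init = bulge, internal_init = internal,
    tmismatch_h = tm(1.5), tmismatch_i = tm(1.0),
    dangle5 = d5, dangle3 = d3,
    terminal_au = 0.5,
    ml_a = 3.4, ml_b = 0.4, ml_c = 0.4,
    h = 3L, l_max = 30L,
    extrapolation = 1.08, rt = 0.62,
    asym_coeff = 0.5, asym_max = 3.0
  )
}
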