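# Parent/child structure of a nested pair set: for each pair, the pairs it
# directly encloses; plus the top-level (exterior) branches.
pair_tree <- function(pairs, n) {
  m <- nrow(pairs)
  children <- rep(list(integer(0)), m)
  toplevel <- integer(0)
  if (m == 0L) return(list(children = children, toplevel = toplevel))
  opens <- integer(n); closes <- integer(n)
  opens[pairs[, 1L]] <- seq_len(m)
  closes[pairs[, 2L]] <- seq_len(m)
  stack <- integer(0)
  for (pos in seq_len(n)) {
    k <- opens[pos]
    if (k > 0L) {
      if (length(stack) == 0L) {
        toplevel <- c(toplevel, k)
      } else {
        par <- stack[length(stack)]
        children[[par]] <- c(children[[par]], k)
      }
      stack <- c(stack, k)
    } else if (closes[pos] > 0L) {
      stack <- stack[-length(stack)]
    }
  }
  list(children = children, toplevel = toplevel)
}

validate_structure_for <- function(s, st, params) {
  pairs <- st$pairs
  if (st$n != s$n) {
    stop(sprintf("structure length %d does not match sequence length %d", st$n, s$n),
         call. = FALSE)
  }
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L | pairs > s$n) || any(pairs[, 1L] >= pairs[, 2L])) {
      stop("structure has out-of-range or inverted pairs", call. = FALSE)
    }
    pos <- c(pairs)
    if (anyDuplicated(pos)) {
      stop(sprintf("position %d occurs in more than one pair", pos[duplicated(pos)][1L]),
           call. = FALSE)
    }
    o <- order(pairs[, 1L])
    cr <- find_crossing(pairs[o, , drop = FALSE])
    if (!is.null(cr)) {
      stop(sprintf("pairs (%d,%d) and (%d,%d) cross", cr[1L], cr[2L], cr[3L], cr[4L]),
           call. = FALSE)
    }
    short <- which(pairs[, 2L] - pairs[, 1L] - 1L < params$h)
    if (length(short) > 0L) {
      stop(sprintf("pair (%d,%d) violates the hairpin bound h = %d",
                   pairs[short[1L], 1L], pairs[short[1L], 2L], params$h), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Independent structure re-scoring with loop decomposition
#'
#' Decomposes a secondary structure into its unique set of loops (hairpin,
#' stack, internal, bulge, multiloop, external) and sums the loop
#' evaluators of the nearest-neighbor model, plus SHAPE pseudo-energies
#' for paired positions when a profile is supplied. This scorer never
#' consults the DP tables — it is the certification path for the engine
#' and the scoring engine of the enumeration oracle. Invalid structures
#' (crossing pairs, reused positions, hairpins below `h`) raise a
#' structural validation error naming the offending pair.
#'
#' @param seq An [rna_sequence] (or string).
#' @param structure A [secondary_structure].
#' @param params An `nntm_params` object.
#' @param dangle Helix-end mode, as in [fill_tables()].
#' @param shape A [shape_profile] or `NULL`.
#' @param shape_centi Internal: precomputed per-position pseudo-energies.
#' @return An `energy_decomposition`: a tibble with one row per loop
#'   (columns `kind`, `i`, `j`, `ip`, `jp`, `energy` in kcal/mol) carrying
#'   the exact total as attributes `total` (kcal/mol) and `total_centi`;
#'   retrieve it with [total_energy()]. The total is `Inf` if any loop is
#'   forbidden under the parameter set.
#' @examples
#' p <- toy_parameters()
#' st <- from_dotbracket("(((....)))")
#' dec <- score_structure("GGGAAAACCC", st, p)
#' total_energy(dec)
#' @export
score_structure <- function(seq, structure, params,
                            dangle = c("none", "dangles", "mismatch"),
                            shape = NULL, shape_centi = NULL) {
  s <- as_rna_sequence(seq)
  stopifnot(inherits(structure, "secondary_structure"))
  dangle <- dangle_mode_code(dangle)
  mode_code <- match(dangle, c("none", "dangles", "mismatch")) - 1L
  validate_structure_for(s, structure, params)
  sh <- shape_centi %||% shape_centi(s, shape)
  core <- score_core(s, structure$pairs, params, mode_code, sh, keep_rows = TRUE)
  rows <- core$rows
  total <- core$total
  out <- tibble::tibble(
    kind = vapply(rows, `[[`, character(1), "kind"),
    i = vapply(rows, `[[`, integer(1), "i"),
    j = vapply(rows, `[[`, integer(1), "j"),
    ip = vapply(rows, `[[`, integer(1), "ip"),
    jp = vapply(rows, `[[`, integer(1), "jp"),
    energy = vapply(rows, function(r) centi_out(r$e), numeric(1))
  )
  attr(out, "total_centi") <- total
  attr(out, "total") <- if (total >= ENERGY_INF) Inf else from_centi(total)
  class(out) <- c("energy_decomposition", class(out))
  out
}

# Shared decomposition/scoring core: loop multiset and exact centi-kcal
# total for a validated pair set. keep_rows = FALSE skips row bookkeeping
# for bulk scoring (the enumeration oracle).
score_core <- function(s, pairs, params, mode_code, sh, keep_rows = FALSE,
                       adm = pair_admissible_code(params)) {
  codes <- s$codes
  n <- s$n
  tree <- pair_tree(pairs, n)
  rows <- if (keep_rows) vector("list", nrow(pairs) + 2L) else NULL
  nrow_used <- 0L
  total <- 0L
  add <- function(kind, i, j, ip, jp, e) {
    e <- unname(e)
    if (keep_rows) {
      nrow_used <<- nrow_used + 1L
      rows[[nrow_used]] <<- list(kind = kind, i = unname(i), j = unname(j),
                                 ip = unname(ip), jp = unname(jp), e = e)
    }
    total <<- sat_add(total, e)
  }
  pt_of <- function(k) adm[codes[pairs[k, 1L]], codes[pairs[k, 2L]]]

  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    cs <- tree$children[[k]]
    if (length(cs) == 0L) {
      add("hairpin", i, j, NA_integer_, NA_integer_,
          hairpin_centi(codes, i, j, params, adm))
    } else if (length(cs) == 1L) {
      ip <- pairs[cs, 1L]; jp <- pairs[cs, 2L]
      if (ip == i + 1L && jp == j - 1L) {
        add("stack", i, j, ip, jp, stack_centi(codes, i, j, params, adm))
      } else {
        kind <- if (ip - i - 1L == 0L || j - jp - 1L == 0L) "bulge" else "internal"
        add(kind, i, j, ip, jp, internal_centi(codes, i, j, ip, jp, params, adm))
      }
    } else {
      spans <- pairs[cs, 2L] - pairs[cs, 1L] + 1L
      unpaired <- (j - i - 1L) - sum(spans)
      pt <- if (adm[codes[i], codes[j]] == 0L) 0L else adm[codes[i], codes[j]]
      e <- multiloop_centi(length(cs) + 1L, unpaired, params)
      e <- if (pt == 0L) ENERGY_INF else sat_add(e, au_pen_centi(pt, params))
      e <- sat_add(e, end_close_centi(codes, i, j, mode_code, params))
      for (c_ in cs) {
        ptc <- pt_of(c_)
        e <- if (ptc == 0L) ENERGY_INF else sat_add(e, au_pen_centi(ptc, params))
        e <- sat_add(e, end_branch_centi(codes, n, pairs[c_, 1L], pairs[c_, 2L],
                                         mode_code, params))
      }
      add("multiloop", i, j, NA_integer_, NA_integer_, e)
    }
  }
  # exterior loop: unpaired bases are free; each top-level branch pays its
  # terminal penalty and end contribution
  e_ext <- 0L
  for (k in tree$toplevel) {
    ptk <- pt_of(k)
    e_ext <- if (ptk == 0L) ENERGY_INF else sat_add(e_ext, au_pen_centi(ptk, params))
    e_ext <- sat_add(e_ext, end_branch_centi(codes, n, pairs[k, 1L], pairs[k, 2L],
                                             mode_code, params))
  }
  add("external", NA_integer_, NA_integer_, NA_integer_, NA_integer_, e_ext)
  if (any(sh != 0L) && nrow(pairs) > 0L) {
    add("shape", NA_integer_, NA_integer_, NA_integer_, NA_integer_,
        sum(sh[c(pairs)]))
  }
  list(rows = if (keep_rows) rows[seq_len(nrow_used)] else NULL, total = total)
}

#' Total energy of a decomposition
#'
#' @param decomposition An `energy_decomposition` from [score_structure()].
#' @return The exact total energy in kcal/mol (`Inf` if forbidden).
#' @export
total_energy <- function(decomposition) {
  attr(decomposition, "total")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("<energy_decomposition> total = %s kcal/mol\n", format(attr(x, "total"))))
  NextMethod()
}
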