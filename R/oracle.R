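#' Exhaustively enumerate nested secondary structures
#'
#' Ground-truth machinery: recursively enumerates every pair set on the
#' sequence that satisfies nestedness, pair admissibility, the hairpin
#' bound and the supplied constraints, scores each with the independent
#' re-scorer [score_structure()], and returns the full argmin set. The
#' engine's DP result can then be checked for exact equality against
#' `min_energy`. Refuses sequences longer than `length_cap` (combinatorial
#' explosion guard).
#'
#' @inheritParams fill_tables
#' @param length_cap Maximum sequence length accepted (default 25).
#' @return A list with `structures` (list of [secondary_structure]),
#'   `count`, `energies` (kcal/mol), `min_energy`, and `argmin` (indices
#'   of all co-optimal structures).
#' @examples
#' enumerate_structures("GCGAAACGC", toy_parameters())$count
#' @export
enumerate_structures <- function(seq, params, constraints = NULL,
                                 dangle = c("none", "dangles", "mismatch"),
                                 prefilter = FALSE, shape = NULL,
                                 length_cap = 25L) {
  s <- as_rna_sequence(seq)
  if (s$n > length_cap) {
    stop(sprintf("sequence length %d exceeds the enumeration cap %d; raise length_cap explicitly if you accept the combinatorial cost",
                 s$n, length_cap), call. = FALSE)
  }
  dangle <- dangle_mode_code(dangle)
  cons <- constraints %||% empty_constraints()
  cm <- candidate_matrix(s, params, cons, prefilter)
  cand <- cm$cand
  h <- params$h
  n <- s$n

  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), ncol = 2L)
  enum_region <- function(i, j) {
    if (j - i < h + 1L) return(list(empty))
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(enum_region(i + 1L, j), identity)   # i unpaired
    ks <- seq.int(i + h + 1L, j)
    ks <- ks[cand[i, ks]]
    for (k in ks) {
      inner <- enum_region(i + 1L, k - 1L)
      outer <- enum_region(k + 1L, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  raw <- enum_region(1L, n)
  if (nrow(cons$forced) > 0L) {
    fk <- paste(cons$forced[, 1L], cons$forced[, 2L])
    raw <- Filter(function(p) {
      all(fk %in% (if (nrow(p) == 0L) character(0) else paste(p[, 1L], p[, 2L])))
    }, raw)
  }
  # enumerated pair sets are nested and position-disjoint by construction
  # (and emitted sorted by i), so skip re-validation when wrapping them
  structures <- lapply(raw, function(p) {
    dimnames(p) <- list(NULL, c("i", "j"))
    structure(list(pairs = p, n = n), class = "secondary_structure")
  })
  sh <- shape_centi(s, shape)
  mode_code <- match(dangle, c("none", "dangles", "mismatch")) - 1L
  adm <- pair_admissible_code(params)
  energies_centi <- vapply(raw, function(p) {
    score_core(s, p, params, mode_code, sh, adm = adm)$total
  }, integer(1))
  energies <- ifelse(energies_centi >= ENERGY_INF, Inf, from_centi(energies_centi))
  mn <- min(energies)
  list(structures = structures,
       count = length(structures),
       energies = energies,
       min_energy = mn,
       argmin = which(energies == mn))
}

#' Independently count nested structures
#'
#' A second, non-enumerating implementation of the structure count: an
#' iterative interval recursion
#' `N(i,j) = N(i+1,j) + sum_k [candidate (i,k)] N(i+1,k-1) * N(k+1,j)`
#' evaluated bottom-up over interval lengths. Used to verify that the
#' enumeration in [enumerate_structures()] is exhaustive.
#'
#' @inheritParams enumerate_structures
#' @return The number of valid nested structures (a double; counts grow
#'   fast).
#' @export
count_structures <- function(seq, params, constraints = NULL, prefilter = FALSE) {
  s <- as_rna_sequence(seq)
  cm <- candidate_matrix(s, params, constraints, prefilter)
  cand <- cm$cand
  h <- params$h
  n <- s$n
  # N[i, j+1] holds N(i, j); the extra column covers empty regions j = i-1
  N <- matrix(1, n + 1L, n + 2L)
  for (len in seq_len(n)) {
    if (len < h + 2L) next
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      tot <- N[i + 1L, j + 1L]
      for (k in seq.int(i + h + 1L, j)) {
        if (!cand[i, k]) next
        tot <- tot + N[i + 1L, k - 1L + 1L] * N[k + 1L, j + 1L]
      }
      N[i, j + 1L] <- tot
    }
  }
  N[1L, n + 1L]
}

# Draw a random internally consistent constraint set for seq: forced pairs
# sampled compatibly from the candidate list, plus prohibited pairs and
# forced-single positions avoiding them.
random_constraints <- function(seq, params, n_forced = 1L, n_prohibited = 2L,
                               n_single = 1L) {
  s <- as_rna_sequence(seq)
  cp <- candidate_pairs(s, params)
  if (nrow(cp) == 0L) return(empty_constraints())
  forced <- matrix(integer(0), ncol = 2L)
  pool <- cp[sample.int(nrow(cp)), , drop = FALSE]
  for (r in seq_len(nrow(pool))) {
    cand_pair <- c(pool$i[r], pool$j[r])
    ok <- TRUE
    if (nrow(forced) > 0L) {
      i <- cand_pair[1L]; j <- cand_pair[2L]
      for (q in seq_len(nrow(forced))) {
        a <- forced[q, 1L]; b <- forced[q, 2L]
        if (any(c(a, b) %in% c(i, j)) ||
            (i < a && a < j && j < b) || (a < i && i < b && b < j)) { ok <- FALSE; break }
      }
    }
    if (ok) forced <- rbind(forced, cand_pair)
    if (nrow(forced) >= n_forced) break
  }
  key <- function(i, j) paste(i, j)
  fk <- if (nrow(forced) > 0L) key(forced[, 1L], forced[, 2L]) else character(0)
  rest <- cp[!(key(cp$i, cp$j) %in% fk), , drop = FALSE]
  prohibited <- if (nrow(rest) > 0L) {
    take <- rest[sample.int(nrow(rest), min(n_prohibited, nrow(rest))), , drop = FALSE]
    cbind(take$i, take$j)
  } else NULL
  free_pos <- setdiff(seq_len(s$n), c(forced))
  single <- if (length(free_pos) > 0L && n_single > 0L) {
    sample(free_pos, min(n_single, length(free_pos)))
  } else integer(0)
  fold_constraints(forced = if (nrow(forced) > 0L) forced else NULL,
                   prohibited = prohibited, single = single)
}

#' Consistency self-test harness
#'
#' Runs the package's cross-module invariant suite on seeded random
#' inputs: DP-versus-enumeration oracle equivalence over helix-end and
#' prefilter modes and parameter sets, traceback certification, wavefront
#' scheduler invariance, constraint soundness, prefilter monotonicity,
#' format round trips, and agreement of the compatible-pair count with an
#' insertion-revalidation brute force. Deterministic for a fixed seed.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_oracle Number of random sequences for the oracle check.
#' @param oracle_max_len Maximum sequence length for enumeration.
#' @param n_sched,sched_len Scheduler-invariance panel size and length.
#' @param n_constraint Number of constrained folds.
#' @param n_metric Number of random cases for the metric brute force.
#' @return A tibble with columns `check`, `cases`, `failures`, `pass`;
#'   attribute `counterexamples` holds the first failing inputs, if any.
#' @export
fold_selftest <- function(seed = 1L, n_oracle = 40L, oracle_max_len = 18L,
                          n_sched = 8L, sched_len = 60L, n_constraint = 20L,
                          n_metric = 100L) {
  toy <- toy_parameters()
  zero <- zero_parameters()
  checks <- list()
  cx <- list()
  note <- function(check, cases, failures, example = NULL) {
    checks[[length(checks) + 1L]] <<- list(check = check, cases = cases, failures = failures)
    if (failures > 0L && !is.null(example)) cx[[check]] <<- example
  }

  # --- oracle equivalence + traceback certification
  lens <- 5L + (seq_len(n_oracle) %% (oracle_max_len - 4L))
  seqs <- random_sequences(n_oracle, lens, gc_bias = 0.5, seed = seed)
  fail_or <- 0L; fail_cert <- 0L; cases_or <- 0L; ex <- NULL
  for (s in seqs) {
    for (pset in list(toy, zero)) for (dg in c("none", "dangles")) for (pf in c(FALSE, TRUE)) {
      en <- enumerate_structures(s, pset, dangle = dg, prefilter = pf,
                                 length_cap = oracle_max_len + 1L)
      tb <- fill_tables(s, pset, dangle = dg, prefilter = pf)
      cases_or <- cases_or + 1L
      if (!isTRUE(all.equal(table_mfe(tb), en$min_energy))) {
        fail_or <- fail_or + 1L
        ex <- ex %||% list(seq = as.character(s), dangle = dg, prefilter = pf)
      }
      tr <- fold_traceback(tb)
      if (total_energy(tr$decomposition) != table_mfe(tb)) fail_cert <- fail_cert + 1L
    }
  }
  note("oracle_equivalence", cases_or, fail_or, ex)
  note("traceback_certification", cases_or, fail_cert)

  # --- scheduler invariance
  sseqs <- random_sequences(n_sched, sched_len, seed = seed + 1L)
  fail_s <- 0L
  for (s in sseqs) {
    t1 <- fill_tables(s, toy, dangle = "dangles", workers = 1L)
    t2 <- fill_tables(s, toy, dangle = "dangles", workers = 2L)
    t4 <- fill_tables(s, toy, dangle = "dangles", workers = 4L)
    same <- identical(t1$V, t2$V) && identical(t1$V, t4$V) &&
      identical(t1$W, t2$W) && identical(t1$W, t4$W) &&
      identical(t1$WM, t2$WM) && identical(t1$WM, t4$WM)
    if (same) {
      cts <- vapply(list(t1, t2, t4), function(tt) {
        f <- fold_traceback(tt)
        tmp <- tempfile(fileext = ".ct")
        on.exit(unlink(tmp), add = TRUE)
        write_ct(s, f$structure, tmp, energy = table_mfe(tt))
        paste(readLines(tmp), collapse = "\n")
      }, character(1))
      same <- length(unique(cts)) == 1L
    }
    if (!same) fail_s <- fail_s + 1L
  }
  note("scheduler_invariance", n_sched, fail_s)

  # --- constraint soundness + prefilter monotonicity
  cseqs <- random_sequences(n_constraint, 40L, seed = seed + 2L)
  fail_c <- 0L; fail_p <- 0L
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed + 3L)
  for (s in cseqs) {
    cons <- random_constraints(s, toy)
    f0 <- rna_fold(s, toy, dangle = "dangles")
    fc <- rna_fold(s, toy, constraints = cons, dangle = "dangles")
    ok <- fc$mfe >= f0$mfe - 1e-9 && constraints_satisfied(fc$structure, cons)
    if (!ok) fail_c <- fail_c + 1L
    fp <- rna_fold(s, toy, dangle = "dangles", prefilter = TRUE)
    cp_on <- candidate_pairs(s, toy, prefilter = TRUE)
    cp_off <- candidate_pairs(s, toy, prefilter = FALSE)
    sub <- all(paste(cp_on$i, cp_on$j) %in% paste(cp_off$i, cp_off$j))
    if (!(sub && fp$mfe >= f0$mfe - 1e-9)) fail_p <- fail_p + 1L
  }
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  note("constraint_soundness", n_constraint, fail_c)
  note("prefilter_monotonicity", n_constraint, fail_p)

  # --- format round trips
  rseqs <- random_sequences(10L, 30L, seed = seed + 4L)
  fail_r <- 0L
  for (s in rseqs) {
    f <- rna_fold(s, toy)
    tmp_fa <- tempfile(fileext = ".fa"); tmp_ct <- tempfile(fileext = ".ct")
    write_fasta(s, tmp_fa)
    s2 <- read_fasta(tmp_fa)[[1L]]
    write_ct(s, f$structure, tmp_ct, energy = f$mfe)
    ct <- read_ct(tmp_ct)
    db_ok <- same_pairs(from_dotbracket(to_dotbracket(f$structure)), f$structure)
    if (!(identical(s2$residues, s$residues) &&
          identical(as.character(ct$seq), as.character(s)) &&
          same_pairs(ct$structure, f$structure) && db_ok)) fail_r <- fail_r + 1L
    unlink(c(tmp_fa, tmp_ct))
  }
  note("format_round_trips", 10L, fail_r)

  # --- compatible-count brute force
  fail_m <- 0L
  mseqs <- random_sequences(ceiling(n_metric / 4), 14L, seed = seed + 5L)
  cases_m <- 0L
  set.seed(seed + 6L)
  for (s in mseqs) {
    en <- enumerate_structures(s, toy)
    if (en$count < 2L) next
    for (rep in 1:4) {
      ref <- en$structures[[sample.int(en$count, 1L)]]
      prd <- en$structures[[sample.int(en$count, 1L)]]
      cls <- classify_pairs(prd, ref)
      xi <- compatible_count(cls$FP, ref, h = toy$h)
      xi_bf <- brute_force_xi(cls$FP, ref, h = toy$h)
      cases_m <- cases_m + 1L
      if (xi != xi_bf) fail_m <- fail_m + 1L
    }
  }
  note("metric_brute_force", cases_m, fail_m)

  out <- tibble::tibble(
    check = vapply(checks, `[[`, character(1), "check"),
    cases = vapply(checks, `[[`, numeric(1), "cases"),
    failures = vapply(checks, `[[`, numeric(1), "failures")
  )
  out$pass <- out$failures == 0L
  attr(out, "counterexamples") <- cx
  out
}

# Literal insertion-revalidation check: a pair is compatible iff adding it
# alone to the reference and re-validating the whole structure succeeds.
brute_force_xi <- function(fp, reference, h = 3L) {
  fp <- as.matrix(fp)
  if (length(fp) == 0L) return(0L)
  xi <- 0L
  for (r in seq_len(nrow(fp))) {
    ok <- fp[r, 2L] - fp[r, 1L] - 1L >= h &&
      !inherits(tryCatch(secondary_structure(rbind(reference$pairs, fp[r, , drop = FALSE]),
                                             n = reference$n),
                         error = function(e) e), "error")
    if (ok) xi <- xi + 1L
  }
  xi
}

#' Does a structure satisfy a constraint set?
#'
#' Structural check used by the soundness tests: all forced pairs present,
#' no prohibited pair present, no pair touching a forced-single position.
#'
#' @param structure A [secondary_structure].
#' @param constraints A [fold_constraints] object.
#' @return `TRUE` or `FALSE`.
#' @export
constraints_satisfied <- function(structure, constraints) {
  key <- pair_keys(structure)
  forced_ok <- nrow(constraints$forced) == 0L ||
    all(paste(constraints$forced[, 1L], constraints$forced[, 2L]) %in% key)
  proh_ok <- nrow(constraints$prohibited) == 0L ||
    !any(paste(constraints$prohibited[, 1L], constraints$prohibited[, 2L]) %in% key)
  single_ok <- length(constraints$single) == 0L ||
    !any(constraints$single %in% c(structure$pairs))
  forced_ok && proh_ok && single_ok
}
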