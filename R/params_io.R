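PARAM_SECTIONS <- c("STACK", "HAIRPIN_INIT", "BULGE_INIT", "INTERNAL_INIT",
                    "TMISMATCH_H", "TMISMATCH_I", "DANGLE5", "DANGLE3",
                    "MULTILOOP", "MISC")

#' Read and write thermodynamic parameter files
#'
#' The parameter file dialect is plain text: sections headed by the
#' keywords STACK, HAIRPIN_INIT, BULGE_INIT, INTERNAL_INIT, TMISMATCH_H,
#' TMISMATCH_I, DANGLE5, DANGLE3, MULTILOOP and MISC; whitespace-separated
#' entries; `#` starts a comment; energies in kcal/mol with up to two
#' decimals. Table rows are keyed symbolically — `STACK`: `outer inner
#' energy` (pair types such as `CG`); initiation tables: `length energy`;
#' mismatch tables: `pair base5 base3 energy`; dangles: `pair base energy`.
#' `MULTILOOP` holds `offset`, `branch`, `unpaired`; `MISC` holds
#' `terminal_au`, `min_hairpin_unpaired`, `loop_max`,
#' `extrapolation_coeff`, `rt`, `asymmetry_coeff`, `asymmetry_max` and
#' `allowed_pairs`. Every section must be present and every table entry
#' defined; a missing table, malformed line or unknown pair type is a
#' parse error naming the file, line and field. `read_parameters()` and
#' [write_parameters()] are exact inverses (round-trip identity) because
#' energies are fixed-decimal.
#'
#' @param path Path to a parameter file.
#' @return `read_parameters()` returns an `nntm_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @examples
#' p <- read_parameters(system.file("extdata", "params_toy.txt", package = "wavefold"))
#' tmp <- tempfile(fileext = ".txt")
#' write_parameters(p, tmp)
#' identical(read_parameters(tmp), p)
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  perr <- function(line_no, msg) {
    stop(sprintf("%s:%d: %s", path, line_no, msg), call. = FALSE)
  }
  # first pass: assign every non-empty line to its section
  sec <- NULL
  rows <- list()
  for (ln in seq_along(raw)) {
    txt <- sub("#.*$", "", raw[ln])
    toks <- strsplit(trimws(txt), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) next
    if (length(toks) == 1L && toks %in% PARAM_SECTIONS) {
      sec <- toks
      rows[[sec]] <- rows[[sec]] %||% list()
      next
    }
    if (is.null(sec)) perr(ln, sprintf("entry '%s' before any section header", toks[1L]))
    rows[[sec]] <- c(rows[[sec]], list(list(ln = ln, toks = toks)))
  }
  missing <- setdiff(PARAM_SECTIONS, names(rows))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing parameter section(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num <- function(tok, ln, field) {
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) perr(ln, sprintf("field '%s': '%s' is not a number", field, tok))
    v
  }
  ptype <- function(tok, ln) {
    k <- match(tok, PAIR_TYPES)
    if (is.na(k)) perr(ln, sprintf("unknown pair type '%s'", tok))
    k
  }
  base1 <- function(tok, ln) {
    k <- match(tok, BASES)
    if (is.na(k)) perr(ln, sprintf("unknown base '%s'", tok))
    k
  }
  kv <- function(section) {
    out <- list()
    for (r in rows[[section]]) {
      if (length(r$toks) < 2L) perr(r$ln, sprintf("%s entry needs a key and a value", section))
      out[[r$toks[1L]]] <- r
    }
    out
  }

  misc <- kv("MISC")
  need <- function(tab, key, section) {
    r <- tab[[key]]
    if (is.null(r)) stop(sprintf("%s: %s is missing required key '%s'", path, section, key),
                         call. = FALSE)
    r
  }
  r <- need(misc, "loop_max", "MISC"); l_max <- as.integer(num(r$toks[2L], r$ln, "loop_max"))
  r <- need(misc, "min_hairpin_unpaired", "MISC"); h <- as.integer(num(r$toks[2L], r$ln, "min_hairpin_unpaired"))
  scalar <- function(key) { r <- need(misc, key, "MISC"); num(r$toks[2L], r$ln, key) }
  ap_row <- need(misc, "allowed_pairs", "MISC")
  allowed <- ap_row$toks[-1L]
  for (tok in allowed) ptype(tok, ap_row$ln)

  ml <- kv("MULTILOOP")
  ml_val <- function(key) { r <- need(ml, key, "MULTILOOP"); num(r$toks[2L], r$ln, key) }

  stack <- matrix(NA_real_, 6, 6)
  for (r in rows[["STACK"]]) {
    if (length(r$toks) != 3L) perr(r$ln, "STACK rows are: outer inner energy")
    stack[ptype(r$toks[1L], r$ln), ptype(r$toks[2L], r$ln)] <- num(r$toks[3L], r$ln, "energy")
  }
  init_tab <- function(section) {
    v <- rep(NA_real_, l_max)
    for (r in rows[[section]]) {
      if (length(r$toks) != 2L) perr(r$ln, sprintf("%s rows are: length energy", section))
      len <- as.integer(num(r$toks[1L], r$ln, "length"))
      if (len < 1L || len > l_max) perr(r$ln, sprintf("length %d outside 1..loop_max=%d", len, l_max))
      v[len] <- num(r$toks[2L], r$ln, "energy")
    }
    if (anyNA(v)) {
      stop(sprintf("%s: %s is missing lengths: %s", path, section,
                   paste(utils::head(which(is.na(v)), 5), collapse = ", ")), call. = FALSE)
    }
    v
  }
  mm_tab <- function(section) {
    a <- array(NA_real_, c(6, 4, 4))
    for (r in rows[[section]]) {
      if (length(r$toks) != 4L) perr(r$ln, sprintf("%s rows are: pair base5 base3 energy", section))
      a[ptype(r$toks[1L], r$ln), base1(r$toks[2L], r$ln), base1(r$toks[3L], r$ln)] <-
        num(r$toks[4L], r$ln, "energy")
    }
    if (anyNA(a)) stop(sprintf("%s: %s table is incomplete", path, section), call. = FALSE)
    a
  }
  dg_tab <- function(section) {
    m <- matrix(NA_real_, 6, 4)
    for (r in rows[[section]]) {
      if (length(r$toks) != 3L) perr(r$ln, sprintf("%s rows are: pair base energy", section))
      m[ptype(r$toks[1L], r$ln), base1(r$toks[2L], r$ln)] <- num(r$toks[3L], r$ln, "energy")
    }
    if (anyNA(m)) stop(sprintf("%s: %s table is incomplete", path, section), call. = FALSE)
    m
  }
  if (anyNA(stack)) stop(sprintf("%s: STACK table is incomplete (36 entries required)", path),
                         call. = FALSE)

  energy_parameters(
    stack = stack,
    hairpin_init = init_tab("HAIRPIN_INIT"),
    bulge_init = init_tab("BULGE_INIT"),
    internal_init = init_tab("INTERNAL_INIT"),
    tmismatch_h = mm_tab("TMISMATCH_H"),
    tmismatch_i = mm_tab("TMISMATCH_I"),
    dangle5 = dg_tab("DANGLE5"),
    dangle3 = dg_tab("DANGLE3"),
    terminal_au = scalar("terminal_au"),
    ml_a = ml_val("offset"), ml_b = ml_val("branch"), ml_c = ml_val("unpaired"),
    h = h, l_max = l_max,
    extrapolation = scalar("extrapolation_coeff"),
    rt = scalar("rt"),
    asym_coeff = scalar("asymmetry_coeff"),
    asym_max = scalar("asymmetry_max"),
    allowed_pairs = allowed
  )
}

#' @param params An `nntm_params` object.
#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "nntm_params"))
  f <- function(x) sprintf("%.2f", from_centi(x))
  out <- c("# wavefold nearest-neighbor thermodynamic parameter file",
           "# energies in kcal/mol, two decimals")
  out <- c(out, "MISC",
           paste("terminal_au", f(params$terminal_au)),
           paste("min_hairpin_unpaired", params$h),
           paste("loop_max", params$l_max),
           paste("extrapolation_coeff", f(params$extrapolation)),
           paste("rt", f(params$rt)),
           paste("asymmetry_coeff", f(params$asym_coeff)),
           paste("asymmetry_max", f(params$asym_max)),
           paste(c("allowed_pairs", params$allowed_pairs), collapse = " "))
  out <- c(out, "MULTILOOP",
           paste("offset", f(params$ml_a)),
           paste("branch", f(params$ml_b)),
           paste("unpaired", f(params$ml_c)))
  out <- c(out, "STACK")
  for (p in 1:6) for (q in 1:6) {
    out <- c(out, paste(PAIR_TYPES[p], PAIR_TYPES[q], f(params$stack[p, q])))
  }
  for (section in c("HAIRPIN_INIT", "BULGE_INIT", "INTERNAL_INIT")) {
    tab <- switch(section, HAIRPIN_INIT = params$hairpin_init,
                  BULGE_INIT = params$bulge_init, INTERNAL_INIT = params$internal_init)
    out <- c(out, section, paste(seq_len(params$l_max), f(tab)))
  }
  for (section in c("TMISMATCH_H", "TMISMATCH_I")) {
    a <- if (section == "TMISMATCH_H") params$tmismatch_h else params$tmismatch_i
    out <- c(out, section)
    for (p in 1:6) for (b1 in 1:4) for (b2 in 1:4) {
      out <- c(out, paste(PAIR_TYPES[p], BASES[b1], BASES[b2], f(a[p, b1, b2])))
    }
  }
  for (section in c("DANGLE5", "DANGLE3")) {
    m <- if (section == "DANGLE5") params$dangle5 else params$dangle3
    out <- c(out, section)
    for (p in 1:6) for (b in 1:4) {
      out <- c(out, paste(PAIR_TYPES[p], BASES[b], f(m[p, b])))
    }
  }
  writeLines(out, path)
  invisible(path)
}
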