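# Tiny hand-built parameter sets for worked examples: every table zeroed
# except the stated entries, so expected energies are single lookups or
# short hand sums.

params_with <- function(...) {
  p <- zero_parameters()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# hairpin_init[3] = 5.00 kcal/mol, everything else zero
params_hairpin5 <- function() {
  hp <- integer(30)
  hp[3] <- 500L
  params_with(hairpin_init = hp)
}

# only CG/GC-on-CG/GC stacks at -1.00 kcal/mol, everything else zero
params_gc_stack <- function() {
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- matrix(0L, 6, 6, dimnames = list(pt, pt))
  for (a in c("CG", "GC")) for (b in c("CG", "GC")) st[a, b] <- -100L
  params_with(stack = st)
}

# oracle comparison via exported API only: enumeration minimum under the
# same mode flags, with the prefilter applied as a feasible-set restriction
oracle_min <- function(seq, params, dangle = "none", prefilter = FALSE,
                       constraints = NULL, shape = NULL, length_cap = 26L) {
  en <- enumerate_structures(seq, params, constraints = constraints,
                             dangle = dangle, shape = shape,
                             prefilter = FALSE, length_cap = length_cap)
  if (!prefilter) return(en$min_energy)
  cp <- candidate_pairs(seq, params, constraints = constraints, prefilter = TRUE)
  allowed <- paste(cp$i, cp$j)
  keep <- vapply(en$structures, function(st) {
    p <- st$pairs
    nrow(p) == 0L || all(paste(p[, 1], p[, 2]) %in% allowed)
  }, logical(1))
  min(en$energies[keep])
}
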