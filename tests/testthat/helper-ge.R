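# Shared fixtures: a hand-driven grammar expansion (the derivation oracle
# for the genotype-phenotype mapping), and small synthetic signal sets.

# Expand the grammar leftmost-first, taking production indices from
# `choices` (1-based) at every choice point.  Independent re-implementation
# of the derivation process used as the oracle for map_genotype(): the
# codon string `choices - 1` must map to the same phenotype.
derive_phenotype <- function(grammar, choices) {
  stack <- list(list(type = "nt", value = grammar$start))
  out <- character(0)
  ci <- 0L
  while (length(stack)) {
    tok <- stack[[1L]]
    stack <- stack[-1L]
    if (tok$type == "t") { out <- c(out, tok$value); next }
    prods <- grammar$rules[[tok$value]]
    if (length(prods) == 1L) {
      pick <- 1L
    } else {
      ci <- ci + 1L
      if (ci > length(choices)) stop("choice list exhausted")
      pick <- choices[ci]
      if (pick < 1L || pick > length(prods))
        stop("invalid choice for [", tok$value, "]")
    }
    rep_toks <- prods[[pick]]
    if (length(rep_toks)) stack <- c(rep_toks, stack)
  }
  list(phenotype = paste(out, collapse = ""), n_choices = ci)
}

# A smooth, positive CGM-like trace plus matching Ra/IOB-like inputs.
synthetic_inputs <- function(n = 400, seed = 99) {
  set.seed(seed)
  tt <- seq_len(n)
  g <- 120 + 30 * sin(2 * pi * tt / 288) + 15 * sin(2 * pi * tt / 37) +
    cumsum(stats::rnorm(n, 0, 1))
  list(g = pmax(g, 45),
       ra = pmax(0, 2 * sin(2 * pi * tt / 288 + 1)),
       iob = pmax(0, 1 + sin(2 * pi * tt / 144)))
}

# Training set whose targets are generated exactly by a planted
# grammar-derivable expression (carry-forward of the current CGM value
# shifted by a constant offset).
planted_training_set <- function(n = 400, seed = 99) {
  sig <- synthetic_inputs(n, seed)
  grammar <- glucose_grammar()
  planted <- as.integer(c(0, 0, 12, 0, 0, 7, 0, 1, 0, 0, 5, 5, 1,
                          0, 0, 1, 0, 0, 1, 0, 0, 1))
  expr <- parse_predictor(map_genotype(planted, grammar)$phenotype)
  ns <- 25:(n - 24)
  targets <- evaluate_predictor(expr, sig$g, sig$ra, sig$iob, ns)
  list(train = glucoge:::ge_training_set(sig$g, sig$ra, sig$iob, ns, targets),
       expr = expr, genotype = planted, grammar = grammar)
}

# Small-budget GE control for fast tests.
fast_control <- function(...) {
  ge_control(population_size = 20L, generations = 10L, rng_seed = 42L, ...)
}
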