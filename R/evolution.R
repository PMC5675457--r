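#' Grammatical-evolution run configuration
#'
#' Defaults follow the standard setup for this forecasting problem:
#' population 50, 2000 generations, single-point variable crossover with
#' probability 0.90, integer-flip mutation with probability 0.005 per
#' codon, tournament selection of size 2, elitism of 2 and at most 2
#' genotype wraps during mapping.  Initial genotype lengths are uniform on
#' `[min_len, max_len]` codons.  `seed_baseline` injects the persistence
#' genotype into the initial population so the returned model never
#' underperforms the trivial carry-forward forecast.
#'
#' @param population_size,generations,elitism_count,tournament_size,max_wraps
#'   positive integers (`elitism_count < population_size`).
#' @param crossover_prob,mutation_prob probabilities in `[0, 1]`.
#' @param min_len,max_len initial genotype length bounds (codons).
#' @param rng_seed integer seed for the run.
#' @param seed_baseline logical; include [persistence_genotype()] in the
#'   initial population (default `TRUE`).
#' @return A list of class `ge_control`.
#' @export
ge_control <- function(population_size = 50L, generations = 2000L,
                       crossover_prob = 0.90, mutation_prob = 0.005,
                       elitism_count = 2L, tournament_size = 2L,
                       max_wraps = 2L, min_len = 15L, max_len = 100L,
                       rng_seed = 1L, seed_baseline = TRUE) {
  stopifnot(population_size >= 1, generations >= 0,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism_count >= 0, elitism_count < population_size,
            tournament_size >= 1, max_wraps >= 0,
            min_len >= 1, min_len <= max_len)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 max_wraps = as.integer(max_wraps),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 rng_seed = as.integer(rng_seed),
                 seed_baseline = isTRUE(seed_baseline)),
            class = "ge_control")
}

#' Tournament selection
#'
#' Draws `tournament_size` individuals uniformly with replacement and
#' returns the index of the fittest (lowest fitness; ties keep the first
#' drawn).
#'
#' @param fitness numeric vector of fitness values (lower is better;
#'   `Inf` marks invalid individuals).
#' @param tournament_size number of contestants.
#' @return The selected index.
#' @export
tournament_select <- function(fitness, tournament_size = 2L) {
  if (!length(fitness)) stop("empty population")
  idx <- sample.int(length(fitness), tournament_size, replace = TRUE)
  idx[which.min(fitness[idx])]
}

#' Single-point variable-length crossover
#'
#' Draws an independent cut point in each parent (uniform over
#' `0..length`, i.e. before the first codon through after the last) and
#' exchanges tails.  With probability `1 - crossover_prob` the parents
#' are returned unchanged.  Cut pairs that would leave a child empty are
#' redrawn, preserving the length->=1 genotype invariant; the summed
#' length of the children always equals that of the parents.
#'
#' @param parent_a,parent_b integer codon vectors.
#' @param crossover_prob probability that crossover is applied.
#' @return A list of two children.
#' @export
single_point_crossover <- function(parent_a, parent_b,
                                   crossover_prob = 1) {
  la <- length(parent_a); lb <- length(parent_b)
  stopifnot(la >= 1, lb >= 1)
  if (stats::runif(1) > crossover_prob)
    return(list(parent_a, parent_b))
  repeat {
    ca <- sample.int(la + 1L, 1L) - 1L   # keep first ca codons of a
    cb <- sample.int(lb + 1L, 1L) - 1L
    if (ca + (lb - cb) >= 1L && cb + (la - ca) >= 1L) break
  }
  child_a <- c(parent_a[seq_len(ca)], parent_b[seq_len(lb - cb) + cb])
  child_b <- c(parent_b[seq_len(cb)], parent_a[seq_len(la - ca) + ca])
  list(as.integer(child_a), as.integer(child_b))
}

#' Integer-flip mutation
#'
#' Replaces each codon, independently with probability `mutation_prob`,
#' by a fresh uniform draw from `[0, 255]`.  Length is always preserved.
#'
#' @param genotype integer codon vector.
#' @param mutation_prob per-codon replacement probability.
#' @return Mutated codon vector.
#' @export
integer_flip_mutation <- function(genotype, mutation_prob = 0.005) {
  if (mutation_prob <= 0) return(genotype)
  hit <- stats::runif(length(genotype)) < mutation_prob
  if (any(hit))
    genotype[hit] <- sample(0:255, sum(hit), replace = TRUE)
  genotype
}

# Build the training-set container consumed by evolve(): aligned numeric
# vectors on the 5-min grid plus the (n, target) pairs of the segment.
ge_training_set <- function(g, ra, iob, n_idx, target) {
  g <- if (inherits(g, "uniform_signal")) g$values else as.numeric(g)
  ra <- if (inherits(ra, "uniform_signal")) ra$values else as.numeric(ra)
  iob <- if (inherits(iob, "uniform_signal")) iob$values else as.numeric(iob)
  if (length(unique(c(length(g), length(ra), length(iob)))) != 1L)
    stop("signals must be aligned")
  if (!length(n_idx)) stop("training segment contains no (history, target) pairs")
  if (length(n_idx) != length(target)) stop("n_idx/target length mismatch")
  list(g = g, ra = ra, iob = iob,
       n_idx = as.integer(n_idx), target = as.numeric(target))
}

# Fitness of one genotype on a training set: gMSE of its predictions at
# the segment's timestamps; Inf for invalid mappings or unparsable /
# lag-violating phenotypes.
ge_fitness <- function(genotype, grammar, train, pen_par, max_wraps = 2L) {
  mp <- map_genotype(genotype, grammar, max_wraps)
  if (!mp$valid) return(list(fitness = Inf, phenotype = NA_character_))
  expr <- parse_predictor(mp$phenotype)
  if (is.null(expr)) return(list(fitness = Inf, phenotype = mp$phenotype))
  preds <- evaluate_predictor(expr, train$g, train$ra, train$iob, train$n_idx)
  list(fitness = gmse(train$target, preds, pen_par),
       phenotype = mp$phenotype)
}

#' Run the generational grammatical-evolution loop
#'
#' Minimizes the glucose-specific fitness ([gmse()]) of mapped predictor
#' expressions over one training segment.  Each generation copies the
#' `elitism_count` best individuals unchanged and fills the rest of the
#' population with offspring produced by tournament selection,
#' single-point crossover and integer-flip mutation.  Invalid mappings
#' stay in the population with worst-marker fitness (`Inf`).  Fitness
#' values are cached by genotype, and only timestamps belonging to the
#' training segment enter the loss.  Fully deterministic for a fixed
#' `control$rng_seed`.
#'
#' @param train training set from the internal pair builder: list with
#'   aligned `g`, `ra`, `iob` vectors (5-min grid), pair indices `n_idx`
#'   and CGM `target` values one horizon ahead.
#' @param grammar a [ge_grammar][load_grammar] object.
#' @param control a [ge_control()] configuration.
#' @param pen_par a [pen_params()] object.
#' @return A list of class `ge_run`: `best` (genotype, fitness,
#'   phenotype, expression), `log` (per-generation data.frame),
#'   `population` (final genotypes) and `control`.
#' @export
evolve <- function(train, grammar, control = ge_control(),
                   pen_par = pen_params()) {
  stopifnot(inherits(grammar, "ge_grammar"), inherits(control, "ge_control"))
  if (!length(train$n_idx)) stop("empty training data")
  set.seed(control$rng_seed)
  np <- control$population_size
  pop <- vector("list", np)
  start <- 1L
  if (control$seed_baseline) { pop[[1L]] <- persistence_genotype(); start <- 2L }
  for (i in seq.int(start, np))
    pop[[i]] <- random_genotype(control$min_len, control$max_len)

  cache <- new.env(parent = emptyenv())
  eval_pop <- function(pop) {
    fit <- numeric(np); phen <- character(np)
    for (i in seq_len(np)) {
      key <- paste(pop[[i]], collapse = ",")
      cacheable <- nchar(key) < 9000L   # env names are size-limited
      hit <- if (cacheable) cache[[key]] else NULL
      if (is.null(hit)) {
        hit <- ge_fitness(pop[[i]], grammar, train, pen_par,
                          control$max_wraps)
        if (cacheable) cache[[key]] <- hit
      }
      fit[i] <- hit$fitness; phen[i] <- hit$phenotype
    }
    list(fitness = fit, phenotype = phen)
  }

  ev <- eval_pop(pop)
  best_i <- which.min(ev$fitness)
  best <- list(genotype = pop[[best_i]], fitness = ev$fitness[best_i],
               phenotype = ev$phenotype[best_i])
  log_rows <- vector("list", control$generations + 1L)
  snapshot <- function(gen, ev) {
    fin <- is.finite(ev$fitness)
    data.frame(generation = gen,
               best_fitness = best$fitness,
               mean_fitness = if (any(fin)) mean(ev$fitness[fin]) else NA_real_,
               invalid_frac = mean(!fin),
               best_phenotype = best$phenotype,
               stringsAsFactors = FALSE)
  }
  log_rows[[1L]] <- snapshot(0L, ev)

  gen <- 0L
  while (gen < control$generations) {
    gen <- gen + 1L
    elite_idx <- order(ev$fitness)[seq_len(control$elitism_count)]
    offspring <- vector("list", np)
    for (i in seq_along(elite_idx)) offspring[[i]] <- pop[[elite_idx[i]]]
    k <- control$elitism_count
    while (k < np) {
      pa <- pop[[tournament_select(ev$fitness, control$tournament_size)]]
      pb <- pop[[tournament_select(ev$fitness, control$tournament_size)]]
      kids <- single_point_crossover(pa, pb, control$crossover_prob)
      for (kid in kids) {
        if (k >= np) break
        k <- k + 1L
        offspring[[k]] <- integer_flip_mutation(kid, control$mutation_prob)
      }
    }
    pop <- offspring
    ev <- eval_pop(pop)
    gi <- which.min(ev$fitness)
    if (ev$fitness[gi] < best$fitness)
      best <- list(genotype = pop[[gi]], fitness = ev$fitness[gi],
                   phenotype = ev$phenotype[gi])
    log_rows[[gen + 1L]] <- snapshot(gen, ev)
  }
  best$expression <- if (!is.na(best$phenotype))
    parse_predictor(best$phenotype) else NULL
  structure(list(best = best,
                 log = do.call(rbind, log_rows),
                 population = pop,
                 control = control),
            class = "ge_run")
}

#' @export
print.ge_run <- function(x, ...) {
  cat(sprintf("<ge_run> %d generations, best fitness %.4g\n  %s\n",
              max(x$log$generation), x$best$fitness, x$best$phenotype))
  invisible(x)
}
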