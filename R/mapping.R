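#' Genotype-phenotype mapping
#'
#' Standard grammatical-evolution mapping: the leftmost non-terminal of the
#' derivation is repeatedly expanded; at every choice point (a rule with
#' more than one production) the next codon selects the production as
#' `codon mod n_productions`, consuming codons left to right.  Rules with
#' a single production consume no codon.  When the codon string is
#' exhausted it is reused from the start ("wrapping") at most `max_wraps`
#' additional times; if non-terminals remain after that, the mapping is
#' invalid.  Invalidity is a value, not an error.
#'
#' @param genotype integer vector of codons in `[0, 255]` (length >= 1).
#' @param grammar a [load_grammar()] object.
#' @param max_wraps maximum number of additional passes over the genotype
#'   (default 2).
#' @return A list of class `ge_mapping` with elements `phenotype` (the
#'   derived terminal string, or `NA_character_` when invalid), `valid`,
#'   `codons_consumed` and `wraps_used`.
#' @examples
#' g <- load_grammar("[S] ::= a | b")
#' map_genotype(7, g)$phenotype   # 7 mod 2 = 1 -> "b"
#' @export
map_genotype <- function(genotype, grammar, max_wraps = 2L) {
  stopifnot(inherits(grammar, "ge_grammar"))
  genotype <- as.integer(genotype)
  if (length(genotype) < 1L || anyNA(genotype) ||
      any(genotype < 0L | genotype > 255L))
    stop("'genotype' must be a non-empty vector of codons in [0, 255]")
  ncod <- length(genotype)
  cp <- 0L            # codons consumed so far (within current pass count)
  wraps <- 0L
  limit <- (max_wraps + 1L) * ncod
  # stack of pending symbols, leftmost on top
  stack <- list(list(type = "nt", value = grammar$start))
  out <- character(0)
  expansions <- 0L
  max_expansions <- 200000L
  invalid <- FALSE
  while (length(stack)) {
    expansions <- expansions + 1L
    if (expansions > max_expansions) { invalid <- TRUE; break }
    tok <- stack[[1L]]
    stack <- stack[-1L]
    if (tok$type == "t") { out[length(out) + 1L] <- tok$value; next }
    prods <- grammar$rules[[tok$value]]
    if (length(prods) == 1L) {
      choice <- 1L
    } else {
      if (cp >= limit) { invalid <- TRUE; break }
      codon <- genotype[(cp %% ncod) + 1L]
      cp <- cp + 1L
      choice <- (codon %% length(prods)) + 1L
    }
    rep_toks <- prods[[choice]]
    if (length(rep_toks)) stack <- c(rep_toks, stack)
  }
  wraps <- if (cp == 0L) 0L else (cp - 1L) %/% ncod
  if (invalid) wraps <- max_wraps
  structure(list(
    phenotype = if (invalid) NA_character_ else paste(out, collapse = ""),
    valid = !invalid,
    codons_consumed = cp,
    wraps_used = as.integer(wraps)
  ), class = "ge_mapping")
}

#' @export
print.ge_mapping <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<ge_mapping> valid, %d codons consumed, %d wrap(s)\n  %s\n",
                x$codons_consumed, x$wraps_used, x$phenotype))
  else
    cat(sprintf("<ge_mapping> INVALID after %d wrap(s)\n", x$wraps_used))
  invisible(x)
}

#' Random genotype initialization
#'
#' Draws a variable-length codon string: the length is uniform on
#' `[min_len, max_len]` and each codon uniform on `[0, 255]`.  Uses R's
#' global random-number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param min_len,max_len inclusive length bounds (`1 <= min_len <=
#'   max_len`).
#' @return Integer vector of codons.
#' @export
random_genotype <- function(min_len = 15L, max_len = 100L) {
  if (!(min_len >= 1L && min_len <= max_len))
    stop("need 1 <= min_len <= max_len")
  len <- if (min_len == max_len) min_len else
    sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
  sample(0:255, len, replace = TRUE)
}

#' Reference genotypes for grammar-derivable baselines
#'
#' `persistence_genotype()` returns the codon string that derives the
#' persistence predictor `ExprG=(GetG(0,24,+,,(01.0),(00.0))++)+` under
#' the shipped glucose grammar: the current CGM value, unchanged, as the
#' 120-min forecast.  It is injected into the initial population so the
#' evolved model never underperforms this clinical baseline.
#'
#' @return Integer codon vector.
#' @export
persistence_genotype <- function() {
  # choices, leftmost derivation: [G]->GetG (0), PrevIni=0 (0),
  # PrevFin=24 (12), op->OpA (0), OpA->+ (0), preop->λ (7),
  # scale 01.0 (0,1,0), offset 00.0 (0,0,0), [G]->λ (1),
  # op1 + (0,0), [Ra]->λ (1), op2 + (0,0), [IOB]->λ (1),
  # op3 + (0,0), [Circadian]->λ (1)
  as.integer(c(0, 0, 12, 0, 0, 7, 0, 1, 0, 0, 0, 0, 1,
               0, 0, 1, 0, 0, 1, 0, 0, 1))
}
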