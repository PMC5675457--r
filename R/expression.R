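# Predictor expressions: parsing of grammar phenotypes and protected
# evaluation on the aligned (G, Ra, IOB) 5-min signal triplet.

PREOPS <- c("sqrt", "sin", "log", "pow", "exp", "cos")

# Protected unary operators.  Standard genetic-programming protection:
# every expression the grammar can produce evaluates to a finite number on
# finite inputs, so fitness is always defined.
protected_unary <- function(opname, x) {
  switch(opname,
    sqrt = sqrt(abs(x)),
    sin  = sin(x),
    cos  = cos(x),
    log  = ifelse(x == 0, 0, log(abs(x))),
    exp  = exp(pmin(pmax(x, -50), 50)),
    pow  = pmin(pmax(x * x, -1e10), 1e10),  # unary context: squaring
    stop("unknown pre-operator: ", opname))
}

protected_binary <- function(opname, a, b) {
  switch(opname,
    "+" = a + b,
    "-" = a - b,
    "*" = a * b,
    "/" = { r <- a / b; r[rep_len(b == 0, length(r))] <- 1; r },
    stop("unknown operator: ", opname))
}

op_neutral <- function(opname) if (opname %in% c("+", "-")) 0 else 1

# Maximum circadian amplitude (mg/dl): 20% of a nominal 150 mg/dl mean
# CGM level; keeps day-to-day modulation within a 20% band.
CIRCADIAN_AMP_MAX <- 30

#' Parse a phenotype string into a predictor expression
#'
#' Converts a sentence of the shipped glucose grammar (the `phenotype` of a
#' valid [map_genotype()] result) into a structured predictor: three lists
#' of lagged signal terms (CGM, Ra, IOB), the operators joining the blocks
#' and an optional circadian sinusoid.  A term `GetX(l0,l1,op,pre,(a),(d))`
#' reads `X[n - l0]` (lags in 5-min samples), divides by `a`, applies the
#' pre-operator chain `pre` (outermost first) and combines with `d` under
#' `op`; the terms of a block are summed.  The lag window must satisfy
#' `l0 < l1`; a violating term makes the whole expression invalid
#' (returned as `NULL`).
#'
#' @param phenotype character string produced by the glucose grammar.
#' @return A list of class `predictor_expression`, or `NULL` when the
#'   sentence violates the lag-window constraint.
#' @export
parse_predictor <- function(phenotype) {
  if (is.na(phenotype)) return(NULL)
  s <- phenotype
  fail <- function(msg) stop("cannot parse phenotype: ", msg, " at: ",
                             substr(s, 1, 40))
  eat <- function(lit) {
    if (!startsWith(s, lit)) fail(paste0("expected '", lit, "'"))
    s <<- substr(s, nchar(lit) + 1L, nchar(s))
  }
  term_re <- paste0("^Get(G|Ra|IOB)\\((\\d+),(\\d+),([+*/-]),([a-z]*),",
                    "\\((\\d\\d\\.\\d)\\),\\((\\d\\d\\.\\d)\\)\\)")
  bad_lag <- FALSE
  parse_terms <- function(source) {
    terms <- list()
    repeat {
      m <- regmatches(s, regexec(term_re, s))[[1]]
      if (!length(m) || m[2] != source) break
      s <<- substr(s, nchar(m[1]) + 1L, nchar(s))
      lag0 <- as.integer(m[3]); lag1 <- as.integer(m[4])
      if (lag0 >= lag1) bad_lag <<- TRUE
      terms[[length(terms) + 1L]] <- list(
        source = source, lag = lag0, lag_end = lag1,
        offset_op = m[5], preops = split_preops(m[6]),
        scale = as.numeric(m[7]), offset = as.numeric(m[8]))
    }
    terms
  }
  parse_op <- function() {
    ch <- substr(s, 1, 1)
    if (!ch %in% c("+", "-", "*", "/")) fail("expected operator")
    s <<- substr(s, 2L, nchar(s))
    ch
  }
  eat("ExprG=(")
  g_terms <- parse_terms("G")
  op1 <- parse_op()
  ra_terms <- parse_terms("Ra")
  op2 <- parse_op()
  iob_terms <- parse_terms("IOB")
  eat(")")
  op3 <- parse_op()
  circ <- NULL
  circ_re <- paste0("^GetCircadian\\(([*/]),\\((\\d\\d\\.\\d)\\),",
                    "\\((\\d\\d\\.\\d)\\),\\((\\d\\d\\.\\d)\\)\\)")
  mc <- regmatches(s, regexec(circ_re, s))[[1]]
  if (length(mc)) {
    s <- substr(s, nchar(mc[1]) + 1L, nchar(s))
    circ <- list(combine_op = mc[2],
                 amplitude = min(as.numeric(mc[3]), CIRCADIAN_AMP_MAX),
                 angular_freq = as.numeric(mc[4]) * 2 * pi / 288,
                 phase = as.numeric(mc[5]))
  }
  if (nzchar(s)) fail("trailing text")
  if (bad_lag) return(NULL)
  structure(list(g_terms = g_terms, ra_terms = ra_terms,
                 iob_terms = iob_terms, ops = c(op1, op2, op3),
                 circadian = circ, phenotype = phenotype),
            class = "predictor_expression")
}

split_preops <- function(txt) {
  out <- character(0)
  while (nzchar(txt)) {
    hit <- PREOPS[startsWith(txt, PREOPS)]
    if (!length(hit)) stop("unknown pre-operator text: ", txt)
    out <- c(out, hit[1])
    txt <- substr(txt, nchar(hit[1]) + 1L, nchar(txt))
  }
  out
}

#' @export
print.predictor_expression <- function(x, ...) {
  cat("<predictor_expression>\n  ", x$phenotype, "\n", sep = "")
  invisible(x)
}

#' Maximum lag (in 5-min samples) used by an expression
#' @param expr a `predictor_expression`.
#' @export
expression_max_lag <- function(expr) {
  lags <- vapply(c(expr$g_terms, expr$ra_terms, expr$iob_terms),
                 function(t) t$lag, numeric(1))
  if (length(lags)) max(lags) else 0
}

eval_block <- function(terms, values, n, joining_op) {
  if (!length(terms)) return(rep(op_neutral(joining_op), length(n)))
  acc <- 0
  for (tm in terms) {
    x <- values[[tm$source]][n - tm$lag]
    v <- protected_binary("/", x, tm$scale)
    for (p in rev(tm$preops)) v <- protected_unary(p, v)
    v <- protected_binary(tm$offset_op, v, tm$offset)
    acc <- acc + v
  }
  acc
}

#' Evaluate a predictor expression
#'
#' Computes the predicted CGM value for each requested sample index `n`.
#' The three signals must share the 5-min grid (same start time, period
#' and length); lags are taken in samples of that grid, so every `n` must
#' leave at least `expression_max_lag(expr)` samples of history.  The
#' value at `n` is the forecast of the CGM reading one prediction horizon
#' (by convention 24 samples = 120 min) ahead of `n`.  All arithmetic is
#' protected, so the result is finite for finite inputs.
#'
#' @param expr a [parse_predictor()] expression.
#' @param g,ra,iob aligned [uniform_signal()]s (CGM mg/dl, Ra, IOB), or
#'   plain numeric vectors of equal length.
#' @param n integer vector of 1-based sample indices at which to evaluate.
#' @return Numeric vector of predictions, one per element of `n`.
#' @export
evaluate_predictor <- function(expr, g, ra, iob, n) {
  stopifnot(inherits(expr, "predictor_expression"))
  sigs <- list(G = g, Ra = ra, IOB = iob)
  vals <- lapply(sigs, function(x) {
    if (inherits(x, "uniform_signal")) x$values else as.numeric(x)
  })
  meta <- lapply(sigs, function(x)
    if (inherits(x, "uniform_signal")) c(x$t0, x$dt, length(x$values)) else NULL)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta) > 1L && !all(vapply(meta, identical, logical(1), meta[[1]])))
    stop("signals are not aligned (start time, period and length must match)")
  nv <- vapply(vals, length, integer(1))
  if (length(unique(nv)) != 1L)
    stop("signals are not aligned (lengths differ)")
  n <- as.integer(n)
  if (any(n - expression_max_lag(expr) < 1L) || any(n > nv[1]))
    stop("sample indices leave insufficient history for the expression")
  b_g  <- eval_block(expr$g_terms,  vals, n, expr$ops[1])
  b_ra <- eval_block(expr$ra_terms, vals, n, expr$ops[1])
  b_io <- eval_block(expr$iob_terms, vals, n, expr$ops[2])
  core <- protected_binary(expr$ops[2],
                           protected_binary(expr$ops[1], b_g, b_ra), b_io)
  if (is.null(expr$circadian)) {
    circ <- rep(op_neutral(expr$ops[3]), length(n))
  } else {
    cc <- expr$circadian
    wave <- cos(cc$angular_freq * n + cc$phase)
    circ <- protected_binary(cc$combine_op, cc$amplitude, wave)
  }
  out <- protected_binary(expr$ops[3], core, circ)
  out[!is.finite(out)] <- 0  # belt and braces; protection should prevent this
  out
}
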