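#' Parse a BNF grammar
#'
#' Reads a context-free grammar in Backus-Naur form.  Non-terminals are
#' written in square brackets (`[G]`); a rule is
#' `[symbol] ::= production | production | ...` (the arrow form
#' `[symbol] -> ...` is also accepted).  Everything outside brackets is
#' terminal text, kept verbatim (including commas and parentheses).  The
#' token `λ` (or `<empty>`) denotes the empty production.  Rule order and
#' production order are preserved exactly: the codon arithmetic of the
#' genotype-phenotype mapping depends on them.  Lines starting with `#`
#' are comments; a rule must fit on one line.
#'
#' @param text grammar source, as a single string or character vector of
#'   lines.
#' @return An object of class `ge_grammar`: a named list of rules, each a
#'   list of productions, each production a list of tokens
#'   (`list(type = "nt"|"t", value = ...)`), plus the start symbol (the
#'   first rule).
#' @seealso [glucose_grammar()] for the grammar shipped with the package.
#' @export
load_grammar <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty grammar")
  rules <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\[([^]]+)\\]\\s*(::=|->|→)\\s*(.*)$", ln))[[1]]
    if (length(m) != 4L)
      stop("malformed grammar rule: ", ln)
    sym <- m[2]
    rhs <- m[3 + 1]
    alts <- strsplit(rhs, "|", fixed = TRUE)[[1]]
    if (!length(alts) || !nzchar(trimws(rhs)))
      stop("empty production list for symbol [", sym, "]")
    prods <- lapply(alts, function(a) tokenize_production(trimws(a)))
    if (!is.null(rules[[sym]]))
      stop("duplicate rule for symbol [", sym, "]")
    rules[[sym]] <- prods
  }
  gr <- structure(list(rules = rules, start = names(rules)[1]),
                  class = "ge_grammar")
  # every referenced non-terminal must be defined
  for (sym in names(rules)) {
    for (p in rules[[sym]]) {
      for (tok in p) {
        if (tok$type == "nt" && is.null(rules[[tok$value]]))
          stop("undefined non-terminal [", tok$value,
               "] referenced from rule [", sym, "]")
      }
    }
  }
  gr
}

tokenize_production <- function(s) {
  if (s == "λ" || s == "<empty>" || s == "") return(list())
  toks <- list()
  buf <- ""
  i <- 1L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in production: ", s)
      if (nzchar(buf)) { toks[[length(toks) + 1L]] <- list(type = "t", value = buf); buf <- "" }
      toks[[length(toks) + 1L]] <-
        list(type = "nt", value = paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else {
      buf <- paste0(buf, chars[i])
      i <- i + 1L
    }
  }
  if (nzchar(buf)) toks[[length(toks) + 1L]] <- list(type = "t", value = buf)
  toks
}

#' @export
print.ge_grammar <- function(x, ...) {
  cat(sprintf("<ge_grammar> %d rules, start symbol [%s]\n",
              length(x$rules), x$start))
  for (sym in names(x$rules))
    cat(sprintf("  [%s]: %d production(s)\n", sym, length(x$rules[[sym]])))
  invisible(x)
}

#' The glucose predictor grammar shipped with the package
#'
#' Loads `glucose.bnf` from the package installation: the grammar whose
#' sentences are mid-term glucose predictors combining lagged CGM, meal
#' rate-of-appearance and insulin-on-board terms with an optional
#' circadian sinusoid.
#'
#' @return A `ge_grammar` object.
#' @export
glucose_grammar <- function() {
  path <- system.file("extdata", "glucose.bnf", package = "glucoge",
                      mustWork = TRUE)
  load_grammar(readLines(path, encoding = "UTF-8"))
}
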