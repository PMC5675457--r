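test_that("the persistence phenotype evaluates to the current CGM value", {
  g <- glucose_grammar()
  m <- map_genotype(persistence_genotype(), g)
  expect_true(m$valid)
  expect_identical(m$phenotype, "ExprG=(GetG(0,24,+,,(01.0),(00.0))++)+")
  expr <- parse_predictor(m$phenotype)
  sig <- synthetic_inputs(300)
  ns <- 25:276
  expect_equal(evaluate_predictor(expr, sig$g, sig$ra, sig$iob, ns),
               sig$g[ns])
})

test_that("a multi-block worked phenotype is grammar-derivable and matches
           hand evaluation on constant inputs", {
  g <- glucose_grammar()
  # structure mirroring the published worked example: a summed multi-term
  # CGM block with log/pow pre-operators, sin terms on the Ra and IOB
  # blocks, and a circadian sinusoid combined multiplicatively
  choices <- c(
    1,                        # [G] -> GetG [G]
    13, 13,                   # PrevIni 22, PrevFin 24
    2, 2,                     # op -> OpB -> *
    3,                        # preop -> log
    6, 8, 10,                 # scale (57.9)
    1, 4, 8,                  # offset (03.7)
    1,                        # [G] -> GetG [G]  (second term)
    1, 13,                    # PrevIni 0, PrevFin 24
    1, 1,                     # op -> OpA -> +
    4,                        # preop -> pow
    1, 3, 1,                  # scale (02.0)
    6, 8, 8,                  # offset (57.7)
    2,                        # [G] -> λ
    1, 1,                     # op1 -> OpA -> +
    1,                        # [Ra] -> GetRa [Ra]
    3, 13,                    # PrevIni 2, PrevFin 24
    1, 2,                     # op -> OpA -> -
    2,                        # preop -> sin
    1, 3, 8,                  # scale (02.7)
    10, 1, 1,                 # offset (90.0)
    2,                        # [Ra] -> λ
    2, 2,                     # op2 -> OpB -> *
    1,                        # [IOB] -> GetIOB [IOB]
    1, 4,                     # PrevIni 0, PrevFin 6
    1, 2,                     # op -> OpA -> -
    2,                        # preop -> sin
    1, 5, 2,                  # scale (04.1)
    1, 3, 1,                  # offset (02.0)
    2,                        # [IOB] -> λ
    1, 2,                     # op3 -> OpA -> -
    1,                        # [Circadian] -> GetCircadian
    2,                        # OpB -> *
    2, 10, 10,                # amplitude (19.9)
    1, 6, 6,                  # frequency constant (05.5)
    1, 1, 1)                  # phase (00.0)
  oracle <- derive_phenotype(g, choices)
  expect_identical(
    oracle$phenotype,
    paste0("ExprG=(GetG(22,24,*,log,(57.9),(03.7))",
           "GetG(0,24,+,pow,(02.0),(57.7))+",
           "GetRa(2,24,-,sin,(02.7),(90.0))*",
           "GetIOB(0,6,-,sin,(04.1),(02.0)))-",
           "GetCircadian(*,(19.9),(05.5),(00.0))"))
  mapped <- map_genotype(as.integer(choices - 1), g)
  expect_identical(mapped$phenotype, oracle$phenotype)

  expr <- parse_predictor(mapped$phenotype)
  n <- 30L
  g_const <- rep(100, 60); ra_const <- rep(2, 60); iob_const <- rep(1.5, 60)
  got <- evaluate_predictor(expr, g_const, ra_const, iob_const, n)
  # hand evaluation under the package's term semantics
  g_block <- (log(100 / 57.9) * 3.7) + ((100 / 2)^2 + 57.7)
  ra_block <- sin(2 / 2.7) - 90
  iob_block <- sin(1.5 / 4.1) - 2
  circ <- 19.9 * cos(5.5 * 2 * pi / 288 * n + 0)
  expect_equal(got, ((g_block + ra_block) * iob_block) - circ)
})

test_that("protected operators keep every evaluation finite", {
  pu <- glucoge:::protected_unary
  expect_equal(pu("log", 0), 0)
  expect_equal(pu("log", -10), log(10))
  expect_equal(pu("sqrt", -4), 2)
  expect_equal(pu("exp", 1000), exp(50))
  expect_equal(pu("exp", -1000), exp(-50))
  expect_equal(pu("pow", 1e9), 1e10)    # clipped square
  pb <- glucoge:::protected_binary
  expect_equal(pb("/", 5, 0), 1)
  expect_equal(pb("/", c(1, 2), c(0, 2)), c(1, 1))

  # closure: random valid expressions evaluate finite on positive signals
  g <- glucose_grammar()
  sig <- synthetic_inputs(200, seed = 7)
  set.seed(8)
  n_checked <- 0
  while (n_checked < 50) {
    m <- map_genotype(random_genotype(20, 90), g)
    if (!m$valid) next
    expr <- parse_predictor(m$phenotype)
    if (is.null(expr)) next   # lag-window violation
    v <- evaluate_predictor(expr, sig$g, sig$ra, sig$iob, 25:176)
    expect_true(all(is.finite(v)))
    n_checked <- n_checked + 1
  }
})

test_that("protected log handles zero-valued signal samples in terms", {
  g <- glucose_grammar()
  # log term reading the Ra signal, which is exactly zero before meals
  ph <- paste0("ExprG=(GetG(0,24,+,,(01.0),(00.0))+",
               "GetRa(0,1,+,log,(01.0),(00.0))+)+")
  expr <- parse_predictor(ph)
  v <- evaluate_predictor(expr, rep(100, 60), rep(0, 60), rep(0, 60), 30)
  expect_true(is.finite(v))
  expect_equal(v, 100)   # log contribution collapses to 0
})

test_that("lag-window violations invalidate the expression as a value", {
  ph_bad <- "ExprG=(GetG(22,22,+,,(01.0),(00.0))++)+"
  expect_null(parse_predictor(ph_bad))
  ph_ok <- "ExprG=(GetG(20,22,+,,(01.0),(00.0))++)+"
  expect_s3_class(parse_predictor(ph_ok), "predictor_expression")
  expect_null(parse_predictor(NA_character_))
})

test_that("misaligned signals and missing history are rejected", {
  expr <- parse_predictor("ExprG=(GetG(22,24,+,,(01.0),(00.0))++)+")
  s1 <- uniform_signal(rep(100, 50), t0 = 0, dt = 5)
  s2 <- uniform_signal(rep(1, 50), t0 = 0, dt = 1)
  expect_error(evaluate_predictor(expr, s1, s2, s1, 30), "aligned")
  expect_error(evaluate_predictor(expr, rep(100, 50), rep(1, 40),
                                  rep(1, 50), 30), "aligned")
  expect_error(evaluate_predictor(expr, rep(100, 50), rep(1, 50),
                                  rep(1, 50), 10), "history")
})

test_that("circadian amplitude is clipped to the day-to-day bound", {
  ph <- "ExprG=(GetG(0,24,+,,(01.0),(00.0))++)-GetCircadian(*,(99.9),(01.0),(00.0))"
  expr <- parse_predictor(ph)
  expect_equal(expr$circadian$amplitude, 30)
  v <- evaluate_predictor(expr, rep(100, 300), rep(0, 300), rep(0, 300),
                          25:280)
  expect_true(all(abs(v - 100) <= 30 + 1e-9))
})
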