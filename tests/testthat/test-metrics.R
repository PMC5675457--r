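test_that("the clinical penalty is bounded, near-unit at midrange, and
           ranks missed hypoglycemia above conservative hyperglycemia", {
  expect_equal(pen(120, 120), 1, tolerance = 0.01)
  expect_gt(pen(50, 75), pen(175, 150))
  expect_gt(pen(50, 75), 2)      # strongly penalized
  # bounds over a dense grid
  grid <- expand.grid(g = seq(21, 400, by = 2), gh = seq(1, 400, by = 2))
  p <- pen(grid$g, grid$gh)
  expect_true(all(p >= 1))
  expect_true(all(p <= 1 + 1.5 + 1))
  expect_error(pen(-5, 100), "positive")
  expect_error(pen_params(t_l = 200, t_h = 100))
})

test_that("the penalty is continuous and directionally monotone", {
  # continuity: small input perturbations give small penalty changes
  g0 <- seq(30, 390, by = 3)
  for (gh in c(40, 120, 300)) {
    d <- abs(pen(g0 + 0.1, gh) - pen(g0, gh))
    expect_true(all(d < 0.02))
  }
  # hypoglycemic reference: penalty rises as the prediction overestimates
  # (strict over the clinically relevant error band, before both logistic
  # transitions saturate)
  overs <- pen(50, seq(50, 105, by = 5))
  expect_true(all(diff(overs) > 0))
  expect_gt(pen(50, 120), pen(50, 55))
  # hyperglycemic reference: penalty rises as the prediction underestimates
  unders <- pen(250, seq(250, 150, by = -5))
  expect_true(all(diff(unders) > 0))
})

test_that("gMSE is the mean of pointwise penalized squared errors", {
  expect_equal(gmse(c(100, 120), c(100, 120)), 0)
  # midrange small errors: penalty is inactive, gMSE collapses to MSE
  g <- c(115, 120, 125); gh <- g + c(2, -3, 1)
  mse <- mean((g - gh)^2)
  expect_equal(gmse(g, gh), mse, tolerance = 0.01)
  expect_gte(gmse(g, gh), mse)
  # two-point mixed series: manual pointwise evaluation is the oracle
  g2 <- c(50, 175); gh2 <- c(75, 150)
  manual <- mean(pen(g2, gh2) * (g2 - gh2)^2)
  expect_equal(gmse(g2, gh2), manual)
  expect_gt(gmse(g2, gh2), mean((g2 - gh2)^2))
  expect_error(gmse(numeric(0), numeric(0)), "empty")
})

test_that("metric suite matches closed forms and ordering invariants", {
  g <- rep(100, 12); gh <- g - 10
  m <- glucose_metrics(g, gh)
  expect_equal(m$rmse, 10)
  expect_equal(m$mad, 10)
  expect_equal(m$mard, 10)
  z <- glucose_metrics(g, g)
  expect_equal(unlist(z[c("rmse", "g_rmse", "mad", "g_mad",
                          "mard", "g_mard")]),
               c(rmse = 0, g_rmse = 0, mad = 0, g_mad = 0,
                 mard = 0, g_mard = 0))
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    gr <- runif(n, 40, 350)
    gp <- pmax(1, gr + rnorm(n, 0, 25))
    mm <- glucose_metrics(gr, gp)
    expect_gte(mm$rmse, mm$mad)
    expect_gte(mm$g_rmse, mm$rmse)
    expect_gte(mm$g_mad, mm$mad)
    expect_gte(mm$g_mard, mm$mard)
  }
})

test_that("error-grid classification matches the canonical inequalities", {
  expect_identical(ceg_classify(100, 100), "A")
  expect_identical(ceg_classify(65, 60), "A")     # both below 70
  expect_identical(ceg_classify(200, 100), "B")
  expect_identical(ceg_classify(150, 300), "C")   # overtreatment
  expect_identical(ceg_classify(50, 120), "D")    # missed hypoglycemia
  expect_identical(ceg_classify(250, 50), "E")
  expect_error(ceg_classify(0, 100), "positive")
  # independent scalar re-implementation of the published boundaries
  oracle <- function(y, yp) {
    y <- min(y, 400); yp <- min(yp, 400)
    if ((y <= 70 && yp <= 70) || (yp <= 1.2 * y && yp >= 0.8 * y)) return("A")
    if ((y >= 180 && yp <= 70) || (y <= 70 && yp >= 180)) return("E")
    if ((y >= 70 && y <= 290 && yp >= y + 110) ||
        (y >= 130 && y <= 180 && yp <= (7 / 5) * y - 182)) return("C")
    if ((y >= 240 && yp >= 70 && yp <= 180) ||
        (y <= 175 / 3 && yp <= 180 && yp >= 70) ||
        (y >= 175 / 3 && y <= 70 && yp >= (6 / 5) * y)) return("D")
    "B"
  }
  lat <- expand.grid(y = seq(5, 400, by = 5), yp = seq(5, 400, by = 5))
  got <- ceg_classify(lat$y, lat$yp)
  want <- mapply(oracle, lat$y, lat$yp)
  expect_identical(got, unname(want))
  expect_false(anyNA(got))   # every pair classified exactly once
})

test_that("non-boundary pairs are stable to sub-mg/dl perturbation", {
  set.seed(12)
  y <- runif(400, 10, 390); yp <- runif(400, 10, 390)
  z0 <- ceg_classify(y, yp)
  for (d in c(-0.4, 0.4)) {
    zd <- ceg_classify(y + d, yp)
    same <- zd == z0
    # allow changes only for pairs within 1 mg/dl of a zone boundary,
    # detected by a coarse probe
    near <- ceg_classify(y + 1, yp) != ceg_classify(y - 1, yp)
    expect_true(all(same | near))
  }
})

test_that("error-grid summaries count zones and close to 100 percent", {
  s <- ceg_summary(rep(120, 8), rep(120, 8))
  expect_equal(unname(s$percent["A"]), 100)
  expect_equal(s$ab_percent, 100)
  set.seed(2)
  gr <- runif(10, 40, 350); gp <- runif(10, 40, 350)
  s2 <- ceg_summary(gr, gp)
  expect_equal(sum(s2$percent), 100)
  expect_equal(sum(s2$counts), 10L)
  labels <- ceg_classify(gr, gp)
  for (z in c("A", "B", "C", "D", "E"))
    expect_identical(unname(s2$counts[z]), sum(labels == z))
})
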