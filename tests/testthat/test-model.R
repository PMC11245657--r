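# simulate a simple case-control-free logistic data set
sim_logistic <- function(n, beta, intercept = -1, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- intercept + as.numeric(x %*% beta)
  y <- rbinom(n, 1, inv_logit(eta))
  list(x = as.data.frame(x), y = y)
}

test_that("lasso screening reduces to the unpenalized fit at zero penalty", {
  d <- sim_logistic(4000, c(1.2, -0.8, 0.5, 0), seed = 2)
  scr <- lasso_screen(d$x, d$y, penalty = 0)
  ref <- glm(d$y ~ ., data = d$x, family = binomial())
  expect_setequal(scr$selected, paste0("x", 1:4))
  expect_equal(unname(scr$coefficients[paste0("x", 1:4)]),
               unname(coef(ref)[paste0("x", 1:4)]), tolerance = 1e-4)
})

test_that("lasso screening shrinks to the empty set at a huge penalty", {
  d <- sim_logistic(2000, c(1.2, -0.8), seed = 3)
  scr <- lasso_screen(d$x, d$y, penalty = 10)
  expect_length(scr$selected, 0)
})

test_that("lasso screening rejects degenerate outcomes and tiny designs", {
  d <- sim_logistic(500, c(1, 0.5), seed = 4)
  expect_error(lasso_screen(d$x, rep(0, 500)), "degenerate")
  expect_error(lasso_screen(d$x["x1"], d$y), "at least 2")
})

test_that("cross-validated lasso keeps a strong predictor across replicates", {
  hits <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 5000
    x <- matrix(rbinom(n * 11, 1, 0.3), n, 11,
                dimnames = list(NULL, c("strong", paste0("noise", 1:10))))
    y <- rbinom(n, 1, inv_logit(-2 + 1.5 * x[, "strong"]))
    scr <- lasso_screen(as.data.frame(x), y, seed = r)
    hits <- hits + ("strong" %in% scr$selected)
  }
  expect_gte(hits, 19L)
})

test_that("correlation filter flags pairs at the threshold and keeps priority", {
  set.seed(9)
  n <- 10000
  a <- rbinom(n, 1, 0.4)
  m <- data.frame(a = a, dup = a, b = rbinom(n, 1, 0.4),
                  konst = rep(1, n))
  res <- correlation_filter(m, threshold = 0.60, priority = c("a", "dup", "b"))
  expect_true(any(res$flagged$correlation == 1))
  expect_true("dup" %in% res$dropped)
  expect_true(all(c("a", "b") %in% res$retained))
  expect_equal(res$undefined, "konst")
  # independent columns at n = 10,000 are never near |r| = 0.6
  expect_false(any(apply(res$flagged[c("var1", "var2")], 1,
                         function(p) "b" %in% p)))
  # orthogonal 2x2 design has r = 0
  m2 <- data.frame(u = c(0, 0, 1, 1), v = c(0, 1, 0, 1))
  expect_equal(nrow(correlation_filter(m2)$flagged), 0L)
  expect_error(correlation_filter(m, selected = "nope"), "subset")
})

test_that("logistic fitting recovers closed forms and flags degeneracies", {
  # intercept-only: prevalence 0.2
  y <- rep(c(1, 0), c(20, 80))
  m0 <- fit_logistic(data.frame(z = rnorm(100)), y, predictors = character(0))
  expect_equal(m0$intercept, logit(0.2), tolerance = 1e-8)
  # constant predictor dropped with a warning, never silently
  d <- sim_logistic(2000, 1, seed = 5)
  d$x$flat <- 1
  expect_warning(fit_logistic(d$x, d$y), "constant")
  # complete separation raises an error naming a predictor
  xs <- data.frame(sep = c(rep(0, 50), rep(1, 50)))
  ys <- c(rep(0, 50), rep(1, 50))
  expect_error(suppressWarnings(fit_logistic(xs, ys)), "sep")
})

test_that("fitted slopes recover the generating coefficients", {
  d <- sim_logistic(20000, c(1, -0.7), intercept = -2, seed = 6)
  m <- fit_logistic(d$x, d$y)
  for (i in 1:2) {
    b <- m$coefficients[[paste0("x", i)]]
    s <- m$se[[paste0("x", i)]]
    expect_lt(abs(b - c(1, -0.7)[i]), 3 * s)
  }
  expect_equal(unname(m$odds_ratios["x1"]), exp(m$coefficients[["x1"]]))
  # diagnostics are populated and coherent
  cs <- m$diagnostics$c_statistic
  expect_true(cs$ci_lower <= cs$c_statistic && cs$c_statistic <= cs$ci_upper)
  expect_equal(sum(m$diagnostics$calibration$n), length(d$y))
})

test_that("backward selection eliminates noise and never worsens its criterion", {
  set.seed(17)
  n <- 20000
  x <- as.data.frame(matrix(rbinom(n * 6, 1, 0.3), n, 6,
                            dimnames = list(NULL, c("t1", "t2", paste0("n", 1:4)))))
  y <- rbinom(n, 1, inv_logit(-2 + 1.1 * x$t1 - 0.9 * x$t2))
  m <- backward_select(x, y, names(x), criterion = "BIC")
  expect_true(all(c("t1", "t2") %in% names(m$coefficients)))
  expect_true(all(diff(m$selection_trace$criterion) <= 0))
  expect_lt(length(m$coefficients), 6L)
  # a strong lone predictor survives: removing it would worsen the criterion
  m1 <- backward_select(x, y, "t1", criterion = "AIC")
  expect_equal(names(m1$coefficients), "t1")
  null_aic <- fit_logistic(x, y, character(0))$aic
  expect_lt(m1$aic, null_aic)
  expect_error(backward_select(x, y, character(0)), "nonempty")
})
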