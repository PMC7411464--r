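make_cohort <- function(n, hr = 1, seed = 1, censor = 0.02) {
  expr <- generate_expression("G1", n, 0, seed = seed)
  expr["G1", ] <- withr::with_seed(seed + 1000, rbinom(n, 1, 0.5))
  cl <- generate_survival(expr, c(G1 = log(hr)), baseline_hazard = 0.05,
                          censor_rate = censor, seed = seed + 2000)
  list(expr = expr, clinical = cl)
}

test_that("Cox coefficient matches a grid maximum of the Efron partial likelihood", {
  # 10-subject toy cohort with tied event times
  time <- c(2, 2, 3, 5, 5, 5, 8, 9, 12, 15)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1)
  x <- c(1.2, 0.3, -0.5, 0.8, 1.5, 0.1, -0.2, 0.9, -1.0, -0.3)
  cl <- tibble::tibble(sample_id = sprintf("S%02d", 1:10), time = time, event = event)
  fit <- fit_cox_univariate(setNames(x, cl$sample_id), cl)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event, x = x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Cox errors on constant covariates and too few events", {
  cl <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                       time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 0, 1))
  expect_error(fit_cox_univariate(setNames(rep(2, 6), cl$sample_id), cl),
               "no information")
  cl2 <- dplyr::mutate(cl, event = c(1, 0, 0, 0, 0, 0))
  expect_error(fit_cox_univariate(setNames(rnorm(6), cl2$sample_id), cl2),
               ">= 2")
})

test_that("planted hazard ratio of 3 is recovered at n = 300", {
  hrs <- vapply(1:20, function(s) {
    d <- make_cohort(300, hr = 3, seed = s)
    fit_cox_univariate(setNames(d$expr["G1", ], colnames(d$expr)),
                       d$clinical, "G1")$hr
  }, numeric(1))
  expect_gte(median(hrs), 2.4)
  expect_lte(median(hrs), 3.8)
})

test_that("null covariates reject at roughly the nominal 5% level", {
  rejections <- 0L
  total <- 0L
  for (s in 1:20) {
    genes <- sprintf("G%02d", 1:10)
    expr <- generate_expression(genes, 150, 0, seed = 300 + s)
    cl <- generate_survival(expr, numeric(), baseline_hazard = 0.05,
                            censor_rate = 0.02, seed = 600 + s)
    sc <- cox_screen(expr, cl)
    rejections <- rejections + sum(sc$p < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(sc$p))
  }
  rate <- rejections / total
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.12)
})

test_that("risk score is the exact linear combination of Eq-style weights", {
  expr <- matrix(c(2, 1, 4, 3), 2, 2,
                 dimnames = list(c("G1", "G2"), c("S1", "S2")))
  sc <- risk_score(c(G1 = 0.5, G2 = -0.2), expr)
  expect_equal(sc$score, c(0.5 * 2 - 0.2 * 1, 0.5 * 4 - 0.2 * 3))
  # zero coefficients -> zero scores
  expect_equal(risk_score(c(G1 = 0, G2 = 0), expr)$score, c(0, 0))
  # single gene with unit weight -> that gene's expression
  expect_equal(risk_score(c(G2 = 1), expr)$score, unname(expr["G2", ]))
  # gene ordering in the model does not matter
  expect_equal(risk_score(c(G2 = -0.2, G1 = 0.5), expr)$score, sc$score)
  # model gene absent from expression is an error
  expect_error(risk_score(c(G9 = 1), expr), "absent")
  # sample missing a model gene's value is scored NA with a message
  expr2 <- expr; expr2["G1", "S2"] <- NA
  expect_message(sc2 <- risk_score(c(G1 = 0.5, G2 = -0.2), expr2), "NA")
  expect_true(is.na(sc2$score[2]))
})

test_that("mean-cutoff stratification puts ties in the low group", {
  s <- stratify_by_mean(c(a = 1, b = 2, c = 3))
  expect_equal(as.character(s$group), c("low", "low", "high"))
  s2 <- stratify_by_mean(c(0, 10))
  expect_equal(as.character(s2$group), c("low", "high"))
  s3 <- stratify_by_mean(c(-2, -1, 1, 2))
  expect_equal(table(s3$group)[["low"]], 2L)
  expect_error(stratify_by_mean(rep(5, 4)), "identical")
})

# empirical P(T <= t) evaluated at the sorted unique event times
ecdf_right <- function(t) {
  ut <- sort(unique(t))
  vapply(ut, function(u) mean(t <= u), numeric(1))
}

test_that("Kaplan-Meier estimator has the product-limit properties", {
  # all censored: survival stays at 1
  km <- kaplan_meier(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  # two subjects with events at 1 and 2: 1 -> 0.5 -> 0
  km2 <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km2$surv, c(1, 0.5, 0))
  # non-increasing on arbitrary inputs; equals empirical survival w/o censoring
  t <- withr::with_seed(5, rexp(40)); e <- rep(1L, 40)
  km3 <- kaplan_meier(t, e)
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_equal(km3$surv[km3$time > 0], 1 - ecdf_right(t))
  expect_error(kaplan_meier(numeric(), integer()), "empty")
})

test_that("log-rank statistic matches a hand-computed O-E table", {
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 4 subjects: A events at 1, 2; B censored at 3, 4
  # t=1: n=4, nA=2, d=1 -> E_A = 1/2, V = (2*2*1*3)/(16*3) = 1/4
  # t=2: n=3, nA=1, d=1 -> E_A = 1/3, V = (1*2*1*2)/(9*2)  = 2/9
  # O_A - E_A = 2 - 5/6 = 7/6 ; chisq = (7/6)^2 / (1/4 + 2/9)
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, (7 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-9)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), ">= 2")
})

test_that("log-rank has power against a planted HR of 3", {
  hits <- vapply(1:30, function(s) {
    expr <- generate_expression("G1", 400, 0, seed = 9000 + s)
    expr["G1", ] <- rep(c(0, 1), each = 200)
    cl <- generate_survival(expr, c(G1 = log(3)), baseline_hazard = 0.05,
                            censor_rate = 0.02, seed = 9500 + s)
    logrank_test(cl$time, cl$event, expr["G1", ])$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("module prognosis separates planted risk groups and calibrates on noise", {
  hits <- vapply(1:10, function(s) {
    genes <- sprintf("G%02d", 1:6)
    expr <- generate_expression(genes, 250, 0, seed = 40 + s)
    coefs <- setNames(rep(log(2), 3), genes[1:3])
    cl <- generate_survival(expr, coefs, baseline_hazard = 0.05,
                            censor_rate = 0.02, seed = 80 + s)
    module_prognosis(genes, expr, cl)$logrank$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # subset filter that matches nothing errors
  genes <- sprintf("G%02d", 1:4)
  expr <- generate_expression(genes, 100, 0, seed = 7)
  cl <- generate_survival(expr, numeric(), seed = 8)
  expect_error(module_prognosis(genes, expr, cl, sample_id == "nope"),
               "zero samples")
})

test_that("group comparison matches the exact rank-sum enumeration for small n", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      g1 <- rnorm(5); g2 <- rnorm(6) + 0.5
      got <- compare_expression_groups(c(g1, g2),
                                       rep(c("a", "b"), c(5, 6)))
      expect_equal(got$p, wilcox_exact_oracle(g1, g2), tolerance = 1e-12)
    }
  })
  # planted 2-SD shift is detected decisively
  withr::with_seed(12, {
    x <- c(rnorm(50), rnorm(50, mean = 2))
    got <- compare_expression_groups(x, rep(c("a", "b"), each = 50))
    expect_lt(got$p, 1e-3)
    gott <- compare_expression_groups(x, rep(c("a", "b"), each = 50), method = "t")
    expect_lt(gott$p, 1e-3)
  })
  expect_error(compare_expression_groups(rnorm(4), c("a", "a", "b", "b")),
               ">= 3")
})
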