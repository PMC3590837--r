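test_that("questionnaire item 1 encodes pain and missing records are excluded", {
  q <- data.frame(id = 1:4, item1 = c("yes", "no", "Y", NA),
                  item2 = c("weekly", "", "monthly", ""),
                  item3 = c(4, 0, 6, 2))
  expect_message(out <- encode_pain(q), "excluding 1")
  expect_equal(out$pain, c(1L, 0L, 1L))
  expect_equal(attr(out, "excluded"), 4L)
  expect_equal(out$item3, c(4, 0, 6))  # other items untouched
})

test_that("a 7-of-19 cohort reports 36.8% prevalence", {
  q <- data.frame(item1 = c(rep("yes", 7), rep("no", 12)))
  out <- encode_pain(q)
  expect_equal(round(100 * mean(out$pain), 1), 36.8)
})

test_that("point-biserial equals Pearson on the 0/1 coding", {
  r <- point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(round(r$r, 3), 0.894)
  set.seed(3)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(x))
  if (var(y) == 0) y[1] <- 1 - y[1]
  expect_identical(point_biserial(x, y)$r, pearson_cor(x, as.numeric(y))$r)
})

test_that("the t-transform reproduces printed p-values at n = 19", {
  expect_equal(round(pitchload:::correlation_result(0.704, 19, "")$p, 3), 0.001)
  expect_equal(round(pitchload:::correlation_result(-0.141, 19, "")$p, 3), 0.565)
})

test_that("correlation degenerate inputs are rejected", {
  expect_error(point_biserial(1:4, c(0, 0, 0, 0)), "both")
  expect_error(point_biserial(rep(2, 4), c(0, 1, 0, 1)), "variance")
  expect_error(pearson_cor(1:3, rep(1, 3)), "variance")
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_cor(1:5, -(1:5))$r, -1)
})

test_that("independent exposures correlate near zero at large n", {
  set.seed(12)
  x1 <- rnorm(1e4)
  x2 <- rnorm(1e4)
  expect_lt(abs(pearson_cor(x1, x2)$r), 0.03)
})

test_that("grouped two-level exposure recovers the closed-form log odds ratio", {
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 3), rep(0, 7), rep(1, 2), rep(0, 8))
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$coefficients["slope"]), log(3 * 8 / (7 * 2)),
               tolerance = 1e-6)
  expect_equal(fit$status, "converged")
})

test_that("IRLS agrees with a direct likelihood-maximization oracle and glm", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    x <- rnorm(n, 200, 50)
    y <- rbinom(n, 1, plogis(0.04 * x - 8))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(x, y)
    if (fit$status != "converged") next
    # oracle: direct likelihood maximization on the standardized exposure
    xs <- (x - mean(x)) / sd(x)
    nll <- function(b) -sum(y * (b[1] + b[2] * xs) - log1p(exp(b[1] + b[2] * xs)))
    orc <- optim(c(0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000))
    # Newton polish on numerically differentiated likelihood
    b <- orc$par
    h <- 1e-5
    for (it in 1:8) {
      gr <- c((nll(b + c(h, 0)) - nll(b - c(h, 0))) / (2 * h),
              (nll(b + c(0, h)) - nll(b - c(0, h))) / (2 * h))
      H <- matrix(0, 2, 2)
      H[1, 1] <- (nll(b + c(h, 0)) - 2 * nll(b) + nll(b - c(h, 0))) / h^2
      H[2, 2] <- (nll(b + c(0, h)) - 2 * nll(b) + nll(b - c(0, h))) / h^2
      H[1, 2] <- H[2, 1] <- (nll(b + c(h, h)) - nll(b + c(h, -h)) -
                               nll(b + c(-h, h)) + nll(b - c(h, h))) / (4 * h^2)
      b <- b - solve(H, gr)
    }
    slope_orc <- b[2] / sd(x)
    int_orc <- b[1] - b[2] * mean(x) / sd(x)
    expect_lt(max(abs(unname(fit$coefficients) - c(int_orc, slope_orc))), 1e-6)
    g <- glm(y ~ x, family = binomial())
    expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  }
})

test_that("Wald statistics are invariant to rescaling the exposure", {
  set.seed(17)
  x <- rnorm(60, 200, 40)
  y <- rbinom(60, 1, plogis(0.03 * x - 6))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  f1 <- fit_logistic(x, y)
  f2 <- fit_logistic(x / 10, y)
  expect_equal(unname(f2$coefficients["slope"]), unname(10 * f1$coefficients["slope"]),
               tolerance = 1e-8)
  expect_equal(unname(f2$wald["slope"]), unname(f1$wald["slope"]), tolerance = 1e-6)
  expect_equal(f2$model_chisq, f1$model_chisq, tolerance = 1e-8)
})

test_that("degenerate outcomes and separation are distinct failure modes", {
  expect_error(fit_logistic(1:6, rep(1, 6)), "both classes")
  fit <- fit_logistic(1:6, c(0, 0, 0, 1, 1, 1))
  expect_identical(fit$status, "separation")
  expect_false(fit$converged)
})

test_that("odds-ratio arithmetic matches the Wald form", {
  ci <- wald_or_ci(0.046, 0.019)
  expect_equal(round(ci$or, 3), 1.047)
  expect_equal(round(ci$lower, 3), 1.009)
  fit <- fit_logistic(c(rep(1, 10), rep(0, 10)),
                      c(rep(1, 3), rep(0, 7), rep(1, 2), rep(0, 8)))
  expect_equal(unname(fit$or), exp(unname(fit$coefficients["slope"])))
  expect_lt(fit$or_ci["lower"], fit$or)
  expect_gt(fit$or_ci["upper"], fit$or)
})

test_that("classification percentages recompute exactly from the counts", {
  # 19 subjects, 7 pain: 5 pain predicted correctly, 11 of 12 no-pain correct
  fit <- structure(list(coefficients = c(intercept = 0, slope = 10),
                        x = NULL, y = NULL), class = "pitchload_logit")
  x <- c(rep(1, 5), rep(-1, 2),     # pain: 5 predicted pain, 2 predicted no
         rep(-1, 11), rep(1, 1))    # no-pain: 11 correct, 1 false positive
  y <- c(rep(1, 7), rep(0, 12))
  cl <- classification_table(fit, x, y)
  expect_equal(cl$overall_pct, 84.2)
  expect_equal(cl$pain_pct, 71.4)
  expect_equal(cl$tp + cl$tn + cl$fp + cl$fn, 19)
  expect_equal(cl$overall_pct, round(100 * (cl$tp + cl$tn) / 19, 1))
  # a perfectly separating rule scores 100/100
  cl2 <- classification_table(fit, c(-1, -1, 1, 1, 1), c(0, 0, 1, 1, 1))
  expect_equal(cl2$overall_pct, 100)
  expect_equal(cl2$pain_pct, 100)
})

test_that("slope bias shrinks as the cohort grows", {
  errs <- vapply(c(200, 2000, 100000), function(n) {
    co <- generate_cohort(cohort_params(n = n, seed = 77))
    fit <- fit_logistic(co$ppf_n, co$pain)
    c(abs(unname(fit$coefficients["slope"]) - 0.046), unname(fit$se["slope"]))
  }, numeric(2))
  expect_true(all(errs[1, ] < 3 * errs[2, ]))   # within 3 SE at every n
  expect_lt(errs[1, 3], errs[2, 1])             # large-n error below small-n SE
})

test_that("descriptive statistics match the e1071 sample formulas", {
  set.seed(23)
  x <- rnorm(19, 200, 50)
  d <- describe_stats(x)
  expect_equal(d$se, sd(x) / sqrt(19))
  expect_equal(d$skewness, e1071::skewness(x, type = 2))
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2))
})

test_that("association report selects PPF under the printed generative model", {
  co <- generate_cohort(cohort_params(n = 5000, seed = 6))
  rep <- run_association(co)
  expect_identical(rep$selected, "PPF")
  expect_false("PAF" %in% rep$qualifying)
  expect_lt(abs(rep$fit$coefficients["slope"] - 0.046), 0.01)
  expect_s3_class(rep$classification, "classification_summary")
})

test_that("with both slopes null no predictor is selected", {
  co <- generate_cohort(cohort_params(n = 2000, slope = 0, intercept = -0.6, seed = 13))
  rep <- run_association(co)
  expect_length(rep$selected, 0)
  expect_null(rep$fit)
  txt <- capture.output(print(rep))
  expect_true(any(grepl("No exposure passed", txt)))
})

test_that("PPF is selected in the majority of 19-subject replicates", {
  hits <- 0L
  for (s in 1:500) {
    co <- generate_cohort(cohort_params(n = 19, seed = s))
    if (length(unique(co$pain)) < 2) next
    pb <- point_biserial(co$ppf_n, co$pain)
    if (pb$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits, 250)
})
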