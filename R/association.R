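# Statistical layer: pain encoding, correlation screening, single-predictor
# logistic regression by IRLS with Wald inference, classification analysis.

#' Encode binary shoulder-pain status from questionnaire records
#'
#' Pain status is 1 iff the first questionnaire item ("shoulder pain
#' following a throwing outing during the current competitive season") is
#' affirmative. Remaining items (pain frequency, 10-point intensity, lost
#' time) are carried through untouched. Records with item 1 missing are
#' excluded and listed in the `excluded` attribute with a message.
#'
#' @param records data.frame; `item_col` holds yes/no (or 1/0, TRUE/FALSE).
#' @param item_col name of the pain item column (default `"item1"`).
#' @return the records with a `pain` column (0/1), missing-item rows
#'   dropped; attribute `excluded` holds the dropped row indices.
#' @export
encode_pain <- function(records, item_col = "item1") {
  stopifnot(is.data.frame(records))
  if (!item_col %in% names(records)) stop("column '", item_col, "' not found")
  v <- records[[item_col]]
  low <- tolower(trimws(as.character(v)))
  pain <- ifelse(low %in% c("yes", "y", "1", "true"), 1L,
                 ifelse(low %in% c("no", "n", "0", "false"), 0L, NA_integer_))
  bad <- which(is.na(pain))
  if (length(bad)) {
    message("excluding ", length(bad), " record(s) with missing/unreadable '",
            item_col, "': rows ", paste(bad, collapse = ", "))
    records <- records[-bad, , drop = FALSE]
    pain <- pain[-bad]
  }
  records$pain <- pain
  attr(records, "excluded") <- bad
  records
}

correlation_result <- function(r, n, label) {
  df <- n - 2L
  t <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else sign(r) * Inf
  p <- 2 * pt(-abs(t), df)
  structure(list(label = label, r = r, t = t, df = df, p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: r = %.3f, t(%d) = %.3f, p = %.3f\n",
              x$label, x$r, x$df, x$t, x$p))
  invisible(x)
}

#' Point-biserial correlation between a continuous and a binary variable
#'
#' The point-biserial coefficient is the Pearson product-moment correlation
#' of the continuous variable with the 0/1 coding of the binary variable;
#' significance is the usual two-tailed Student t test with n - 2 degrees
#' of freedom, `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x continuous vector (nonzero variance).
#' @param y binary vector in \{0, 1\} with both classes present.
#' @param label description carried into the result.
#' @return object of class `correlation_result`: `r`, `t`, `df`, `p`, `n`.
#' @export
point_biserial <- function(x, y, label = "point-biserial") {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both pain classes must be present")
  if (var(x) == 0) stop("x has zero variance")
  correlation_result(stats::cor(x, as.numeric(y)), n, label)
}

#' Pearson product-moment correlation with t-based significance
#'
#' Used as the multicollinearity screen between the two kinetic exposures
#' (PAF and PPF) before model building.
#'
#' @param x1,x2 numeric vectors, nonzero variance, n >= 3.
#' @param label description carried into the result.
#' @return object of class `correlation_result`.
#' @export
pearson_cor <- function(x1, x2, label = "Pearson") {
  n <- length(x1)
  if (length(x2) != n) stop("x1 and x2 lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  if (var(x1) == 0 || var(x2) == 0) stop("zero-variance input")
  correlation_result(stats::cor(x1, x2), n, label)
}

#' Odds ratio and Wald confidence interval from a logistic coefficient
#'
#' `OR = exp(beta)` with the Wald interval
#' `exp(beta +/- z * se)`, `z = 1.959964` for 95% coverage (the interval
#' style of standard statistical-package logistic output).
#'
#' @param beta coefficient (logit scale).
#' @param se standard error of `beta`.
#' @param z normal quantile (default `1.959964`).
#' @return list with `or`, `lower`, `upper`.
#' @export
wald_or_ci <- function(beta, se, z = 1.959964) {
  beta <- unname(beta); se <- unname(se)
  list(or = exp(beta), lower = exp(beta - z * se), upper = exp(beta + z * se))
}

#' Single-predictor logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' exposure, fitted by iteratively reweighted least squares (Newton-Raphson
#' on the log-likelihood). Convergence is declared when the log-likelihood
#' changes by less than `tol` (default 1e-10), up to `max_iter` iterations.
#' Standard errors come from the inverse observed information at the
#' optimum; Wald statistics are `(beta / se)^2` on 1 df; the model
#' chi-square is the likelihood ratio against the intercept-only model.
#' Complete or quasi-complete separation (the likelihood improving
#' monotonically while the linear predictor diverges) is detected and
#' reported as status `"separation"` rather than silent non-convergence.
#'
#' @param x exposure vector.
#' @param y binary outcome in \{0, 1\}, both classes present, n >= 5.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap (default 100).
#' @return object of class `pitchload_logit`: coefficients, `se`, `wald`,
#'   `p`, `or`, `or_ci`, `loglik`, `loglik_null`, `model_chisq`,
#'   `model_chisq_p`, `status` (`"converged"`, `"separation"`,
#'   `"maxiter"`), `iterations`, `vcov`, and the data.
#' @examples
#' co <- generate_cohort(cohort_params(n = 500, seed = 2))
#' fit <- fit_logistic(co$ppf_n, co$pain)
#' summary(fit)
#' @export
fit_logistic <- function(x, y, tol = 1e-10, max_iter = 100L) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 5L) stop("need at least 5 observations")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2L) stop("outcome is degenerate: both classes must be present")
  if (!all(is.finite(x))) stop("x must be finite")
  X <- cbind(intercept = 1, x = x)
  beta <- c(qlogis_safe(mean(y)), 0)
  ll_of <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- ll_of(beta)
  status <- "maxiter"
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtW <- t(X * w)
    H <- XtW %*% X
    score <- drop(t(X) %*% (y - mu))
    step <- solve(H, score)
    beta_new <- beta + step
    ll_new <- ll_of(beta_new)
    # step-halve if the step overshoots
    halv <- 0L
    while (ll_new < ll && halv < 20L) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- ll_of(beta_new)
      halv <- halv + 1L
    }
    dll <- ll_new - ll
    beta <- beta_new
    ll <- ll_new
    if (max(abs(drop(X %*% beta))) > 30 && dll >= 0) {
      status <- "separation"
      break
    }
    if (abs(dll) < tol) {
      status <- "converged"
      break
    }
  }
  beta <- unname(beta)
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- t(X * w) %*% X
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(V) <- list(c("intercept", "slope"), c("intercept", "slope"))
  se <- unname(sqrt(diag(V)))
  wald <- (beta / se)^2
  p <- pchisq(wald, 1, lower.tail = FALSE)
  py <- mean(y)
  ll0 <- n * (py * log(py) + (1 - py) * log(1 - py))
  chisq <- 2 * (ll - ll0)
  ci <- wald_or_ci(beta[2], se[2])
  structure(list(
    coefficients = setNames(beta, c("intercept", "slope")),
    se = setNames(se, c("intercept", "slope")),
    wald = setNames(wald, c("intercept", "slope")),
    p = setNames(p, c("intercept", "slope")),
    or = exp(beta[2]), or_ci = c(lower = ci$lower, upper = ci$upper),
    loglik = ll, loglik_null = ll0,
    model_chisq = chisq,
    model_chisq_p = pchisq(chisq, 1, lower.tail = FALSE),
    status = status, converged = status == "converged",
    iterations = iter, vcov = V, x = x, y = y, n = n
  ), class = "pitchload_logit")
}

qlogis_safe <- function(p) stats::qlogis(min(max(p, 1e-6), 1 - 1e-6))

#' @export
print.pitchload_logit <- function(x, ...) {
  cat("Logistic regression (IRLS), status:", x$status,
      "in", x$iterations, "iterations\n")
  cat(sprintf("  logit(p) = %.4f + %.4f * x\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), model chi2 = %.3f (p = %.3f)\n",
              x$or, x$or_ci[1], x$or_ci[2], x$model_chisq, x$model_chisq_p))
  invisible(x)
}

#' @export
summary.pitchload_logit <- function(object, ...) {
  tab <- data.frame(
    B = object$coefficients, S.E. = object$se, Wald = object$wald,
    df = 1L, p = object$p, `Exp(B)` = exp(object$coefficients),
    check.names = FALSE
  )
  out <- list(table = tab, or_ci = object$or_ci,
              model_chisq = object$model_chisq,
              model_chisq_p = object$model_chisq_p,
              loglik = object$loglik, status = object$status, n = object$n)
  class(out) <- "summary.pitchload_logit"
  out
}

#' @export
print.summary.pitchload_logit <- function(x, ...) {
  cat("Logistic regression fit (n =", x$n, ", status:", x$status, ")\n")
  print(round(x$table, 3))
  cat(sprintf("slope 95%% CI for Exp(B): %.3f-%.3f\n", x$or_ci[1], x$or_ci[2]))
  cat(sprintf("model chi-square = %.3f, df = 1, p = %.3f; log-likelihood = %.3f\n",
              x$model_chisq, x$model_chisq_p, x$loglik))
  invisible(x)
}

#' @export
coef.pitchload_logit <- function(object, ...) object$coefficients

#' @export
vcov.pitchload_logit <- function(object, ...) object$vcov

#' Predicted pain probability from a fitted logistic model
#'
#' @param object a `pitchload_logit` fit.
#' @param newdata exposure values (numeric vector); defaults to the
#'   training exposures.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @export
predict.pitchload_logit <- function(object, newdata = NULL,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  eta <- object$coefficients[1] + object$coefficients[2] * x
  if (type == "link") unname(eta) else unname(plogis(eta))
}

#' Classification analysis of a fitted logistic model
#'
#' Cross-tabulates observed against predicted pain status at a probability
#' threshold (default 0.5; a fitted probability exactly equal to the
#' threshold classifies as no-pain). Reports the counts and the overall,
#' pain-case and no-pain-case percent correct to one decimal.
#'
#' @param fit a `pitchload_logit`.
#' @param x,y exposure and observed outcome; default the training data.
#' @param threshold probability threshold in (0, 1).
#' @return object of class `classification_summary`: `tp`, `tn`, `fp`,
#'   `fn`, `overall_pct`, `pain_pct`, `nopain_pct`, `threshold`.
#' @export
classification_table <- function(fit, x = NULL, y = NULL, threshold = 0.5) {
  stopifnot(inherits(fit, "pitchload_logit"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(x)) x <- fit$x
  if (is.null(y)) y <- fit$y
  if (!length(x)) stop("no observations to classify")
  pred <- as.integer(predict(fit, x) > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, threshold = threshold,
    overall_pct = round(100 * (tp + tn) / length(y), 1),
    pain_pct = if (tp + fn > 0) round(100 * tp / (tp + fn), 1) else NA_real_,
    nopain_pct = if (tn + fp > 0) round(100 * tn / (tn + fp), 1) else NA_real_
  ), class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("Classification at threshold %.2f: overall %.1f%% correct; pain cases %.1f%%; no-pain cases %.1f%%\n",
              x$threshold, x$overall_pct, x$pain_pct, x$nopain_pct))
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Descriptive statistics in reporting style
#'
#' Min, max, mean, SD, SE (SD / sqrt(n)), and the bias-adjusted sample
#' skewness and excess kurtosis used by standard statistical packages.
#'
#' @param x numeric vector.
#' @return one-row data.frame.
#' @export
describe_stats <- function(x) {
  n <- length(x)
  m <- mean(x); s <- sd(x)
  z <- (x - m) / s
  skew <- if (n > 2) n / ((n - 1) * (n - 2)) * sum(z^3) else NA_real_
  kurt <- if (n > 3) {
    n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  } else NA_real_
  data.frame(n = n, min = min(x), max = max(x), mean = m, sd = s,
             se = s / sqrt(n), skewness = skew, kurtosis = kurt)
}

#' Full pain-association analysis of a cohort
#'
#' Runs the study's statistical chain on a cohort table: descriptive
#' statistics for both kinetic exposures; point-biserial correlation of
#' each exposure with pain; the PAF-PPF Pearson multicollinearity screen;
#' then a single-predictor logistic model containing only the exposures
#' whose point-biserial p-value falls below `alpha` (if both qualify the
#' more strongly correlated one is modelled — the layer is deliberately
#' univariable); finally classification analysis of the fitted model. With
#' no exposure selected, no model is fitted and the report says so.
#'
#' @param cohort a `cohort_table` (from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param alpha selection threshold on the point-biserial p (default 0.05).
#' @param class_threshold classification probability threshold.
#' @return object of class `pain_association`.
#' @examples
#' co <- generate_cohort(cohort_params(n = 200, seed = 3))
#' run_association(co)
#' @export
run_association <- function(cohort, alpha = 0.05, class_threshold = 0.5) {
  cohort <- as_cohort_table(as.data.frame(cohort))
  if (!nrow(cohort)) stop("empty cohort")
  exposures <- c(PAF = "paf_n", PPF = "ppf_n")
  descr <- do.call(rbind, lapply(exposures, function(cl) describe_stats(cohort[[cl]])))
  rownames(descr) <- names(exposures)
  corr <- lapply(names(exposures), function(lab)
    point_biserial(cohort[[exposures[[lab]]]], cohort$pain,
                   label = paste0(lab, " vs pain")))
  names(corr) <- names(exposures)
  screen <- pearson_cor(cohort$paf_n, cohort$ppf_n, label = "PAF vs PPF")
  pvals <- vapply(corr, function(cr) cr$p, numeric(1))
  qualifying <- names(exposures)[pvals < alpha]
  selected <- if (length(qualifying)) qualifying[which.min(pvals[qualifying])] else character(0)
  fit <- NULL; classification <- NULL
  if (length(selected)) {
    fit <- fit_logistic(cohort[[exposures[[selected]]]], cohort$pain)
    classification <- classification_table(fit, threshold = class_threshold)
  }
  structure(list(
    n = nrow(cohort), prevalence_pct = round(100 * mean(cohort$pain), 1),
    descriptives = descr, correlations = corr, pearson_screen = screen,
    qualifying = qualifying, selected = selected,
    fit = fit, classification = classification, alpha = alpha
  ), class = "pain_association")
}

#' @export
print.pain_association <- function(x, ...) {
  cat("Pain-association analysis: n =", x$n,
      sprintf("(pain prevalence %.1f%%)\n", x$prevalence_pct))
  cat("\nDescriptive statistics (N):\n")
  print(round(x$descriptives, 2))
  cat("\nPoint-biserial correlations with pain:\n")
  for (cr in x$correlations) print(cr)
  cat("Multicollinearity screen: ")
  print(x$pearson_screen)
  if (length(x$selected)) {
    cat("\nExposure selected at p <", x$alpha, ":", x$selected, "\n")
    print(summary(x$fit))
    print(x$classification)
  } else {
    cat("\nNo exposure passed the correlation screen (p <", x$alpha,
        "); no predictive model fitted.\n")
  }
  invisible(x)
}
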