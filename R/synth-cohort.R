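#' Cohort generative-model parameters
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the
#' published study conditions for 11-year-old pitchers: peak proximal force
#' (PPF) drawn Normal(201.59, 48.68) N, peak anterior force (PAF)
#' Normal(28.50, 17.08) N, and shoulder pain drawn Bernoulli with
#' probability `plogis(0.046 * PPF - 10.126)`. PAF is generated independent
#' of pain; its correlation with PPF defaults to 0 and is configurable.
#'
#' @param n number of subjects (>= 0).
#' @param ppf_mean,ppf_sd PPF distribution (N); SD > 0.
#' @param paf_mean,paf_sd PAF distribution (N); SD > 0.
#' @param slope,intercept logistic risk model on PPF (logit per N, logit).
#' @param paf_ppf_cor correlation between PAF and PPF in [-1, 1].
#' @param seed integer seed.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n = 19L, ppf_mean = 201.59, ppf_sd = 48.68,
                          paf_mean = 28.50, paf_sd = 17.08,
                          slope = 0.046, intercept = -10.126,
                          paf_ppf_cor = 0, seed = 1L) {
  vals <- c(n, ppf_mean, ppf_sd, paf_mean, paf_sd, slope, intercept, paf_ppf_cor)
  if (any(!is.finite(vals))) stop("cohort parameters must be finite")
  if (n < 0) stop("n must be >= 0")
  if (ppf_sd <= 0 || paf_sd <= 0) stop("SDs must be > 0")
  if (abs(paf_ppf_cor) > 1) stop("paf_ppf_cor must lie in [-1, 1]")
  structure(list(n = as.integer(n), ppf_mean = ppf_mean, ppf_sd = ppf_sd,
                 paf_mean = paf_mean, paf_sd = paf_sd, slope = slope,
                 intercept = intercept, paf_ppf_cor = paf_ppf_cor,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a synthetic pitcher cohort
#'
#' Draws a cohort from the printed generative model: PPF Gaussian, PAF
#' Gaussian (optionally correlated with PPF), pain Bernoulli under the
#' single-predictor logistic risk model on PPF. Demographics (age, height,
#' mass, handedness) are drawn from the study cohort's summary
#' distributions and carried for downstream plumbing. Deterministic given
#' the seed.
#'
#' @param params a [cohort_params()].
#' @return a `cohort_table` data.frame with columns `id`, `age_y`,
#'   `height_cm`, `mass_kg`, `handedness`, `paf_n`, `ppf_n`, `pain`.
#' @examples
#' head(generate_cohort(cohort_params(n = 10, seed = 7)))
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n
  cols <- c("id", "age_y", "height_cm", "mass_kg", "handedness",
            "paf_n", "ppf_n", "pain")
  if (n == 0L) {
    df <- data.frame(id = character(0), age_y = numeric(0),
                     height_cm = numeric(0), mass_kg = numeric(0),
                     handedness = character(0), paf_n = numeric(0),
                     ppf_n = numeric(0), pain = integer(0))
    return(as_cohort_table(df))
  }
  set.seed(params$seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  rho <- params$paf_ppf_cor
  ppf <- params$ppf_mean + params$ppf_sd * z1
  paf <- params$paf_mean + params$paf_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  p <- plogis(params$slope * ppf + params$intercept)
  pain <- rbinom(n, 1L, p)
  df <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age_y = round(rnorm(n, 11.2, 1.7), 1),
    height_cm = round(rnorm(n, 142.6, 9), 1),
    mass_kg = round(rnorm(n, 41.1, 6.3), 1),
    handedness = ifelse(runif(n) < 0.1, "L", "R"),
    paf_n = paf, ppf_n = ppf, pain = as.integer(pain),
    stringsAsFactors = FALSE
  )
  as_cohort_table(df)
}

as_cohort_table <- function(df) {
  need <- c("id", "paf_n", "ppf_n", "pain")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("cohort table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id)) stop("cohort ids must be unique")
  if (nrow(df) && !all(df$pain %in% c(0L, 1L))) stop("pain must be coded 0/1")
  if (nrow(df) && !all(is.finite(df$paf_n)) || nrow(df) && !all(is.finite(df$ppf_n)))
    stop("kinetic columns must be finite")
  class(df) <- c("cohort_table", "data.frame")
  df
}
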