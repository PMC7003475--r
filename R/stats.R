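#' Confusion matrix constructor
#'
#' @param TP,FP,TN,FN non-negative integer counts
#' @return object of class `confusion_matrix`
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix counts must be non-negative integers")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Diagnostic performance metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and negative
#' predictive values, and accuracy, each in percent. A metric whose
#' denominator is zero is reported as NA with a warning rather than failing
#' silently.
#'
#' @param cm a `confusion_matrix`
#' @return named numeric vector (percent)
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); return(NA_real_) }
    100 * num / den
  }
  with(cm, c(
    sensitivity = safe(TP, TP + FN, "sensitivity"),
    specificity = safe(TN, TN + FP, "specificity"),
    ppv         = safe(TP, TP + FP, "PPV"),
    npv         = safe(TN, TN + FN, "NPV"),
    accuracy    = safe(TP + TN, TP + FP + TN + FN, "accuracy")))
}

#' Dichotomize index values at a threshold
#'
#' Positive (disease requiring treatment) iff value < threshold, strict:
#' a value exactly at the threshold is negative. This boundary convention is
#' fixed package-wide.
#'
#' @param values numeric vector of index values
#' @param threshold cut-off
#' @param positive_below if FALSE, positive iff value > threshold
#' @return logical vector, TRUE = positive
#' @export
classify <- function(values, threshold, positive_below = TRUE) {
  if (positive_below) values < threshold else values > threshold
}

#' Build a confusion matrix from predictions and reference classes
#'
#' @param predicted,reference logical vectors (TRUE = positive)
#' @return a `confusion_matrix`
#' @export
tabulate_classes <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  confusion_matrix(TP = sum(predicted & reference),
                   FP = sum(predicted & !reference),
                   TN = sum(!predicted & !reference),
                   FN = sum(!predicted & reference))
}

#' Ordinary least-squares polynomial fit between two indices
#'
#' Fits y on x with a raw polynomial of the requested degree and returns the
#' coefficients highest-degree-first together with fit diagnostics.
#'
#' @param x,y paired numeric vectors (e.g. cFFR and ciFR)
#' @param degree polynomial degree, 1 to 3
#' @return list with `coefficients` (highest degree first), `r_squared`,
#'   `residual_sd`, `fitted`, and the `lm` object
#' @export
fit_polynomial <- function(x, y, degree = 2) {
  stopifnot(degree %in% 1:3, length(x) == length(y))
  if (length(x) <= degree + 1) stop("need n > degree + 1 points")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient polynomial fit")
  co <- rev(unname(stats::coef(fit)))       # highest degree first
  s <- summary(fit)
  list(coefficients = co, r_squared = s$r.squared,
       residual_sd = s$sigma, fitted = unname(stats::fitted(fit)), lm = fit)
}

#' Evaluate a fitted index relation at a reference cut-off
#'
#' Evaluates the polynomial (coefficients highest-degree-first, as returned
#' by [fit_polynomial]) at `ffr_cut`, giving the corresponding ciFR
#' threshold.
#'
#' @param coefficients numeric vector, highest degree first
#' @param ffr_cut reference FFR cut-off (default 0.8)
#' @return threshold value
#' @export
threshold_from_fit <- function(coefficients, ffr_cut = 0.8) {
  if (is.list(coefficients)) coefficients <- coefficients$coefficients
  deg <- length(coefficients) - 1
  sum(coefficients * ffr_cut^(deg:0))
}

#' Bland-Altman agreement statistics
#'
#' Differences a - b; mean, sample SD (n-1 denominator) and 95% limits of
#' agreement (mean +/- 1.96 SD).
#'
#' @param a,b paired numeric vectors, n >= 2
#' @return list with `mean_difference`, `sd_difference`,
#'   `limits_of_agreement` (length 2), `mean_values`, `differences`
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  list(mean_difference = m, sd_difference = s,
       limits_of_agreement = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       mean_values = (a + b) / 2, differences = d)
}

#' Pearson product-moment correlation
#'
#' @param a,b paired numeric vectors, n >= 3, each with nonzero variance
#' @return correlation coefficient r
#' @export
pearson <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance input")
  stats::cor(a, b)
}

#' ROC analysis of an index against binary reference classes
#'
#' Sweeps the decision threshold over the observed index values (positive iff
#' value < threshold, matching [classify]); returns the step ROC curve, the
#' trapezoidal AUC (identical to the Mann-Whitney statistic), and the
#' threshold maximizing Youden's J = sensitivity + specificity - 1 (ties
#' broken toward the higher threshold).
#'
#' @param values numeric index values
#' @param reference logical (TRUE = positive) or factor/character coercible
#'   to "positive"/"negative"
#' @return list with `thresholds`, `sensitivity`, `specificity`, `fpr`,
#'   `auc`, `optimal_threshold`, `youden_j`
#' @export
roc <- function(values, reference) {
  if (!is.logical(reference))
    reference <- as.character(reference) == "positive"
  stopifnot(length(values) == length(reference))
  n_pos <- sum(reference); n_neg <- sum(!reference)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  uv <- sort(unique(values))
  # min(values) yields zero positives (strict <); beyond max yields all
  thr <- c(uv, max(uv) + 1)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- classify(values, thr[i])
    sens[i] <- sum(pred & reference) / n_pos
    spec[i] <- sum(!pred & !reference) / n_neg
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  j <- sens + spec - 1
  best <- max(which(j == max(j)))          # tie -> higher threshold
  list(thresholds = thr, sensitivity = sens, specificity = spec, fpr = fpr,
       auc = auc, optimal_threshold = thr[best], youden_j = j[best])
}

#' Synthetic diagnostic cohort from a quadratic index relation
#'
#' Draws n cFFR values uniformly over `ffr_range` and generates ciFR from a
#' quadratic relation plus Gaussian noise; reference classes are cFFR < 0.8.
#' Used to test parameter/threshold recovery of the statistics pipeline.
#'
#' @param n cohort size (default 66, lesions rather than patients)
#' @param coefficients quadratic coefficients highest-degree-first (default
#'   the package's reference relation c(-0.5926, 1.5616, 0.0218))
#' @param noise_sd Gaussian noise SD on ciFR (default 0.005)
#' @param ffr_range sampling range of cFFR
#' @param seed RNG seed
#' @return data.frame with case_id, cffr, cifr, ref_class
#' @export
synthetic_cohort <- function(n = 66, coefficients = c(-0.5926, 1.5616, 0.0218),
                             noise_sd = 0.005, ffr_range = c(0.4, 1.0),
                             seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cffr <- stats::runif(n, ffr_range[1], ffr_range[2])
  deg <- length(coefficients) - 1
  cifr <- vapply(cffr, function(v) sum(coefficients * v^(deg:0)), numeric(1)) +
    stats::rnorm(n, 0, noise_sd)
  data.frame(case_id = sprintf("case%03d", seq_len(n)), cffr = cffr,
             cifr = cifr,
             ref_class = ifelse(cffr < 0.8, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Full statistics report for a cohort table
#'
#' Runs the analysis layer on a cohort of paired (cFFR, ciFR) records:
#' Pearson correlation, Bland-Altman, polynomial fits of degree 1-3 with
#' thresholds at the FFR cut-off, ROC of ciFR against the reference classes,
#' and diagnostic metrics of ciFR at its ROC-optimal threshold.
#'
#' @param cohort data.frame with columns cffr, cifr, ref_class (or logical
#'   ref); see [synthetic_cohort]
#' @param ffr_cut reference FFR cut-off (default 0.8)
#' @return list report
#' @export
cohort_report <- function(cohort, ffr_cut = 0.8) {
  stopifnot(all(c("cffr", "cifr") %in% names(cohort)))
  ref <- if ("ref_class" %in% names(cohort))
    as.character(cohort$ref_class) == "positive" else classify(cohort$cffr, ffr_cut)
  fits <- lapply(1:3, function(d) fit_polynomial(cohort$cffr, cohort$cifr, d))
  thresholds <- vapply(fits, threshold_from_fit, numeric(1), ffr_cut = ffr_cut)
  rc <- roc(cohort$cifr, ref)
  cmx <- tabulate_classes(classify(cohort$cifr, rc$optimal_threshold), ref)
  list(n = nrow(cohort),
       pearson = pearson(cohort$cffr, cohort$cifr),
       bland_altman = bland_altman(cohort$cffr, cohort$cifr)[
         c("mean_difference", "sd_difference", "limits_of_agreement")],
       fit_coefficients = lapply(fits, `[[`, "coefficients"),
       fit_r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
       thresholds_at_cut = thresholds,
       roc_auc = rc$auc, roc_optimal_threshold = rc$optimal_threshold,
       metrics_at_optimum = as.list(diagnostic_metrics(cmx)),
       ffr_cut = ffr_cut)
}
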