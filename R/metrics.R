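#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive receives a higher score than
#' a randomly chosen negative, with ties counted one half. Computed via the
#' rank (Mann-Whitney) identity, which equals brute-force pairwise
#' concordance.
#'
#' @param labels Binary vector (0/1 or logical); both classes must be present.
#' @param scores Numeric scores, higher meaning "more positive".
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- check_binary_labels(labels, length(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Max-SSS classification threshold
#'
#' Threshold maximizing sensitivity + specificity, found by exhaustive scan
#' over midpoints of consecutive sorted unique scores (plus open-ended
#' candidates below the minimum and above the maximum). Ties take the lowest
#' threshold.
#'
#' @inheritParams auc
#' @return A single threshold; classification rule is `score >= threshold`.
#' @export
max_sss_threshold <- function(labels, scores) {
  labels <- check_binary_labels(labels, length(scores))
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else (u[-length(u)] + u[-1L]) / 2
  cand <- c(min(u) - 1, cand, max(u) + 1)
  sss <- vapply(cand, function(th) {
    sens_spec(labels, scores, th)["sens"] + sens_spec(labels, scores, th)["spec"]
  }, numeric(1))
  cand[which.max(sss)] # which.max returns first (lowest) on ties
}

#' True skill statistic at a threshold
#'
#' Sensitivity + specificity - 1 for the rule `score >= threshold`.
#'
#' @inheritParams auc
#' @param threshold Classification threshold.
#' @return TSS in \[-1, 1\].
#' @export
tss <- function(labels, scores, threshold) {
  labels <- check_binary_labels(labels, length(scores))
  ss <- sens_spec(labels, scores, threshold)
  unname(ss["sens"] + ss["spec"] - 1)
}

sens_spec <- function(labels, scores, threshold) {
  pred <- scores >= threshold
  c(sens = sum(pred & labels == 1L) / sum(labels == 1L),
    spec = sum(!pred & labels == 0L) / sum(labels == 0L))
}

check_binary_labels <- function(labels, n_scores) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(labels) != n_scores)
    stop("labels and scores must have equal length")
  if (anyNA(labels)) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes (presence and absence) must be present")
  labels
}

#' Percent explained deviance of a fitted model
#'
#' @param fit A fitted model exposing `deviance` and `null.deviance`
#'   (e.g. objects from [fit_count_model()]), or a list with elements
#'   `deviance` and `null.deviance`.
#' @return Percentage 100 * (1 - residual/null).
#' @export
explained_deviance <- function(fit) {
  if (inherits(fit, "cetsdm_fit")) fit <- fit$model
  dev <- fit$deviance
  null_dev <- fit$null.deviance
  if (is.null(dev) || is.null(null_dev))
    stop("fit must expose deviance and null.deviance")
  if (null_dev == 0) stop("null deviance is zero; explained deviance undefined")
  100 * (1 - dev / null_dev)
}

#' Observed-to-predicted ratio
#'
#' @param observed_total,predicted_total Scalars; totals over a region
#'   (abundance for density models, summed presences vs. summed predicted
#'   probabilities for suitability models).
#' @return observed / predicted.
#' @export
obs_pred_ratio <- function(observed_total, predicted_total) {
  if (!is.finite(predicted_total) || predicted_total <= 0)
    stop("predicted total must be positive")
  observed_total / predicted_total
}

#' Spearman rank correlation with exact small-sample one-tailed p-value
#'
#' Computes rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) on average ranks and, for
#' n <= 9, an exact one-tailed p-value by complete enumeration of all n!
#' rank permutations; above that a large-sample t approximation is used.
#' Intended for comparing observed vs. predicted values across a small
#' number of geographic strata.
#'
#' @param observed,predicted Numeric vectors of equal length (no NAs).
#' @param alpha One-tailed significance level for the `significant` flag.
#' @return List with `rho`, `p_value` (one-tailed, upper), `significant`,
#'   and `n`.
#' @export
spearman_stratified <- function(observed, predicted, alpha = 0.05) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (anyNA(observed) || anyNA(predicted))
    stop("undefined (NA) stratum values are not allowed")
  n <- length(observed)
  if (n < 3) stop("need at least 3 strata")
  rho <- spearman_rho(observed, predicted)
  if (n <= 9) {
    rhos <- exact_spearman_null(n)
    p <- mean(rhos >= rho - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, significant = p <= alpha, n = n)
}

spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# all rho values of the exact permutation null for sample size n (n! values)
exact_spearman_null <- function(n) {
  perms <- all_permutations(n)
  base <- seq_len(n)
  denom <- n * (n^2 - 1)
  1 - 6 * colSums((perms - base)^2) / denom
}

# n x n! matrix of all permutations of 1..n (column-wise), iterative heap-free
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  k <- ncol(sub)
  out <- matrix(0L, n, k * n)
  for (pos in seq_len(n)) {
    cols <- ((pos - 1L) * k + 1L):(pos * k)
    out[pos, cols] <- n
    out[-pos, cols] <- sub
  }
  out
}

#' Exact one-tailed critical value of the Spearman null
#'
#' Smallest achievable rho whose upper-tail probability under the exact
#' permutation null (all n! rank orderings) does not exceed `alpha`.
#'
#' @param n Number of paired ranks (n <= 9 for exact enumeration).
#' @param alpha One-tailed level.
#' @return Critical rho.
#' @export
spearman_critical_value <- function(n, alpha = 0.05) {
  if (n > 9) stop("exact enumeration supported for n <= 9 only")
  rhos <- sort(exact_spearman_null(n))
  m <- length(rhos)
  # P(rho >= r) <= alpha  <=>  r > rhos[m - floor(alpha*m)] handling ties
  u <- sort(unique(rhos))
  tail_p <- vapply(u, function(r) mean(rhos >= r - 1e-12), numeric(1))
  min(u[tail_p <= alpha])
}
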