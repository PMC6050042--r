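#' Nuclear coefficient of variation
#'
#' The CV of reporter intensity over a nuclear ROI — population standard
#' deviation divided by mean — a scale-free statistic of how punctate
#' (granular) versus diffuse the signal is: a uniform nucleus has CV 0,
#' bright puncta on a depleted background push it up.
#'
#' @param reporter_image Numeric intensity matrix (AU).
#' @param nuclear_mask Logical matrix of the same shape, nonempty.
#' @return The CV (dimensionless, >= 0).
#' @export
nuclear_cv <- function(reporter_image, nuclear_mask) {
  stopifnot(identical(dim(reporter_image), dim(nuclear_mask)))
  v <- reporter_image[nuclear_mask]
  if (length(v) == 0L) stop("empty nuclear mask")
  m <- mean(v)
  if (m <= 0) stop("undefined CV: zero-mean region")
  sd_pop(v) / m
}

#' ROC curve for a CV-based granule classifier
#'
#' Sweeps every distinct CV value as a candidate threshold for the rule
#' "granule-positive iff CV >= t", computing sensitivity and specificity
#' against annotated labels, and selects the threshold maximizing the
#' Youden index J = sensitivity + specificity - 1 (smallest threshold on
#' ties).
#'
#' @param cvs Numeric CV values.
#' @param truth Logical (or coercible) vector: `TRUE`/`"granular"` =
#'   granule-positive.
#' @return A `roc_curve`: data.frame `curve` (`threshold`, `sensitivity`,
#'   `specificity`), `auc` (Mann-Whitney, ties counted half), `threshold`
#'   (chosen), `youden_j`, `sensitivity`/`specificity` at the chosen
#'   threshold.
#' @export
build_roc <- function(cvs, truth) {
  if (is.character(truth) || is.factor(truth))
    truth <- as.character(truth) == "granular"
  truth <- as.logical(truth)
  stopifnot(length(cvs) == length(truth), !any(is.na(cvs)), !any(is.na(truth)))
  if (all(truth) || !any(truth)) stop("both classes must be present")
  th <- sort(unique(cvs))
  pos <- cvs[truth]; neg <- cvs[!truth]
  sens <- vapply(th, function(t) mean(pos >= t), 1)
  spec <- vapply(th, function(t) mean(neg < t), 1)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]
  # Mann-Whitney AUC with ties counted 1/2
  r <- rank(cvs)
  auc <- (sum(r[truth]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  structure(list(
    curve = data.frame(threshold = th, sensitivity = sens,
                       specificity = spec),
    auc = auc, threshold = th[best], youden_j = j[best],
    sensitivity = sens[best], specificity = spec[best]
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f; chosen threshold %.3f (sens %.1f%%, spec %.1f%%, J = %.3f)\n",
    x$auc, x$threshold, 100 * x$sensitivity, 100 * x$specificity,
    x$youden_j))
  invisible(x)
}

#' Classify cells as granule-positive by CV threshold
#'
#' Deterministic thresholding with the boundary counted positive
#' (CV equal to the threshold is called granule-positive). The shipped
#' default threshold 0.92 is the published operating point of the CV
#' classifier.
#'
#' @param cvs Numeric CV values.
#' @param threshold Classification threshold (> 0); default 0.92.
#' @param groups Optional group labels for the per-group summary.
#' @param ids Optional cell ids.
#' @return A list with `calls` (data.frame: `id`, `cv`, `threshold`,
#'   `call`) and `summary` (per group: `n_positive`, `n_total`,
#'   `percent` to 1 decimal).
#' @export
classify_cells <- function(cvs, threshold = 0.92, groups = NULL,
                           ids = seq_along(cvs)) {
  stopifnot(threshold > 0)
  call <- ifelse(cvs >= threshold, "granule-positive", "diffuse")
  calls <- data.frame(id = ids, cv = cvs, threshold = threshold,
                      call = call, stringsAsFactors = FALSE)
  if (is.null(groups)) groups <- rep("all", length(cvs))
  pos <- tapply(call == "granule-positive", groups, sum)
  tot <- tapply(call, groups, length)
  summary <- data.frame(
    group = names(pos), n_positive = as.integer(pos),
    n_total = as.integer(tot),
    percent = round(100 * as.integer(pos) / as.integer(tot), 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(calls = calls, summary = summary)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric two-sided p (the sum of probabilities of all
#' tables with fixed margins no more probable than the observed one) and
#' the conditional-MLE odds ratio, via [stats::fisher.test()].
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return List with `p` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin")
  ft <- stats::fisher.test(table)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Survival of granule-bearing versus diffuse cells against the pooled cohort
#'
#' Compares each stratum (granule-positive by the classification day,
#' diffuse) to the pooled combination of all cells, replicating the
#' stratified Cox contrasts used to ask whether granule formation is
#' protective: each contrast is a two-group Cox fit of the stratum
#' against a pooled copy of the full cohort.
#'
#' @param records Survival table with `id`.
#' @param calls `calls` data.frame from [classify_cells()] (or any frame
#'   with `id` and `call`), covering every record.
#' @return List with `granular`, `diffuse` (each a `cox_fit` vs pooled)
#'   and `n` per stratum.
#' @export
stratified_survival_by_granule <- function(records, calls) {
  m <- match(records$id, calls$id)
  if (anyNA(m)) stop("calls must be available for every record")
  call <- calls$call[m]
  strata <- list(granular = records[call == "granule-positive", ],
                 diffuse = records[call == "diffuse", ])
  if (any(vapply(strata, nrow, 1L) == 0L)) stop("empty stratum")
  pooled <- records
  pooled$group <- "pooled"
  fits <- lapply(strata, function(s) {
    s$group <- "stratum"
    fit_cox(rbind(pooled, s), reference = "pooled")
  })
  list(granular = fits$granular, diffuse = fits$diffuse,
       n = c(granular = nrow(strata$granular),
             diffuse = nrow(strata$diffuse), pooled = nrow(pooled)))
}
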