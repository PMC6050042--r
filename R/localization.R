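#' Segment the nucleus inside a soma ROI
#'
#' The nucleus is taken as the largest above-threshold connected region
#' of the nuclear channel (tagged-protein or DNA-dye fluorescence) inside
#' the soma ROI; the returned mask is always a subset of the soma mask.
#'
#' @param soma_mask Logical matrix: the cell's soma ROI (nonempty).
#' @param nuclear_image Numeric matrix: the nuclear channel (AU).
#' @param threshold Optional absolute threshold; default Otsu over the
#'   soma pixels.
#' @return Logical nuclear mask.
#' @export
nuclear_mask <- function(soma_mask, nuclear_image, threshold = NULL) {
  stopifnot(identical(dim(soma_mask), dim(nuclear_image)))
  if (!any(soma_mask)) stop("empty soma ROI")
  v <- nuclear_image[soma_mask]
  if (diff(range(v)) <= 0) stop("nucleus not found: no nuclear signal")
  thr <- threshold %||% otsu_threshold(v)
  bw <- nuclear_image > thr & soma_mask
  if (!any(bw)) stop("nucleus not found: no nuclear signal")
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Nucleocytoplasmic ratio of a reporter
#'
#' Ratio of mean reporter intensity in the nucleus to that in the
#' cytoplasm (soma minus nucleus). When the cytoplasmic mean falls below
#' the noise floor (median background + 2 MAD by default) the ratio is
#' flagged unbounded and reported as `NA` rather than as an arbitrarily
#' large number, so flagged cells drop out of group means.
#'
#' @param soma_mask,nuc_mask Logical masks; the cytoplasm
#'   `soma_mask & !nuc_mask` must be nonempty.
#' @param reporter_image Numeric intensity matrix (AU).
#' @param noise_floor Intensity below which the cytoplasmic mean is
#'   considered indistinguishable from background; default estimated from
#'   the non-soma pixels as `median + 2 * mad`.
#' @return A `nc_measurement` list: `nuclear_mean`, `cytoplasmic_mean`,
#'   `ratio` (`NA` if unbounded), `unbounded`.
#' @export
nuc_cyto_ratio <- function(soma_mask, nuc_mask, reporter_image,
                           noise_floor = NULL) {
  stopifnot(identical(dim(soma_mask), dim(nuc_mask)))
  cyto <- soma_mask & !nuc_mask
  if (!any(cyto)) stop("empty cytoplasmic region")
  nuc_mean <- mean(reporter_image[nuc_mask & soma_mask])
  cyto_mean <- mean(reporter_image[cyto])
  if (is.null(noise_floor)) {
    bg <- reporter_image[!soma_mask]
    noise_floor <- if (length(bg)) median(bg) + 2 * mad(bg) else 0
  }
  unbounded <- cyto_mean <= noise_floor
  structure(list(
    nuclear_mean = nuc_mean, cytoplasmic_mean = cyto_mean,
    ratio = if (unbounded) NA_real_ else nuc_mean / cyto_mean,
    unbounded = unbounded, noise_floor = noise_floor
  ), class = "nc_measurement")
}

#' Quantitative immunofluorescence over soma ROIs
#'
#' Per-cell background-subtracted mean antibody-channel intensity, with
#' background estimated per image (median of non-ROI pixels by default)
#' and negative values clamped to zero, plus condition fold-changes
#' against a reference condition (fold-change = mean(condition) /
#' mean(reference); knockdown percent = 1 - fold-change).
#'
#' @param images List of numeric matrices (antibody channel), one per
#'   cell, or a single matrix shared by all cells.
#' @param soma_rois List of logical soma masks, one per cell.
#' @param conditions Character vector of condition labels per cell.
#' @param reference Reference condition (default the first).
#' @param background `"image_median"` (default) or a numeric value.
#' @return A list with `cells` (data.frame: `id`, `condition`,
#'   `intensity`) and `fold_changes` (data.frame: `condition`,
#'   `fold_change`, `knockdown_percent`).
#' @export
quantify_immunoreactivity <- function(images, soma_rois, conditions,
                                      reference = NULL,
                                      background = "image_median") {
  n <- length(soma_rois)
  if (is.matrix(images)) images <- rep(list(images), n)
  stopifnot(length(images) == n, length(conditions) == n)
  if (length(unique(conditions)) < 2L)
    stop("need at least 2 conditions for fold-changes")
  reference <- reference %||% conditions[1]
  vals <- vapply(seq_len(n), function(i) {
    img <- images[[i]]; roi <- soma_rois[[i]]
    bg <- if (identical(background, "image_median"))
      median(img[!roi]) else background
    max(mean(img[roi]) - bg, 0)
  }, 1)
  cells <- data.frame(id = seq_len(n), condition = conditions,
                      intensity = vals, stringsAsFactors = FALSE)
  ref_mean <- mean(vals[conditions == reference])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference condition mean is not positive")
  conds <- setdiff(unique(conditions), reference)
  fc <- vapply(conds, function(cn) mean(vals[conditions == cn]) / ref_mean, 1)
  list(cells = cells,
       fold_changes = data.frame(condition = conds, fold_change = fc,
                                 knockdown_percent = 100 * (1 - fc),
                                 stringsAsFactors = FALSE,
                                 row.names = NULL),
       reference = reference)
}

#' Compare group means by t-test or one-way ANOVA with Tukey HSD
#'
#' Two-tailed Welch (default) or Student t-test for two groups, or
#' one-way ANOVA with Tukey honest-significant-difference pairwise
#' adjusted p-values — the standard comparisons for nucleocytoplasmic
#' ratios, viscosities, diffusion coefficients and half-lives. Groups
#' with zero variance are handled exactly: equal means give p = 1,
#' unequal means p = 0.
#'
#' @param values_by_group Named list of numeric vectors (each n >= 2).
#' @param method `"t_test"` or `"anova_tukey"`.
#' @param var_equal Student (TRUE) vs Welch (FALSE) t-test.
#' @return For `t_test`: list with `statistic`, `p`, `means`. For
#'   `anova_tukey`: list with `f_statistic`, `p` (overall F), and
#'   `pairwise` (data.frame: `comparison`, `diff`, `p_adj`).
#' @export
compare_groups <- function(values_by_group,
                           method = c("t_test", "anova_tukey"),
                           var_equal = FALSE) {
  method <- match.arg(method)
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L,
            !is.null(names(values_by_group)))
  if (any(vapply(values_by_group, length, 1L) < 2L))
    stop("every group needs n >= 2")
  if (method == "t_test") {
    if (length(values_by_group) != 2L)
      stop("t_test requires exactly 2 groups")
    a <- values_by_group[[1]]; b <- values_by_group[[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      equal <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(statistic = if (equal) 0 else Inf,
                  p = if (equal) 1 else 0,
                  means = c(mean(a), mean(b)), degenerate = TRUE))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                means = unname(tt$estimate), degenerate = FALSE))
  }
  v <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 1L)))
  if (sd(v) == 0)
    return(list(f_statistic = 0, p = 1, pairwise = NULL, degenerate = TRUE))
  fit <- aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(f_statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"], p_adj = tk[, "p adj"],
                             row.names = NULL, stringsAsFactors = FALSE),
       degenerate = FALSE)
}
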