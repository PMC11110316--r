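#' Kernel density of methylation differences
#'
#' Estimates the density of per-CpG methylation differences (delta-beta =
#' case minus baseline) with a Gaussian kernel on a fixed grid of 1024 equally
#' spaced points spanning `[-1, 1]` inclusive (1023 subintervals), bandwidth
#' 0.01 by default. Missing pairs are dropped before estimation.
#'
#' @param case_betas Numeric vector of case beta values.
#' @param baseline_betas Numeric vector of baseline beta values aligned to
#'   `case_betas` on the same CpG set (typically the per-CpG mean over the
#'   normal B-cell samples).
#' @param bw Kernel bandwidth (Gaussian kernel standard deviation).
#' @param n_grid Number of grid points, default 1024.
#' @return A list of class `"delta_density"`: `x` (grid), `y` (density
#'   ordinates), `bw`, `n_source` (number of delta-beta values used).
#' @export
delta_density <- function(case_betas, baseline_betas, bw = 0.01,
                          n_grid = 1024L) {
  stopifnot(length(case_betas) == length(baseline_betas),
            is.numeric(bw), bw > 0, n_grid >= 2L)
  delta <- case_betas - baseline_betas
  delta <- delta[!is.na(delta)]
  if (length(delta) < 2L)
    stop("need at least 2 aligned non-missing CpG pairs, got ", length(delta))
  d <- stats::density(delta, bw = bw, kernel = "gaussian", n = n_grid,
                      from = -1, to = 1)
  structure(list(x = d$x, y = d$y, bw = bw, n_source = length(delta)),
            class = "delta_density")
}

#' @export
print.delta_density <- function(x, ...) {
  cat("<delta_density> ", length(x$x), " grid points on [",
      min(x$x), ", ", max(x$x), "], bw = ", x$bw,
      ", n = ", x$n_source, "\n", sep = "")
  invisible(x)
}

#' Methylation Variability Score between two density curves
#'
#' The score is the trapezoid-rule integral over `[-1, 1]` of the absolute
#' difference between two delta-beta densities on the same grid (the area
#' between the curves). Since each density integrates to about 1, the score
#' lies in `[0, ~2]`: 0 means the case density is identical to the reference
#' density on the grid; 2 means the two distributions are fully disjoint.
#' The score is symmetric in its arguments.
#'
#' @param case_curve,reference_curve Two [delta_density()] curves on the
#'   identical grid.
#' @return Non-negative numeric score.
#' @examples
#' a <- delta_density(c(0.5, 0.5, 0.5), c(0, 0, 0))
#' mvs_score(a, a)  # 0
#' @export
mvs_score <- function(case_curve, reference_curve) {
  stopifnot(inherits(case_curve, "delta_density"),
            inherits(reference_curve, "delta_density"))
  if (!isTRUE(all.equal(case_curve$x, reference_curve$x)))
    stop("the two density curves are not on the same grid")
  trapezoid(case_curve$x, abs(case_curve$y - reference_curve$y))
}

#' Methylation Variability Scores for a cohort
#'
#' Full MVS pipeline: per-CpG baseline = mean beta over the baseline group's
#' samples (missing values excluded per CpG); the reference curve is the
#' delta-beta density of the reference sample (normal GC B-cells) against
#' that baseline; every other non-baseline sample is scored against the
#' reference curve with [mvs_score()]. With `region = "promoter"` the CpG set
#' is first restricted to promoter-associated CpGs (TSS1500, TSS200, 5'UTR,
#' 1stExon).
#'
#' @param x A [beta_set()].
#' @param baseline_group Entity label of the baseline group in
#'   `x$samples$entity` (default `"normal-B"`).
#' @param reference_sample Sample id of the reference sample.
#' @param region `"global"` or `"promoter"`.
#' @param bw Kernel bandwidth passed to [delta_density()].
#' @param keep_curves Retain each sample's density curve in the result.
#' @return `data.frame` of class `"mvs_result"` with columns `sample_id`,
#'   `mvs`, `n_cpgs`; attributes `region`, `reference_sample`,
#'   `baseline_group`, `reference_curve`, and (optionally) `curves`.
#' @export
mvs_scores <- function(x, baseline_group = "normal-B", reference_sample,
                       region = c("global", "promoter"), bw = 0.01,
                       keep_curves = FALSE) {
  stopifnot(inherits(x, "beta_set"))
  region <- match.arg(region)
  if (!"entity" %in% names(x$samples))
    stop("sample sheet lacks an 'entity' column")
  base_ids <- x$samples$sample_id[x$samples$entity == baseline_group]
  if (!length(base_ids))
    stop("baseline group '", baseline_group, "' has no samples")
  if (!reference_sample %in% x$samples$sample_id)
    stop("reference sample '", reference_sample, "' not found")

  if (region == "promoter") {
    keep <- is_promoter_cpg(x$annotation)
    if (!any(keep)) stop("empty promoter-associated CpG subset")
    x <- x[keep, ]
  }
  v <- x$values
  baseline <- rowMeans(v[, base_ids, drop = FALSE], na.rm = TRUE)
  ref_curve <- delta_density(v[, reference_sample], baseline, bw = bw)

  score_ids <- setdiff(colnames(v), c(base_ids, reference_sample))
  curves <- lapply(score_ids, function(s)
    delta_density(v[, s], baseline, bw = bw))
  names(curves) <- score_ids
  out <- data.frame(
    sample_id = score_ids,
    mvs = vapply(curves, mvs_score, numeric(1L),
                 reference_curve = ref_curve),
    n_cpgs = vapply(curves, function(cv) cv$n_source, numeric(1L)),
    row.names = NULL
  )
  class(out) <- c("mvs_result", "data.frame")
  attr(out, "region") <- region
  attr(out, "reference_sample") <- reference_sample
  attr(out, "baseline_group") <- baseline_group
  attr(out, "reference_curve") <- ref_curve
  if (keep_curves) attr(out, "curves") <- curves
  out
}
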