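#' Methylation class thresholds
#'
#' Beta-value cutoffs separating the hypomethylated peak, the semimethylated
#' mid-range and the hypermethylated peak of the bimodal array distribution.
#' Defaults: hypo below 0.15, hyper above 0.8, semi the closed interval in
#' between (both boundaries belong to the semi class).
#'
#' @param hypo_upper Upper (exclusive) beta bound of the hypo class.
#' @param hyper_lower Lower (exclusive) beta bound of the hyper class.
#' @return A list of class `"partition_thresholds"`.
#' @export
partition_thresholds <- function(hypo_upper = 0.15, hyper_lower = 0.8) {
  stopifnot(is.numeric(hypo_upper), is.numeric(hyper_lower),
            hypo_upper > 0, hypo_upper < hyper_lower, hyper_lower < 1)
  structure(list(hypo_upper = hypo_upper, hyper_lower = hyper_lower),
            class = "partition_thresholds")
}

#' Classify beta values into hypo / semi / hyper
#'
#' `hypo` iff `beta < hypo_upper`; `semi` iff
#' `hypo_upper <= beta <= hyper_lower`; `hyper` iff `beta > hyper_lower`.
#'
#' @param beta Numeric vector of beta values in `[0, 1]` (no `NA`; drop
#'   missing values upstream).
#' @param thresholds A [partition_thresholds()].
#' @return Factor with levels `hypo`, `semi`, `hyper`.
#' @examples
#' classify_beta(c(0.10, 0.15, 0.80, 0.81))
#' @export
classify_beta <- function(beta, thresholds = partition_thresholds()) {
  stopifnot(inherits(thresholds, "partition_thresholds"))
  if (anyNA(beta)) stop("missing beta values must be excluded upstream")
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  out <- ifelse(beta < thresholds$hypo_upper, "hypo",
                ifelse(beta > thresholds$hyper_lower, "hyper", "semi"))
  factor(out, levels = c("hypo", "semi", "hyper"))
}

#' Per-sample methylation partition summary
#'
#' For each sample, counts and percentages of hypo-, semi- and hypermethylated
#' CpGs over its non-missing beta values, plus the mean beta. Percentages are
#' `count / evaluable * 100` and sum to 100. Samples with zero evaluable CpGs
#' are excluded with a warning.
#'
#' @param x A [beta_set()].
#' @param thresholds A [partition_thresholds()].
#' @return `data.frame` of class `"partition_summary"` with columns
#'   `sample_id`, `n_evaluable`, `n_hypo`, `n_semi`, `n_hyper`, `pct_hypo`,
#'   `pct_semi`, `pct_hyper`, `mean_beta`.
#' @export
sample_partition <- function(x, thresholds = partition_thresholds()) {
  stopifnot(inherits(x, "beta_set"))
  v <- x$values
  ok <- !is.na(v)
  n_eval <- colSums(ok)
  if (any(n_eval == 0)) {
    warning("excluding sample(s) with zero evaluable CpGs: ",
            paste(colnames(v)[n_eval == 0], collapse = ", "))
    v <- v[, n_eval > 0, drop = FALSE]
    ok <- ok[, n_eval > 0, drop = FALSE]
    n_eval <- n_eval[n_eval > 0]
  }
  hypo <- colSums(v < thresholds$hypo_upper & ok, na.rm = TRUE)
  hyper <- colSums(v > thresholds$hyper_lower & ok, na.rm = TRUE)
  semi <- n_eval - hypo - hyper
  out <- data.frame(
    sample_id = colnames(v),
    n_evaluable = as.integer(n_eval),
    n_hypo = as.integer(hypo), n_semi = as.integer(semi),
    n_hyper = as.integer(hyper),
    pct_hypo = hypo / n_eval * 100,
    pct_semi = semi / n_eval * 100,
    pct_hyper = hyper / n_eval * 100,
    mean_beta = colMeans(v, na.rm = TRUE),
    row.names = NULL
  )
  class(out) <- c("partition_summary", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-CpG cohort classes and interquartile ranges
#'
#' Assigns each CpG one class from the mean of its beta values across samples
#' (missing values excluded) and reports the IQR of its beta values, the
#' cohort-level measure of intertumor variability within each class. CpGs with
#' no non-missing value are excluded with a warning; the IQR needs at least
#' two samples.
#'
#' @inheritParams sample_partition
#' @return `data.frame` of class `"cpg_partition"` with columns `cpg_id`,
#'   `n_evaluable`, `mean_beta`, `class`, `iqr`.
#' @export
cpg_partition <- function(x, thresholds = partition_thresholds()) {
  stopifnot(inherits(x, "beta_set"))
  if (ncol(x$values) < 2L) stop("IQR needs at least two samples")
  v <- x$values
  n_eval <- rowSums(!is.na(v))
  if (any(n_eval == 0)) {
    warning("excluding ", sum(n_eval == 0), " all-missing CpG row(s)")
    keep <- n_eval > 0
    v <- v[keep, , drop = FALSE]
    n_eval <- n_eval[keep]
  }
  mb <- rowMeans(v, na.rm = TRUE)
  iqr <- apply(v, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) NA_real_ else stats::IQR(r)
  })
  out <- data.frame(
    cpg_id = rownames(v),
    n_evaluable = as.integer(n_eval),
    mean_beta = mb,
    class = classify_beta(mb, thresholds),
    iqr = iqr,
    row.names = NULL
  )
  class(out) <- c("cpg_partition", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

# Island membership for island-annotated CpGs: use an explicit island_id
# column when the annotation provides one, otherwise group contiguous runs of
# Island-annotated CpGs within a chromosome (positions sorted).
island_ids <- function(annotation) {
  is_island <- annotation$relation_to_island == "Island"
  if ("island_id" %in% names(annotation)) {
    ids <- as.character(annotation$island_id)
    ids[!is_island | is.na(ids) | ids == ""] <- NA_character_
    return(ids)
  }
  ids <- rep(NA_character_, nrow(annotation))
  ord <- order(annotation$chrom, annotation$pos)
  isl <- is_island[ord]
  chrom <- annotation$chrom[ord]
  new_run <- isl & (!c(FALSE, isl[-length(isl)]) |
                      c(TRUE, chrom[-1L] != chrom[-length(chrom)]))
  run_id <- cumsum(new_run)
  ids[ord[isl]] <- paste0("cgi_", chrom[isl], "_", run_id[isl])
  ids
}

#' CpG island methylation metrics
#'
#' Restricts to island-annotated CpGs (optionally further to
#' promoter-associated ones: TSS1500, TSS200, 5'UTR, 1stExon), computes each
#' sample's mean beta over island CpGs, aggregates CpGs into islands and calls
#' an island hypermethylated in a sample when its aggregate exceeds
#' `hyper_lower`. Two aggregation rules are available: `"mean"` (island mean
#' beta above the cutoff; default) and `"any"` (any member CpG above it).
#'
#' @inheritParams sample_partition
#' @param promoter_only Restrict to promoter-associated island CpGs.
#' @param island_rule `"mean"` or `"any"` (see Description).
#' @return A list of class `"cgi_metrics"`: `per_sample` (`data.frame` with
#'   `sample_id`, `cgi_mean_beta`, `pct_hyper_cgi`), `status` (logical island
#'   x sample matrix), `island_genes` (named list island -> gene symbols),
#'   `n_islands`, `promoter_only`.
#' @export
cgi_metrics <- function(x, thresholds = partition_thresholds(),
                        promoter_only = FALSE,
                        island_rule = c("mean", "any")) {
  stopifnot(inherits(x, "beta_set"))
  island_rule <- match.arg(island_rule)
  ids <- island_ids(x$annotation)
  keep <- !is.na(ids)
  if (promoter_only) keep <- keep & is_promoter_cpg(x$annotation)
  if (!any(keep)) stop("no ", if (promoter_only) "promoter-associated ",
                       "island-annotated CpGs in the input")
  v <- x$values[keep, , drop = FALSE]
  ids <- ids[keep]
  genes <- as.character(x$annotation$gene[keep])

  cgi_mean_beta <- colMeans(v, na.rm = TRUE)
  grp <- split(seq_along(ids), ids)
  agg <- vapply(grp, function(i) {
    sub <- v[i, , drop = FALSE]
    if (island_rule == "mean") colMeans(sub, na.rm = TRUE)
    else suppressWarnings(apply(sub, 2L, max, na.rm = TRUE))
  }, numeric(ncol(v)))
  agg <- if (ncol(v) == 1L) matrix(agg, ncol = 1L) else t(agg)
  dimnames(agg) <- list(names(grp), colnames(v))
  status <- agg > thresholds$hyper_lower
  island_genes <- lapply(grp, function(i) {
    g <- unique(genes[i])
    g[!is.na(g) & g != ""]
  })
  per_sample <- data.frame(
    sample_id = colnames(v),
    cgi_mean_beta = cgi_mean_beta,
    pct_hyper_cgi = colMeans(status, na.rm = TRUE) * 100,
    row.names = NULL
  )
  structure(
    list(per_sample = per_sample, status = status,
         island_genes = island_genes, n_islands = length(grp),
         promoter_only = promoter_only, island_rule = island_rule),
    class = "cgi_metrics"
  )
}

#' @export
print.cgi_metrics <- function(x, ...) {
  cat("<cgi_metrics> ", x$n_islands, " islands x ", ncol(x$status),
      " samples (", x$island_rule, " rule",
      if (x$promoter_only) ", promoter-associated", ")\n", sep = "")
  invisible(x)
}

#' Quantile-based group labels
#'
#' Labels per-sample values by quartile (`<Q1`, `Q1-Q3`, `>Q3`; both quantile
#' values belong to the middle group) or by median (`<median`, `>=median`).
#' Quantiles are always computed on the reference cohort — by default the
#' values themselves — so a subset can be labeled with full-cohort cutpoints.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Named numeric vector of per-sample values to label.
#' @param scheme `"quartile"` or `"median"`.
#' @param reference Numeric vector over which the quantiles are computed
#'   (default `values`).
#' @return A list of class `"quantile_groups"`: `labels` (factor, named as
#'   `values`), `cutpoints`, `scheme`.
#' @examples
#' quantile_groups(stats::setNames(1:8, paste0("s", 1:8)))$labels
#' @export
quantile_groups <- function(values, scheme = c("quartile", "median"),
                            reference = values) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(values), is.numeric(reference))
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("empty reference cohort")
  if (scheme == "quartile") {
    q <- stats::quantile(reference, c(0.25, 0.75), names = FALSE, type = 7)
    lab <- ifelse(values < q[1], "<Q1", ifelse(values > q[2], ">Q3", "Q1-Q3"))
    lab <- factor(lab, levels = c("<Q1", "Q1-Q3", ">Q3"))
    cut <- c(Q1 = q[1], Q3 = q[2])
  } else {
    m <- stats::median(reference)
    lab <- ifelse(values < m, "<median", ">=median")
    lab <- factor(lab, levels = c("<median", ">=median"))
    cut <- c(median = m)
  }
  names(lab) <- names(values)
  structure(list(labels = lab, cutpoints = cut, scheme = scheme),
            class = "quantile_groups")
}

#' @export
print.quantile_groups <- function(x, ...) {
  cat("<quantile_groups> scheme=", x$scheme, "; cutpoints: ",
      paste(names(x$cutpoints), signif(x$cutpoints, 5), sep = "=",
            collapse = ", "), "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}
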