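#' Differentially methylated CpGs between two groups
#'
#' Per-CpG group means (missing values excluded) and their difference
#' `delta = mean_A - mean_B`; a CpG is differentially methylated when
#' `|delta| >= threshold` (inclusive). CpGs with fewer than two evaluable
#' samples in either group are skipped with a warning.
#'
#' @param x A [beta_set()].
#' @param group_a,group_b Character vectors of sample ids, or entity labels
#'   looked up in `x$samples$entity`.
#' @param threshold Absolute mean-difference cutoff, default 0.2.
#' @return `data.frame` of class `"dm_cpg_set"` with columns `cpg_id`,
#'   `mean_a`, `mean_b`, `delta`, `gene`; attribute `comparison`.
#' @export
select_dm_cpgs <- function(x, group_a, group_b, threshold = 0.2) {
  stopifnot(inherits(x, "beta_set"), is.numeric(threshold), threshold >= 0)
  ids_a <- resolve_group(x, group_a)
  ids_b <- resolve_group(x, group_b)
  if (!length(ids_a) || !length(ids_b)) stop("empty comparison group")
  va <- x$values[, ids_a, drop = FALSE]
  vb <- x$values[, ids_b, drop = FALSE]
  na_ <- rowSums(!is.na(va))
  nb_ <- rowSums(!is.na(vb))
  skip <- na_ < 2L | nb_ < 2L
  usable <- !skip
  if (any(skip))
    warning("skipping ", sum(skip),
            " CpG(s) with < 2 evaluable samples in a group")
  ma <- rowMeans(va, na.rm = TRUE)[usable]
  mb <- rowMeans(vb, na.rm = TRUE)[usable]
  delta <- ma - mb
  sel <- abs(delta) >= threshold
  out <- data.frame(
    cpg_id = rownames(x$values)[usable][sel],
    mean_a = ma[sel], mean_b = mb[sel], delta = delta[sel],
    gene = as.character(
      x$annotation$gene[usable][sel]),
    row.names = NULL
  )
  class(out) <- c("dm_cpg_set", "data.frame")
  attr(out, "comparison") <- c(a = paste(group_a, collapse = "+"),
                               b = paste(group_b, collapse = "+"))
  attr(out, "threshold") <- threshold
  out
}

resolve_group <- function(x, group) {
  if (all(group %in% x$samples$sample_id)) return(as.character(group))
  if ("entity" %in% names(x$samples) && all(group %in% x$samples$entity))
    return(x$samples$sample_id[x$samples$entity %in% group])
  stop("group members not found as sample ids or entity labels: ",
       paste(group, collapse = ", "))
}

#' Entity-unique differentially methylated CpGs
#'
#' CpG ids present in the target entity's DM set and in none of the other
#' entities' sets (all sets computed against the same reference group).
#'
#' @param sets Named list of [select_dm_cpgs()] results (or of character id
#'   vectors), one per entity.
#' @param target Name of the target entity within `sets`.
#' @return Character vector of CpG ids unique to the target.
#' @export
unique_dm_cpgs <- function(sets, target) {
  if (!target %in% names(sets)) stop("target entity '", target,
                                     "' absent from sets")
  get_ids <- function(s) if (is.data.frame(s)) as.character(s$cpg_id)
                         else as.character(s)
  target_ids <- get_ids(sets[[target]])
  other <- unlist(lapply(sets[setdiff(names(sets), target)], get_ids),
                  use.names = FALSE)
  setdiff(target_ids, other)
}

#' CGI hypermethylation enrichment filter
#'
#' Retains islands hypermethylated in at least `high_min` of the high group's
#' samples and in no more than `rest_max` of the rest group's samples (both
#' boundaries inclusive). Used to pull out the CpG islands whose
#' hypermethylation is enriched in the highly hypomethylated (Hypo > Q3)
#' cases relative to the remaining cohort.
#'
#' @param island_status Logical island x sample matrix as produced by
#'   [cgi_metrics()] (`$status`).
#' @param group_high,group_rest Disjoint, non-empty character vectors of
#'   sample ids (columns of `island_status`).
#' @param high_min Minimum hypermethylation frequency in the high group,
#'   default 0.7.
#' @param rest_max Maximum hypermethylation frequency in the rest group,
#'   default 0.3.
#' @param island_genes Optional named list (island -> gene symbols) used to
#'   report the unique genes touched, as produced by [cgi_metrics()].
#' @return `data.frame` of class `"cgi_enrichment"` with columns `island_id`,
#'   `freq_high`, `freq_rest`, `genes` (semicolon-joined); attribute
#'   `unique_genes`.
#' @export
cgi_enrichment_filter <- function(island_status, group_high, group_rest,
                                  high_min = 0.7, rest_max = 0.3,
                                  island_genes = NULL) {
  stopifnot(is.matrix(island_status), is.logical(island_status))
  group_high <- as.character(group_high)
  group_rest <- as.character(group_rest)
  if (!length(group_high) || !length(group_rest))
    stop("both groups must be non-empty")
  if (length(intersect(group_high, group_rest)))
    stop("groups overlap: ",
         paste(intersect(group_high, group_rest), collapse = ", "))
  missing_ids <- setdiff(c(group_high, group_rest), colnames(island_status))
  if (length(missing_ids))
    stop("sample id(s) absent from island_status: ",
         paste(missing_ids, collapse = ", "))
  freq_high <- rowMeans(island_status[, group_high, drop = FALSE],
                        na.rm = TRUE)
  freq_rest <- rowMeans(island_status[, group_rest, drop = FALSE],
                        na.rm = TRUE)
  sel <- freq_high >= high_min & freq_rest <= rest_max
  sel[is.na(sel)] <- FALSE
  isl <- rownames(island_status)[sel]
  genes_per_island <- if (is.null(island_genes)) rep(list(character(0)),
                                                     sum(sel))
                      else island_genes[isl]
  out <- data.frame(
    island_id = isl,
    freq_high = freq_high[sel],
    freq_rest = freq_rest[sel],
    genes = vapply(genes_per_island, paste, character(1L), collapse = ";"),
    row.names = NULL
  )
  class(out) <- c("cgi_enrichment", "data.frame")
  attr(out, "thresholds") <- c(high_min = high_min, rest_max = rest_max)
  attr(out, "unique_genes") <- unique(unlist(genes_per_island,
                                             use.names = FALSE))
  out
}
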