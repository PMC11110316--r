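#' Methylation beta-value set
#'
#' Container for a CpG-by-sample matrix of methylation beta values together
#' with the CpG annotation, the sample sheet and an optional detection-p
#' matrix of the same shape. Beta values are fractions in `[0, 1]`; `NA`
#' encodes a missing measurement.
#'
#' The annotation must carry one row per CpG, aligned to the matrix rows, with
#' columns `cpg_id`, `chrom`, `pos`, `relation_to_island`, `refgene_group`,
#' `gene`, `snp_within_5bp`, `multimap`, `mqtl` (an `island_id` column is
#' optional and used by [cgi_metrics()] when present). `refgene_group` may
#' hold several semicolon-joined region labels. Chromosome labels are
#' normalized to the `chr`-prefixed form.
#'
#' @param values Numeric matrix, CpGs in rows, samples in columns; values in
#'   `[0, 1]` or `NA`. Row and column names, if absent, are taken from
#'   `annotation$cpg_id` and `samples$sample_id`.
#' @param annotation `data.frame` of per-CpG annotation (see Details).
#' @param samples `data.frame` sample sheet with at least `sample_id`;
#'   typically also `entity`, `age`, `sex`, `aaipi`, `treatment_group`.
#' @param detection_p Optional numeric matrix of detection p values, same
#'   dimensions as `values`.
#' @return An object of class `"beta_set"`.
#' @seealso [read_beta_matrix()], [filter_cpgs()], [sample_partition()]
#' @export
beta_set <- function(values, annotation, samples, detection_p = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- annotation$cpg_id
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  rng <- range(values, na.rm = TRUE)
  if (any(!is.na(values) & (values < 0 | values > 1)))
    stop("beta values must lie in [0, 1] or be NA; found range ",
         rng[1], "..", rng[2])
  if (anyDuplicated(rownames(values)))
    stop("duplicated CpG ids in the beta matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in the beta matrix")
  annotation <- normalize_annotation(annotation)
  if (!all(rownames(values) %in% annotation$cpg_id))
    stop("annotation does not cover every CpG in the matrix")
  annotation <- annotation[match(rownames(values), annotation$cpg_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) stop("sample sheet needs 'sample_id'")
  if (!all(colnames(values) %in% samples$sample_id))
    stop("sample sheet does not cover every sample in the matrix")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p must have the same dimensions as the beta matrix")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values, annotation = annotation, samples = samples,
         detection_p = detection_p),
    class = "beta_set"
  )
}

normalize_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation)
  needed <- c("cpg_id", "chrom", "pos", "relation_to_island", "refgene_group",
              "gene", "snp_within_5bp", "multimap", "mqtl")
  missing_cols <- setdiff(needed, names(annotation))
  if (length(missing_cols))
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(annotation$cpg_id)) stop("annotation cpg_id not unique")
  if (any(annotation$pos < 1)) stop("annotation pos must be >= 1 (1-based)")
  chrom <- as.character(annotation$chrom)
  chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  ok <- grepl("^chr([0-9]+|X|Y)$", chrom)
  if (any(!ok))
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[!ok]), collapse = ", "))
  annotation$chrom <- chrom
  for (fl in c("snp_within_5bp", "multimap", "mqtl"))
    annotation[[fl]] <- as.logical(annotation[[fl]])
  annotation
}

#' @export
dim.beta_set <- function(x) dim(x$values)

#' @export
dimnames.beta_set <- function(x) dimnames(x$values)

#' Subset a beta set
#'
#' Row (CpG) and column (sample) subsetting that keeps the annotation, sample
#' sheet and detection-p matrix aligned.
#'
#' @param x A [beta_set()].
#' @param i,j CpG and sample indices (logical, integer or character).
#' @param ... Ignored.
#' @return A `"beta_set"`.
#' @export
`[.beta_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, rownames(x$values))
  if (is.character(j)) j <- match(j, colnames(x$values))
  beta_set(x$values[i, j, drop = FALSE],
           x$annotation[i, , drop = FALSE],
           x$samples[j, , drop = FALSE],
           if (!is.null(x$detection_p)) x$detection_p[i, j, drop = FALSE])
}

#' @export
print.beta_set <- function(x, ...) {
  cat("<beta_set> ", nrow(x$values), " CpGs x ", ncol(x$values), " samples\n",
      sep = "")
  cat("  missing beta: ",
      format(100 * mean(is.na(x$values)), digits = 3), "%\n", sep = "")
  if ("entity" %in% names(x$samples)) {
    tab <- table(x$samples$entity)
    cat("  entities: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), "\n", sep = "")
  }
  cat("  detection p: ", if (is.null(x$detection_p)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

# Promoter-associated CpGs: any refgene_group label among TSS1500, TSS200,
# 5'UTR, 1stExon (labels semicolon-joined in the manifest style).
PROMOTER_GROUPS <- c("TSS1500", "TSS200", "5'UTR", "1stExon")

is_promoter_cpg <- function(annotation) {
  groups <- strsplit(as.character(annotation$refgene_group), ";", fixed = TRUE)
  vapply(groups, function(g) any(g %in% PROMOTER_GROUPS), logical(1L))
}

#' Read a beta matrix with annotation from tab-delimited files
#'
#' The beta (and optional detection-p) file is tab-delimited with a header row
#' of sample ids and the CpG id in the first column. The annotation file is
#' tab-delimited with the columns documented in [beta_set()]. The sample sheet
#' is a CSV; if omitted, a minimal sheet holding only the sample ids is built.
#'
#' @param beta_file Path to the beta-value table.
#' @param annotation_file Path to the CpG annotation table.
#' @param sample_file Optional path to the sample-sheet CSV.
#' @param detection_file Optional path to the detection-p table.
#' @return A [beta_set()].
#' @export
read_beta_matrix <- function(beta_file, annotation_file, sample_file = NULL,
                             detection_file = NULL) {
  read_mat <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    as.matrix(tab)
  }
  values <- read_mat(beta_file)
  annotation <- utils::read.delim(annotation_file, check.names = FALSE)
  samples <- if (is.null(sample_file)) data.frame(sample_id = colnames(values))
             else utils::read.csv(sample_file, check.names = FALSE)
  detection_p <- if (is.null(detection_file)) NULL else read_mat(detection_file)
  beta_set(values, annotation, samples, detection_p)
}

#' Write a beta set to tab-delimited files
#'
#' Inverse of [read_beta_matrix()]: writes the beta matrix (first column
#' `cpg_id`, then one column per sample), the annotation table, a sample-sheet
#' CSV and, when present, the detection-p matrix.
#'
#' @param x A [beta_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"methylome"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_beta_matrix <- function(x, dir, prefix = "methylome") {
  stopifnot(inherits(x, "beta_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, paste0(prefix, "_beta.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    samples = file.path(dir, paste0(prefix, "_samples.csv"))
  )
  write_mat <- function(m, path) {
    out <- data.frame(cpg_id = rownames(m), m, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(x$values, paths[["beta"]])
  utils::write.table(x$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(x$samples, paths[["samples"]], row.names = FALSE)
  if (!is.null(x$detection_p)) {
    paths[["detection"]] <- file.path(dir, paste0(prefix, "_detection.tsv"))
    write_mat(x$detection_p, paths[["detection"]])
  }
  invisible(paths)
}
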