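#' Read a CIMP panel file
#'
#' Plain-text panel: one CpG id per line; `#` starts a comment; blank lines
#' ignored.
#'
#' @param path Path to the panel file.
#' @return Character vector of class `"cimp_panel"` (unique CpG ids).
#' @export
read_cimp_panel <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  cimp_panel(lines[nzchar(lines)])
}

#' CIMP panel constructor
#'
#' @param cpg_ids Character vector of panel CpG identifiers (unique,
#'   non-empty).
#' @param note Optional provenance note.
#' @return Character vector of class `"cimp_panel"`.
#' @export
cimp_panel <- function(cpg_ids, note = NULL) {
  cpg_ids <- as.character(cpg_ids)
  if (!length(cpg_ids)) stop("empty CIMP panel")
  if (anyDuplicated(cpg_ids)) stop("duplicated ids in CIMP panel")
  structure(cpg_ids, class = "cimp_panel", note = note)
}

#' CpG island methylator phenotype classification
#'
#' For each sample, the fraction of panel CpGs (present in the matrix, with a
#' non-missing beta) whose beta is strictly greater than `beta_threshold`.
#' A sample is `CIMP-` if that fraction is at most `fraction_threshold`
#' (default 0.25) and `CIMP+` otherwise. Panel CpGs absent from the matrix
#' are dropped from the denominator, mirroring how panels are intersected
#' with filtered array data rather than imputed.
#'
#' @param x A [beta_set()].
#' @param panel A [cimp_panel()] or plain character vector of CpG ids.
#' @param beta_threshold Beta cutoff; strictly greater counts. Default 0.4.
#' @param fraction_threshold Fraction cutoff; at or below is `CIMP-`.
#'   Default 0.25.
#' @param min_coverage Minimum fraction of the panel that must be present in
#'   the matrix before labels are reported without a low-coverage warning.
#' @return `data.frame` of class `"cimp_result"`: `sample_id`,
#'   `n_panel_present`, `fraction_above`, `label` (factor `CIMP-` / `CIMP+`).
#' @export
classify_cimp <- function(x, panel, beta_threshold = 0.4,
                          fraction_threshold = 0.25, min_coverage = 0.5) {
  stopifnot(inherits(x, "beta_set"),
            beta_threshold > 0, beta_threshold < 1,
            fraction_threshold > 0, fraction_threshold < 1)
  panel <- as.character(panel)
  present <- intersect(panel, rownames(x$values))
  if (!length(present))
    stop("no CIMP panel CpGs present in the matrix")
  if (length(present) / length(panel) < min_coverage)
    warning("low panel coverage: ", length(present), "/", length(panel),
            " panel CpGs present; labels may be unreliable")
  v <- x$values[present, , drop = FALSE]
  n_present <- colSums(!is.na(v))
  frac <- colSums(v > beta_threshold, na.rm = TRUE) / n_present
  label <- ifelse(frac <= fraction_threshold, "CIMP-", "CIMP+")
  label[n_present == 0] <- NA
  if (any(n_present == 0))
    warning("sample(s) with no evaluable panel CpGs left unlabeled: ",
            paste(colnames(v)[n_present == 0], collapse = ", "))
  out <- data.frame(
    sample_id = colnames(v),
    n_panel_present = as.integer(n_present),
    fraction_above = frac,
    label = factor(label, levels = c("CIMP-", "CIMP+")),
    row.names = NULL
  )
  class(out) <- c("cimp_result", "data.frame")
  attr(out, "beta_threshold") <- beta_threshold
  attr(out, "fraction_threshold") <- fraction_threshold
  out
}
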