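#' CpG exclusion rules
#'
#' Configuration for [filter_cpgs()]. The rules mirror standard
#' methylation-array pre-processing: sex-chromosome CpGs (to avoid
#' sex-related bias), CpGs failing detection (p above threshold in any
#' sample), CpGs within 5 bp of a known SNP, non-specific multi-mapping
#' probes, CpGs in methylation QTLs, and duplicated CpGs mapping to the same
#' gene and position. Rules are applied in that order and a CpG removed by an
#' earlier rule is not counted again by a later one.
#'
#' @param sex_chrom Drop CpGs on chrX / chrY.
#' @param detection Drop CpGs whose detection p exceeds `detection_threshold`
#'   in any sample (requires a detection-p matrix).
#' @param detection_threshold Detection p cutoff, default 0.05.
#' @param snp Drop CpGs flagged `snp_within_5bp`.
#' @param multimap Drop CpGs flagged as multi-mapping probes.
#' @param mqtl Drop CpGs flagged as mQTL.
#' @param duplicate Drop duplicated CpGs mapping to the same (gene, position),
#'   keeping the lexicographically smallest `cpg_id`.
#' @return A list of class `"filter_rules"`.
#' @export
filter_rules <- function(sex_chrom = TRUE, detection = TRUE,
                         detection_threshold = 0.05, snp = TRUE,
                         multimap = TRUE, mqtl = TRUE, duplicate = TRUE) {
  stopifnot(is.numeric(detection_threshold), detection_threshold > 0,
            detection_threshold < 1)
  structure(list(sex_chrom = sex_chrom, detection = detection,
                 detection_threshold = detection_threshold, snp = snp,
                 multimap = multimap, mqtl = mqtl, duplicate = duplicate),
            class = "filter_rules")
}

#' Apply CpG exclusion rules to a beta set
#'
#' Drops rows only; no beta value is altered. The removal report counts each
#' CpG once, under the first rule that removed it, so the per-rule counts plus
#' the survivors always add up to the input CpG count.
#'
#' @param x A [beta_set()].
#' @param rules A [filter_rules()] configuration.
#' @return A list of class `"cpg_filter_result"` with elements `data` (the
#'   filtered `"beta_set"`) and `report` (a `data.frame` of per-rule removal
#'   counts, plus survivors and input size as attributes).
#' @examples
#' cfg <- methylome_sim_config(n_cpgs = 300, seed = 1)
#' res <- filter_cpgs(simulate_methylome(cfg))
#' res$report
#' @export
filter_cpgs <- function(x, rules = filter_rules()) {
  stopifnot(inherits(x, "beta_set"), inherits(rules, "filter_rules"))
  ann <- x$annotation
  n_in <- nrow(x$values)
  removed <- logical(n_in)
  report <- c()

  apply_rule <- function(name, hit) {
    hit <- hit & !removed
    report <<- c(report, stats::setNames(sum(hit), name))
    removed <<- removed | hit
  }

  if (isTRUE(rules$sex_chrom))
    apply_rule("sex_chrom", ann$chrom %in% c("chrX", "chrY"))
  if (isTRUE(rules$detection)) {
    if (is.null(x$detection_p))
      stop("detection rule enabled but no detection-p matrix is present")
    bad <- rowSums(x$detection_p > rules$detection_threshold,
                   na.rm = TRUE) > 0
    apply_rule("detection", bad)
  }
  if (isTRUE(rules$snp)) apply_rule("snp", ann$snp_within_5bp %in% TRUE)
  if (isTRUE(rules$multimap)) apply_rule("multimap", ann$multimap %in% TRUE)
  if (isTRUE(rules$mqtl)) apply_rule("mqtl", ann$mqtl %in% TRUE)
  if (isTRUE(rules$duplicate)) {
    # duplicated CpGs mapping to the same gene and position; among the
    # still-unremoved members of a duplicate group the lexicographically
    # smallest cpg_id is kept
    key <- paste(ann$gene, ann$chrom, ann$pos, sep = "\r")
    alive <- which(!removed)
    orda <- alive[order(key[alive], ann$cpg_id[alive])]
    dup_hit <- logical(n_in)
    dup_hit[orda] <- duplicated(key[orda])
    apply_rule("duplicate", dup_hit)
  }

  keep <- !removed
  report_df <- data.frame(rule = names(report), removed = as.integer(report))
  out <- structure(
    list(data = x[keep, ], report = report_df),
    class = "cpg_filter_result"
  )
  attr(out, "n_input") <- n_in
  attr(out, "n_survivors") <- sum(keep)
  out
}

#' @export
print.cpg_filter_result <- function(x, ...) {
  cat("<cpg_filter_result> ", attr(x, "n_input"), " CpGs in, ",
      attr(x, "n_survivors"), " surviving\n", sep = "")
  rep <- x$report[x$report$removed > 0, , drop = FALSE]
  if (nrow(rep))
    cat(paste0("  ", rep$rule, ": ", rep$removed, collapse = "\n"), "\n")
  invisible(x)
}
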