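# Small hand-built beta sets used across the unit tests.

# Annotation row with sensible defaults; override any field.
ann_row <- function(cpg_id, chrom = "chr1", pos = 1000,
                    relation_to_island = "OpenSea", refgene_group = "Body",
                    gene = "GENE1", snp_within_5bp = FALSE, multimap = FALSE,
                    mqtl = FALSE, island_id = NA_character_) {
  data.frame(cpg_id = cpg_id, chrom = chrom, pos = pos,
             relation_to_island = relation_to_island,
             refgene_group = refgene_group, gene = gene,
             snp_within_5bp = snp_within_5bp, multimap = multimap,
             mqtl = mqtl, island_id = island_id)
}

# beta_set from a matrix, with auto-generated clean annotation.
toy_beta_set <- function(values, annotation = NULL, samples = NULL,
                         detection_p = NULL, entity = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- if (!is.null(annotation)) annotation$cpg_id
                        else sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(annotation))
    annotation <- do.call(rbind, lapply(seq_len(nrow(values)), function(i)
      ann_row(rownames(values)[i], pos = i * 1000,
              gene = sprintf("GENE%d", i))))
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values))
    if (!is.null(entity)) samples$entity <- entity
  }
  beta_set(values, annotation, samples, detection_p)
}

expect_close <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
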