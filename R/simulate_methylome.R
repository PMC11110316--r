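#' Beta-mixture archetype
#'
#' A group-level methylome archetype: a mixture of Beta-family components on
#' `[0, 1]`, each parameterized by its mode and a concentration (larger =
#' tighter). Component `i` has shape parameters
#' `mode[i] * (conc[i] - 2) + 1` and `(1 - mode[i]) * (conc[i] - 2) + 1`, so
#' the stated mode is the density mode for `conc > 2`. Weights must sum to 1.
#'
#' @param weights Component weights, summing to 1 (within 1e-9).
#' @param modes Component modes in `[0, 1]`.
#' @param concentrations Component concentrations (> 2).
#' @return A list of class `"beta_mixture"`.
#' @export
beta_mixture <- function(weights, modes, concentrations) {
  stopifnot(length(weights) == length(modes),
            length(weights) == length(concentrations))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1, got ", sum(weights))
  if (any(weights < 0) || any(modes < 0) || any(modes > 1) ||
      any(concentrations <= 2))
    stop("invalid mixture parameters (weights >= 0, modes in [0,1], ",
         "concentrations > 2)")
  structure(list(weights = weights, modes = modes,
                 concentrations = concentrations),
            class = "beta_mixture")
}

# Draw one beta value per element of `component` (component index vector).
draw_beta_mixture <- function(mix, component) {
  a <- mix$modes * (mix$concentrations - 2) + 1
  b <- (1 - mix$modes) * (mix$concentrations - 2) + 1
  stats::rbeta(length(component), a[component], b[component])
}

#' Default methylome archetypes
#'
#' Archetypes matching the study conditions: sharply bimodal normal B-cell
#' profiles (peaks near 0 and 1) and lymphoma profiles with inflated
#' semimethylation. Class weights follow the reported per-entity medians of
#' hypo/semi/hyper percentages (and, for normal B-cells, that cohort's
#' per-CpG class proportions).
#'
#' @return Named list of [beta_mixture()] archetypes, one per group label
#'   used by [methylome_sim_config()].
#' @export
default_archetypes <- function() {
  arch <- function(w) beta_mixture(w / sum(w), c(0.03, 0.50, 0.96),
                                   c(150, 10, 100))
  list(
    "normal-B"     = arch(c(26.4, 20.9, 52.7)),
    "normal-GC-B"  = arch(c(28.0, 24.0, 48.0)),
    "DLBCL-GC"     = arch(c(23.82, 45.17, 28.63)),
    "DLBCL-nonGC"  = arch(c(24.43, 49.06, 25.76)),
    "HGBL"         = arch(c(21.59, 47.21, 30.24)),
    "PCNSL"        = arch(c(41.78, 29.68, 25.67)),
    "t-DLBCL"      = arch(c(22.70, 42.45, 32.48))
  )
}

#' Methylome simulation configuration
#'
#' Settings for [simulate_methylome()]. Defaults emulate the study cohort:
#' 28 normal B-cell samples, 1 normal GC B-cell sample and 93 lymphoma cases
#' across five entities, with bimodal normal profiles (peaks near 0 and 1)
#' and semimethylation-inflated lymphoma profiles whose class weights follow
#' the reported per-entity medians.
#'
#' Each CpG is assigned, per group, one mixture component (the group's state
#' at that CpG, drawn by the archetype weights); samples within the group
#' then draw their beta values independently from that component. This gives
#' coherent per-CpG classes within groups and mean-level differences between
#' groups. `component_links` lets a group reuse another group's component
#' assignment, making the two groups differ only by sampling noise.
#'
#' @param n_cpgs Number of CpGs. Default 670233, the post-filtration CpG
#'   count of an EPIC-array cohort; pass something small for toy runs.
#' @param n_samples_per_group Named integer vector, group label -> sample
#'   count.
#' @param archetypes Named list of [beta_mixture()] per group.
#' @param component_links Named character vector: group -> group whose
#'   per-CpG component assignment is reused.
#' @param fraction_island Fraction of CpGs annotated `Island`.
#' @param fraction_promoter Fraction annotated promoter-associated.
#' @param fraction_sex_chrom Fraction placed on chrX/chrY.
#' @param snp_rate,multimap_rate,mqtl_rate Rates of exclusion-flagged CpGs.
#' @param missing_rate Fraction of beta values set missing.
#' @param detection_exceed_rate Fraction of wells given a failing
#'   detection p (> 0.05); a detection-p matrix is always generated.
#' @param island_size Mean number of CpGs per simulated island.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `"methylome_sim_config"`.
#' @export
methylome_sim_config <- function(
    n_cpgs = 670233L,
    n_samples_per_group = c("normal-B" = 28L, "normal-GC-B" = 1L,
                            "DLBCL-GC" = 36L, "DLBCL-nonGC" = 30L,
                            "HGBL" = 7L, "PCNSL" = 8L, "t-DLBCL" = 12L),
    archetypes = NULL, component_links = NULL,
    fraction_island = 0.20, fraction_promoter = 0.32,
    fraction_sex_chrom = 0.03, snp_rate = 0.01, multimap_rate = 0.005,
    mqtl_rate = 0.01, missing_rate = 0, detection_exceed_rate = 0.001,
    island_size = 8, seed = 1L) {
  if (n_cpgs < 1) stop("n_cpgs must be >= 1")
  if (any(n_samples_per_group < 0) || is.null(names(n_samples_per_group)))
    stop("n_samples_per_group must be a named vector of non-negative counts")
  archetypes <- archetypes %||%
    default_archetypes()[names(n_samples_per_group)]
  miss <- setdiff(names(n_samples_per_group), names(archetypes))
  if (length(miss) || any(vapply(archetypes, is.null, logical(1L))))
    stop("no archetype for group(s): ", paste(miss, collapse = ", "))
  for (a in archetypes)
    if (!inherits(a, "beta_mixture")) stop("archetypes must be beta_mixture")
  for (f in c(fraction_island, fraction_promoter, fraction_sex_chrom,
              snp_rate, multimap_rate, mqtl_rate, missing_rate,
              detection_exceed_rate))
    if (f < 0 || f > 1) stop("all fractions/rates must lie in [0, 1]")
  if (!is.null(component_links)) {
    bad <- !(component_links %in% names(n_samples_per_group)) |
      !(names(component_links) %in% names(n_samples_per_group))
    if (any(bad)) stop("component_links must map known groups to known groups")
  }
  structure(
    list(n_cpgs = as.integer(n_cpgs),
         n_samples_per_group = n_samples_per_group,
         archetypes = archetypes, component_links = component_links,
         fraction_island = fraction_island,
         fraction_promoter = fraction_promoter,
         fraction_sex_chrom = fraction_sex_chrom,
         snp_rate = snp_rate, multimap_rate = multimap_rate,
         mqtl_rate = mqtl_rate, missing_rate = missing_rate,
         detection_exceed_rate = detection_exceed_rate,
         island_size = island_size, seed = as.integer(seed)),
    class = "methylome_sim_config"
  )
}

#' Simulate a methylome beta matrix
#'
#' Generates a [beta_set()] (beta matrix, CpG annotation, sample sheet,
#' detection-p matrix) under a [methylome_sim_config()]. Identical
#' configuration and seed give bitwise-identical output.
#'
#' @param config A [methylome_sim_config()].
#' @return A [beta_set()].
#' @examples
#' x <- simulate_methylome(methylome_sim_config(
#'   n_cpgs = 500, n_samples_per_group = c("normal-B" = 3, "DLBCL-GC" = 2),
#'   seed = 7))
#' x
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "methylome_sim_config"))
  with_seed(config$seed, {
    n <- config$n_cpgs
    groups <- names(config$n_samples_per_group)

    annotation <- simulate_annotation(config)

    # per-group component assignment, then per-sample draws
    components <- list()
    linked <- names(config$component_links)
    for (g in setdiff(groups, linked))
      components[[g]] <- sample.int(
        length(config$archetypes[[g]]$weights), n, replace = TRUE,
        prob = config$archetypes[[g]]$weights)
    for (g in intersect(groups, linked))
      components[[g]] <- components[[config$component_links[[g]]]]

    total <- sum(config$n_samples_per_group)
    values <- matrix(NA_real_, nrow = n, ncol = total)
    sample_id <- character(total)
    entity <- character(total)
    col <- 0L
    for (g in groups) {
      for (k in seq_len(config$n_samples_per_group[[g]])) {
        col <- col + 1L
        sample_id[col] <- sprintf("%s_%02d", g, k)
        entity[col] <- g
        values[, col] <- draw_beta_mixture(config$archetypes[[g]],
                                           components[[g]])
      }
    }
    colnames(values) <- sample_id
    rownames(values) <- annotation$cpg_id

    if (config$missing_rate > 0)
      values[stats::runif(length(values)) < config$missing_rate] <- NA_real_

    detection_p <- matrix(stats::runif(length(values), 0, 0.01),
                          nrow = n, dimnames = dimnames(values))
    if (config$detection_exceed_rate > 0) {
      fail <- stats::runif(length(values)) < config$detection_exceed_rate
      detection_p[fail] <- stats::runif(sum(fail), 0.051, 0.5)
    }

    samples <- data.frame(
      sample_id = sample_id, entity = entity,
      age = round(stats::runif(total, 25, 89)),
      sex = sample(c("M", "F"), total, replace = TRUE),
      row.names = NULL)
    beta_set(values, annotation, samples, detection_p)
  })
}

simulate_annotation <- function(config) {
  n <- config$n_cpgs
  n_sex <- round(n * config$fraction_sex_chrom)
  chrom <- c(sample(paste0("chr", 1:22), n - n_sex, replace = TRUE),
             sample(c("chrX", "chrY"), n_sex, replace = TRUE))
  ord <- order(chrom)
  chrom <- chrom[ord]
  pos <- unlist(lapply(split(seq_along(chrom), chrom), function(i)
    sort(sample.int(2e8, length(i)))), use.names = FALSE)

  is_island <- stats::runif(n) < config$fraction_island
  relation <- ifelse(is_island, "Island",
                     sample(c("Shore", "Shelf", "OpenSea"), n,
                            replace = TRUE, prob = c(0.25, 0.1, 0.65)))
  island_id <- rep(NA_character_, n)
  idx <- which(is_island)
  if (length(idx))
    island_id[idx] <- paste0(
      "cgi_", sprintf("%06d", ceiling(seq_along(idx) / config$island_size)))

  is_prom <- stats::runif(n) < config$fraction_promoter
  refgene_group <- ifelse(
    is_prom,
    sample(c("TSS1500", "TSS200", "5'UTR", "1stExon", "TSS200;5'UTR"),
           n, replace = TRUE),
    sample(c("Body", "3'UTR", "intergenic", "Body;3'UTR"), n, replace = TRUE))
  gene <- ifelse(refgene_group == "intergenic", "",
                 sprintf("GENE%05d", ceiling(seq_len(n) / 10)))
  data.frame(
    cpg_id = sprintf("cg%08d", seq_len(n)),
    chrom = chrom, pos = pos,
    relation_to_island = relation, island_id = island_id,
    refgene_group = refgene_group, gene = gene,
    snp_within_5bp = stats::runif(n) < config$snp_rate,
    multimap = stats::runif(n) < config$multimap_rate,
    mqtl = stats::runif(n) < config$mqtl_rate,
    row.names = NULL)
}
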