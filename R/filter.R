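#' SNP filtering configuration
#'
#' Thresholds mirroring a conservative ddRAD cleaning recipe: a minor-allele
#' frequency floor (computed on observed alleles only), a cap on the observed
#' heterozygote fraction per locus (paralog guard), and a per-locus presence
#' requirement expressed either as the minimum fraction of genotyped
#' individuals (0.70 for a permissive "full" dataset, 0.95 for a strict
#' "reduced" one) or as a maximum count of missing individuals.
#'
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`; default 0.05.
#' @param obs_het_max maximum observed heterozygote fraction in `[0, 1]`;
#'   default 0.70.
#' @param locus_presence_min minimum fraction of non-missing individuals per
#'   locus in `[0, 1]`; default 0.70.
#' @param max_missing_individuals optional integer; when set it replaces
#'   `locus_presence_min` (a locus passes if at most this many individuals
#'   are missing).
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf_min = 0.05, obs_het_max = 0.70,
                          locus_presence_min = 0.70,
                          max_missing_individuals = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            obs_het_max >= 0, obs_het_max <= 1,
            locus_presence_min >= 0, locus_presence_min <= 1)
  if (!is.null(max_missing_individuals))
    stopifnot(max_missing_individuals >= 0)
  structure(list(maf_min = maf_min, obs_het_max = obs_het_max,
                 locus_presence_min = locus_presence_min,
                 max_missing_individuals = max_missing_individuals),
            class = "filter_config")
}

#' Filter loci of a genotype matrix
#'
#' Retains exactly the loci that pass all three predicates of the
#' [filter_config()]: presence, minor allele frequency (on observed alleles;
#' loci with zero observed alleles are removed), and heterozygote-excess cap.
#' The predicates are conjunctive, so the evaluation order (presence, MAF,
#' het) only affects logging, not the result. Locus order is preserved and
#' the operation is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @param verbose log the per-step locus funnel via `message()`.
#' @return the filtered [genotype_matrix()]; an empty matrix (with a warning)
#'   if no locus survives.
#' @export
filter_loci <- function(g, cfg = filter_config(), verbose = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_loci(g) == 0L) stop("empty genotype matrix")
  gt <- g$genotypes
  n_ind <- nrow(gt)
  n_obs <- colSums(!is.na(gt))

  if (is.null(cfg$max_missing_individuals)) {
    pass_presence <- (n_obs / n_ind) >= cfg$locus_presence_min
  } else {
    pass_presence <- (n_ind - n_obs) <= cfg$max_missing_individuals
  }

  alt <- colSums(gt, na.rm = TRUE)
  p_alt <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  pass_maf <- !is.na(maf) & maf >= cfg$maf_min

  het <- colSums(gt == 1L, na.rm = TRUE)
  het_frac <- ifelse(n_obs > 0, het / n_obs, NA_real_)
  pass_het <- !is.na(het_frac) & het_frac <= cfg$obs_het_max

  keep <- pass_presence & pass_maf & pass_het
  if (verbose) {
    message(sprintf("filter_loci: %d loci in; presence %d, maf %d, het %d; %d retained",
                    ncol(gt), sum(pass_presence), sum(pass_maf),
                    sum(pass_het), sum(keep)))
  }
  if (!any(keep)) warning("all loci removed by filtering")
  genotype_matrix(gt[, keep, drop = FALSE],
                  individual_ids = g$individual_ids,
                  locus_ids = g$locus_ids[keep],
                  chrom = g$chrom[keep], pos = g$pos[keep])
}

#' Subset individuals
#'
#' Returns the sub-matrix restricted to `keep`, in the requested order; loci
#' are untouched. Intended for building reduced datasets of low-missingness
#' individuals (see [individuals_by_missingness()]).
#'
#' @param g a [genotype_matrix()].
#' @param keep character vector of individual ids, all present in `g`.
#' @return a [genotype_matrix()].
#' @export
select_individuals <- function(g, keep) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, g$individual_ids)
  if (length(unknown))
    stop("unknown individual id(s): ", paste(unknown, collapse = ", "))
  idx <- match(keep, g$individual_ids)
  genotype_matrix(g$genotypes[idx, , drop = FALSE],
                  individual_ids = keep, locus_ids = g$locus_ids,
                  chrom = g$chrom, pos = g$pos)
}

#' Rank individuals by completeness
#'
#' Ids of the `n` individuals with the lowest fraction of missing genotypes
#' (ties broken by original order). Post-VCF stand-in for selecting
#' individuals by sequencing depth.
#'
#' @param g a [genotype_matrix()].
#' @param n number of individuals to keep.
#' @return character vector of ids.
#' @export
individuals_by_missingness <- function(g, n) {
  miss <- rowMeans(is.na(g$genotypes))
  g$individual_ids[order(miss)][seq_len(min(n, length(miss)))]
}
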