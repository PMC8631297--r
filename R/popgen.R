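#' Labelled symmetric distance matrix
#'
#' @param values symmetric numeric matrix, zero diagonal (small negative Fst
#'   estimates are kept as-is).
#' @param labels axis labels.
#' @param kind one of `"allele_sharing"`, `"coancestry_differences"`,
#'   `"fst"`, `"hamming"`.
#' @return a `distance_matrix` object (numeric matrix with attributes).
#' @export
distance_matrix <- function(values, labels = rownames(values),
                            kind = c("allele_sharing",
                                     "coancestry_differences", "fst",
                                     "hamming")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(values)))
  ok <- !is.na(values)
  if (any(abs(values[ok] - t(values)[ok]) > 1e-8, na.rm = TRUE))
    stop("distance matrix must be symmetric")
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("distance_matrix", "matrix",
                                           "array"))
}

#' @exportS3Method base::print
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s), %d labels\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Write a distance matrix as tab-separated text
#' @param d a [distance_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(cbind(id = rownames(d), as.data.frame(unclass(d))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## per-locus allele frequency / heterozygosity helpers on a genotype matrix
locus_freq_het <- function(gt) {
  n_obs <- colSums(!is.na(gt))
  p_alt <- ifelse(n_obs > 0, colSums(gt, na.rm = TRUE) / (2 * n_obs),
                  NA_real_)
  het <- ifelse(n_obs > 0, colSums(gt == 1L, na.rm = TRUE) / n_obs, NA_real_)
  list(n = n_obs, p = p_alt, het = het)
}

#' Per-population diversity statistics
#'
#' Per locus and population: observed heterozygosity `Ho` is the heterozygote
#' fraction among non-missing genotypes; expected heterozygosity `He` is
#' Nei's unbiased gene diversity `(2n/(2n-1)) * (1 - sum p^2)` over the `n`
#' non-missing diploids. Per-population values are means over loci with data,
#' and `Fis = 1 - mean(Ho)/mean(He)` (ratio of means, which is stable when
#' monomorphic loci are included; `NA` when mean He is 0). The `Mean` row
#' holds arithmetic means of the per-population Ho and He (no mean Fis is
#' defined here).
#'
#' @param g a [genotype_matrix()].
#' @param pm a [population_map()] covering all individuals of `g`.
#' @return data.frame with columns `population`, `Ho`, `He`, `Fis`, `n_ind`,
#'   plus a final `Mean` row.
#' @export
diversity_stats <- function(g, pm) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- pops_of(g, pm)
  labels <- unique(pops)
  rows <- lapply(labels, function(pp) {
    gt <- g$genotypes[pops == pp, , drop = FALSE]
    if (all(is.na(gt)))
      return(data.frame(population = pp, Ho = NA_real_, He = NA_real_,
                        Fis = NA_real_, n_ind = nrow(gt)))
    fh <- locus_freq_het(gt)
    use <- fh$n > 0
    ho <- mean(fh$het[use])
    he_locus <- (2 * fh$n[use]) / (2 * fh$n[use] - 1) *
      (1 - (fh$p[use]^2 + (1 - fh$p[use])^2))
    # loci with a single genotyped diploid have undefined unbiased He
    he_locus[fh$n[use] == 1] <- NA_real_
    he <- mean(he_locus, na.rm = TRUE)
    fis <- if (is.finite(he) && he > 0) 1 - ho / he else NA_real_
    data.frame(population = pp, Ho = ho, He = he, Fis = fis,
               n_ind = nrow(gt))
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(population = "Mean", Ho = mean(out$Ho),
                         He = mean(out$He), Fis = NA_real_,
                         n_ind = sum(out$n_ind))
  rbind(out, mean_row)
}

## Weir & Cockerham (1984) per-locus variance components for r populations.
## n: diploid counts per pop, p: alt-allele freqs per pop, h: observed het
## fractions per pop. Returns c(a, b, c).
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1 || sum(n) == 0) return(c(NA_real_, NA_real_, NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  if (nc <= 0) return(c(NA_real_, NA_real_, NA_real_))
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

## theta for one population pair, vectorized over loci; returns the summed
## numerator (a) and denominator (a+b+c)
wc_pair_sums <- function(gt1, gt2) {
  f1 <- locus_freq_het(gt1)
  f2 <- locus_freq_het(gt2)
  use <- f1$n >= 1 & f2$n >= 1
  n1 <- f1$n[use]; n2 <- f2$n[use]
  p1 <- f1$p[use]; p2 <- f2$p[use]
  h1 <- f1$het[use]; h2 <- f2$het[use]
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  ok <- nbar > 1 & nc > 0
  n1 <- n1[ok]; n2 <- n2[ok]; p1 <- p1[ok]; p2 <- p2[ok]
  h1 <- h1[ok]; h2 <- h2[ok]; nbar <- nbar[ok]; nc <- nc[ok]
  if (!length(nbar)) return(c(num = 0, den = 0))
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(num = sum(a), den = sum(a + b + cc))
}

#' Pairwise Weir–Cockerham Fst
#'
#' Weir & Cockerham's (1984) theta for every population pair, combining loci
#' as the ratio of summed variance components (`sum a / sum (a+b+c)`).
#' Negative estimates are reported as-is; pairs with no informative locus
#' (denominator 0 or no jointly genotyped polymorphic site) are `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param pm a [population_map()]; at least two populations with >= 2
#'   individuals each.
#' @return a [distance_matrix()] of kind `"fst"` over population labels.
#' @export
pairwise_fst <- function(g, pm) {
  pops <- pops_of(g, pm)
  labels <- unique(pops)
  if (length(labels) < 2) stop("need at least two populations")
  k <- length(labels)
  out <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      s <- wc_pair_sums(g$genotypes[pops == labels[i], , drop = FALSE],
                        g$genotypes[pops == labels[j], , drop = FALSE])
      theta <- if (s[["den"]] != 0) s[["num"]] / s[["den"]] else NA_real_
      out[i, j] <- out[j, i] <- theta
    }
  }
  distance_matrix(out, labels, kind = "fst")
}

#' Allele-sharing distance between individuals
#'
#' For each pair of individuals the distance is
#' `1 - shared_alleles / (2 * L)`, over the `L` loci genotyped in both, where
#' genotypes are compared as unordered allele multisets (`0/0` vs `0/1` share
#' one allele, so `shared = 2 - |g_i - g_j|`). Pairs with no jointly observed
#' locus are `NA`.
#'
#' @param g a [genotype_matrix()] with >= 2 individuals.
#' @return a [distance_matrix()] of kind `"allele_sharing"`.
#' @export
allele_sharing_distance <- function(g) {
  gt <- g$genotypes
  n <- nrow(gt)
  L <- ncol(gt)
  if (n < 2) stop("need at least two individuals")
  # 1 - shared/(2*Lc) == manhattan(g_i, g_j)/(2*Lc) over the Lc jointly
  # observed loci; stats::dist already rescales its NA-excluded manhattan
  # sum by L/Lc, so dividing by 2L lands on the definition directly.
  man <- as.matrix(stats::dist(gt, method = "manhattan"))
  out <- man / (2 * L)
  diag(out) <- 0
  distance_matrix(out, g$individual_ids, kind = "allele_sharing")
}

#' Pairwise co-ancestry difference counts
#'
#' Counts, for every pair of individuals, the loci at which their genotypes
#' differ (both non-missing) — the raw dissimilarity behind the co-ancestry
#' heatmap. A similarity transform (`max(count) - count`) is attached as
#' attribute `similarity` for display.
#'
#' @param g a [genotype_matrix()] with >= 2 individuals.
#' @return a [distance_matrix()] of kind `"coancestry_differences"` with a
#'   `similarity` matrix attribute and a `comparable_loci` count matrix
#'   attribute.
#' @export
coancestry_matrix <- function(g) {
  gt <- g$genotypes
  n <- nrow(gt)
  if (n < 2) stop("need at least two individuals")
  out <- matrix(0, n, n)
  comp <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- !is.na(gt[i, ]) & !is.na(gt[j, ])
      comp[i, j] <- comp[j, i] <- sum(both)
      if (!any(both)) { out[i, j] <- out[j, i] <- NA_real_; next }
      d <- sum(gt[i, both] != gt[j, both])
      out[i, j] <- out[j, i] <- d
    }
  }
  dm <- distance_matrix(out, g$individual_ids,
                        kind = "coancestry_differences")
  mx <- max(out, na.rm = TRUE)
  attr(dm, "similarity") <- mx - unclass(dm)
  attr(dm, "comparable_loci") <- comp
  dm
}

#' Nei's standard genetic distance between two populations
#'
#' `D = -log( Jxy / sqrt(Jx * Jy) )` with the gene identities `J` averaged
#' over loci (biallelic case). Used as a reference-table summary statistic.
#'
#' @param gt1,gt2 genotype sub-matrices (individuals x loci) of the two
#'   populations, allele counts in \{0,1,2,NA\}.
#' @return a single numeric distance (>= 0, `NA` if undefined).
#' @export
nei_distance <- function(gt1, gt2) {
  f1 <- locus_freq_het(gt1)
  f2 <- locus_freq_het(gt2)
  use <- f1$n > 0 & f2$n > 0
  if (!any(use)) return(NA_real_)
  p1 <- f1$p[use]; p2 <- f2$p[use]
  jx <- mean(p1^2 + (1 - p1)^2)
  jy <- mean(p2^2 + (1 - p2)^2)
  jxy <- mean(p1 * p2 + (1 - p1) * (1 - p2))
  -log(jxy / sqrt(jx * jy))
}
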