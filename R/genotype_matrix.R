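#' Diploid genotype matrix
#'
#' Container for diploid biallelic genotypes coded as the count of alternate
#' alleles (0, 1, 2) with `NA` for missing calls. Rows are individuals,
#' columns are loci. Locus coordinates (chromosome, 1-based position) are kept
#' when the matrix was read from VCF so it can be written back.
#'
#' @param genotypes integer matrix (individuals x loci) with entries in
#'   \{0, 1, 2, NA\}.
#' @param individual_ids character vector of unique row labels.
#' @param locus_ids character vector of unique column labels.
#' @param chrom,pos optional per-locus chromosome names and 1-based positions;
#'   defaults place all loci on a synthetic chromosome at consecutive
#'   positions.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, individual_ids = rownames(genotypes),
                            locus_ids = colnames(genotypes),
                            chrom = NULL, pos = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(locus_ids))
    locus_ids <- paste0("locus", seq_len(ncol(genotypes)))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (length(individual_ids) != nrow(genotypes))
    stop("individual_ids length does not match genotype rows")
  if (length(locus_ids) != ncol(genotypes))
    stop("locus_ids length does not match genotype columns")
  if (anyDuplicated(individual_ids))
    stop("individual_ids must be unique")
  if (anyDuplicated(locus_ids))
    stop("locus_ids must be unique")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("genotypes must be 0, 1, 2 or NA")
  if (is.null(chrom)) chrom <- rep("chrSim", ncol(genotypes))
  if (is.null(pos)) pos <- seq_len(ncol(genotypes))
  dimnames(genotypes) <- list(individual_ids, locus_ids)
  structure(list(genotypes = genotypes,
                 individual_ids = individual_ids,
                 locus_ids = locus_ids,
                 chrom = as.character(chrom),
                 pos = as.integer(pos)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  g <- x$genotypes
  miss <- mean(is.na(g))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(g), ncol(g), 100 * miss))
  invisible(x)
}

#' Number of individuals / loci
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$genotypes)

#' @rdname n_individuals
#' @export
n_loci <- function(g) ncol(g$genotypes)

#' Per-genotype and per-locus missingness
#'
#' Reports the overall fraction of missing genotype calls and the mean
#' per-locus missing fraction. The two summaries answer the two common
#' definitions of "percent missing data" for a SNP table; both are returned
#' because they differ once loci drop out unevenly.
#'
#' @param g a `genotype_matrix`.
#' @return named list with `per_genotype`, `per_locus_mean`, and the
#'   per-locus vector `per_locus`.
#' @export
missingness_summary <- function(g) {
  m <- is.na(g$genotypes)
  per_locus <- colMeans(m)
  list(per_genotype = mean(m),
       per_locus_mean = mean(per_locus),
       per_locus = stats::setNames(per_locus, g$locus_ids))
}

#' Population map
#'
#' Assignment of each individual to one population label.
#'
#' @param individual_ids character vector of individual ids.
#' @param populations character vector of population labels, recycled checked
#'   to the same length.
#' @return named character vector (id -> population) of class
#'   `population_map`.
#' @export
population_map <- function(individual_ids, populations) {
  individual_ids <- as.character(individual_ids)
  populations <- as.character(populations)
  if (length(individual_ids) != length(populations))
    stop("individual_ids and populations must have equal length")
  if (anyDuplicated(individual_ids))
    stop("each individual must have exactly one population label")
  structure(stats::setNames(populations, individual_ids),
            class = "population_map")
}

#' Read / write a two-column population map
#'
#' Plain tab-separated text with columns `individual` and `population`.
#'
#' @param path file path.
#' @param pm a `population_map`.
#' @return `read_popmap` returns a `population_map`; `write_popmap` returns
#'   `path` invisibly.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("individual", "population") %in% names(tab)))
    stop("population map must have columns 'individual' and 'population'")
  population_map(tab$individual, tab$population)
}

#' @rdname read_popmap
#' @export
write_popmap <- function(pm, path) {
  tab <- data.frame(individual = names(pm), population = as.character(pm))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pops_of <- function(g, pm) {
  missing_ids <- setdiff(g$individual_ids, names(pm))
  if (length(missing_ids))
    stop("individuals without a population label: ",
         paste(missing_ids, collapse = ", "))
  as.character(pm[g$individual_ids])
}
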