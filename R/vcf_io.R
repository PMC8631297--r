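#' Read a genotype matrix from VCF
#'
#' Reads a VCF (v4.x) and decodes the GT field of every biallelic SNP record
#' into alternate-allele counts. Multiallelic records are skipped with a
#' warning; `./.` (or `.|.` / `.`) becomes `NA`. Only the GT subfield is
#' interpreted; phasing is ignored.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return a [genotype_matrix()] whose loci carry the VCF CHROM/POS
#'   coordinates (1-based, as in the standard) and whose locus ids are
#'   `CHROM_POS` (or the ID column where set).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("cannot read VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi))
    warning(sum(multi), " multiallelic or ALT-less record(s) skipped")
  keep <- which(!multi)
  if (!length(keep)) stop("VCF contains zero biallelic sites: ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  decode <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  mat <- apply(gt, 2, decode)
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = ncol(gt))
  mat <- t(mat)  # individuals x loci

  ids <- fix[, "ID"]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  locus_ids <- ifelse(is.na(ids) | ids == ".", paste(chrom, pos, sep = "_"),
                      ids)
  locus_ids <- make.unique(locus_ids)
  genotype_matrix(mat, individual_ids = colnames(gt), locus_ids = locus_ids,
                  chrom = chrom, pos = pos)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal plain-text VCFv4.2 with GT-only genotype columns; REF/ALT
#' are written as A/T placeholders for simulated data (the matrix stores
#' allele counts, not nucleotide states). `read_vcf(write_vcf(g))` reproduces
#' genotypes, ids and missingness exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write VCF: ", path))
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eokochia",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$individual_ids), collapse = "\t"))
  writeLines(header, con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- g$genotypes
  for (l in seq_len(ncol(gt))) {
    calls <- rep("./.", nrow(gt))
    ok <- !is.na(gt[, l])
    calls[ok] <- code[as.character(gt[ok, l])]
    rec <- paste(c(g$chrom[l], g$pos[l], g$locus_ids[l], "A", "T", ".",
                   "PASS", ".", "GT", calls), collapse = "\t")
    writeLines(rec, con)
  }
  invisible(path)
}
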