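# Small in-code fixtures shared across test files.

# genotype matrix from a plain integer matrix (NA = missing)
gm <- function(mat, ids = NULL, loci = NULL) {
  genotype_matrix(mat, individual_ids = ids, locus_ids = loci)
}

# random complete-data genotype matrix
random_gm <- function(n_ind, n_loci, seed) {
  set.seed(seed)
  gm(matrix(sample(0:2, n_ind * n_loci, replace = TRUE), n_ind))
}

# the three-haplotype plastid structure used throughout: H1-H2 one step,
# H2-H3 two steps (H1-H3 three steps)
fixture_haps <- function() {
  haplotype_set(c(H1 = "ATC", H2 = "GTC", H3 = "GCT"),
                c(H1 = 5L, H2 = 9L, H3 = 2L))
}

mid_draw <- function() {
  parameter_draw(N_Palinuro = 300, N_Capri = 255, N_Strombolicchio = 30,
                 N1b = 27, N2b = 27, t1 = 25005, t2 = 12507, db = 55)
}

write_tmp_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# a hand-written 3-record VCF: two biallelic SNPs and one triallelic record
vcf3_lines <- function() {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("chr1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT",
            "0/1", "1/1"), collapse = "\t"),
    paste(c("chr1", "200", "tri1", "A", "T,G", ".", "PASS", ".", "GT",
            "0/1", "1/2"), collapse = "\t"),
    paste(c("chr1", "300", "snp2", "C", "G", ".", "PASS", ".", "GT",
            "./.", "0/0"), collapse = "\t"))
}
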