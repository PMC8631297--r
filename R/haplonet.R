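#' Haplotype set
#'
#' Equal-length haploid sequences with per-haplotype carrier counts and an
#' optional haplotype x population occurrence table.
#'
#' @param sequences named character vector of equal-length nucleotide
#'   strings (ids as names).
#' @param frequencies named integer vector of carrier counts (>= 1); default
#'   1 per haplotype.
#' @param population_counts optional matrix (haplotype x population) of
#'   occurrence counts; rows must sum to `frequencies`.
#' @return object of class `haplotype_set`.
#' @export
haplotype_set <- function(sequences, frequencies = NULL,
                          population_counts = NULL) {
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("H", seq_along(sequences))
  if (length(unique(nchar(sequences))) != 1)
    stop("all haplotype sequences must have equal length")
  if (is.null(frequencies))
    frequencies <- stats::setNames(rep(1L, length(sequences)),
                                   names(sequences))
  frequencies <- frequencies[names(sequences)]
  if (any(frequencies < 1)) stop("frequencies must be >= 1")
  if (!is.null(population_counts)) {
    population_counts <- as.matrix(population_counts)
    population_counts <- population_counts[names(sequences), , drop = FALSE]
    if (!all(rowSums(population_counts) == frequencies))
      stop("population_counts rows must sum to frequencies")
  }
  structure(list(sequences = sequences,
                 frequencies = as.integer(frequencies),
                 population_counts = population_counts,
                 ids = names(sequences)),
            class = "haplotype_set")
}

#' @exportS3Method base::print
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes, length %d, %d individuals\n",
              length(x$sequences), nchar(x$sequences[1]),
              sum(x$frequencies)))
  invisible(x)
}

#' Read per-individual haploid sequences from FASTA
#'
#' Collapses identical sequences into haplotypes. Haplotype ids are assigned
#' `H1`, `H2`, ... in order of first appearance in the file. When a
#' [population_map()] is supplied, the haplotype x population count table is
#' filled from it.
#'
#' @param path FASTA file of equal-length sequences, one per individual.
#' @param pm optional [population_map()] keyed by the FASTA names.
#' @return a [haplotype_set()].
#' @export
read_haplotype_fasta <- function(path, pm = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste0, collapse = "",
                         FUN.VALUE = character(1)))
  uniq <- unique(seqs)
  hap_id <- stats::setNames(paste0("H", seq_along(uniq)), uniq)
  assign <- hap_id[seqs]
  freq <- table(factor(assign, levels = hap_id))
  pop_counts <- NULL
  if (!is.null(pm)) {
    pops <- as.character(pm[names(seqs)])
    pop_counts <- as.matrix(table(factor(assign, levels = hap_id),
                                  pops))
  }
  haplotype_set(stats::setNames(uniq, hap_id),
                stats::setNames(as.integer(freq), hap_id), pop_counts)
}

#' Read a haplotype table
#'
#' Tab-separated columns `id`, `sequence`, `count` (and optionally one count
#' column per population).
#' @param path file path.
#' @return a [haplotype_set()].
#' @export
read_haplotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sequence", "count") %in% names(tab)))
  extra <- setdiff(names(tab), c("id", "sequence", "count"))
  pc <- NULL
  if (length(extra)) {
    pc <- as.matrix(tab[, extra, drop = FALSE])
    rownames(pc) <- tab$id
  }
  haplotype_set(stats::setNames(tab$sequence, tab$id),
                stats::setNames(as.integer(tab$count), tab$id), pc)
}

hamming_pair <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) stop("sequence length mismatch")
  ok <- !(x %in% c("N", "-", "?")) & !(y %in% c("N", "-", "?"))
  sum(x[ok] != y[ok])
}

#' Pairwise Hamming distances between haplotypes
#'
#' Counts differing positions per pair; gaps and `N` are treated as missing
#' and excluded pairwise.
#'
#' @param h a [haplotype_set()].
#' @return a [distance_matrix()] of kind `"hamming"`.
#' @export
hamming_matrix <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  n <- length(h$sequences)
  out <- matrix(0, n, n, dimnames = list(h$ids, h$ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        out[i, j] <- out[j, i] <- hamming_pair(h$sequences[i],
                                               h$sequences[j])
      }
    }
  }
  distance_matrix(out, h$ids, kind = "hamming")
}

#' Statistical-parsimony connection probability and limit
#'
#' `parsimony_prob(j, seq_len)` is the probability that two sequences of
#' length `m` observed to differ at `j` sites are separated by exactly `j`
#' mutations (no hidden multiple hits), under per-site Poisson mutation with
#' Jukes-Cantor state dynamics at the divergence implied by `j/m`:
#' with `q = j/m` and `d = -3/4 log(1 - 4q/3)` hits per site,
#' `P(j) = (d e^-d / q)^j * (e^-d / (1-q))^(m-j)`.
#' `parsimony_limit()` returns the largest step count `j` with
#' `P(j) >= alpha`, floored at 1 (single-step connections are always
#' trusted). This is the connection criterion of statistical-parsimony
#' (TCS-style) networks.
#'
#' @param j number of observed differences (>= 1).
#' @param seq_len sequence length `m` (>= 1).
#' @param alpha parsimony confidence in (0, 1), default 0.95.
#' @return `parsimony_prob`: probability in `[0, 1]`; `parsimony_limit`:
#'   integer step limit >= 1.
#' @export
parsimony_prob <- function(j, seq_len) {
  stopifnot(seq_len >= 1, all(j >= 0))
  vapply(j, function(jj) {
    if (jj == 0) return(1)
    q <- jj / seq_len
    if (q >= 3 / 4) return(0)
    d <- -0.75 * log(1 - 4 * q / 3)
    p <- (d * exp(-d) / q)^jj * (exp(-d) / (1 - q))^(seq_len - jj)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' @rdname parsimony_prob
#' @export
parsimony_limit <- function(seq_len, alpha = 0.95) {
  stopifnot(seq_len >= 1, alpha > 0, alpha < 1)
  limit <- 1L
  j <- 1L
  while (j < seq_len) {
    if (parsimony_prob(j, seq_len) >= alpha) {
      limit <- j
      j <- j + 1L
    } else {
      break
    }
  }
  max(limit, 1L)
}
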