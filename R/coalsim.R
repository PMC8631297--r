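#' Prior ranges for the demographic parameters
#'
#' Uniform integer priors on the effective sizes of the three extant
#' populations, the two founder (bottleneck) sizes, the two split times in
#' generations, and the bottleneck duration, with the joint constraints
#' `t1 > t2` and `db < t2`. Defaults are the study priors: effective sizes
#' chosen from census rarity (Palinuro 100-500, Capri 10-500, Strombolicchio
#' 10-50), founder sizes 5-50, split times 10-50000 generations, bottleneck
#' duration 10-100 generations.
#'
#' @param N_Palinuro,N_Capri,N_Strombolicchio,N1b,N2b,t1,t2,db length-2
#'   integer ranges `c(min, max)`.
#' @return a `prior_set` list.
#' @export
prior_set <- function(N_Palinuro = c(100, 500), N_Capri = c(10, 500),
                      N_Strombolicchio = c(10, 50), N1b = c(5, 50),
                      N2b = c(5, 50), t1 = c(10, 50000), t2 = c(10, 50000),
                      db = c(10, 100)) {
  p <- list(N_Palinuro = N_Palinuro, N_Capri = N_Capri,
            N_Strombolicchio = N_Strombolicchio, N1b = N1b, N2b = N2b,
            t1 = t1, t2 = t2, db = db)
  for (nm in names(p)) {
    if (length(p[[nm]]) != 2 || p[[nm]][1] > p[[nm]][2])
      stop("prior range for ", nm, " must be c(min, max) with min <= max")
  }
  structure(p, class = "prior_set")
}

#' Names of the demographic parameters, in reference-table order
#' @export
PARAM_NAMES <- c("N_Palinuro", "N_Capri", "N_Strombolicchio", "N1b", "N2b",
                 "t1", "t2", "db")

#' A concrete draw of the demographic parameters
#'
#' @param ... the eight parameters named as in [PARAM_NAMES].
#' @param generation_time_years generation time used by
#'   [generations_to_years()]; default 10.
#' @return a `parameter_draw` list.
#' @export
parameter_draw <- function(N_Palinuro, N_Capri, N_Strombolicchio, N1b, N2b,
                           t1, t2, db, generation_time_years = 10) {
  if (!(t1 > t2 && t2 > 0)) stop("requires t1 > t2 > 0")
  if (!(db < t2)) stop("requires db < t2")
  structure(list(N_Palinuro = N_Palinuro, N_Capri = N_Capri,
                 N_Strombolicchio = N_Strombolicchio, N1b = N1b, N2b = N2b,
                 t1 = t1, t2 = t2, db = db,
                 generation_time_years = generation_time_years),
            class = "parameter_draw")
}

runif_int <- function(range) {
  range[1] + floor(stats::runif(1) * (range[2] - range[1] + 1))
}

#' Sample one parameter draw from the priors
#'
#' Uniform integer draws within each range; rejection sampling enforces
#' `t1 > t2` and `db < t2`. Deterministic given `seed`.
#'
#' @param p a [prior_set()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param max_tries rejection cap before failing.
#' @return a [parameter_draw()].
#' @export
sample_prior <- function(p = prior_set(), seed = NULL, max_tries = 10000) {
  stopifnot(inherits(p, "prior_set"))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    v <- lapply(p, runif_int)
    if (v$t1 > v$t2 && v$db < v$t2) {
      return(parameter_draw(v$N_Palinuro, v$N_Capri, v$N_Strombolicchio,
                            v$N1b, v$N2b, v$t1, v$t2, v$db))
    }
  }
  stop("could not satisfy t1 > t2 and db < t2 within ", max_tries,
       " draws; check the prior ranges")
}

#' The four island-colonization scenarios
#'
#' Scenario 1: Capri founded from Palinuro at `t1` through `N1b` founders
#' (bottleneck for `db` generations), then Strombolicchio founded from Capri
#' at `t2` through `N2b` founders (bottleneck for `db` generations).
#' Scenario 2: as 1, but Strombolicchio is founded from Palinuro.
#' Scenario 3: an ancestral population splits into Capri and Palinuro at
#' `t1` with no bottleneck; Strombolicchio founded from Capri at `t2` with a
#' bottleneck. Scenario 4: as 3, but Strombolicchio founded from Palinuro.
#' The ancestral population size equals `N_Palinuro`.
#'
#' @param scenario_id integer in 1..4.
#' @return a `demographic_model` list with the scenario id, the
#'   Strombolicchio source population, and whether Capri is bottlenecked.
#' @export
demographic_model <- function(scenario_id) {
  stopifnot(scenario_id %in% 1:4)
  structure(list(scenario_id = as.integer(scenario_id),
                 strombolicchio_source = c("Capri", "Palinuro", "Capri",
                                           "Palinuro")[scenario_id],
                 capri_bottleneck = scenario_id %in% c(1, 2)),
            class = "demographic_model")
}

## demes: 0 = Palinuro, 1 = Capri, 2 = Strombolicchio.
## scale factor: pair-coalescence timescale per unit effective size
## (2 for diploid nuclear loci, 1/2 for the haploid plastid genome).
scenario_events <- function(m, d, factor) {
  if (!inherits(m, "demographic_model")) m <- demographic_model(m)
  src <- if (m$strombolicchio_source == "Capri") 1 else 0
  ev <- rbind(
    c(d$t2 - d$db, 0, 2, factor * d$N2b),  # Strombolicchio founder phase
    c(d$t2, 1, 2, src))                    # Strombolicchio founding event
  if (m$capri_bottleneck)
    ev <- rbind(ev, c(d$t1 - d$db, 0, 1, factor * d$N1b))
  ev <- rbind(ev, c(d$t1, 1, 1, 0))        # Capri joins Palinuro/ancestor
  ev
}

scenario_scales <- function(d, factor) {
  factor * c(d$N_Palinuro, d$N_Capri, d$N_Strombolicchio)
}

#' Default diploid sample sizes of the study design
#' @export
SAMPLE_SIZES <- c(Palinuro = 10, Capri = 8, Strombolicchio = 7)

#' Population map matching simulated sample sizes
#' @param sample_sizes named per-population diploid counts.
#' @return a [population_map()] with ids `Pal01`, `Cap01`, `Str01`, ...
#' @export
default_population_map <- function(sample_sizes = SAMPLE_SIZES) {
  prefix <- c(Palinuro = "Pal", Capri = "Cap", Strombolicchio = "Str")
  pops <- rep(names(sample_sizes), sample_sizes)
  ids <- unlist(lapply(names(sample_sizes), function(pp) {
    pre <- if (pp %in% names(prefix)) prefix[[pp]] else substr(pp, 1, 3)
    sprintf("%s%02d", pre, seq_len(sample_sizes[[pp]]))
  }))
  population_map(ids, pops)
}

#' Simulate a nuclear SNP dataset under a demographic scenario
#'
#' For each of `n_loci` unlinked loci an independent coalescent genealogy of
#' all sampled lineages is generated under the scenario (exponential
#' coalescence within demes, deme merging at `t1`/`t2`, founder sizes active
#' during the `db`-generation windows), and a single mutation is placed on a
#' branch chosen with probability proportional to its length (the
#' one-SNP-per-locus convention of SNP-mode ABC simulators, which makes every
#' locus polymorphic in the pooled sample). The two lineages sampled per
#' individual form its diploid genotype.
#'
#' @param m a [demographic_model()] or a scenario id in 1..4.
#' @param d a [parameter_draw()].
#' @param sample_sizes named per-population diploid counts (default 10/8/7).
#' @param n_loci number of loci (default 120).
#' @param seed integer seed (or `NULL` for current RNG state); output is
#'   bit-reproducible given the seed.
#' @param missing_prob optional per-genotype missingness probability to
#'   emulate ddRAD dropout (default 0).
#' @param maf_floor optional minimum pooled minor-allele frequency for
#'   simulated loci (default 0, off); failing loci are redrawn.
#' @return a [genotype_matrix()] with attributes `scenario_id` and `draw`.
#' @export
simulate_dataset <- function(m, d, sample_sizes = SAMPLE_SIZES,
                             n_loci = 120, seed = NULL, missing_prob = 0,
                             maf_floor = 0) {
  if (!inherits(m, "demographic_model")) m <- demographic_model(m)
  stopifnot(inherits(d, "parameter_draw"), all(sample_sizes >= 0),
            sum(sample_sizes) >= 1, n_loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  pm <- default_population_map(sample_sizes)
  deme_idx <- c(Palinuro = 0L, Capri = 1L, Strombolicchio = 2L)
  pop_per_ind <- as.character(pm)
  if (!all(pop_per_ind %in% names(deme_idx)))
    stop("sample_sizes must be named Palinuro/Capri/Strombolicchio")
  deme0 <- rep(deme_idx[pop_per_ind], each = 2)

  scales <- scenario_scales(d, 2)
  events <- scenario_events(m, d, 2)
  derived <- .sim_snp_loci(as.integer(deme0), scales, events,
                           as.integer(n_loci))
  if (maf_floor > 0) {
    for (it in 1:100) {
      p <- colMeans(derived)
      bad <- which(pmin(p, 1 - p) < maf_floor)
      if (!length(bad)) break
      redo <- .sim_snp_loci(as.integer(deme0), scales, events,
                            length(bad))
      derived[, bad] <- redo
    }
  }
  n_ind <- length(pop_per_ind)
  gt <- derived[seq(1, 2 * n_ind, by = 2), , drop = FALSE] +
    derived[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  if (missing_prob > 0) {
    drop <- matrix(stats::runif(length(gt)) < missing_prob, nrow(gt))
    gt[drop] <- NA_integer_
  }
  g <- genotype_matrix(gt, individual_ids = names(pm),
                       locus_ids = sprintf("sim%04d", seq_len(n_loci)))
  attr(g, "scenario_id") <- m$scenario_id
  attr(g, "draw") <- d
  g
}

#' Simulate the plastid haplotypes under a demographic scenario
#'
#' A single non-recombining haploid locus: one lineage per sampled
#' individual, haploid effective size equal to half the diploid deme size,
#' and infinite-sites mutations dropped as a Poisson process on branches
#' with total rate `mu_per_seq` per sequence per generation.
#'
#' @param m a [demographic_model()] or scenario id.
#' @param d a [parameter_draw()].
#' @param sample_sizes named per-population haploid counts.
#' @param seq_len sequence length in bp (default 600).
#' @param mu_per_seq mutation rate per sequence per generation.
#' @param seed integer seed (or `NULL`).
#' @return a [haplotype_set()] with population counts.
#' @export
simulate_plastid <- function(m, d, sample_sizes = SAMPLE_SIZES,
                             seq_len = 600, mu_per_seq = 1e-5,
                             seed = NULL) {
  if (!inherits(m, "demographic_model")) m <- demographic_model(m)
  stopifnot(inherits(d, "parameter_draw"), seq_len >= 1, mu_per_seq >= 0)
  if (!is.null(seed)) set.seed(seed)
  deme_idx <- c(Palinuro = 0L, Capri = 1L, Strombolicchio = 2L)
  pops <- rep(names(sample_sizes), sample_sizes)
  deme0 <- deme_idx[pops]

  gen <- .sim_genealogy_branches(as.integer(deme0),
                                 scenario_scales(d, 0.5),
                                 scenario_events(m, d, 0.5))
  n <- length(deme0)
  n_mut <- stats::rpois(1, gen$total_length * mu_per_seq)
  n_mut <- min(n_mut, seq_len)  # infinite-sites cap
  seqs <- matrix("A", nrow = n, ncol = seq_len)
  if (n_mut > 0) {
    sites <- sample.int(seq_len, n_mut)
    lens <- gen$lengths
    for (k in seq_len(n_mut)) {
      b <- sample.int(length(lens), 1, prob = lens)
      carriers <- gen$leaves[[b]] + 1L
      base <- sample(c("C", "G", "T"), 1)
      seqs[carriers, sites[k]] <- base
    }
  }
  seq_str <- apply(seqs, 1, paste0, collapse = "")
  uniq <- unique(seq_str)
  hap_id <- stats::setNames(paste0("H", seq_along(uniq)), uniq)
  assign <- hap_id[seq_str]
  freq <- table(factor(assign, levels = hap_id))
  pc <- as.matrix(table(factor(assign, levels = hap_id),
                        factor(pops, levels = unique(pops))))
  haplotype_set(stats::setNames(uniq, hap_id),
                stats::setNames(as.integer(freq), hap_id), pc)
}

#' Replicate genealogy summaries (TMRCA, total branch length)
#'
#' Low-level access to the coalescent engine for calibration checks: returns
#' the time to the most recent common ancestor and the total branch length
#' of independent genealogies under an arbitrary scenario, or under a single
#' panmictic population when `m` is `NULL`.
#'
#' @param n_lineages number of sampled lineages (haploid copies).
#' @param N diploid effective size of the panmictic control.
#' @param n_reps number of replicate genealogies.
#' @param seed integer seed (or `NULL`).
#' @return matrix with columns `tmrca` and `total_length`.
#' @export
genealogy_stats <- function(n_lineages, N, n_reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .sim_genealogy_stats(integer(n_lineages), 2 * N,
                       matrix(numeric(0), 0, 4), as.integer(n_reps))
}
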