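#' Write the packaged synthetic study fixtures
#'
#' Creates, deterministically for a given seed:
#' \itemize{
#' \item `sampling_manifest.tsv` — the six sampling sites with visual-census
#'   and sampled counts (sampled counts sum to 51 individuals);
#' \item `plastid_synthetic.fasta` + `plastid_popmap.tsv` — a synthetic
#'   per-individual plastid fixture with exactly three haplotypes: H1 one
#'   step from H2, H3 two steps from H2; H2 present in all three sites, H1
#'   in Palinuro and Capri only, H3 exclusive to Strombolicchio. The
#'   nucleotide states are arbitrary (synthetic); only the distance and
#'   sharing structure is meaningful;
#' \item `nuclear_synthetic.vcf` + `nuclear_popmap.tsv` — 25 diploids
#'   (10/8/7 across Palinuro/Capri/Strombolicchio) at 120 unlinked SNP loci
#'   simulated under scenario 1 with mid-prior parameters;
#' \item `fixtures_manifest.json` — seeds and simulation parameters.
#' }
#'
#' @param out_dir writable output directory (created if absent).
#' @param seed integer seed.
#' @return invisible named list of the written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("unwritable directory: ", out_dir)
  paths <- list(
    manifest = file.path(out_dir, "sampling_manifest.tsv"),
    plastid_fasta = file.path(out_dir, "plastid_synthetic.fasta"),
    plastid_popmap = file.path(out_dir, "plastid_popmap.tsv"),
    vcf = file.path(out_dir, "nuclear_synthetic.vcf"),
    popmap = file.path(out_dir, "nuclear_popmap.tsv"),
    json = file.path(out_dir, "fixtures_manifest.json"))

  manifest <- data.frame(
    site = c("Capri - Grotta dell'Acqua", "Strombolicchio", "Palinuro Porto",
             "Palinuro Punta Iacco", "Palinuro Cala Fetente",
             "Palinuro-Camerota"),
    abbreviation = c("C", "K", "P", "PIK", "CFK", "CAM"),
    population = c("Capri", "Strombolicchio", "Palinuro", "Palinuro",
                   "Palinuro", "Palinuro"),
    census_individuals = c(120L, 60L, 40L, 40L, 50L, 15L),
    sampled_individuals = c(18L, 12L, 16L, 1L, 2L, 2L))
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # three-haplotype plastid fixture (synthetic states, 3 SNPs in 600 bp)
  base <- rep("A", 600)
  h2 <- base
  h1 <- base; h1[100] <- "G"
  h3 <- base; h3[300] <- "C"; h3[500] <- "T"
  hap_seq <- c(H1 = paste0(h1, collapse = ""),
               H2 = paste0(h2, collapse = ""),
               H3 = paste0(h3, collapse = ""))
  carriers <- data.frame(
    individual = c(sprintf("Pal%02d", 1:6), sprintf("Cap%02d", 1:5),
                   sprintf("Str%02d", 1:5)),
    population = rep(c("Palinuro", "Capri", "Strombolicchio"), c(6, 5, 5)),
    haplotype = c(rep(c("H1", "H2"), c(3, 3)),     # Palinuro: H1 + H2
                  rep(c("H1", "H2"), c(2, 3)),     # Capri: H1 + H2
                  rep(c("H2", "H3"), c(3, 2))))    # Strombolicchio: H2 + H3
  fasta <- character(0)
  for (r in seq_len(nrow(carriers))) {
    fasta <- c(fasta, paste0(">", carriers$individual[r]),
               hap_seq[[carriers$haplotype[r]]])
  }
  writeLines(fasta, paths$plastid_fasta)
  write_popmap(population_map(carriers$individual, carriers$population),
               paths$plastid_popmap)

  # nuclear dataset: scenario 1, mid-prior parameter draw
  draw <- parameter_draw(N_Palinuro = 300, N_Capri = 255,
                         N_Strombolicchio = 30, N1b = 27, N2b = 27,
                         t1 = 25005, t2 = 12507, db = 55)
  g <- simulate_dataset(1, draw, sample_sizes = SAMPLE_SIZES, n_loci = 120,
                        seed = seed)
  write_vcf(g, paths$vcf)
  write_popmap(default_population_map(SAMPLE_SIZES), paths$popmap)

  jsonlite::write_json(list(seed = seed, scenario_id = 1,
                            draw = draw[PARAM_NAMES],
                            sample_sizes = as.list(SAMPLE_SIZES),
                            n_loci = 120,
                            plastid_note = paste(
                              "synthetic nucleotide states; distance and",
                              "site-sharing structure only")),
                       paths$json, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown fields are
#' rejected; the effective configuration is echoed into the run report.
#'
#' @param vcf,popmap,plastid_fasta,plastid_popmap input paths (plastid
#'   entries may be `NULL` to skip the network stage).
#' @param out_dir run output directory (must not already contain a report).
#' @param filter a [filter_config()].
#' @param prior a [prior_set()].
#' @param n_per_scenario,n_loci,n_trees ABC settings.
#' @param k_min,k_max,n_ref gap-statistic settings.
#' @param seed master seed; every stage derives its own seed from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, popmap, plastid_fasta = NULL,
                            plastid_popmap = NULL, out_dir,
                            filter = filter_config(locus_presence_min = 0.95),
                            prior = prior_set(), n_per_scenario = 500,
                            n_loci = 120, n_trees = 1500, k_min = 1,
                            k_max = 6, n_ref = 100, seed = 1) {
  stopifnot(inherits(filter, "filter_config"), inherits(prior, "prior_set"))
  structure(list(vcf = vcf, popmap = popmap, plastid_fasta = plastid_fasta,
                 plastid_popmap = plastid_popmap, out_dir = out_dir,
                 filter = filter, prior = prior,
                 n_per_scenario = n_per_scenario, n_loci = n_loci,
                 n_trees = n_trees, k_min = k_min, k_max = k_max,
                 n_ref = n_ref, seed = seed),
            class = "pipeline_config")
}

stage_seed <- function(master, k) (master * 131L + k) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes filter, diversity/Fst/clustering/tree, co-ancestry, plastid
#' network, and the ABC build/choose/estimate stages, writing every table
#' plus a single JSON report into `out_dir`. All stage seeds derive from the
#' configured master seed, so the report suffices to replay the run exactly;
#' inputs are never mutated and a directory holding a previous report is
#' refused.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage progress with `message()`.
#' @return the report, invisibly (list, also written as `report.json`).
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(cfg$out_dir, "report.json")
  if (file.exists(report_path))
    stop("out_dir already holds a report (runs are write-once): ",
         cfg$out_dir)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage input: reading %s", cfg$vcf)
  g_raw <- run_stage("input", read_vcf(cfg$vcf))
  pm <- run_stage("input", read_popmap(cfg$popmap))
  miss <- missingness_summary(g_raw)

  say("stage filter: %d loci in", n_loci(g_raw))
  g <- run_stage("filter", filter_loci(g_raw, cfg$filter, verbose = verbose))
  say("stage filter: %d loci retained", n_loci(g))

  say("stage stats: diversity and Fst")
  div <- run_stage("stats", diversity_stats(g, pm))
  fst <- run_stage("stats", pairwise_fst(g, pm))
  utils::write.table(div, file.path(cfg$out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_matrix(fst, file.path(cfg$out_dir, "fst.tsv"))

  say("stage cluster: gap statistic K = %d..%d", cfg$k_min, cfg$k_max)
  asd <- run_stage("cluster", allele_sharing_distance(g))
  ks <- run_stage("cluster",
                  select_k_gap(asd, cfg$k_min, cfg$k_max, cfg$n_ref,
                               seed = stage_seed(cfg$seed, 1L)))
  emb <- run_stage("cluster", mds_embed(asd, dims = 2))
  utils::write.table(data.frame(individual = rownames(emb), emb),
                     file.path(cfg$out_dir, "mds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nwk <- run_stage("cluster", nj_tree(fst))
  writeLines(as.character(nwk), file.path(cfg$out_dir, "fst_nj.nwk"))

  say("stage coancestry")
  coan <- run_stage("coancestry", coancestry_matrix(g))
  write_distance_matrix(coan, file.path(cfg$out_dir, "coancestry.tsv"))

  network_summary <- NULL
  if (!is.null(cfg$plastid_fasta)) {
    say("stage network: %s", cfg$plastid_fasta)
    ppm <- if (is.null(cfg$plastid_popmap)) NULL else
      read_popmap(cfg$plastid_popmap)
    hap <- run_stage("network", read_haplotype_fasta(cfg$plastid_fasta, ppm))
    net <- run_stage("network", build_network(hap))
    write_network(net,
                  graphml_path = file.path(cfg$out_dir, "network.graphml"),
                  edgelist_path = file.path(cfg$out_dir, "network_edges.tsv"),
                  composition_path = file.path(cfg$out_dir,
                                               "network_composition.tsv"))
    network_summary <- list(n_haplotypes = length(hap$sequences),
                            frequencies = as.list(stats::setNames(
                              hap$frequencies, hap$ids)),
                            n_inferred = net$n_inferred,
                            n_components = net$n_components,
                            limit = net$limit)
  }

  say("stage abc: %d sims/scenario, %d loci, %d trees",
      cfg$n_per_scenario, cfg$n_loci, cfg$n_trees)
  pop_counts <- table(factor(as.character(pm),
                             levels = unique(as.character(pm))))
  ss <- stats::setNames(as.integer(pop_counts), names(pop_counts))
  rt <- run_stage("abc-build",
                  build_reference_table(1:4, cfg$prior, cfg$n_per_scenario,
                                        sample_sizes = ss,
                                        n_loci = cfg$n_loci,
                                        seed = stage_seed(cfg$seed, 2L)))
  write_reference_table(rt, file.path(cfg$out_dir, "reference_table.tsv"))
  obs <- run_stage("abc-choose", summary_vector(g, pm))
  mc <- run_stage("abc-choose",
                  choose_scenario(rt, obs, n_trees = cfg$n_trees,
                                  seed = stage_seed(cfg$seed, 3L)))
  est <- run_stage("abc-estimate",
                   estimate_parameters(subset_scenario(rt, mc$best_scenario),
                                       obs, n_trees = cfg$n_trees,
                                       seed = stage_seed(cfg$seed, 4L)))
  utils::write.table(est, file.path(cfg$out_dir, "posterior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    config = list(vcf = cfg$vcf, popmap = cfg$popmap,
                  plastid_fasta = cfg$plastid_fasta,
                  filter = unclass(cfg$filter), prior = unclass(cfg$prior),
                  n_per_scenario = cfg$n_per_scenario, n_loci = cfg$n_loci,
                  n_trees = cfg$n_trees, k_min = cfg$k_min,
                  k_max = cfg$k_max, n_ref = cfg$n_ref, seed = cfg$seed),
    input = list(n_individuals = n_individuals(g_raw),
                 n_loci_in = n_loci(g_raw),
                 missing_per_genotype = miss$per_genotype,
                 missing_per_locus_mean = miss$per_locus_mean),
    filter = list(n_loci_retained = n_loci(g)),
    diversity = div,
    fst = as.data.frame(unclass(fst)),
    cluster = list(best_k = ks$best_k, gap = as.list(ks$gap),
                   se = as.list(ks$se)),
    nj_newick = as.character(nwk),
    coancestry = list(max_differences = max(unclass(coan), na.rm = TRUE),
                      mean_differences = mean(unclass(coan)[upper.tri(coan)],
                                              na.rm = TRUE)),
    network = network_summary,
    abc = list(votes = as.list(mc$votes), best_scenario = mc$best_scenario,
               posterior_probability = mc$posterior_probability,
               n_trees = mc$n_trees, n_imputed_cells = rt$n_imputed,
               posterior = est),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("eokochia")))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  writeLines(c(
    sprintf("run seed %d", cfg$seed),
    sprintf("loci: %d in, %d retained", n_loci(g_raw), n_loci(g)),
    sprintf("best K: %d", ks$best_k),
    sprintf("best scenario: %d (votes %s; posterior p = %.3f)",
            mc$best_scenario, paste(mc$votes, collapse = "/"),
            mc$posterior_probability)),
    file.path(cfg$out_dir, "report.txt"))
  say("pipeline done in %.1f s", report$elapsed_sec)
  invisible(report)
}
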