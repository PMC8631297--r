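test_that("prior draws respect ranges and the time-ordering constraints", {
  p <- prior_set()
  set.seed(5)
  for (s in 1:1000) {
    d <- sample_prior(p, seed = NULL)
    expect_true(d$t1 > d$t2)
    expect_true(d$db < d$t2)
    expect_true(d$N_Palinuro >= 100 && d$N_Palinuro <= 500)
    expect_true(d$N_Strombolicchio >= 10 && d$N_Strombolicchio <= 50)
    expect_true(d$N1b >= 5 && d$N1b <= 50)
  }

  # degenerate ranges admit the single feasible draw
  pd <- prior_set(N_Palinuro = c(200, 200), N_Capri = c(100, 100),
                  N_Strombolicchio = c(20, 20), N1b = c(10, 10),
                  N2b = c(10, 10), t1 = c(1000, 1000), t2 = c(500, 500),
                  db = c(50, 50))
  d <- sample_prior(pd, seed = 1)
  expect_equal(unlist(d[PARAM_NAMES]),
               c(N_Palinuro = 200, N_Capri = 100, N_Strombolicchio = 20,
                 N1b = 10, N2b = 10, t1 = 1000, t2 = 500, db = 50))

  # infeasible constraint fails loudly
  expect_error(sample_prior(prior_set(t1 = c(10, 20), t2 = c(30, 40)),
                            seed = 1, max_tries = 50), "t1 > t2")
})

test_that("N_Strombolicchio draws have the uniform(10,50) mean", {
  set.seed(11)
  draws <- vapply(1:10000, function(i) sample_prior(seed = NULL)$N_Strombolicchio,
                  numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 30), 3 * se)
})

test_that("panmictic pairwise coalescence time is centred on 2N", {
  N <- 100
  gs <- genealogy_stats(2, N = N, n_reps = 2000, seed = 42)
  se <- sd(gs[, "tmrca"]) / sqrt(nrow(gs))
  expect_lt(abs(mean(gs[, "tmrca"]) - 2 * N), 3 * se)
})

test_that("the panmictic site frequency spectrum follows 1/i", {
  # single deme: scenario events are no-ops when only Palinuro is sampled
  d <- parameter_draw(100, 100, 100, 100, 100, 31, 30, 10)
  g <- simulate_dataset(1, d,
                        sample_sizes = c(Palinuro = 10, Capri = 0,
                                         Strombolicchio = 0),
                        n_loci = 2000, seed = 9)
  counts <- colSums(g$genotypes)  # derived copies among 20 sampled alleles
  expect_true(all(counts >= 1 & counts <= 19))
  sfs <- tabulate(counts, nbins = 19)
  expected <- (1 / 1:19) / sum(1 / 1:19) * 2000
  chi2 <- sum((sfs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 18))
})

test_that("every simulated locus is polymorphic in the pooled sample", {
  g <- simulate_dataset(2, mid_draw(), n_loci = 300, seed = 4)
  p <- colSums(g$genotypes) / (2 * nrow(g$genotypes))
  expect_true(all(p > 0 & p < 1))
})

test_that("seeded simulation is bit-reproducible", {
  a <- simulate_dataset(1, mid_draw(), n_loci = 50, seed = 123,
                        missing_prob = 0.1)
  b <- simulate_dataset(1, mid_draw(), n_loci = 50, seed = 123,
                        missing_prob = 0.1)
  expect_identical(a$genotypes, b$genotypes)
  hp1 <- simulate_plastid(1, mid_draw(), mu_per_seq = 1e-4, seed = 77)
  hp2 <- simulate_plastid(1, mid_draw(), mu_per_seq = 1e-4, seed = 77)
  expect_identical(hp1$sequences, hp2$sequences)
  expect_identical(hp1$population_counts, hp2$population_counts)
})

test_that("summary statistics are invariant to within-deme relabelling", {
  g <- simulate_dataset(1, mid_draw(), n_loci = 60, seed = 15,
                        missing_prob = 0.05)
  pm <- default_population_map()
  sv <- summary_vector(g, pm)
  # swap two Palinuro individuals and two Capri individuals
  ids <- g$individual_ids
  perm <- ids
  perm[c(1, 2)] <- ids[c(2, 1)]
  perm[c(11, 12)] <- ids[c(12, 11)]
  gp <- select_individuals(g, perm)
  gp$individual_ids <- ids
  rownames(gp$genotypes) <- ids
  expect_equal(summary_vector(gp, pm), sv, tolerance = 1e-12)
})

test_that("a severe founder bottleneck depresses island diversity", {
  he_strom <- function(n2b, db, seed) {
    d <- parameter_draw(300, 255, 30, 27, n2b, 25005, 150, db)
    g <- simulate_dataset(1, d, n_loci = 80, seed = seed)
    div <- diversity_stats(g, default_population_map())
    div$He[div$population == "Strombolicchio"]
  }
  severe <- vapply(1:120, function(s) he_strom(5, 140, s), numeric(1))
  mild <- vapply(1:120, function(s) he_strom(50, 10, s + 7000), numeric(1))
  expect_lt(mean(severe), mean(mild))
  expect_lt(t.test(severe, mild)$p.value, 0.01)
})

test_that("island source populations separate scenarios 1 and 2", {
  # Strombolicchio founded from Capri (scenario 1) leaves a lower
  # Capri-Strombolicchio Fst than founding from Palinuro (scenario 2)
  pm <- default_population_map()
  fst_cs <- function(scen, seed) {
    g <- simulate_dataset(scen, mid_draw(), n_loci = 100, seed = seed)
    unclass(pairwise_fst(g, pm))["Capri", "Strombolicchio"]
  }
  s1 <- vapply(1:150, function(s) fst_cs(1, s), numeric(1))
  s2 <- vapply(1:150, function(s) fst_cs(2, s + 9000), numeric(1))
  expect_lt(mean(s1), mean(s2))
  expect_lt(t.test(s1, s2)$p.value, 0.01)
})

test_that("plastid simulation respects the mutation model", {
  # zero mutation rate: a single haplotype, no SNPs
  h0 <- simulate_plastid(1, mid_draw(), mu_per_seq = 0, seed = 3)
  expect_equal(length(h0$sequences), 1L)
  expect_equal(sum(h0$frequencies), sum(SAMPLE_SIZES))

  # panmictic Watterson check: E[S] = mu * N_dip * H_{n-1} for n haploids
  d <- parameter_draw(100, 100, 100, 100, 100, 31, 30, 10)
  n <- 20
  mu <- 0.01
  segs <- vapply(1:400, function(s) {
    h <- simulate_plastid(1, d,
                          sample_sizes = c(Palinuro = n, Capri = 0,
                                           Strombolicchio = 0),
                          seq_len = 5000, mu_per_seq = mu, seed = s)
    chars <- do.call(rbind, strsplit(h$sequences, ""))
    # count segregating sites over carriers weighted by frequency
    expanded <- chars[rep(seq_along(h$frequencies), h$frequencies), ,
                      drop = FALSE]
    sum(apply(expanded, 2, function(col) length(unique(col)) > 1))
  }, numeric(1))
  expected <- mu * 100 * sum(1 / (1:(n - 1)))
  se <- sd(segs) / sqrt(length(segs))
  expect_lt(abs(mean(segs) - expected), 3 * se)
})

test_that("long isolation sorts plastid haplotypes into private sets", {
  d <- parameter_draw(50, 50, 50, 10, 10, 49999, 49998, 10)
  shared <- vapply(1:60, function(s) {
    h <- simulate_plastid(1, d, sample_sizes = c(Palinuro = 8, Capri = 8,
                                                 Strombolicchio = 0),
                          seq_len = 2000, mu_per_seq = 5e-4, seed = 200 + s)
    if (is.null(h$population_counts)) return(0L)
    pc <- h$population_counts
    sum(pc[, "Palinuro"] > 0 & pc[, "Capri"] > 0)
  }, integer(1))
  expect_gt(mean(shared == 0), 0.7)
})

test_that("generation-to-year conversion matches the 10-year clock", {
  expect_equal(generations_to_years(24615, 10)$Mya, 0.25)
  expect_equal(generations_to_years(9003, 10)$Mya, 0.09)
  expect_equal(generations_to_years(0)$years, 0)
})
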