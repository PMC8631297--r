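pm2 <- function(g, pops) population_map(g$individual_ids, pops)

test_that("diversity statistics match hand-evaluated formulas", {
  # two individuals, both heterozygous: Ho = 1, p = 0.5,
  # He = (2n/(2n-1)) (1 - sum p^2) = (4/3) * 0.5, Fis = 1 - Ho/He = -0.5
  g <- gm(matrix(c(1L, 1L), 2, 1))
  d <- diversity_stats(g, pm2(g, c("A", "A")))
  a <- d[d$population == "A", ]
  expect_equal(a$Ho, 1)
  expect_equal(a$He, 4 / 3 * 0.5)
  expect_equal(a$Fis, 1 - 1 / (4 / 3 * 0.5))

  # monomorphic population: Ho = He = 0, Fis undefined (flagged NA)
  g0 <- gm(matrix(0L, 3, 2))
  d0 <- diversity_stats(g0, pm2(g0, rep("A", 3)))
  expect_equal(d0$Ho[1], 0)
  expect_equal(d0$He[1], 0)
  expect_true(is.na(d0$Fis[1]))
})

test_that("diversity means stay in [0,1] across random datasets", {
  for (s in 1:5) {
    g <- random_gm(12, 30, seed = 100 + s)
    pops <- rep(c("A", "B", "C"), each = 4)
    d <- diversity_stats(g, pm2(g, pops))
    expect_true(all(d$Ho >= 0 & d$Ho <= 1))
    expect_true(all(d$He >= 0 & d$He <= 1, na.rm = TRUE))
  }
})

test_that("pairwise Fst equals brute-force Weir-Cockerham components", {
  # 2 populations x 3 diploids x 2 loci toy table
  p1 <- rbind(c(0L, 1L), c(1L, 2L), c(0L, 1L))
  p2 <- rbind(c(2L, 0L), c(1L, 0L), c(2L, 1L))
  g <- gm(rbind(p1, p2))
  pops <- rep(c("A", "B"), each = 3)
  theta <- unclass(pairwise_fst(g, pm2(g, pops)))["A", "B"]

  # direct scalar evaluation of a, b, c per locus (r = 2)
  num <- den <- 0
  for (l in 1:2) {
    n <- c(3, 3)
    p <- c(sum(p1[, l]) / 6, sum(p2[, l]) / 6)
    h <- c(mean(p1[, l] == 1), mean(p2[, l] == 1))
    r <- 2; nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  expect_equal(theta, num / den, tolerance = 1e-12)
})

test_that("Fst hits the boundary cases", {
  # fixed for alternative alleles at every locus -> theta = 1
  g <- gm(rbind(matrix(0L, 4, 5), matrix(2L, 4, 5)))
  th <- unclass(pairwise_fst(g, pm2(g, rep(c("A", "B"), each = 4))))["A", "B"]
  expect_equal(th, 1)

  # the same individuals duplicated -> no true differentiation
  half <- random_gm(6, 80, seed = 3)$genotypes
  g2 <- gm(rbind(half, half))
  th2 <- unclass(pairwise_fst(g2, pm2(g2, rep(c("A", "B"), each = 6))))["A", "B"]
  expect_lte(th2, 0)
  expect_lt(abs(th2), 0.15)
})

test_that("Fst on panmictic simulated data is centred near zero", {
  set.seed(77)
  reps <- 50
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    # one panmictic pool split arbitrarily into two labels
    pool <- matrix(rbinom(12 * 40, 2, runif(40, 0.2, 0.8)[rep(1:40, each = 12)]),
                   nrow = 12)
    g <- gm(pool)
    vals[r] <- unclass(pairwise_fst(g, pm2(g, rep(c("A", "B"), 6))))["A", "B"]
  }
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals)), 3 * se + 1e-6)
})

test_that("allele-sharing distance matches its definition", {
  g <- gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(unclass(allele_sharing_distance(g))[1, 2], 0)

  g2 <- gm(rbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(unclass(allele_sharing_distance(g2))[1, 2], 1)

  g3 <- gm(matrix(c(0L, 1L), 2, 1))  # 0/0 vs 0/1 at a single locus
  expect_equal(unclass(allele_sharing_distance(g3))[1, 2], 0.5)

  # missingness: distance computed over jointly observed loci only
  g4 <- gm(rbind(c(0L, NA, 2L, 1L), c(0L, 1L, 0L, NA)))
  # comparable loci 1 and 3: shared = 2 + 0 of 4 alleles
  expect_equal(unclass(allele_sharing_distance(g4))[1, 2], 1 - 2 / 4)
})

test_that("allele-sharing distance is a metric on complete data", {
  for (s in 1:20) {
    g <- random_gm(4, 6, seed = 400 + s)
    d <- unclass(allele_sharing_distance(g))
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("co-ancestry difference counts complement identity counts", {
  g <- gm(rbind(c(0L, 1L, 2L, 0L, 1L), c(0L, 2L, 2L, 1L, NA)))
  cm <- coancestry_matrix(g)
  # loci 2 and 4 differ; locus 5 missing in one -> 2 differences / 4 loci
  expect_equal(unclass(cm)[1, 2], 2)
  expect_equal(attr(cm, "comparable_loci")[1, 2], 4L)

  # identical individuals and maximally different individuals
  gi <- gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(unclass(coancestry_matrix(gi))[1, 2], 0)
  gd <- gm(rbind(rep(0L, 7), rep(2L, 7)))
  expect_equal(unclass(coancestry_matrix(gd))[1, 2], 7)

  # invariant: differences + identical comparable = jointly observed
  g5 <- random_gm(5, 25, seed = 31)
  g5$genotypes[sample(length(g5$genotypes), 20)] <- NA
  g5 <- gm(g5$genotypes)
  cm5 <- coancestry_matrix(g5)
  for (i in 1:4) for (j in (i + 1):5) {
    both <- !is.na(g5$genotypes[i, ]) & !is.na(g5$genotypes[j, ])
    same <- sum(g5$genotypes[i, both] == g5$genotypes[j, both])
    expect_equal(unclass(cm5)[i, j] + same,
                 attr(cm5, "comparable_loci")[i, j])
  }
})

test_that("classical MDS reproduces embeddable configurations", {
  # 3-4-5 right triangle
  d <- distance_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3),
                       c("a", "b", "c"), kind = "allele_sharing")
  emb <- mds_embed(d, dims = 2)
  expect_equal(as.matrix(dist(emb)), unclass(d), tolerance = 1e-9,
               ignore_attr = TRUE)

  # unit square: distances {1,1,1,1,sqrt 2,sqrt 2}
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- distance_matrix(as.matrix(dist(sq)), letters[1:4],
                         kind = "allele_sharing")
  emb2 <- mds_embed(dsq, dims = 2)
  expect_equal(sort(as.vector(dist(emb2))), sort(as.vector(dist(sq))),
               tolerance = 1e-9)

  # duplicated individuals embed to coincident coordinates
  g <- gm(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L)))
  emb3 <- mds_embed(allele_sharing_distance(g), dims = 2)
  expect_lt(max(abs(emb3[1, ] - emb3[2, ])), 1e-6)
})

test_that("gap statistic finds planted structure and respects determinism", {
  # three tight clusters, separation ~10x the within-cluster spread
  set.seed(9)
  pts <- rbind(matrix(rnorm(16, 0, 0.5), ncol = 2),
               matrix(rnorm(16, 10, 0.5), ncol = 2),
               cbind(rnorm(8, 5, 0.5), rnorm(8, 9, 0.5)))
  d <- distance_matrix(as.matrix(dist(pts)), paste0("i", 1:24),
                       kind = "allele_sharing")
  sel <- select_k_gap(d, 1, 6, n_ref = 100, seed = 5)
  expect_equal(sel$best_k, 3L)
  expect_equal(length(sel$gap), 6L)

  # structureless (all-equal) distances -> K = 1
  n <- 12
  flat <- distance_matrix(matrix(1, n, n) - diag(n), paste0("i", 1:n),
                          kind = "allele_sharing")
  expect_equal(select_k_gap(flat, 1, 6, n_ref = 50, seed = 3)$best_k, 1L)

  # same seed twice -> identical selection object
  s1 <- select_k_gap(d, 1, 6, n_ref = 30, seed = 11)
  s2 <- select_k_gap(d, 1, 6, n_ref = 30, seed = 11)
  expect_identical(s1, s2)
})

test_that("neighbour joining is exact on additive matrices", {
  # three taxa: d(A,B)=2, d(A,C)=3, d(B,C)=3 -> leaf branches 1, 1, 2
  d3 <- distance_matrix(matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3),
                        c("A", "B", "C"), kind = "fst")
  nwk <- nj_tree(d3)
  tr <- attr(nwk, "phylo")
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 2)

  # 4-taxon additive matrix from a known tree: ((A:1,B:2):1.5,(C:0.5,D:3):1);
  ref <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  dmat <- ape::cophenetic.phylo(ref)
  dmat <- dmat[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  nwk4 <- nj_tree(distance_matrix(dmat, colnames(dmat), kind = "fst"))
  tr4 <- attr(nwk4, "phylo")
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(dmat), colnames(dmat)],
               dmat, tolerance = 1e-9)
  expect_equal(unname(ape::dist.topo(ape::unroot(ref), tr4)[1]), 0,
               ignore_attr = TRUE)

  # Newick text re-parses losslessly (ultrametric 3-taxon case)
  du <- distance_matrix(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3),
                        c("x", "y", "z"), kind = "fst")
  nwku <- nj_tree(du)
  reparsed <- ape::read.tree(text = as.character(nwku))
  expect_equal(sort(reparsed$tip.label), c("x", "y", "z"))
  expect_equal(ape::cophenetic.phylo(reparsed)[c("x", "y", "z"), c("x", "y", "z")],
               unclass(du), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(nj_tree(distance_matrix(matrix(0, 2, 2), c("a", "b"),
                                       kind = "fst")), "three")
})

test_that("Nei distance is zero for identical populations", {
  g <- random_gm(8, 40, seed = 12)
  gt <- g$genotypes
  expect_equal(nei_distance(gt, gt), 0, tolerance = 1e-12)
  expect_gt(nei_distance(matrix(0L, 4, 5), matrix(2L, 4, 5)), 1)
})
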