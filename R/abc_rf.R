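#' Summary-statistic vector of a genotype dataset
#'
#' Fixed, versioned statistic set used for the ABC reference table
#' (`stat_set_version = 2`): per population (in map order) mean observed
#' heterozygosity, mean expected heterozygosity, the proportion of loci
#' polymorphic within the population, the mean within-population minor
#' allele frequency over polymorphic loci, and the singleton proportion
#' (polymorphic loci whose minor allele occurs once) — the last two carry
#' the site-frequency-spectrum shape that founder bottlenecks distort; per
#' population pair (in order of the first index) Weir-Cockerham Fst, Nei's
#' standard genetic distance, the mean between-population allele-sharing
#' distance, and the proportion of fixed differences. Undefined entries (e.g.
#' Fst of a pair with no informative locus) are returned as `NA` and imputed
#' by column medians when the reference table is assembled.
#'
#' @param g a [genotype_matrix()].
#' @param pm a [population_map()]; every population must have at least one
#'   individual.
#' @return named numeric vector with attribute `stat_set_version`.
#' @export
summary_vector <- function(g, pm) {
  pops <- pops_of(g, pm)
  labels <- unique(pops)
  if (any(table(pops) < 1)) stop("empty population")
  gt <- g$genotypes

  per_pop <- lapply(labels, function(pp) {
    sub <- gt[pops == pp, , drop = FALSE]
    fh <- locus_freq_het(sub)
    use <- fh$n > 0
    ho <- mean(fh$het[use])
    he_l <- (2 * fh$n[use]) / (2 * fh$n[use] - 1) *
      (1 - (fh$p[use]^2 + (1 - fh$p[use])^2))
    he_l[fh$n[use] == 1] <- NA_real_
    he <- mean(he_l, na.rm = TRUE)
    p <- fh$p[use]
    is_poly <- p > 0 & p < 1
    poly <- mean(is_poly)
    # within-population SFS shape: bottlenecks prune rare alleles, shifting
    # the minor-allele frequency up and the singleton fraction down
    maf <- pmin(p, 1 - p)
    maf_mean <- if (any(is_poly)) mean(maf[is_poly]) else 0
    mac <- maf * 2 * fh$n[use]
    singleton <- if (any(is_poly)) mean(mac[is_poly] <= 1 + 1e-9) else 0
    c(Ho = ho, He = he, poly = poly, maf = maf_mean, singl = singleton)
  })

  asd <- NULL
  stats_out <- numeric(0)
  for (k in seq_along(labels)) {
    v <- per_pop[[k]]
    names(v) <- paste0(c("Ho_", "He_", "poly_", "maf_", "singl_"),
                       labels[k])
    stats_out <- c(stats_out, v)
  }
  for (i in seq_len(length(labels) - 1)) {
    for (j in seq(i + 1, length(labels))) {
      g1 <- gt[pops == labels[i], , drop = FALSE]
      g2 <- gt[pops == labels[j], , drop = FALSE]
      s <- wc_pair_sums(g1, g2)
      fst <- if (s[["den"]] != 0) s[["num"]] / s[["den"]] else NA_real_
      nei <- nei_distance(g1, g2)
      if (is.null(asd)) asd <- unclass(allele_sharing_distance(g))
      cross <- asd[pops == labels[i], pops == labels[j], drop = FALSE]
      f1 <- locus_freq_het(g1)
      f2 <- locus_freq_het(g2)
      both <- f1$n > 0 & f2$n > 0
      fixed <- mean(abs(f1$p[both] - f2$p[both]) >= 1 - 1e-9)
      # shared vs private polymorphism: a freshly founded population
      # carries a subset of its source's variation, an anciently drifted
      # one accumulates private polymorphism
      poly1 <- f1$p[both] > 0 & f1$p[both] < 1
      poly2 <- f2$p[both] > 0 & f2$p[both] < 1
      pair <- c(fst, nei, mean(cross, na.rm = TRUE), fixed,
                mean(poly1 & poly2), mean(poly1 & !poly2),
                mean(!poly1 & poly2))
      names(pair) <- paste0(c("fst_", "neiD_", "asd_", "fixed_",
                              "polyboth_", "polyonly1_", "polyonly2_"),
                            labels[i], "_", labels[j])
      stats_out <- c(stats_out, pair)
    }
  }
  attr(stats_out, "stat_set_version") <- 2L
  stats_out
}

#' Build an ABC reference table
#'
#' Draws `n_per_scenario` parameter sets per scenario from the priors,
#' simulates a SNP dataset for each with [simulate_dataset()], and records
#' `(scenario_id, parameters, summary statistics)`. Per-row seeds are derived
#' reproducibly from the master seed, so any row can be replayed. `NA`
#' statistic cells are imputed by their column median (count reported in
#' `n_imputed`).
#'
#' @param scenarios integer vector of scenario ids (default 1:4).
#' @param p a [prior_set()].
#' @param n_per_scenario simulations per scenario.
#' @param sample_sizes,n_loci,missing_prob passed to [simulate_dataset()].
#' @param seed master integer seed.
#' @return object of class `reference_table`: list with `scenario` (factor),
#'   `params` (matrix, columns [PARAM_NAMES]), `stats` (matrix), `seeds`
#'   (per-row), `n_imputed`, `prior`, and bookkeeping fields.
#' @export
build_reference_table <- function(scenarios = 1:4, p = prior_set(),
                                  n_per_scenario = 500,
                                  sample_sizes = SAMPLE_SIZES, n_loci = 120,
                                  missing_prob = 0, seed = 1) {
  stopifnot(n_per_scenario >= 1)
  n_rows <- length(scenarios) * n_per_scenario
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1, n_rows)
  scen_col <- rep(scenarios, each = n_per_scenario)
  params <- matrix(NA_real_, n_rows, length(PARAM_NAMES),
                   dimnames = list(NULL, PARAM_NAMES))
  stats_list <- vector("list", n_rows)
  for (r in seq_len(n_rows)) {
    set.seed(row_seeds[r])
    d <- sample_prior(p, seed = NULL)
    g <- simulate_dataset(scen_col[r], d, sample_sizes = sample_sizes,
                          n_loci = n_loci, seed = NULL,
                          missing_prob = missing_prob)
    pm <- default_population_map(sample_sizes)
    stats_list[[r]] <- tryCatch(summary_vector(g, pm), error = function(e)
      stop("reference-table row ", r, " (scenario ", scen_col[r], ", seed ",
           row_seeds[r], ") failed: ", conditionMessage(e)))
    params[r, ] <- unlist(d[PARAM_NAMES])
  }
  stats <- do.call(rbind, stats_list)
  stats[!is.finite(stats)] <- NA_real_  # e.g. infinite Nei D (no shared alleles)
  n_imputed <- sum(is.na(stats))
  if (n_imputed > 0) {
    for (cl in which(colSums(is.na(stats)) > 0)) {
      med <- stats::median(stats[, cl], na.rm = TRUE)
      stats[is.na(stats[, cl]), cl] <- med
    }
  }
  structure(list(scenario = factor(scen_col, levels = sort(unique(scenarios))),
                 params = params, stats = stats, seeds = row_seeds,
                 n_imputed = n_imputed, prior = p,
                 sample_sizes = sample_sizes, n_loci = n_loci,
                 missing_prob = missing_prob, master_seed = seed,
                 stat_set_version = 2L),
            class = "reference_table")
}

#' @exportS3Method base::print
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d rows (%s), %d statistics, %d imputed cells\n",
              length(x$scenario),
              paste(table(x$scenario), collapse = "/"),
              ncol(x$stats), x$n_imputed))
  invisible(x)
}

#' Replay one reference-table row
#'
#' Recomputes the summary statistics of row `r` from its recorded seed; used
#' to spot-check table integrity.
#' @param rt a [build_reference_table()] result.
#' @param r row index.
#' @return named statistic vector.
#' @export
replay_reference_row <- function(rt, r) {
  set.seed(rt$seeds[r])
  d <- sample_prior(rt$prior, seed = NULL)
  g <- simulate_dataset(as.integer(as.character(rt$scenario[r])), d,
                        sample_sizes = rt$sample_sizes, n_loci = rt$n_loci,
                        seed = NULL, missing_prob = rt$missing_prob)
  summary_vector(g, default_population_map(rt$sample_sizes))
}

#' Persist / load a reference table as TSV with a JSON header
#'
#' The first line is a `#`-prefixed JSON object holding priors, seeds,
#' statistic ordering and version; the body is tab-separated rows.
#' @param rt a `reference_table`.
#' @param path file path.
#' @return `write_reference_table`: `path` invisibly; `read_reference_table`:
#'   a `reference_table`.
#' @export
write_reference_table <- function(rt, path) {
  hdr <- jsonlite::toJSON(list(prior = unclass(rt$prior),
                               master_seed = rt$master_seed,
                               sample_sizes = as.list(rt$sample_sizes),
                               n_loci = rt$n_loci,
                               missing_prob = rt$missing_prob,
                               n_imputed = rt$n_imputed,
                               stat_names = colnames(rt$stats),
                               stat_set_version = rt$stat_set_version),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  tab <- data.frame(scenario = as.character(rt$scenario), seed = rt$seeds,
                    rt$params, rt$stats, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  first <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           check.names = FALSE)
  params <- as.matrix(tab[, PARAM_NAMES])
  stats <- as.matrix(tab[, meta$stat_names])
  structure(list(scenario = factor(tab$scenario), params = params,
                 stats = stats, seeds = tab$seed,
                 n_imputed = meta$n_imputed,
                 prior = do.call(prior_set, lapply(meta$prior, as.numeric)),
                 sample_sizes = unlist(meta$sample_sizes),
                 n_loci = meta$n_loci, missing_prob = meta$missing_prob,
                 master_seed = meta$master_seed,
                 stat_set_version = meta$stat_set_version),
            class = "reference_table")
}

# single-threaded forests: reproducible wall-times and identical behaviour
# on one-CPU hosts; override via option for exploratory work
num_threads <- function() getOption("eokochia.num_threads", 1L)

impute_observed <- function(observed, rt) {
  if (is.null(dim(observed))) observed <- matrix(observed, 1)
  if (ncol(observed) != ncol(rt$stats))
    stop("observed vector has ", ncol(observed), " entries; reference ",
         "table expects ", ncol(rt$stats))
  for (cl in seq_len(ncol(observed))) {
    bad <- !is.finite(observed[, cl])
    if (any(bad)) observed[bad, cl] <- stats::median(rt$stats[, cl])
  }
  observed
}

lda_features <- function(rt, observed, lda = c("none", "append", "replace")) {
  lda <- match.arg(lda)
  if (lda == "none") return(list(train = rt$stats, obs = observed))
  # LDA cannot use columns that are (near-)constant within every class;
  # screen them out of the discriminant fit (they stay in the raw features)
  usable <- vapply(seq_len(ncol(rt$stats)), function(j) {
    x <- rt$stats[, j]
    sx <- stats::sd(x)
    if (!is.finite(sx) || sx < 1e-12) return(FALSE)
    within <- x - stats::ave(x, rt$scenario)
    stats::sd(within) / sx > 1e-3
  }, logical(1))
  if (sum(usable) < 2) stop("too few informative statistics for LDA")
  ld <- MASS::lda(rt$stats[, usable, drop = FALSE], grouping = rt$scenario)
  train_axes <- stats::predict(ld, rt$stats[, usable, drop = FALSE])$x
  obs_axes <- stats::predict(ld, observed[, usable, drop = FALSE])$x
  if (lda == "append") {
    list(train = cbind(rt$stats, train_axes),
         obs = cbind(observed, obs_axes))
  } else {
    list(train = train_axes, obs = obs_axes)
  }
}

#' Random-forest scenario choice
#'
#' Trains a classification forest of `n_trees` trees on the
#' reference-table statistics, drops the observed vector down every tree,
#' and reports the per-scenario tree counts as votes. Optionally a linear
#' discriminant analysis is fit on the reference statistics first (scenario
#' id as class; one axis fewer than scenarios) and its axes appended to, or
#' substituted for, the raw statistics. The default uses the raw
#' statistics: in calibration runs the LDA axes, fit on the bulk of the
#' prior predictive, extrapolated unstably to extreme parameter corners and
#' made the classification table-seed dependent there (see the methods
#' vignette). The posterior
#' probability of the winning scenario is estimated in the usual ABC-RF way:
#' a regression forest is trained on the out-of-bag
#' classification-correctness indicator and evaluated at the observed point
#' (clipped to `[0, 1]`).
#'
#' @param rt a [build_reference_table()] result with >= 2 scenarios.
#' @param observed summary vector of the observed dataset (from
#'   [summary_vector()]), or a matrix with one such vector per row to
#'   classify many datasets with a single trained forest.
#' @param n_trees number of trees (study setting: 1500).
#' @param seed integer seed for both forests.
#' @param lda `"none"` (default: raw statistics), `"append"` (raw
#'   statistics plus LDA axes), or `"replace"` (LDA axes only).
#' @param posterior estimate the posterior probability (default `TRUE`);
#'   set `FALSE` to skip the second forest when only votes are needed,
#'   e.g. in large calibration experiments.
#' @return object of class `model_choice`: `votes` (named integer),
#'   `best_scenario`, `posterior_probability`, `n_trees` — or a list of such
#'   objects when `observed` is a matrix.
#' @export
choose_scenario <- function(rt, observed, n_trees = 1500, seed = 1,
                            lda = c("none", "append", "replace"),
                            posterior = TRUE) {
  stopifnot(inherits(rt, "reference_table"), n_trees >= 1)
  if (nlevels(rt$scenario) < 2) stop("need at least two scenarios")
  single <- is.null(dim(observed))
  observed <- impute_observed(observed, rt)
  ft <- lda_features(rt, observed, match.arg(lda))
  train <- data.frame(ft$train, check.names = FALSE)
  train$..scenario <- rt$scenario
  obs_df <- data.frame(ft$obs, check.names = FALSE)
  colnames(obs_df) <- colnames(ft$train)
  rf <- ranger::ranger(dependent.variable.name = "..scenario", data = train,
                       num.trees = n_trees, seed = seed, verbose = FALSE, num.threads = num_threads(),
                       keep.inbag = FALSE)
  per_tree <- stats::predict(rf, obs_df, predict.all = TRUE)$predictions
  if (is.null(dim(per_tree))) per_tree <- matrix(per_tree, 1)
  lev <- levels(rt$scenario)
  votes <- t(apply(per_tree, 1, tabulate, nbins = length(lev)))
  colnames(votes) <- lev

  if (posterior) {
    correct <- as.numeric(rf$predictions == rt$scenario)  # OOB correctness
    train2 <- data.frame(ft$train, check.names = FALSE)
    train2$..correct <- correct
    rf2 <- ranger::ranger(dependent.variable.name = "..correct",
                          data = train2, num.trees = n_trees,
                          seed = seed + 1, verbose = FALSE,
                          num.threads = num_threads())
    post <- stats::predict(rf2, obs_df)$predictions
    post <- pmin(pmax(post, 0), 1)
  } else {
    post <- rep(NA_real_, nrow(obs_df))
  }

  results <- lapply(seq_len(nrow(obs_df)), function(r) {
    v <- stats::setNames(votes[r, ], lev)
    structure(list(votes = v,
                   best_scenario = as.integer(lev[which.max(v)]),
                   posterior_probability = post[r], n_trees = n_trees),
              class = "model_choice")
  })
  if (single) results[[1]] else results
}

#' @exportS3Method base::print
print.model_choice <- function(x, ...) {
  cat(sprintf("model_choice: best scenario %d (votes %s of %d trees, posterior p = %.3f)\n",
              x$best_scenario, paste(x$votes, collapse = "/"), x$n_trees,
              x$posterior_probability))
  invisible(x)
}

#' Restrict a reference table to one scenario
#' @param rt a `reference_table`.
#' @param scenario_id scenario to keep.
#' @return a `reference_table` with a single scenario level.
#' @export
subset_scenario <- function(rt, scenario_id) {
  keep <- rt$scenario == as.character(scenario_id)
  out <- rt
  out$scenario <- factor(as.character(rt$scenario[keep]))
  out$params <- rt$params[keep, , drop = FALSE]
  out$stats <- rt$stats[keep, , drop = FALSE]
  out$seeds <- rt$seeds[keep]
  out
}

#' Random-forest posterior parameter estimation
#'
#' For each demographic parameter a quantile regression forest is trained on
#' the reference table of the chosen scenario. The posterior mean is the
#' forest prediction at the observed vector; the 5%/50%/95% posterior
#' quantiles come from the quantile-forest leaf weights (sorted so
#' `q5 <= median <= q95` by construction); the posterior variance is
#' estimated by a second forest trained on squared out-of-bag residuals.
#' Constant parameter columns yield a degenerate (all-equal) summary,
#' flagged in the `degenerate` column.
#'
#' @param rt_best reference table restricted to the best scenario
#'   ([subset_scenario()]).
#' @param observed observed summary vector, or a matrix of vectors (one row
#'   per dataset) to estimate for many pseudo-observed datasets with a
#'   single training pass.
#' @param n_trees trees per forest (study setting: 1500).
#' @param seed integer seed.
#' @param parameters subset of [PARAM_NAMES] to estimate (default: all).
#' @param min_node_size minimum terminal-node size of the quantile forest;
#'   quantile estimation benefits from larger nodes than point prediction,
#'   so the default (20) is above ranger's regression default.
#' @return data.frame (class `posterior_summary`) with one row per
#'   parameter: `mean`, `median`, `q5`, `q95`, `variance`, `degenerate`.
#' @export
estimate_parameters <- function(rt_best, observed, n_trees = 1500,
                                seed = 1, parameters = PARAM_NAMES,
                                min_node_size = 20) {
  stopifnot(inherits(rt_best, "reference_table"),
            nrow(rt_best$stats) >= 1,
            all(parameters %in% colnames(rt_best$params)))
  single <- is.null(dim(observed))
  observed <- impute_observed(observed, rt_best)
  n_obs <- nrow(observed)
  train_x <- data.frame(rt_best$stats, check.names = FALSE)
  obs_df <- data.frame(observed, check.names = FALSE)
  colnames(obs_df) <- colnames(rt_best$stats)
  rows <- lapply(match(parameters, colnames(rt_best$params)), function(k) {
    y <- rt_best$params[, k]
    pname <- colnames(rt_best$params)[k]
    if (stats::var(y) == 0) {
      return(data.frame(obs = seq_len(n_obs), parameter = pname,
                        mean = y[1], median = y[1], q5 = y[1], q95 = y[1],
                        variance = 0, degenerate = TRUE))
    }
    dat <- train_x
    dat$..y <- y
    rf <- ranger::ranger(dependent.variable.name = "..y", data = dat,
                         num.trees = n_trees, seed = seed, quantreg = TRUE,
                         min.node.size = min_node_size, verbose = FALSE,
                         num.threads = num_threads())
    mn <- stats::predict(rf, obs_df)$predictions
    qs <- stats::predict(rf, obs_df, type = "quantiles",
                         quantiles = c(0.05, 0.5, 0.95))$predictions
    qs <- t(apply(qs, 1, sort))
    resid2 <- (y - rf$predictions)^2
    dat2 <- train_x
    dat2$..y <- resid2
    rf_var <- ranger::ranger(dependent.variable.name = "..y", data = dat2,
                             num.trees = n_trees, seed = seed + 1, verbose = FALSE, num.threads = num_threads())
    vr <- pmax(stats::predict(rf_var, obs_df)$predictions, 0)
    data.frame(obs = seq_len(n_obs), parameter = pname, mean = mn,
               median = qs[, 2], q5 = qs[, 1], q95 = qs[, 3], variance = vr,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  if (single) {
    out$obs <- NULL
  } else {
    out <- out[order(out$obs), ]
    rownames(out) <- NULL
  }
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Convert generations to calendar years and Mya
#'
#' `years = generations * generation_time`; `Mya = years / 1e6` reported
#' rounded to two decimals (so e.g. 24615 generations at a 10-year
#' generation time is 0.25 Mya).
#'
#' @param g generations (>= 0).
#' @param generation_time generation time in years (default 10).
#' @return list with `years` and `Mya` (2 dp).
#' @export
generations_to_years <- function(g, generation_time = 10) {
  stopifnot(all(g >= 0))
  years <- g * generation_time
  list(years = years, Mya = round(years / 1e6, 2))
}
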