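#' Build a statistical-parsimony haplotype network
#'
#' Connects sampled haplotypes agglomeratively in increasing Hamming-distance
#' order (Kruskal-style: a pair already in the same component is skipped, so
#' no loops form). A connection of distance `d <= limit` inserts a chain of
#' `d - 1` inferred intermediate nodes whose reconstructed sequences mutate
#' one differing position at a time (positions in ascending order). Pairs
#' beyond `limit` stay in separate components. Among candidate connections at
#' equal distance, the pair with the higher combined carrier frequency is
#' attached first (ties broken lexicographically by id pair).
#'
#' @param h a [haplotype_set()].
#' @param limit maximum connectable step count, e.g. from
#'   [parsimony_limit()].
#' @return object of class `haplotype_network`: list with an `igraph`
#'   `graph` (vertex attributes `type` = sampled/inferred, `frequency`,
#'   `sequence`, population composition), `n_inferred`, `n_components`, and
#'   the input `haplotypes`.
#' @export
build_network <- function(h, limit = parsimony_limit(nchar(h$sequences[1]))) {
  stopifnot(inherits(h, "haplotype_set"), limit >= 1)
  n <- length(h$sequences)
  if (n == 0) stop("empty haplotype set")
  dm <- hamming_matrix(h)

  # candidate pairs ordered by the connection preference
  pairs <- NULL
  if (n > 1) {
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                        d = dm[idx],
                        freq = h$frequencies[idx[, 1]] +
                          h$frequencies[idx[, 2]],
                        key = paste(pmin(h$ids[idx[, 1]], h$ids[idx[, 2]]),
                                    pmax(h$ids[idx[, 1]], h$ids[idx[, 2]])))
    pairs <- pairs[order(pairs$d, -pairs$freq, pairs$key), , drop = FALSE]
  }

  # union-find over sampled haplotypes
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }

  vertices <- data.frame(name = h$ids, type = "sampled",
                         frequency = h$frequencies,
                         sequence = unname(h$sequences),
                         stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0))
  n_inferred <- 0L

  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      d <- pairs$d[r]
      if (d > limit) next
      i <- pairs$i[r]; j <- pairs$j[r]
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      parent[ri] <- rj
      if (d == 0) d <- 1  # identical ids kept distinct: direct edge
      sa <- strsplit(h$sequences[i], "")[[1]]
      sb <- strsplit(h$sequences[j], "")[[1]]
      diffpos <- which(sa != sb &
                         !(sa %in% c("N", "-", "?")) &
                         !(sb %in% c("N", "-", "?")))
      chain <- h$ids[i]
      cur <- sa
      if (length(diffpos) > 1) {
        for (s in seq_len(length(diffpos) - 1)) {
          cur[diffpos[s]] <- sb[diffpos[s]]
          n_inferred <- n_inferred + 1L
          mv <- paste0("mv", n_inferred)
          vertices <- rbind(vertices,
                            data.frame(name = mv, type = "inferred",
                                       frequency = 0L,
                                       sequence = paste0(cur, collapse = ""),
                                       stringsAsFactors = FALSE))
          chain <- c(chain, mv)
        }
      }
      chain <- c(chain, h$ids[j])
      edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                       to = chain[-1]))
    }
  }

  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = vertices)
  if (!is.null(h$population_counts)) {
    for (pp in colnames(h$population_counts)) {
      cnt <- integer(igraph::vcount(gr))
      m <- match(h$ids, igraph::V(gr)$name)
      cnt[m] <- h$population_counts[, pp]
      gr <- igraph::set_vertex_attr(gr, paste0("pop_", pp), value = cnt)
    }
  }
  structure(list(graph = gr,
                 n_inferred = n_inferred,
                 n_components = igraph::components(gr)$no,
                 limit = limit,
                 haplotypes = h),
            class = "haplotype_network")
}

#' @exportS3Method base::print
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype_network: %d sampled + %d inferred nodes, %d edges, %d component(s), limit %d\n",
    length(x$haplotypes$sequences), x$n_inferred,
    igraph::ecount(x$graph), x$n_components, x$limit))
  invisible(x)
}

#' Mutational steps between two sampled haplotypes in a network
#'
#' Path length in edges (each edge is one mutational step); `Inf` when the
#' haplotypes sit in different components.
#'
#' @param net a [build_network()] result.
#' @param a,b haplotype ids.
#' @return numeric step count.
#' @export
network_steps <- function(net, a, b) {
  as.numeric(igraph::distances(net$graph, v = a, to = b))
}

#' Export a haplotype network
#'
#' Writes the graph as GraphML, the edges as a tab-separated list, and (when
#' population counts exist) the per-node population composition table.
#'
#' @param net a [build_network()] result.
#' @param graphml_path,edgelist_path,composition_path output paths; `NULL`
#'   entries are skipped.
#' @return invisible list of the written paths.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL,
                          composition_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(net$graph)
    utils::write.table(data.frame(from = el[, 1], to = el[, 2], steps = 1L),
                       edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(composition_path) && !is.null(net$haplotypes$population_counts)) {
    pc <- net$haplotypes$population_counts
    utils::write.table(cbind(haplotype = rownames(pc), as.data.frame(pc)),
                       composition_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(graphml = graphml_path, edgelist = edgelist_path,
                 composition = composition_path))
}
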