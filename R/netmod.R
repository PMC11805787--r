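# Functional-connectivity network pipeline: per-run Pearson correlation
# matrices, run averaging, density thresholding with binarization, the
# binary-graph modularity measure, and a seeded Newman-style modularity
# maximizer (greedy agglomeration plus node-move refinement with restarts).

#' Per-run connectivity matrices from a time-series panel
#'
#' One Pearson correlation matrix per run: edge (i, j) is the correlation of
#' node i's and node j's time series within that run.
#'
#' @param panel A `runs x nodes x timepoints` array (e.g. from
#'   [generate_modular_timeseries()]).
#' @param on_constant `"error"` (default) or `"na"` for nodes with constant
#'   series (undefined correlations).
#' @return List of symmetric `nodes x nodes` correlation matrices.
#' @export
connectivity_from_timeseries <- function(panel, on_constant = c("error", "na")) {
  on_constant <- match.arg(on_constant)
  dm <- dim(panel)
  stop_if_not(length(dm) == 3, "panel must be a runs x nodes x timepoints array")
  stop_if_not(dm[3] >= 2, "need at least 2 timepoints per run")
  lapply(seq_len(dm[1]), function(r) {
    x <- t(panel[r, , , drop = TRUE])  # timepoints x nodes
    const <- apply(x, 2, stats::sd) == 0
    if (any(const) && on_constant == "error")
      stop("constant node series: correlation undefined for nodes ",
           paste(which(const), collapse = ", "))
    suppressWarnings(stats::cor(x))
  })
}

#' Average connectivity matrices across runs
#'
#' Elementwise arithmetic mean of the raw correlations (the default), or of
#' Fisher z-transformed correlations back-transformed after averaging.
#'
#' @param nets List of equal-dimension symmetric matrices.
#' @param fisher_z Average on the Fisher z scale?
#' @return A single symmetric matrix.
#' @export
average_networks <- function(nets, fisher_z = FALSE) {
  stop_if_not(length(nets) >= 1, "need at least one network")
  dims <- vapply(nets, function(m) paste(dim(m), collapse = "x"), character(1))
  stop_if_not(length(unique(dims)) == 1, "dimension mismatch across networks")
  if (fisher_z) {
    z <- Reduce(`+`, lapply(nets, atanh)) / length(nets)
    out <- tanh(z)
    diag(out) <- 1
    out
  } else {
    Reduce(`+`, nets) / length(nets)
  }
}

#' Threshold and binarize a weighted network
#'
#' Retains the k strongest off-diagonal edges, k = ceiling(density x
#' n(n-1)/2), and sets them to 1 (all others 0). "Strongest" ranks edges by
#' signed weight by default (`rank_by = "absolute"` ranks by |weight|). Ties
#' at the cutoff are broken deterministically in lexicographic (i, j) order.
#'
#' @param weights Symmetric weight matrix (diagonal ignored).
#' @param density Proportion of all node pairs to retain, in (0, 1\].
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return List of class `spoarc_graph`: `adjacency` (0/1 symmetric, zero
#'   diagonal), `n_nodes`, `degrees`, `n_edges`, `density`, `ties_at_cutoff`.
#' @export
threshold_binarize <- function(weights, density, rank_by = c("signed",
                                                             "absolute")) {
  rank_by <- match.arg(rank_by)
  stop_if_not(density > 0 && density <= 1, "density must be in (0, 1]")
  stop_if_not(nrow(weights) == ncol(weights), "weights must be square")
  n <- nrow(weights)
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[ut]
  if (rank_by == "absolute") w <- abs(w)
  stop_if_not(all(is.finite(w)), "non-finite edge weights")
  n_pairs <- n * (n - 1) / 2
  k <- as.integer(ceiling(density * n_pairs))
  stop_if_not(k <= n_pairs, "k exceeds available edges")
  ord <- order(-w, ut[, 1], ut[, 2])
  pick <- ord[seq_len(k)]
  ties <- k < n_pairs && w[ord[k]] == w[ord[k + 1]]
  A <- matrix(0L, n, n)
  A[ut[pick, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, n_nodes = n, degrees = rowSums(A),
                 n_edges = sum(A) / 2, density = density,
                 ties_at_cutoff = ties),
            class = "spoarc_graph")
}

as_spoarc_graph <- function(x) {
  if (inherits(x, "spoarc_graph")) return(x)
  A <- as.matrix(x)
  stop_if_not(isTRUE(all.equal(A, t(A))), "adjacency must be symmetric")
  diag(A) <- 0
  A <- (A != 0) + 0L
  structure(list(adjacency = A, n_nodes = nrow(A), degrees = rowSums(A),
                 n_edges = sum(A) / 2, density = NA_real_,
                 ties_at_cutoff = FALSE),
            class = "spoarc_graph")
}

#' Modularity of a partition of a binary graph
#'
#' M = (1/2e) sum over modules of sum over ordered node pairs (i, j) in the
#' module (including i = j) of (A_ij - a_i a_j / 2e), with a_i the degree of
#' node i and e the edge count. M is 0 for the single-module partition and
#' lies in \[-1, 1\].
#'
#' @param graph A `spoarc_graph` (or symmetric 0/1 adjacency matrix).
#' @param membership Integer module labels, one per node.
#' @return The modularity M.
#' @export
modularity_score <- function(graph, membership) {
  g <- as_spoarc_graph(graph)
  stop_if_not(length(membership) == g$n_nodes,
              "membership must label every node")
  e2 <- 2 * g$n_edges
  stop_if_not(e2 > 0, "graph has no edges")
  m <- 0
  for (mod in unique(membership)) {
    ix <- which(membership == mod)
    a_sum <- sum(g$degrees[ix])
    m <- m + sum(g$adjacency[ix, ix]) - a_sum^2 / e2
  }
  m / e2
}

# modularity gain of merging communities c and d (constant terms cancel)
merge_gain <- function(e_cd, a_c, a_d, e2) 2 * (e_cd / e2 - a_c * a_d / e2^2)

#' Maximize modularity over partitions
#'
#' Seeded Newman-style maximization: greedy agglomeration from singleton
#' communities (merging the pair with the largest modularity gain, tracking
#' the best partition along the merge path) followed by a node-move
#' refinement pass (each node moved to the community that most increases M,
#' iterated to a local optimum), with additional restarts from random
#' partitions. Deterministic given `seed`. Isolated nodes remain singleton
#' modules.
#'
#' @param graph A `spoarc_graph` (or adjacency matrix) with at least 1 edge.
#' @param n_restarts Number of random-restart refinements (default 20).
#' @param seed Integer seed.
#' @return List of class `spoarc_modularity`: `modularity`, `membership`
#'   (contiguous labels from 1), `n_modules`.
#' @export
optimize_partition <- function(graph, n_restarts = 20, seed = 1L) {
  g <- as_spoarc_graph(graph)
  stop_if_not(g$n_edges >= 1, "graph must have at least one edge")
  set.seed(seed)
  n <- g$n_nodes
  A <- g$adjacency

  best <- greedy_agglomerate(g)
  best <- refine_partition(g, best, sample(n))
  for (r in seq_len(n_restarts)) {
    ks <- 2:max(2, min(n, 10))
    k <- ks[sample.int(length(ks), 1)]
    init <- sample(seq_len(k), n, replace = TRUE)
    cand <- refine_partition(g, init, sample(n))
    if (modularity_score(g, cand) > modularity_score(g, best)) best <- cand
  }
  best <- match(best, unique(best))  # contiguous labels from 1
  structure(list(modularity = modularity_score(g, best), membership = best,
                 n_modules = length(unique(best))),
            class = "spoarc_modularity")
}

greedy_agglomerate <- function(g) {
  n <- g$n_nodes
  e2 <- 2 * g$n_edges
  memb <- seq_len(n)
  # community-level edge-weight and degree bookkeeping
  E <- g$adjacency * 1
  a <- g$degrees
  alive <- rep(TRUE, n)
  best_memb <- memb
  best_m <- modularity_score(g, memb)
  cur_m <- best_m
  for (step in seq_len(n - 1)) {
    live <- which(alive)
    if (length(live) < 2) break
    gain_best <- -Inf; pair <- NULL
    for (ci in seq_along(live)) {
      ci_id <- live[ci]
      for (cj in seq_len(ci - 1L)) {
        cj_id <- live[cj]
        gn <- merge_gain(E[ci_id, cj_id], a[ci_id], a[cj_id], e2)
        if (gn > gain_best + 1e-15) {
          gain_best <- gn
          pair <- c(cj_id, ci_id)
        }
      }
    }
    if (is.null(pair)) break
    keep <- pair[1]; drop <- pair[2]
    memb[memb == drop] <- keep
    E[keep, ] <- E[keep, ] + E[drop, ]
    E[, keep] <- E[, keep] + E[, drop]
    a[keep] <- a[keep] + a[drop]
    alive[drop] <- FALSE
    cur_m <- cur_m + gain_best
    if (cur_m > best_m) {
      best_m <- cur_m
      best_memb <- memb
    }
  }
  best_memb
}

# node-move local search: repeatedly move single nodes to the community
# (including a fresh singleton) that most increases modularity
refine_partition <- function(g, memb, order_nodes) {
  A <- g$adjacency
  a <- g$degrees
  e2 <- 2 * g$n_edges
  memb <- match(memb, unique(memb))
  repeat {
    improved <- FALSE
    for (i in order_nodes) {
      ci <- memb[i]
      comms <- unique(memb)
      free_label <- max(comms) + 1L
      # links from i to each community and community degree sums
      k_i_to <- vapply(comms, function(cn) sum(A[i, memb == cn]), numeric(1))
      names(k_i_to) <- comms
      a_tot <- vapply(comms, function(cn) sum(a[memb == cn]), numeric(1))
      names(a_tot) <- comms
      # gain of removing i from ci
      remove_gain <- -2 * (k_i_to[[as.character(ci)]] / e2 -
                             a[i] * (a_tot[[as.character(ci)]] - a[i]) / e2^2)
      cand <- c(setdiff(comms, ci), free_label)
      gains <- vapply(cand, function(cn) {
        if (cn == free_label) return(remove_gain)
        remove_gain + 2 * (k_i_to[[as.character(cn)]] / e2 -
                             a[i] * a_tot[[as.character(cn)]] / e2^2)
      }, numeric(1))
      j <- which.max(gains)
      if (gains[j] > 1e-12) {
        memb[i] <- cand[j]
        memb <- match(memb, unique(memb))
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

#' End-to-end network pipeline
#'
#' Composition of the network stages: per-run connectivity, run averaging,
#' density thresholding/binarization, and modularity maximization.
#'
#' @param panel A `runs x nodes x timepoints` array.
#' @param density Edge density to retain (default 0.1147).
#' @param rank_by Edge ranking passed to [threshold_binarize()].
#' @param fisher_z Average runs on the Fisher z scale?
#' @param n_restarts,seed Passed to [optimize_partition()].
#' @return A `spoarc_modularity` result with the retained edge count
#'   (`n_edges`), density and the binary graph attached.
#' @export
network_pipeline <- function(panel, density = 0.1147,
                             rank_by = "signed", fisher_z = FALSE,
                             n_restarts = 20, seed = 1L) {
  nets <- connectivity_from_timeseries(panel)
  avg <- average_networks(nets, fisher_z = fisher_z)
  graph <- threshold_binarize(avg, density, rank_by = rank_by)
  res <- optimize_partition(graph, n_restarts = n_restarts, seed = seed)
  res$n_edges <- graph$n_edges
  res$density <- density
  res$graph <- graph
  res
}
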