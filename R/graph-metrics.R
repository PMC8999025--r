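# Binary-network topology metrics. Conventions (documented in the methods
# vignette): nodes of degree < 2 contribute 0 to clustering and local
# efficiency; efficiencies use 1/Inf = 0 for disconnected pairs;
# characteristic path length averages over connected pairs only;
# betweenness sums over ordered pairs with normalizer (n-1)(n-2).

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

shortest_distances <- function(net) {
  igraph::distances(as_igraph(net), algorithm = "unweighted")
}

#' Keep the strongest edges of a connectivity matrix at a target density
#'
#' Sparsity thresholding: retain the \code{floor(T * n_pairs)} largest
#' upper-triangle correlations as edges (so the network density is
#' approximately \code{T}); ties at the cut are broken by ascending
#' (i, j) order, deterministically. Edge sets are nested across T.
#'
#' @param mat A \code{connectivity_matrix}.
#' @param T Target density in (0, 1).
#' @return A \code{binary_network} with \code{thresholding_mode = "density"}.
#' @export
density_threshold <- function(mat, T) {
  assert_scalar_number(T, "T", lower = -Inf, upper = Inf)
  if (T <= 0 || T >= 1)
    stopf("density T must lie in (0, 1)", class = "rsfnirs_invalid_parameter")
  V <- mat$values
  n <- nrow(V)
  pairs <- upper_tri_pairs(n)
  vals <- V[pairs]
  keep_n <- floor(T * nrow(pairs))
  A <- matrix(0L, n, n)
  if (keep_n > 0) {
    ord <- order(-vals, pairs[, 1], pairs[, 2])
    sel <- pairs[ord[seq_len(keep_n)], , drop = FALSE]
    A[sel] <- 1L
    A[sel[, 2:1, drop = FALSE]] <- 1L
  }
  binary_network(A, threshold_used = T, thresholding_mode = "density")
}

#' Network clustering coefficient
#'
#' Mean over all nodes of \eqn{2 t_i / (k_i (k_i - 1))}, with \eqn{t_i}
#' the triangle count around node i; nodes with degree < 2 contribute 0.
#'
#' @param net A \code{binary_network}.
#' @return Scalar in [0, 1].
#' @export
clustering_coefficient <- function(net) {
  A <- net$adjacency
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Global efficiency
#'
#' \eqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}} with
#' \eqn{1/\infty = 0} for disconnected pairs.
#'
#' @param net A \code{binary_network}.
#' @return Scalar in [0, 1].
#' @export
global_efficiency <- function(net) {
  n <- nrow(net$adjacency)
  if (n < 2) return(0)
  D <- shortest_distances(net)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected pairs of distinct nodes;
#' disconnected pairs are excluded. A graph with no edges has no defined
#' path length and returns \code{NA} with a warning attribute.
#'
#' @param net A \code{binary_network}.
#' @return Scalar >= 1, or \code{NA} for an empty graph.
#' @export
char_path_length <- function(net) {
  if (sum(net$adjacency) == 0) return(NA_real_)
  D <- shortest_distances(net)
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbors (0 for degree < 2); the network value is the mean over all
#' nodes.
#'
#' @param net A \code{binary_network}.
#' @return List with \code{mean} and \code{nodal} (length-n vector).
#' @export
local_efficiency <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) < 2) next
    sub <- binary_network(A[nb, nb, drop = FALSE])
    nodal[i] <- global_efficiency(sub)
  }
  names(nodal) <- channel_labels(n)
  list(mean = mean(nodal), nodal = nodal)
}

#' Betweenness centrality
#'
#' For node h, \eqn{B_h = \frac{1}{(n-1)(n-2)} \sum_{i \ne j, i,j \ne h}
#' \sigma_{ij}(h) / \sigma_{ij}} over ordered pairs, with
#' \eqn{\sigma_{ij}} the number of shortest i-j paths and
#' \eqn{\sigma_{ij}(h)} those passing through h; disconnected pairs
#' contribute 0. Computed by Brandes' accumulation. Set
#' \code{ordered = FALSE} for the halved (unordered-pair) convention.
#'
#' @param net A \code{binary_network}.
#' @param ordered Use the ordered-pair normalization (default).
#' @return Named length-n vector.
#' @export
betweenness_centrality <- function(net, ordered = TRUE) {
  A <- net$adjacency
  n <- nrow(A)
  bc <- numeric(n)
  if (n >= 3) {
    nbrs <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
    for (s in seq_len(n)) {
      # Brandes: BFS from s with path counts, then dependency accumulation
      sigma <- numeric(n); sigma[s] <- 1
      dist <- rep(-1L, n); dist[s] <- 0L
      order_visited <- integer(0)
      frontier <- s
      while (length(frontier)) {
        order_visited <- c(order_visited, frontier)
        nxt <- integer(0)
        for (v in frontier) {
          for (w in nbrs[[v]]) {
            if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
            if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
          }
        }
        frontier <- unique(nxt)
      }
      delta <- numeric(n)
      for (w in rev(order_visited)) {
        if (w == s) next
        for (v in nbrs[[w]]) {
          if (dist[v] == dist[w] - 1L && dist[v] >= 0L)
            delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      delta[s] <- 0
      bc <- bc + delta
    }
    # Brandes over all sources counts each ordered (i, j) pair once in each
    # direction, which is exactly the ordered-pair summation.
    bc <- bc / ((n - 1) * (n - 2))
    if (!ordered) bc <- bc / 2
  }
  names(bc) <- channel_labels(n)
  bc
}

#' Degree-preserving randomization of a binary network
#'
#' Maslov-Sneppen double-edge swaps (\code{igraph} \code{keeping_degseq}
#' rewiring), preserving every node's degree; no self-loops or
#' multi-edges. Deterministic given \code{seed}. Graphs with fewer than
#' two edges cannot be swapped and are returned unchanged with attribute
#' \code{"unswappable" = TRUE}.
#'
#' @param net A \code{binary_network}.
#' @param n_swap_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed.
#' @return A rewired \code{binary_network}.
#' @export
rewire_preserving_degree <- function(net, n_swap_per_edge = 10, seed) {
  g <- as_igraph(net)
  m <- igraph::gsize(g)
  if (m < 2) {
    out <- net
    attr(out, "unswappable") <- TRUE
    return(out)
  }
  g2 <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(niter = n_swap_per_edge * m)))
  A <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  binary_network(A, threshold_used = net$threshold_used,
                 thresholding_mode = net$thresholding_mode)
}

#' Small-world coefficients against degree-preserving random nulls
#'
#' Generates \code{n_null} rewired null networks, averages their
#' clustering coefficient (\code{Cran}) and characteristic path length
#' (\code{Lran}), and reports \eqn{\gamma = C_{net}/C_{ran}},
#' \eqn{\lambda = L_{net}/L_{ran}}, \eqn{\sigma = \gamma/\lambda}.
#' \eqn{\sigma \gg 1} indicates small-world organization.
#'
#' @param net A \code{binary_network}.
#' @param n_null Number of null networks (default 100).
#' @param seed Master seed for the null ensemble.
#' @param n_swap_per_edge Swaps per edge per null.
#' @return A \code{small_world_result}: list with \code{gamma},
#'   \code{lambda}, \code{sigma}, \code{Cnet}, \code{Lnet}, \code{Cran},
#'   \code{Lran}, \code{n_null}, \code{null_seed}, \code{defined}.
#' @export
small_worldness <- function(net, n_null = 100, seed, n_swap_per_edge = 10) {
  Cnet <- clustering_coefficient(net)
  Lnet <- char_path_length(net)
  Cr <- numeric(n_null); Lr <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nb <- rewire_preserving_degree(net, n_swap_per_edge,
                                   seed = derive_seed(seed, 7919, b))
    Cr[b] <- clustering_coefficient(nb)
    Lr[b] <- char_path_length(nb)
  }
  Cran <- mean(Cr)
  Lran <- mean(Lr, na.rm = TRUE)
  defined <- is.finite(Cran) && Cran > 0 && is.finite(Lran) && Lran > 0 &&
    is.finite(Lnet) && !is.na(Lnet)
  gamma <- if (defined) Cnet / Cran else NA_real_
  lambda <- if (defined) Lnet / Lran else NA_real_
  sigma <- if (defined) gamma / lambda else NA_real_
  structure(list(gamma = gamma, lambda = lambda, sigma = sigma,
                 Cnet = Cnet, Lnet = Lnet, Cran = Cran, Lran = Lran,
                 n_null = n_null, null_seed = seed, defined = defined),
            class = "small_world_result")
}

#' Graph metrics across a sparsity threshold sweep
#'
#' Density-thresholds the matrix at each T, computes the scalar metrics
#' (clustering, global/local efficiency, characteristic path length) and
#' the nodal vectors (betweenness, nodal local efficiency), and summarizes
#' each metric by its width-normalized area under the curve over T
#' (trapezoid rule; undefined values are excluded with renormalization, so
#' a constant metric keeps its value).
#'
#' @param mat A \code{connectivity_matrix}.
#' @param thresholds Density grid, default 0.1..0.9 by 0.1.
#' @return A \code{graph_metric_profile}: list with \code{thresholds},
#'   \code{scalar} (data frame T x metric), \code{nodal_bc} and
#'   \code{nodal_eloc} (T x channel matrices), and \code{auc} (list with
#'   scalar and nodal entries).
#' @export
metric_sweep <- function(mat, thresholds = seq(0.1, 0.9, by = 0.1)) {
  n_t <- length(thresholds)
  n_ch <- nrow(mat$values)
  scalar <- data.frame(T = thresholds, Cnet = NA_real_, Eglobal = NA_real_,
                       Eloc = NA_real_, Lp = NA_real_)
  nodal_bc <- matrix(NA_real_, n_t, n_ch,
                     dimnames = list(NULL, channel_labels(n_ch)))
  nodal_eloc <- nodal_bc
  for (k in seq_len(n_t)) {
    net <- density_threshold(mat, thresholds[k])
    scalar$Cnet[k] <- clustering_coefficient(net)
    scalar$Eglobal[k] <- global_efficiency(net)
    le <- local_efficiency(net)
    scalar$Eloc[k] <- le$mean
    scalar$Lp[k] <- char_path_length(net)
    nodal_eloc[k, ] <- le$nodal
    nodal_bc[k, ] <- betweenness_centrality(net)
  }
  auc <- list(
    Cnet = trapezoid_mean(thresholds, scalar$Cnet),
    Eglobal = trapezoid_mean(thresholds, scalar$Eglobal),
    Eloc = trapezoid_mean(thresholds, scalar$Eloc),
    Lp = trapezoid_mean(thresholds, scalar$Lp),
    nodal_bc = apply(nodal_bc, 2, function(y) trapezoid_mean(thresholds, y)),
    nodal_eloc = apply(nodal_eloc, 2, function(y) trapezoid_mean(thresholds, y))
  )
  structure(list(thresholds = thresholds, scalar = scalar,
                 nodal_bc = nodal_bc, nodal_eloc = nodal_eloc, auc = auc),
            class = "graph_metric_profile")
}

#' Paired nodal comparison of graph-metric profiles
#'
#' For each channel, compares the per-subject AUC-over-sweep value of a
#' nodal metric (betweenness or nodal local efficiency) between pre and
#' post sessions with a paired t-test; significance is flagged at the
#' uncorrected level \code{alpha} (matching the presentation convention
#' for nodal tables).
#'
#' @param pre_profiles,post_profiles Lists of \code{graph_metric_profile}
#'   objects (one per subject, matched by position).
#' @param metric \code{"betweenness"} or \code{"nodal_eloc"}.
#' @param alpha Uncorrected significance level (default 0.05).
#' @return Data frame with 22 rows: \code{channel}, \code{mean_pre},
#'   \code{mean_post}, \code{t}, \code{p}, \code{significant}.
#' @export
nodal_group_comparison <- function(pre_profiles, post_profiles,
                                   metric = c("betweenness", "nodal_eloc"),
                                   alpha = 0.05) {
  metric <- match.arg(metric)
  field <- if (metric == "betweenness") "nodal_bc" else "nodal_eloc"
  if (length(pre_profiles) != length(post_profiles) || length(pre_profiles) < 2)
    stopf("paired design needs matching profile lists of >= 2 subjects",
          class = "rsfnirs_invalid_input")
  pre <- do.call(rbind, lapply(pre_profiles, function(p) p$auc[[field]]))
  post <- do.call(rbind, lapply(post_profiles, function(p) p$auc[[field]]))
  n_ch <- ncol(pre)
  out <- data.frame(channel = channel_labels(n_ch),
                    mean_pre = colMeans(pre), mean_post = colMeans(post),
                    t = NA_real_, p = NA_real_, significant = FALSE,
                    row.names = NULL)
  for (ch in seq_len(n_ch)) {
    tt <- paired_t(pre[, ch], post[, ch])
    out$t[ch] <- tt$t
    out$p[ch] <- tt$p
    out$significant[ch] <- !tt$degenerate && !is.na(tt$p) && tt$p < alpha
  }
  out
}
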