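# Brute-force oracles for binary-graph metrics, independent of the package
# implementation: exhaustive simple-path enumeration (no BFS, no igraph).

# all simple paths from i to j as lists of vertex sequences
oracle_all_paths <- function(A, i, j) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in which(A[v, ] == 1L)) if (!(w %in% path)) walk(c(path, w))
  }
  walk(i)
  paths
}

# shortest-path length, path count, and per-node through-counts for a pair
oracle_pair <- function(A, i, j) {
  ps <- oracle_all_paths(A, i, j)
  if (length(ps) == 0)
    return(list(d = Inf, count = 0, through = numeric(nrow(A))))
  lens <- vapply(ps, length, integer(1)) - 1L
  d <- min(lens)
  sp <- ps[lens == d]
  through <- numeric(nrow(A))
  for (p in sp) {
    inner <- setdiff(p, c(i, j))
    through[inner] <- through[inner] + 1
  }
  list(d = d, count = length(sp), through = through)
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- oracle_pair(A, i, j)$d
  }
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + A[nb[a], nb[b]]
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && is.finite(D[i, j]))
    tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) >= 2)
      nodal[i] <- oracle_global_eff(A[nb, nb, drop = FALSE])
  }
  list(mean = mean(nodal), nodal = nodal)
}

# ordered-pair betweenness with (n-1)(n-2) normalizer
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  if (n < 3) return(bc)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pr <- oracle_pair(A, i, j)
    if (pr$count > 0) bc <- bc + 2 * pr$through / pr$count  # both orders
  }
  bc / ((n - 1) * (n - 2))
}

# parse the enumerated non-isomorphic graphs (<= 6 nodes) fixture
load_graph_fixture <- function(path = test_path("graphs-upto6.txt")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    n <- as.integer(parts[1])
    A <- matrix(0L, n, n)
    if (n > 1) {
      bits <- as.integer(strsplit(parts[2], "")[[1]])
      pairs <- t(utils::combn(n, 2))
      on <- which(bits == 1L)
      if (length(on)) { A[pairs[on, , drop = FALSE]] <- 1L; A <- A + t(A) }
    }
    A
  })
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- stats::rbinom(length(ut), 1, p)
  A + t(A)
}
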