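# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with R/.

# O(n^3) Lance-Williams agglomeration with classic Ward coefficients on
# unsquared distances; returns the partition after every merge plus the
# merge heights. Ties break on the lowest pair index.
naive_ward_partitions <- function(D) {
  d <- as.matrix(D)
  n <- nrow(d)
  diag(d) <- Inf
  size <- rep(1, n)
  alive <- rep(TRUE, n)
  membership <- lapply(seq_len(n), identity)
  parts <- vector("list", n - 1L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    bmin <- Inf; bi <- NA; bj <- NA
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (d[i, j] < bmin) { bmin <- d[i, j]; bi <- i; bj <- j }
      }
    }
    heights[step] <- bmin
    for (k in idx) {
      if (k == bi || k == bj) next
      d_new <- ((size[bi] + size[k]) * d[bi, k] +
                (size[bj] + size[k]) * d[bj, k] -
                size[k] * d[bi, bj]) / (size[bi] + size[bj] + size[k])
      d[bi, k] <- d[k, bi] <- d_new
    }
    membership[[bi]] <- c(membership[[bi]], membership[[bj]])
    size[bi] <- size[bi] + size[bj]
    alive[bj] <- FALSE
    lab <- integer(n)
    g <- 0L
    for (cc in which(alive)) { g <- g + 1L; lab[membership[[cc]]] <- g }
    parts[[step]] <- lab
  }
  list(partitions = parts, heights = heights)
}

canonical_labels <- function(l) match(l, unique(l))

# Textbook per-point silhouette from a distance matrix.
oracle_silhouette <- function(D, labels) {
  d <- as.matrix(D)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Rank-transform columns, then Pearson: 1 - cor of ranks.
oracle_spearman_dist <- function(m) {
  r <- apply(m, 2L, rank)
  1 - stats::cor(r)
}

# Running-sum weighted KS enrichment score, explicit loop.
oracle_es <- function(stats_sorted, hit_positions) {
  n <- length(stats_sorted)
  inset <- seq_len(n) %in% hit_positions
  nr <- sum(abs(stats_sorted[inset]))
  miss_step <- 1 / (n - sum(inset))
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- if (inset[i]) run + abs(stats_sorted[i]) / nr else run - miss_step
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exhaustive gene-label permutation null for a set of size m on an
# n-long ranked list; returns ES for every placement.
oracle_es_null <- function(stats_sorted, m) {
  combos <- utils::combn(length(stats_sorted), m)
  apply(combos, 2L, function(ix) oracle_es(stats_sorted, ix))
}

# Step-up BH adjustment from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    i <- o[r]
    prev <- min(prev, p[i] * m / r)
    q[i] <- prev
  }
  q
}
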