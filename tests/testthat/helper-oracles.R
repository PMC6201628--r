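# Independent oracles used across the suite. Each deliberately takes the
# slow, literal route (dense algebra, full enumeration, running sums) so it
# shares no code path with the implementation it checks.

# Dense two-step diffusion: (A D^-1)^2 c with the c_i/D_i := 0 convention.
oracle_diffuse2 <- function(adj_dense, x) {
  deg <- rowSums(adj_dense)
  dinv <- ifelse(deg == 0, 0, 1 / deg)
  step <- function(v) as.numeric(adj_dense %*% (v * dinv))
  step(step(x))
}

# Brute-force KS enrichment: sweep every integer position of the ranking and
# track the two empirical-CDF gaps directly.
oracle_es <- function(positions, n) {
  tprime <- length(positions)
  a <- -Inf
  b <- -Inf
  for (x in seq_len(n)) {
    h_at <- sum(positions <= x) / tprime
    h_before <- sum(positions <= (x - 1)) / tprime
    a <- max(a, h_at - x / n)
    b <- max(b, x / n - h_before)
  }
  if (a > b) a else -b
}

oracle_tms <- function(pos_top, pos_bottom, n) {
  (oracle_es(pos_top, n) - oracle_es(pos_bottom, n)) / 2
}

# Exhaustive hypergeometric upper tail P(X >= k): enumerate every n-subset
# of an N-element urn with K marked elements.
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# Small random connected-ish graph as a raw edge list (no package code).
random_edgelist <- function(n, p = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n - 1)) {
    # spanning path guarantees no isolated nodes
    edges <- rbind(edges, c(nodes[i], nodes[i + 1]))
    extra <- which(stats::runif(n - i) < p) + i
    for (j in extra) edges <- rbind(edges, c(nodes[i], nodes[j]))
  }
  edges
}

random_profile <- function(n, id = "p") {
  ranked_profile(sprintf("g%04d", seq_len(n)), stats::rnorm(n), id = id)
}

# Random disjoint top/bottom signature over a profile's gene universe.
random_signature <- function(profile, t, id = "s") {
  genes <- sample(profile$gene, 2 * t)
  extreme_signature_sets(genes[seq_len(t)], genes[(t + 1):(2 * t)], id = id)
}
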