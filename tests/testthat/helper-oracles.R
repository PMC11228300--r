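# Independent oracles and tiny fixtures used across test files. These
# deliberately avoid the package's own code paths.

# closed-form Spearman for tie-free rank vectors
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y); n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# brute-force BH step-up q-values: q_i = min over p_(j) >= p_(i) of
# m * p_(j) / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# all permutations of 1..5 via grid filtering (independent of the
# package's recursive enumerator)
oracle_perms5 <- local({
  g <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  g[apply(g, 1, function(r) length(unique(r)) == 5), , drop = FALSE]
})

# small hand-built ontology for unit tests
toy_ontology <- function(n = 5, volumes = rep(1, n)) {
  region_ontology(data.frame(
    acronym = paste0("R", seq_len(n)),
    name = paste("region", seq_len(n)),
    division = rep("isocortex", n),
    volume_mm3 = volumes))
}

shipped_ontology <- function() load_region_table(default_region_table())
shipped_networks <- function(ont = shipped_ontology())
  load_network_definitions(default_network_definitions(), ont)
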