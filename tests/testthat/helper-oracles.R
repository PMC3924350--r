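# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Exhaustive hypergeometric upper tail: enumerate every K-subset of 1..N and
# count how often its overlap with {1..n} reaches k.
hyperOracleEnum <- function(k, N, K, n) {
  if (K == 0 || n == 0) return(as.numeric(k <= 0))
  subsets <- combn(N, K)
  overlaps <- colSums(subsets <= n)
  mean(overlaps >= k)
}

# Triple-loop topological overlap.
tomOracle <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- 0; kj <- 0
      for (u in seq_len(n)) {
        if (u != i) ki <- ki + a[i, u]
        if (u != j) kj <- kj + a[j, u]
      }
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# Random symmetric adjacency with unit diagonal, entries in [0, 1].
randomAdjacency <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
}

# Small two-group expression fixture with named features/samples.
makeExpr <- function(values, nTreated, nControl, consumption = NULL) {
  v <- as.matrix(values)
  if (is.null(rownames(v))) rownames(v) <- sprintf("f%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  MirExpression(v, c(rep("treated", nTreated), rep("control", nControl)),
                consumption)
}

# Interaction universe from a bare (mirna, gene) edge data.frame.
makeUniverse <- function(mirna, gene, status = "predicted", nTools = 4L) {
  ed <- data.frame(mirna_id = mirna, gene_symbol = gene,
                   status = rep_len(status, length(mirna)),
                   n_tools = rep_len(as.integer(nTools), length(mirna)),
                   stringsAsFactors = FALSE)
  new("InteractionUniverse", edges = ed, minTools = 4L)
}

extdata <- function(name) system.file("extdata", name, package = "miRcoNet")
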