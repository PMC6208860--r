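# Shared fixture builders. All fixtures are generated in code.

# Small expression dataset with explicit values.
make_ds <- function(values, group = NULL, age = NULL, sex = NULL,
                    batch = "d1", background = NULL) {
  n <- ncol(values)
  if (is.null(group)) group <- rep(c("case", "control"), length.out = n)
  if (is.null(age)) age <- seq(60, 60 + 5 * (n - 1), by = 5)
  if (is.null(sex)) sex <- rep_len(c("M", "F"), n)
  meta <- data.frame(group = group, age = age, sex = sex, batch = batch,
                     row.names = colnames(values))
  expression_dataset(values, meta, background = background)
}

rand_mat <- function(n_genes, n_samples, seed = 1, mean = 8, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Independent breadth-first search shortest paths (oracle; no igraph).
bfs_dist <- function(adj, from) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Adjacency list (by node index) from an edge data.frame over node names.
make_adj <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    adj[[a]] <- c(adj[[a]], match(b, nodes))
    adj[[b]] <- c(adj[[b]], match(a, nodes))
  }
  adj
}

# Brute-force mean cross-pair shortest path between two symbol sets.
oracle_set_distance <- function(nodes, edges, setA, setB) {
  adj <- make_adj(nodes, edges)
  dists <- c()
  for (a in intersect(setA, nodes)) {
    d <- bfs_dist(adj, match(a, nodes))
    for (b in intersect(setB, nodes)) {
      val <- d[match(b, nodes)]
      if (is.finite(val)) dists <- c(dists, val)
    }
  }
  if (length(dists)) mean(dists) else NA_real_
}

# Random connected-ish simple graph as an edge data.frame.
random_graph_edges <- function(n_nodes, n_extra, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  # spanning tree then extra random edges
  edges <- data.frame(a = character(), b = character())
  for (i in 2:n_nodes)
    edges <- rbind(edges, data.frame(a = nodes[sample.int(i - 1L, 1L)],
                                     b = nodes[i]))
  for (k in seq_len(n_extra)) {
    ab <- sample(nodes, 2L)
    edges <- rbind(edges, data.frame(a = ab[1L], b = ab[2L]))
  }
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b),
                paste(edges$b, edges$a))
  edges <- edges[!duplicated(key) & edges$a != edges$b, ]
  list(nodes = nodes, edges = edges)
}
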