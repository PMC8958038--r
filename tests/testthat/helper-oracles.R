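# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles deliberately share no code with the package
# internals they check.

library(igraph)

# Undirected path graph with vertex names "1".."n".
path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Erdos-Renyi graph with named vertices.
random_named_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    g
  })
}

# Brute-force crosstalk: scan all edges, count those bridging the sets.
bf_crosstalk <- function(net, A, B) {
  el <- igraph::as_edgelist(net, names = TRUE)
  cnt <- 0L
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if ((a %in% A && b %in% B) || (a %in% B && b %in% A)) cnt <- cnt + 1L
  }
  cnt
}

# Brute-force maximum crosstalk: enumerate all unordered node pairs drawn
# one from each set, dropping self-pairs and double-counted pairs.
bf_max_crosstalk <- function(A, B) {
  A <- unique(A); B <- unique(B)
  seen <- character(0)
  for (a in A) for (b in B) {
    if (a == b) next
    seen <- c(seen, paste(min(a, b), max(a, b)))
  }
  length(unique(seen))
}

# Brute-force AUROC: mean over all (pos, neg) pairs.
bf_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force step-wise AUPR via explicit precision/recall at every
# distinct threshold.
bf_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_recall <- 0
  npos <- sum(labels)
  for (t in ths) {
    pred <- scores >= t
    prec <- sum(pred & labels) / sum(pred)
    rec <- sum(pred & labels) / npos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# Brute-force Benjamini-Hochberg step-up.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Hand-rolled single-source BFS hop distances (queue based), independent of
# igraph's implementation.
bf_bfs <- function(net, source) {
  vn <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, vn), names)
  names(adj) <- vn
  dist <- stats::setNames(rep(Inf, length(vn)), vn)
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Write a tiny edge-list TSV; rows is a list of character vectors.
write_edge_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

# Toy benchmark inputs: 3 drugs x 2 diseases on a small star network, with
# one label of each kind and one overlapping unknown pair.
toy_benchmark_inputs <- function() {
  edges <- list(
    c("t1", "h"), c("t2", "h"), c("t3", "h"), c("x1", "h"), c("x2", "h"),
    c("a1", "h"), c("a2", "h"), c("a3", "h"), c("b1", "h"), c("b2", "h")
  )
  net <- igraph::graph_from_data_frame(
    do.call(rbind, lapply(edges, function(e) data.frame(from = e[1], to = e[2]))),
    directed = FALSE)
  drug_sets <- list(dr1 = c("t1", "t2"), dr2 = c("t3", "a1"), dr3 = c("x1", "x2"))
  disease_sets <- list(dA = c("a1", "a2", "a3"), dB = c("b1", "b2", "a1"))
  labels <- data.frame(
    drug_id = c("dr1", "dr2", "dr3", "dr1", "dr2"),
    disease_id = c("dA", "dA", "dB", "dB", "dB"),
    label = c("approved", "off_label", "clinical_trial", "contraindicated",
              "unknown"),
    stringsAsFactors = FALSE)
  # The 6th pair (dr3, dA) defaults to unknown, no overlap -> the single
  # negative. (dr2, dB) is unknown WITH overlap (a1) -> overlap-excluded.
  # (dr2, dA) is off_label WITH overlap -> retained positive.
  list(net = net, drug_sets = drug_sets, disease_sets = disease_sets,
       labels = labels)
}
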