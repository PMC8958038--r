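# Network substrate: graph model, degree binning, degree-matched sampling,
# topology-preserving randomization, set shortest paths, crosstalk counting.
# Graphs are igraph objects with named vertices, undirected and simple.

.check_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (igraph::is_directed(net)) stop("`net` must be undirected")
  if (is.null(igraph::V(net)$name)) stop("`net` must have named vertices")
  invisible(net)
}

.check_subset <- function(net, nodes, what = "node set") {
  nodes <- unique(as.character(nodes))
  missing <- setdiff(nodes, igraph::V(net)$name)
  if (length(missing) > 0) {
    stop(sprintf("%s contains %d identifier(s) absent from the network (e.g. %s)",
                 what, length(missing), missing[1]))
  }
  nodes
}

#' Shortest hop distances from a set of source nodes
#'
#' Breadth-first (unweighted) distance from every network node to the nearest
#' member of `sources`. Nodes unreachable from all sources are omitted from
#' the result rather than reported as infinite.
#'
#' @param net an undirected igraph network with named vertices.
#' @param sources character vector of source node identifiers (must be
#'   network members).
#' @return named numeric vector of hop counts for every reachable node;
#'   sources themselves map to 0.
#' @export
shortest_path_from_set <- function(net, sources) {
  .check_network(net)
  sources <- .check_subset(net, sources, "sources")
  if (length(sources) == 0) stop("`sources` must be nonempty")
  d <- igraph::distances(net, v = sources, to = igraph::V(net), weights = NA)
  dmin <- apply(d, 2, min)
  dmin[is.finite(dmin)]
}

#' Crosstalk between two node sets
#'
#' The number of distinct network edges with one endpoint in `setA` and the
#' other in `setB`. Sets may overlap; an edge with both endpoints in the
#' intersection is counted once, keeping the count symmetric and consistent
#' with [max_crosstalk()].
#'
#' @param net an undirected igraph network with named vertices.
#' @param setA,setB character vectors of node identifiers (subsets of the
#'   network's node set).
#' @return nonnegative integer edge count.
#' @export
crosstalk_count <- function(net, setA, setB) {
  .check_network(net)
  setA <- .check_subset(net, setA, "setA")
  setB <- .check_subset(net, setB, "setB")
  if (length(setA) == 0 || length(setB) == 0) return(0L)
  el <- igraph::as_edgelist(net, names = TRUE)
  a1 <- el[, 1] %in% setA
  a2 <- el[, 2] %in% setA
  b1 <- el[, 1] %in% setB
  b2 <- el[, 2] %in% setB
  sum((a1 & b2) | (b1 & a2))
}

# Integer-indexed crosstalk used in sampling loops: `el` is the integer
# edgelist, `inB` a logical membership vector over vertex ids.
.crosstalk_int <- function(el, inA, inB) {
  a1 <- inA[el[, 1]]; a2 <- inA[el[, 2]]
  b1 <- inB[el[, 1]]; b2 <- inB[el[, 2]]
  sum((a1 & b2) | (b1 & a2))
}

#' Maximum possible crosstalk between two node sets
#'
#' The number of unordered node pairs that could carry a crosstalk edge:
#' `|A|*|B| - o - o*(o-1)/2` with `o = |A` \eqn{\cap} `B|`. Pairs internal to
#' the intersection are counted once and self-pairs not at all, matching the
#' edge-counting convention of [crosstalk_count()].
#'
#' @param setA,setB character vectors of node identifiers.
#' @return nonnegative integer.
#' @export
max_crosstalk <- function(setA, setB) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  o <- length(intersect(setA, setB))
  as.integer(length(setA) * length(setB) - o - o * (o - 1) / 2)
}

#' Partition network nodes into degree bins
#'
#' Nodes are sorted by (degree, identifier) and chunked into consecutive bins
#' of `bin_size` members, so each bin spans a contiguous degree range. A
#' trailing remainder bin smaller than `bin_size / 2` is merged into the
#' preceding bin to avoid degenerate bins for degree-matched sampling.
#'
#' @param net an undirected igraph network with named vertices.
#' @param bin_size target number of nodes per bin (default 100).
#' @return an object of class `degree_bins`: list with `bin_size`,
#'   `assignment` (named integer vector node -> bin index), `bins` (list of
#'   character vectors) and `degree` (named degree vector).
#' @export
build_degree_bins <- function(net, bin_size = 100) {
  .check_network(net)
  stopifnot(bin_size >= 1)
  deg <- igraph::degree(net)
  n <- length(deg)
  if (bin_size > n) {
    warning(sprintf("bin_size (%d) exceeds node count (%d); using a single bin",
                    bin_size, n))
  }
  ord <- order(deg, names(deg), method = "radix")
  sorted <- names(deg)[ord]

  n_full <- n %/% bin_size
  remainder <- n %% bin_size
  if (n_full == 0) {
    sizes <- n
  } else if (remainder == 0) {
    sizes <- rep(bin_size, n_full)
  } else if (remainder < bin_size / 2) {
    sizes <- rep(bin_size, n_full)
    sizes[n_full] <- sizes[n_full] + remainder
  } else {
    sizes <- c(rep(bin_size, n_full), remainder)
  }
  idx <- rep(seq_along(sizes), times = sizes)
  assignment <- stats::setNames(idx, sorted)
  bins <- split(sorted, idx)
  names(bins) <- NULL
  structure(
    list(bin_size = as.integer(bin_size),
         assignment = assignment[names(deg)],
         bins = bins,
         degree = deg),
    class = "degree_bins"
  )
}

#' @export
print.degree_bins <- function(x, ...) {
  cat(sprintf("degree bins: %d bins of target size %d over %d nodes\n",
              length(x$bins), x$bin_size, length(x$assignment)))
  invisible(x)
}

# Build a closure that draws one degree-matched replicate of `reference_set`
# from the current RNG stream. Bin composition of every draw equals that of
# the reference set; sampling is uniform without replacement within bin.
.make_matched_sampler <- function(bins, reference_set) {
  reference_set <- unique(as.character(reference_set))
  missing <- setdiff(reference_set, names(bins$assignment))
  if (length(missing) > 0) {
    stop(sprintf("reference set has %d member(s) outside the binned node set",
                 length(missing)))
  }
  counts <- table(bins$assignment[reference_set])
  bin_idx <- as.integer(names(counts))
  k <- as.integer(counts)
  members <- bins$bins[bin_idx]
  for (j in seq_along(k)) {
    if (k[j] > length(members[[j]])) {
      stop("bin multiplicity demand exceeds bin size") # unreachable by construction
    }
  }
  function() {
    out <- vector("list", length(k))
    for (j in seq_along(k)) {
      m <- members[[j]]
      out[[j]] <- if (length(m) == 1L) m else sample(m, k[j])
    }
    unlist(out, use.names = FALSE)
  }
}

#' Draw a degree-matched random node set
#'
#' Samples `|reference_set|` distinct nodes such that, within every degree
#' bin, the sample contains exactly as many nodes as the reference set does.
#' This is the permutation null used by the proximity and beta-binomial
#' crosstalk scorers: it preserves both set size and degree distribution.
#'
#' @param net an undirected igraph network with named vertices.
#' @param bins degree bins from [build_degree_bins()].
#' @param reference_set character vector of node identifiers to match.
#' @param seed integer seed (mandatory; sampling is deterministic given it).
#' @return character vector of sampled node identifiers.
#' @export
sample_degree_matched <- function(net, bins, reference_set, seed) {
  .check_network(net)
  reference_set <- .check_subset(net, reference_set, "reference_set")
  seed <- .require_seed(seed)
  sampler <- .make_matched_sampler(bins, reference_set)
  withr::with_seed(seed, sampler())
}

#' Degree-preserving network randomization
#'
#' Randomizes the edge set by repeated double-edge swaps (pick edges
#' \{a,b\}, \{c,d\}; rewire to \{a,d\}, \{c,b\} when this creates neither a
#' self-loop nor a duplicate edge), leaving the degree sequence untouched.
#' `ceiling(swap_factor * |E|)` swaps are attempted; the default of about 10
#' attempts per edge is a standard burn-in for approximate uniformity over
#' degree-fixed simple graphs.
#'
#' @param net an undirected igraph network with at least 2 edges.
#' @param swap_factor attempted swaps per edge (default 10).
#' @param seed integer seed (mandatory).
#' @return a randomized igraph network with identical node set and degree
#'   sequence, no self-loops and no duplicate edges.
#' @export
shuffle_preserving_degree <- function(net, swap_factor = 10, seed) {
  .check_network(net)
  if (igraph::ecount(net) < 2) stop("`net` must have at least 2 edges")
  stopifnot(swap_factor > 0)
  seed <- .require_seed(seed)
  niter <- ceiling(swap_factor * igraph::ecount(net))
  withr::with_seed(
    seed,
    igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
  )
}

#' Generate an ensemble of degree-preserving randomized networks
#'
#' Convenience wrapper producing `n_networks` independent shuffles (used as
#' the shared null ensemble for binomial crosstalk scoring across many
#' drug--disease pairs).
#'
#' @inheritParams shuffle_preserving_degree
#' @param n_networks number of randomized replicates.
#' @return list of igraph networks.
#' @export
randomize_networks <- function(net, n_networks, swap_factor = 10, seed) {
  .check_network(net)
  stopifnot(n_networks >= 1)
  seed <- .require_seed(seed)
  niter <- ceiling(swap_factor * igraph::ecount(net))
  withr::with_seed(seed, {
    lapply(seq_len(n_networks), function(i) {
      igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
    })
  })
}

#' All-pairs hop distance matrix
#'
#' Unweighted shortest-path distances between all node pairs, as a dense
#' named matrix. Proximity scoring over many pairs and permutations reduces
#' to submatrix indexing of this matrix; for the network sizes this package
#' targets (up to a few thousand nodes) the dense matrix is the fastest
#' representation by a wide margin.
#'
#' @param net an undirected igraph network with named vertices.
#' @return numeric matrix with dimnames = node identifiers; `Inf` marks
#'   unreachable pairs.
#' @export
node_distances <- function(net) {
  .check_network(net)
  igraph::distances(net, weights = NA)
}
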