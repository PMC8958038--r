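# Drug-disease association scorers. Each produces a one-row data.frame
# (class association_score) with the raw statistic, its null moments, the
# z-score, and a direction-aware normal-tail p-value.

.new_association_score <- function(method, drug_id, disease_id, raw,
                                   null_mean, null_sd,
                                   n_targets_used = NA_integer_,
                                   p_empirical = NA_real_,
                                   status = "ok") {
  direction <- if (method == "proximity") "lower_is_stronger" else "higher_is_stronger"
  z <- (raw - null_mean) / null_sd
  out <- data.frame(
    method = method,
    drug_id = as.character(drug_id),
    disease_id = as.character(disease_id),
    raw = raw,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    p = z_to_p(z, direction),
    p_empirical = p_empirical,
    q = NA_real_,
    direction = direction,
    n_targets_used = as.integer(n_targets_used),
    status = status,
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_score", "data.frame")
  out
}

.na_association_score <- function(method, drug_id, disease_id, status) {
  out <- .new_association_score(method, drug_id, disease_id,
                                NA_real_, NA_real_, NA_real_,
                                status = status)
  out$p <- NA_real_
  out
}

#' One-sided tail probability for a z-score
#'
#' Standard-normal tail probability in the direction of association: lower
#' tail for distance-like scores (`lower_is_stronger`, proximity), upper
#' tail for crosstalk-like scores.
#'
#' @param z numeric z-score(s).
#' @param direction `"higher_is_stronger"` or `"lower_is_stronger"`.
#' @return probability in \[0,1\].
#' @export
z_to_p <- function(z, direction = c("higher_is_stronger", "lower_is_stronger")) {
  direction <- match.arg(direction)
  if (direction == "lower_is_stronger") pnorm(z) else pnorm(z, lower.tail = FALSE)
}

#' Orient z-scores so that higher always means stronger association
#'
#' Proximity z-scores are sign-flipped (shorter distance = stronger);
#' crosstalk z-scores pass through. Evaluation consumes oriented scores so a
#' single code path serves all methods.
#'
#' @param score an association score data.frame with columns `z` and
#'   `direction`.
#' @return numeric vector of oriented scores.
#' @export
oriented_score <- function(score) {
  stopifnot(is.data.frame(score), all(c("z", "direction") %in% names(score)))
  ifelse(score$direction == "lower_is_stronger", -score$z, score$z)
}

# Proximity -------------------------------------------------------------------

#' Average shortest path from drug targets to the nearest disease gene
#'
#' `d(T,S) = (1/|T|) * sum over t in T of min over s in S of d(t,s)`, with
#' hop-count (unweighted) distances. Targets that cannot reach any disease
#' gene are excluded from the mean with a warning; if no target can reach
#' any disease gene the distance is undefined and an error is raised.
#'
#' @param net an undirected igraph network with named vertices.
#' @param targets,disease_genes nonempty character vectors of node
#'   identifiers.
#' @param dists optional precomputed distance matrix from
#'   [node_distances()]; computed on the fly when `NULL`.
#' @return nonnegative real distance.
#' @export
proximity_distance <- function(net, targets, disease_genes, dists = NULL) {
  .check_network(net)
  targets <- .check_subset(net, targets, "targets")
  disease_genes <- .check_subset(net, disease_genes, "disease_genes")
  if (length(targets) == 0 || length(disease_genes) == 0) {
    stop("`targets` and `disease_genes` must be nonempty")
  }
  dists <- dists %||% node_distances(net)
  m <- dists[targets, disease_genes, drop = FALSE]
  dmin <- apply(m, 1, min)
  reachable <- is.finite(dmin)
  if (!any(reachable)) {
    abort_degenerate("no drug target can reach any disease gene")
  }
  if (!all(reachable)) {
    warning(sprintf("%d target(s) cannot reach any disease gene; excluded from the mean",
                    sum(!reachable)))
  }
  mean(dmin[reachable])
}

# Mean of row minima over a distance submatrix; NA when nothing is finite.
.set_distance <- function(dists, from, to) {
  m <- dists[from, to, drop = FALSE]
  dmin <- apply(m, 1, min)
  fin <- is.finite(dmin)
  if (!any(fin)) return(NA_real_)
  mean(dmin[fin])
}

#' Proximity association score
#'
#' Normalizes the observed target-to-disease distance against a degree-aware
#' permutation null: `n_perm` times, both a target-like and a disease-like
#' set are drawn degree-matched (same size and per-bin composition) and the
#' distance recomputed; `z = (d_obs - mu_R) / sigma_R` with the null mean
#' and standard deviation taken over the permuted distances. Lower distance
#' means stronger association, so the normal-tail p-value is lower-tailed;
#' an empirical permutation p-value (`(#\{d_null <= d_obs\} + 1)/(n_perm + 1)`)
#' is reported alongside.
#'
#' @inheritParams proximity_distance
#' @param bins degree bins from [build_degree_bins()].
#' @param n_perm number of degree-matched permutations (default 1000).
#' @param seed integer seed (mandatory).
#' @param drug_id,disease_id optional identifiers stored in the result.
#' @return one-row `association_score` data.frame.
#' @export
proximity_score <- function(net, targets, disease_genes, bins,
                            n_perm = 1000, seed, dists = NULL,
                            drug_id = NA_character_,
                            disease_id = NA_character_) {
  seed <- .require_seed(seed)
  dists <- dists %||% node_distances(net)
  d_obs <- proximity_distance(net, targets, disease_genes, dists = dists)
  targets <- unique(as.character(targets))
  disease_genes <- unique(as.character(disease_genes))

  d_null <- withr::with_seed(seed, {
    sample_t <- .make_matched_sampler(bins, targets)
    sample_s <- .make_matched_sampler(bins, disease_genes)
    vapply(seq_len(n_perm), function(i) {
      .set_distance(dists, sample_t(), sample_s())
    }, numeric(1))
  })
  ok <- !is.na(d_null)
  mu <- mean(d_null[ok])
  sigma <- sd(d_null[ok])
  if (!is.finite(sigma) || sigma == 0) {
    abort_degenerate(sprintf(
      "degenerate proximity null (sd = 0) for pair (%s, %s)", drug_id, disease_id))
  }
  p_emp <- (sum(d_null[ok] <= d_obs) + 1) / (sum(ok) + 1)
  .new_association_score("proximity", drug_id, disease_id, d_obs, mu, sigma,
                         n_targets_used = length(targets),
                         p_empirical = p_emp)
}

# NEAT ------------------------------------------------------------------------

#' Hypergeometric crosstalk moments
#'
#' Mean and standard deviation of a hypergeometric crosstalk model:
#' `mean = n*K/N` and `sd = sqrt(mean * (N-K)/N * (N-n)/(N-1))`, where `K`
#' and `n` are the sizes of the two draws and `N` the population size. In
#' [neat_score()] these are link-endpoint counts: `K` and `n` are the total
#' degrees of the two node sets and `N = 2|E|` the total number of link
#' endpoints in the network.
#'
#' @param N population size.
#' @param K,n sizes of the two draws, each at most `N`.
#' @return list with elements `mean` and `sd`.
#' @export
crosstalk_hypergeom_moments <- function(N, K, n) {
  stopifnot(N >= 1, K >= 0, n >= 0, K <= N, n <= N)
  mu <- n * K / N
  sigma <- sqrt(mu * (N - K) / N * (N - n) / max(N - 1, 1))
  list(mean = mu, sd = sigma)
}

#' NEAT-style crosstalk association score
#'
#' Analytic crosstalk test: the observed number of links between drug
#' targets and disease genes is compared to a hypergeometric model of link
#' placement. With `K` the total degree of the target set, `n` the total
#' degree of the disease set, and `N = 2|E|` link endpoints in the network,
#' the null mean is `n*K/N` and the sd the hypergeometric standard
#' deviation; `z = (x - mu_H) / sigma_H`. No randomness is involved.
#'
#' @inheritParams proximity_distance
#' @param drug_id,disease_id optional identifiers stored in the result.
#' @return one-row `association_score` data.frame.
#' @export
neat_score <- function(net, targets, disease_genes,
                       drug_id = NA_character_, disease_id = NA_character_) {
  .check_network(net)
  targets <- .check_subset(net, targets, "targets")
  disease_genes <- .check_subset(net, disease_genes, "disease_genes")
  if (length(targets) == 0 || length(disease_genes) == 0) {
    stop("`targets` and `disease_genes` must be nonempty")
  }
  x <- crosstalk_count(net, targets, disease_genes)
  K <- sum(igraph::degree(net, v = targets))
  n <- sum(igraph::degree(net, v = disease_genes))
  N <- 2 * igraph::ecount(net)
  mom <- crosstalk_hypergeom_moments(N, K, n)
  if (mom$sd == 0) {
    abort_degenerate(sprintf(
      "degenerate hypergeometric null (sd = 0) for pair (%s, %s)",
      drug_id, disease_id))
  }
  .new_association_score("neat", drug_id, disease_id, x, mom$mean, mom$sd,
                         n_targets_used = length(targets))
}

# BinoX -----------------------------------------------------------------------

#' BinoX-style crosstalk association score
#'
#' Crosstalk against a binomial null calibrated by network randomization:
#' the network is shuffled `n_random_networks` times with degree-preserving
#' link swaps, the crosstalk `x_i` of the same two sets recomputed on each
#' replicate, and the per-pair success probability estimated as
#' `p_x = mean(x_i) / n_x` with `n_x` the maximum possible crosstalk. Then
#' `z = (x - n_x p_x) / sqrt(n_x p_x (1 - p_x))`.
#'
#' @inheritParams proximity_distance
#' @param n_random_networks number of degree-preserving shuffles (default
#'   100).
#' @param swap_factor attempted swaps per edge in each shuffle.
#' @param seed integer seed (mandatory unless `shuffled` is supplied).
#' @param shuffled optional precomputed list of randomized networks from
#'   [randomize_networks()]; sharing one ensemble across many pairs is both
#'   faster and statistically paired.
#' @param drug_id,disease_id optional identifiers stored in the result.
#' @return one-row `association_score` data.frame.
#' @export
binox_score <- function(net, targets, disease_genes,
                        n_random_networks = 100, swap_factor = 10,
                        seed = NULL, shuffled = NULL,
                        drug_id = NA_character_, disease_id = NA_character_) {
  .check_network(net)
  targets <- .check_subset(net, targets, "targets")
  disease_genes <- .check_subset(net, disease_genes, "disease_genes")
  if (length(targets) == 0 || length(disease_genes) == 0) {
    stop("`targets` and `disease_genes` must be nonempty")
  }
  if (is.null(shuffled)) {
    shuffled <- randomize_networks(net, n_random_networks, swap_factor,
                                   seed = .require_seed(seed))
  }
  x <- crosstalk_count(net, targets, disease_genes)
  nx <- max_crosstalk(targets, disease_genes)
  ids <- match(c(targets, disease_genes), igraph::V(net)$name)
  nv <- igraph::vcount(net)
  inA <- logical(nv); inA[ids[seq_along(targets)]] <- TRUE
  inB <- logical(nv); inB[ids[-seq_along(targets)]] <- TRUE
  xi <- vapply(shuffled, function(g) {
    .crosstalk_int(igraph::as_edgelist(g, names = FALSE), inA, inB)
  }, numeric(1))
  px <- mean(xi) / nx
  if (px <= 0 || px >= 1) {
    abort_degenerate(sprintf(
      "degenerate binomial null (p_x = %g) for pair (%s, %s); consider raising n_random_networks",
      px, drug_id, disease_id))
  }
  .new_association_score("binox", drug_id, disease_id, x,
                         nx * px, sqrt(nx * px * (1 - px)),
                         n_targets_used = length(targets))
}

# ANUBIX ----------------------------------------------------------------------

#' ANUBIX-style crosstalk association score
#'
#' Crosstalk against a beta-binomial null fitted to degree-matched samples:
#' `n_samples` target-like sets are drawn with the same size and per-bin
#' degree composition as the drug targets (the disease set stays fixed),
#' their crosstalk with the disease genes is computed, and a beta-binomial
#' with `n_trials = ` [max_crosstalk()] is fitted by maximum likelihood. The
#' fitted mean and sd normalize the observed crosstalk.
#'
#' @inheritParams proximity_score
#' @param n_samples number of degree-matched samples (default 100).
#' @return one-row `association_score` data.frame; the fitted model is
#'   attached as attribute `betabinom_fit`.
#' @export
anubix_score <- function(net, targets, disease_genes, bins,
                         n_samples = 100, seed,
                         drug_id = NA_character_, disease_id = NA_character_) {
  .check_network(net)
  targets <- .check_subset(net, targets, "targets")
  disease_genes <- .check_subset(net, disease_genes, "disease_genes")
  if (length(targets) == 0 || length(disease_genes) == 0) {
    stop("`targets` and `disease_genes` must be nonempty")
  }
  seed <- .require_seed(seed)
  x <- crosstalk_count(net, targets, disease_genes)
  nx <- max_crosstalk(targets, disease_genes)
  el <- igraph::as_edgelist(net, names = FALSE)
  nv <- igraph::vcount(net)
  vnames <- igraph::V(net)$name
  inB <- logical(nv); inB[match(disease_genes, vnames)] <- TRUE
  xi <- withr::with_seed(seed, {
    sample_t <- .make_matched_sampler(bins, targets)
    vapply(seq_len(n_samples), function(i) {
      inA <- logical(nv); inA[match(sample_t(), vnames)] <- TRUE
      .crosstalk_int(el, inA, inB)
    }, numeric(1))
  })
  # Sampled sets can overlap the disease set differently than the observed
  # targets do, so cap at the reference n_trials.
  xi <- pmin(xi, nx)
  fit <- withCallingHandlers(
    fit_betabinomial(xi, nx),
    warning = function(w) {
      message(sprintf("pair (%s, %s): %s", drug_id, disease_id,
                      conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  if (!is.finite(fit$sd) || fit$sd == 0) {
    abort_degenerate(sprintf(
      "degenerate beta-binomial null (sd = 0) for pair (%s, %s)",
      drug_id, disease_id))
  }
  out <- .new_association_score("anubix", drug_id, disease_id, x,
                                fit$mean, fit$sd,
                                n_targets_used = length(targets))
  attr(out, "betabinom_fit") <- fit
  out
}

# Dispatch used by score_all_pairs and drug_drug_similarity.
.score_pair <- function(method, net, targets, disease_genes, ctx, seed,
                        drug_id = NA_character_, disease_id = NA_character_) {
  switch(method,
    proximity = proximity_score(net, targets, disease_genes, ctx$bins,
                                n_perm = ctx$n_perm, seed = seed,
                                dists = ctx$dists,
                                drug_id = drug_id, disease_id = disease_id),
    neat = neat_score(net, targets, disease_genes,
                      drug_id = drug_id, disease_id = disease_id),
    binox = binox_score(net, targets, disease_genes,
                        shuffled = ctx$shuffled, seed = seed,
                        drug_id = drug_id, disease_id = disease_id),
    anubix = anubix_score(net, targets, disease_genes, ctx$bins,
                          n_samples = ctx$n_samples, seed = seed,
                          drug_id = drug_id, disease_id = disease_id),
    stop(sprintf("unknown method '%s'", method))
  )
}

# Build the per-method shared context (distance matrix, degree bins,
# randomized network ensemble). `seed` is only consumed for binox.
.method_context <- function(method, net, bin_size = 100, n_perm = 1000,
                            n_samples = 100, n_random_networks = 100,
                            swap_factor = 10, seed = NULL) {
  ctx <- list(n_perm = n_perm, n_samples = n_samples)
  if (method == "proximity") {
    ctx$dists <- node_distances(net)
    ctx$bins <- build_degree_bins(net, bin_size)
  } else if (method == "anubix") {
    ctx$bins <- build_degree_bins(net, bin_size)
  } else if (method == "binox") {
    ctx$shuffled <- randomize_networks(net, n_random_networks, swap_factor,
                                       seed = .require_seed(seed))
  }
  ctx
}

# Drug-drug similarity ---------------------------------------------------------

#' Drug--drug similarity score for a candidate drug
#'
#' Scores a candidate drug against every drug already approved for a
#' disease: the method's z-score is computed between the candidate's target
#' set and each approved drug's target set (target sets play both set
#' roles), and the vector is collapsed to `exp(-min(z))` for proximity
#' (small z = short distance = similar) or `max(z)` for the crosstalk
#' methods. With `leave_one_out` (default), approved target sets identical
#' to the candidate's are excluded, so a drug being scored for its own
#' disease is not trivially matched to itself.
#'
#' @param net an undirected igraph network with named vertices.
#' @param candidate_targets character vector, the candidate drug's targets.
#' @param approved_target_sets list of character vectors, target sets of the
#'   drugs approved for the disease.
#' @param method one of `"proximity"`, `"neat"`, `"binox"`, `"anubix"`.
#' @param ctx optional precomputed context from the scoring machinery (as
#'   built internally by [score_all_similarities()]); when `NULL` it is
#'   built from `net` and the `...` parameters.
#' @param seed integer seed (mandatory for stochastic methods).
#' @param leave_one_out exclude approved sets identical to the candidate's
#'   (default `TRUE`).
#' @param ... method parameters passed to the context builder (`bin_size`,
#'   `n_perm`, `n_samples`, `n_random_networks`, `swap_factor`).
#' @return numeric similarity score; the per-reference z vector is attached
#'   as attribute `z_vector`.
#' @export
drug_drug_similarity <- function(net, candidate_targets, approved_target_sets,
                                 method = c("proximity", "neat", "binox", "anubix"),
                                 ctx = NULL, seed = NULL,
                                 leave_one_out = TRUE, ...) {
  method <- match.arg(method)
  stopifnot(length(approved_target_sets) > 0)
  candidate_targets <- unique(as.character(candidate_targets))
  refs <- lapply(approved_target_sets, function(s) unique(as.character(s)))
  if (leave_one_out) {
    refs <- Filter(function(s) !setequal(s, candidate_targets), refs)
  }
  if (length(refs) == 0) {
    stop(proxtalk_error(
      "no approved reference drugs remain after self-exclusion; similarity undefined",
      "proxtalk_undefined_similarity_error"))
  }
  stochastic <- method != "neat"
  if (is.null(ctx)) {
    ctx <- .method_context(method, net, seed = if (method == "binox") seed, ...)
  }
  seeds <- if (stochastic) {
    withr::with_seed(.require_seed(seed), .child_seeds(length(refs)))
  } else {
    rep(NA_integer_, length(refs))
  }
  z <- vapply(seq_along(refs), function(i) {
    .score_pair(method, net, candidate_targets, refs[[i]], ctx,
                seed = seeds[i])$z
  }, numeric(1))
  out <- if (method == "proximity") exp(-min(z)) else max(z)
  attr(out, "z_vector") <- z
  out
}

# All-pairs driver -------------------------------------------------------------

#' Score every drug--disease pair with one method
#'
#' Restricts all target and gene sets to network members (dropping absent
#' identifiers with a reported count), excludes drugs left with no
#' in-network target, and scores every remaining (drug, disease)
#' combination. Pairs whose null is degenerate are emitted with `z = NA`
#' and a reason code in `status` rather than aborting the run. BH-adjusted
#' q-values are filled across all successfully scored pairs.
#'
#' @param net an undirected igraph network with named vertices.
#' @param drugs named list: drug id -> character vector of targets.
#' @param diseases named list: disease id -> character vector of genes.
#' @param method one of `"proximity"`, `"neat"`, `"binox"`, `"anubix"`.
#' @param bin_size degree-bin size for degree-matched sampling.
#' @param n_perm proximity permutations per pair.
#' @param n_samples ANUBIX degree-matched samples per pair.
#' @param n_random_networks BinoX randomized-network ensemble size.
#' @param swap_factor attempted swaps per edge for network randomization.
#' @param seed integer seed (mandatory for stochastic methods).
#' @param verbose report progress every 50 pairs.
#' @return data.frame with one row per scored pair (columns method,
#'   drug_id, disease_id, raw, null_mean, null_sd, z, p, p_empirical, q,
#'   direction, n_targets_used, status); attribute `exclusions` records
#'   dropped drugs/diseases with reasons.
#' @export
score_all_pairs <- function(net, drugs, diseases,
                            method = c("proximity", "neat", "binox", "anubix"),
                            bin_size = 100, n_perm = 1000, n_samples = 100,
                            n_random_networks = 100, swap_factor = 10,
                            seed = NULL, verbose = FALSE) {
  method <- match.arg(method)
  .check_network(net)
  stopifnot(is.list(drugs), !is.null(names(drugs)),
            is.list(diseases), !is.null(names(diseases)))
  nodes <- igraph::V(net)$name

  restrict <- function(sets) lapply(sets, function(s) intersect(unique(s), nodes))
  drugs_net <- restrict(drugs)
  diseases_net <- restrict(diseases)
  dropped_members <- sum(lengths(drugs) - lengths(drugs_net)) +
    sum(lengths(diseases) - lengths(diseases_net))
  if (dropped_members > 0) {
    message(sprintf("dropped %d set member(s) absent from the network",
                    dropped_members))
  }
  excl <- data.frame(id = character(0), type = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  empty_drugs <- names(drugs_net)[lengths(drugs_net) == 0]
  if (length(empty_drugs) > 0) {
    message(sprintf("excluding %d drug(s) with no in-network target",
                    length(empty_drugs)))
    excl <- rbind(excl, data.frame(id = empty_drugs, type = "drug",
                                   reason = "drug_no_targets"))
  }
  empty_dis <- names(diseases_net)[lengths(diseases_net) == 0]
  if (length(empty_dis) > 0) {
    message(sprintf("excluding %d disease(s) with no in-network gene",
                    length(empty_dis)))
    excl <- rbind(excl, data.frame(id = empty_dis, type = "disease",
                                   reason = "disease_no_genes"))
  }
  drugs_net <- drugs_net[lengths(drugs_net) > 0]
  diseases_net <- diseases_net[lengths(diseases_net) > 0]

  stochastic <- method != "neat"
  if (stochastic) seed <- .require_seed(seed)
  ctx <- .method_context(method, net, bin_size = bin_size, n_perm = n_perm,
                         n_samples = n_samples,
                         n_random_networks = n_random_networks,
                         swap_factor = swap_factor,
                         seed = if (method == "binox") seed)

  grid <- expand.grid(drug_id = names(drugs_net),
                      disease_id = names(diseases_net),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seeds <- if (stochastic) {
    withr::with_seed(seed, .child_seeds(nrow(grid)))
  } else {
    rep(NA_integer_, max(nrow(grid), 1L))
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    did <- grid$drug_id[i]; sid <- grid$disease_id[i]
    rows[[i]] <- tryCatch(
      suppressWarnings(
        .score_pair(method, net, drugs_net[[did]], diseases_net[[sid]], ctx,
                    seed = seeds[i], drug_id = did, disease_id = sid)
      ),
      proxtalk_degenerate_null_error = function(e) {
        .na_association_score(method, did, sid, status = "degenerate_null")
      }
    )
    if (verbose && i %% 50 == 0) {
      message(sprintf("scored %d / %d pairs", i, nrow(grid)))
    }
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q[ok] <- bh_correct(out$p[ok])
  attr(out, "exclusions") <- excl
  attr(out, "params") <- list(method = method, bin_size = bin_size,
                              n_perm = n_perm, n_samples = n_samples,
                              n_random_networks = n_random_networks,
                              swap_factor = swap_factor, seed = seed)
  rownames(out) <- NULL
  out
}

#' Score drug--drug similarity for all candidates against each disease
#'
#' For every disease that has at least one approved drug (per
#' `approved_pairs`), scores every candidate drug by its similarity to the
#' disease's approved drugs (see [drug_drug_similarity()]). Candidates whose
#' similarity is undefined after leave-one-out (disease with a single
#' approved drug, candidate identical to it) are emitted with `NA` and
#' status `undefined_similarity`.
#'
#' @inheritParams score_all_pairs
#' @param approved_pairs data.frame with columns `drug_id`, `disease_id`
#'   listing approved (positive) drug--disease pairs.
#' @param leave_one_out passed to [drug_drug_similarity()].
#' @return data.frame with columns method, drug_id, disease_id, similarity,
#'   status.
#' @export
score_all_similarities <- function(net, drugs, diseases, approved_pairs,
                                   method = c("proximity", "neat", "binox", "anubix"),
                                   bin_size = 100, n_perm = 1000,
                                   n_samples = 100, n_random_networks = 100,
                                   swap_factor = 10, seed = NULL,
                                   leave_one_out = TRUE, verbose = FALSE) {
  method <- match.arg(method)
  .check_network(net)
  nodes <- igraph::V(net)$name
  drugs_net <- lapply(drugs, function(s) intersect(unique(s), nodes))
  drugs_net <- drugs_net[lengths(drugs_net) > 0]
  approved_pairs <- approved_pairs[approved_pairs$drug_id %in% names(drugs_net), ]

  stochastic <- method != "neat"
  if (stochastic) seed <- .require_seed(seed)
  ctx <- .method_context(method, net, bin_size = bin_size, n_perm = n_perm,
                         n_samples = n_samples,
                         n_random_networks = n_random_networks,
                         swap_factor = swap_factor,
                         seed = if (method == "binox") seed)

  disease_ids <- intersect(names(diseases), unique(approved_pairs$disease_id))
  grid <- expand.grid(drug_id = names(drugs_net), disease_id = disease_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seeds <- if (stochastic) {
    withr::with_seed(seed, .child_seeds(max(nrow(grid), 1L)))
  } else {
    rep(NA_integer_, max(nrow(grid), 1L))
  }
  sim <- numeric(nrow(grid)); status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sid <- grid$disease_id[i]
    approved <- approved_pairs$drug_id[approved_pairs$disease_id == sid]
    refs <- drugs_net[approved]
    res <- tryCatch(
      suppressWarnings(
        drug_drug_similarity(net, drugs_net[[grid$drug_id[i]]], refs,
                             method = method, ctx = ctx, seed = seeds[i],
                             leave_one_out = leave_one_out)
      ),
      proxtalk_undefined_similarity_error = function(e) NA_real_,
      proxtalk_degenerate_null_error = function(e) NA_real_
    )
    sim[i] <- as.numeric(res)
    status[i] <- if (is.na(sim[i])) "undefined_similarity" else "ok"
    if (verbose && i %% 20 == 0) {
      message(sprintf("similarity: %d / %d candidates", i, nrow(grid)))
    }
  }
  data.frame(method = method, drug_id = grid$drug_id,
             disease_id = grid$disease_id, similarity = sim,
             status = status, stringsAsFactors = FALSE)
}
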