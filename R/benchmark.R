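# Benchmark construction: inclusion filters, label semantics, overlap
# filtering, and time-stamped relabeling of drug-disease pairs.

#' Build a labeled drug--disease benchmark
#'
#' Applies, in order: (1) restriction of drug target sets and disease gene
#' sets to network members; (2) exclusion of drugs with no in-network target
#' and diseases with fewer than `min_disease_genes` in-network genes;
#' (3) label assignment over the full drug x disease grid (pairs absent from
#' `label_table` default to `unknown`): approved and off-label pairs are
#' positives, contraindicated and clinical-trial pairs are excluded,
#' unknown pairs are negatives; (4) exclusion of negatives whose drug
#' targets overlap the disease genes (such pairs are plausibly unverified
#' positives). Positives are never overlap-filtered. Counts at every stage
#' are recorded in the provenance.
#'
#' @param net an undirected igraph network with named vertices.
#' @param drug_sets named list: drug id -> character vector of targets.
#' @param disease_sets named list: disease id -> character vector of genes.
#' @param label_table data.frame with columns drug_id, disease_id, label
#'   (see [read_label_table()]); at most one row per pair.
#' @param min_disease_genes minimum in-network disease genes (default 20).
#' @param removed_to_positive sensitivity flag: treat contraindicated and
#'   clinical-trial pairs as positives instead of excluding them.
#' @param dedup_identical collapse drugs sharing an identical target set
#'   and identical set of positively-labeled diseases, keeping the
#'   lexicographically first id (default off).
#' @return an object of class `benchmark_set`: list with `pairs` (one row
#'   per drug x disease combination), `drugs` and `diseases`
#'   (network-restricted sets of the retained entities), and `provenance`
#'   (filter-stage counts and configuration).
#' @export
build_benchmark <- function(net, drug_sets, disease_sets, label_table,
                            min_disease_genes = 20,
                            removed_to_positive = FALSE,
                            dedup_identical = FALSE) {
  .check_network(net)
  stopifnot(is.list(drug_sets), !is.null(names(drug_sets)),
            is.list(disease_sets), !is.null(names(disease_sets)))
  label_table <- .validate_label_table(label_table)
  nodes <- igraph::V(net)$name

  drugs_net <- lapply(drug_sets, function(s) intersect(unique(s), nodes))
  diseases_net <- lapply(disease_sets, function(s) intersect(unique(s), nodes))

  drug_ok <- lengths(drugs_net) >= 1
  disease_ok <- lengths(diseases_net) >= min_disease_genes

  if (dedup_identical) {
    pos_labels <- c("approved", "off_label")
    keep_ids <- names(drugs_net)[drug_ok]
    sig <- vapply(keep_ids, function(d) {
      ind <- sort(label_table$disease_id[label_table$drug_id == d &
                                           label_table$label %in% pos_labels])
      paste(paste(sort(drugs_net[[d]]), collapse = ","),
            paste(ind, collapse = ","), sep = "|")
    }, character(1))
    first <- !duplicated(sig)
    dropped_dup <- keep_ids[!first]
    drug_ok[dropped_dup] <- FALSE
  } else {
    dropped_dup <- character(0)
  }

  grid <- expand.grid(drug_id = names(drug_sets),
                      disease_id = names(disease_sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d, s) paste(d, s, sep = "\r")
  lab <- stats::setNames(label_table$label,
                         key(label_table$drug_id, label_table$disease_id))
  source_label <- lab[key(grid$drug_id, grid$disease_id)]
  source_label[is.na(source_label)] <- "unknown"

  positive_labels <- c("approved", "off_label")
  removed_labels <- c("clinical_trial", "contraindicated")
  if (removed_to_positive) {
    positive_labels <- c(positive_labels, removed_labels)
    removed_labels <- character(0)
  }

  overlap <- rep(NA, nrow(grid))
  overlap_size <- rep(NA_integer_, nrow(grid))
  binary <- character(nrow(grid))
  reason <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$drug_id[i]; s <- grid$disease_id[i]
    if (!drug_ok[[d]]) {
      binary[i] <- "excluded"; reason[i] <- "drug_no_targets"
      next
    }
    if (!disease_ok[[s]]) {
      binary[i] <- "excluded"; reason[i] <- "disease_too_small"
      next
    }
    ov <- intersect(drugs_net[[d]], diseases_net[[s]])
    overlap[i] <- length(ov) > 0
    overlap_size[i] <- length(ov)
    l <- source_label[i]
    if (l %in% positive_labels) {
      binary[i] <- "positive"
    } else if (l %in% removed_labels) {
      binary[i] <- "excluded"
      reason[i] <- l
    } else if (overlap[i]) {
      binary[i] <- "excluded"; reason[i] <- "overlap_negative"
    } else {
      binary[i] <- "negative"
    }
  }

  pairs <- data.frame(
    drug_id = grid$drug_id, disease_id = grid$disease_id,
    source_label = unname(source_label), binary_label = binary,
    overlap = overlap, overlap_size = overlap_size,
    exclusion_reason = reason, new_positive = FALSE,
    stringsAsFactors = FALSE
  )
  if (sum(pairs$binary_label == "positive") == 0) {
    warning("benchmark contains no positive pairs after filtering")
  }
  if (sum(pairs$binary_label == "negative") == 0) {
    warning("benchmark contains no negative pairs after filtering")
  }

  provenance <- list(
    n_drugs_input = length(drug_sets),
    n_drugs_kept = sum(drug_ok),
    n_drugs_dropped_no_targets = sum(lengths(drugs_net) < 1),
    n_drugs_dropped_duplicate = length(dropped_dup),
    n_diseases_input = length(disease_sets),
    n_diseases_kept = sum(disease_ok),
    n_pairs_total = nrow(pairs),
    n_positive = sum(pairs$binary_label == "positive"),
    n_negative = sum(pairs$binary_label == "negative"),
    n_excluded = sum(pairs$binary_label == "excluded"),
    exclusion_reasons = as.list(table(pairs$exclusion_reason)),
    config = list(min_disease_genes = min_disease_genes,
                  removed_to_positive = removed_to_positive,
                  dedup_identical = dedup_identical)
  )
  structure(
    list(pairs = pairs,
         drugs = drugs_net[names(drugs_net)[drug_ok]],
         diseases = diseases_net[names(diseases_net)[disease_ok]],
         provenance = provenance),
    class = "benchmark_set"
  )
}

.validate_label_table <- function(label_table) {
  stopifnot(is.data.frame(label_table),
            all(c("drug_id", "disease_id", "label") %in% names(label_table)))
  bad <- which(!label_table$label %in% .benchmark_label_levels)
  if (length(bad) > 0) {
    stop(sprintf("unknown label '%s' at label table row %d",
                 label_table$label[bad[1]], bad[1]))
  }
  k <- paste(label_table$drug_id, label_table$disease_id)
  if (anyDuplicated(k)) {
    stop(sprintf("duplicate label table row for pair (%s)",
                 k[duplicated(k)][1]))
  }
  label_table
}

#' @export
print.benchmark_set <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "benchmark: %d drugs x %d diseases = %d pairs (%d positive, %d negative, %d excluded)\n",
    p$n_drugs_kept, p$n_diseases_kept, p$n_pairs_total,
    p$n_positive, p$n_negative, p$n_excluded))
  invisible(x)
}

#' Relabel pairs that have become positive (time-stamped benchmark)
#'
#' Pairs listed in `new_positive_table` that are currently negative are
#' relabeled positive (source label set to approved) and flagged
#' `new_positive`; pairs already positive are left unchanged with a notice.
#' Listing a pair that is absent from the benchmark, or one that was
#' excluded, is an error.
#'
#' @param benchmark a `benchmark_set` from [build_benchmark()].
#' @param new_positive_table data.frame with columns drug_id, disease_id.
#' @return the updated `benchmark_set` with provenance extended.
#' @export
apply_time_stamp <- function(benchmark, new_positive_table) {
  stopifnot(inherits(benchmark, "benchmark_set"),
            all(c("drug_id", "disease_id") %in% names(new_positive_table)))
  pairs <- benchmark$pairs
  key <- paste(pairs$drug_id, pairs$disease_id, sep = "\r")
  want <- paste(new_positive_table$drug_id, new_positive_table$disease_id,
                sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop(sprintf("pair (%s, %s) listed as new positive is absent from the benchmark",
                 new_positive_table$drug_id[i], new_positive_table$disease_id[i]))
  }
  excluded <- pairs$binary_label[idx] == "excluded"
  if (any(excluded)) {
    i <- which(excluded)[1]
    stop(sprintf("pair (%s, %s) was excluded (%s) and cannot be relabeled",
                 new_positive_table$drug_id[i], new_positive_table$disease_id[i],
                 pairs$exclusion_reason[idx[i]]))
  }
  already <- pairs$binary_label[idx] == "positive"
  if (any(already)) {
    message(sprintf("%d listed pair(s) already positive; left unchanged",
                    sum(already)))
  }
  flip <- idx[!already]
  pairs$binary_label[flip] <- "positive"
  pairs$source_label[flip] <- "approved"
  pairs$new_positive[flip] <- TRUE
  benchmark$pairs <- pairs
  benchmark$provenance$n_new_positives <- length(flip)
  benchmark$provenance$n_positive <- sum(pairs$binary_label == "positive")
  benchmark$provenance$n_negative <- sum(pairs$binary_label == "negative")
  benchmark
}

#' Target--gene overlap flags for all drug--disease combinations
#'
#' Overlap between each drug's in-network targets and each disease's
#' in-network genes. The enrichment of overlap among positive pairs relative
#' to negatives motivates the overlap filter in [build_benchmark()].
#'
#' @inheritParams build_benchmark
#' @return data.frame with columns drug_id, disease_id, overlap (logical),
#'   overlap_size (integer).
#' @export
overlap_flags <- function(net, drug_sets, disease_sets) {
  .check_network(net)
  nodes <- igraph::V(net)$name
  drugs_net <- lapply(drug_sets, function(s) intersect(unique(s), nodes))
  diseases_net <- lapply(disease_sets, function(s) intersect(unique(s), nodes))
  grid <- expand.grid(drug_id = names(drug_sets),
                      disease_id = names(disease_sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  size <- mapply(function(d, s) {
    length(intersect(drugs_net[[d]], diseases_net[[s]]))
  }, grid$drug_id, grid$disease_id, USE.NAMES = FALSE)
  data.frame(drug_id = grid$drug_id, disease_id = grid$disease_id,
             overlap = size > 0, overlap_size = as.integer(size),
             stringsAsFactors = FALSE)
}

#' Export a benchmark as TSV plus a provenance sidecar
#'
#' Writes `<prefix>_pairs.tsv` (the labeled pair table) and
#' `<prefix>_provenance.json`.
#'
#' @param benchmark a `benchmark_set`.
#' @param prefix output path prefix.
#' @export
write_benchmark <- function(benchmark, prefix) {
  stopifnot(inherits(benchmark, "benchmark_set"))
  pairs_path <- paste0(prefix, "_pairs.tsv")
  write.table(benchmark$pairs, pairs_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(benchmark$provenance,
                       paste0(prefix, "_provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(pairs_path)
}
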