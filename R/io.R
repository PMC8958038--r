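# File ingestion and export: TSV edge lists, GMT gene sets, label tables,
# score tables. Dialect: tab-separated, UTF-8, '#'-prefixed comments ignored.

.read_data_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Load an undirected network from a TSV edge list
#'
#' Reads a tab-separated edge list with columns `nodeA`, `nodeB` and an
#' optional third `confidence` column in \[0,1\]. A header line is detected
#' by a non-numeric third field and skipped; `#`-prefixed comment lines are
#' ignored. Edges with confidence below `confidence_threshold` are dropped
#' (all edges kept when no confidence column is present), self-loop rows are
#' dropped with a reported count, and duplicate rows (including reversed
#' duplicates) are collapsed so the result is a simple undirected graph.
#'
#' @param path path to the edge list file.
#' @param confidence_threshold minimum confidence for an edge to be kept
#'   (default 0.8, the conventional high-confidence cutoff for functional
#'   association networks).
#' @param keep_largest_component if `TRUE`, restrict the result to its
#'   largest connected component (default `FALSE`).
#' @return an undirected simple igraph network; edge attribute `confidence`
#'   is set when the file provides one.
#' @export
load_network <- function(path, confidence_threshold = 0.8,
                         keep_largest_component = FALSE) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1)
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0) {
    stop(proxtalk_error(sprintf("no data rows in '%s'", path),
                        "proxtalk_empty_network_error"))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "malformed row at line %d of '%s': expected 2-3 tab-separated fields, got %d",
      dat$lineno[bad[1]], path, nf[bad[1]]))
  }
  # Header detection: a 3-column first row whose third field is non-numeric,
  # or the canonical 2-column header written by write_network().
  if ((nf[1] == 3 &&
       is.na(suppressWarnings(as.numeric(fields[[1]][3])))) ||
      (nf[1] == 2 &&
       identical(tolower(fields[[1]]), c("nodea", "nodeb")))) {
    fields <- fields[-1]
    nf <- nf[-1]
    dat$lineno <- dat$lineno[-1]
    if (length(fields) == 0) {
      stop(proxtalk_error(sprintf("no data rows in '%s'", path),
                          "proxtalk_empty_network_error"))
    }
  }
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  conf <- rep(NA_real_, length(fields))
  has_conf <- nf == 3
  if (any(has_conf)) {
    raw <- vapply(fields[has_conf], `[[`, character(1), 3)
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      i <- which(has_conf)[which(is.na(num))[1]]
      abort_parse(sprintf("non-numeric confidence at line %d of '%s'",
                          dat$lineno[i], path))
    }
    conf[has_conf] <- num
  }

  loops <- a == b
  if (any(loops)) {
    message(sprintf("dropped %d self-loop row(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]; conf <- conf[!loops]
  }
  pass <- is.na(conf) | conf >= confidence_threshold
  a <- a[pass]; b <- b[pass]; conf <- conf[pass]

  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("collapsed %d duplicate edge row(s)", sum(dup)))
    a <- a[!dup]; b <- b[!dup]; conf <- conf[!dup]
  }
  if (length(a) == 0) {
    stop(proxtalk_error(
      sprintf("no edges remain after applying confidence threshold %.3g",
              confidence_threshold),
      "proxtalk_empty_network_error"))
  }
  net <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE)
  if (!all(is.na(conf))) igraph::E(net)$confidence <- conf
  if (keep_largest_component) {
    comp <- igraph::components(net)
    giant <- which.max(comp$csize)
    net <- igraph::induced_subgraph(net, which(comp$membership == giant))
  }
  net
}

#' Write a network as a TSV edge list
#'
#' @param net igraph network.
#' @param path output path. Writes `nodeA`, `nodeB` and, when present, the
#'   `confidence` edge attribute.
#' @export
write_network <- function(net, path) {
  .check_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(nodeA = el[, 1], nodeB = el[, 2], stringsAsFactors = FALSE)
  conf <- igraph::edge_attr(net, "confidence")
  if (!is.null(conf)) df$confidence <- conf
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> member1 <TAB> ...`.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; the `description` attribute
#'   holds the per-set description column.
#' @export
read_gmt <- function(path) {
  dat <- .read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "malformed GMT row at line %d of '%s': need id, description and >=1 member",
      dat$lineno[bad[1]], path))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort_parse(sprintf("duplicate set id '%s' in '%s'",
                        ids[duplicated(ids)][1], path))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), ids)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions
#'   (defaults to the set id).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- description %||% attr(sets, "description") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.benchmark_label_levels <- c("approved", "off_label", "clinical_trial",
                             "contraindicated", "unknown")

#' Read a drug--disease label table
#'
#' TSV with columns `drug_id`, `disease_id`, `label`; label must be one of
#' approved, off_label, clinical_trial, contraindicated, unknown.
#'
#' @param path path to the TSV file (header required).
#' @return data.frame with character columns drug_id, disease_id, label.
#' @export
read_label_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  need <- c("drug_id", "disease_id", "label")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("label table '%s' must have columns %s",
                        path, paste(need, collapse = ", ")))
  }
  bad <- which(!df$label %in% .benchmark_label_levels)
  if (length(bad) > 0) {
    abort_parse(sprintf("unknown label '%s' at data row %d of '%s'",
                        df$label[bad[1]], bad[1], path))
  }
  df[need]
}

#' Read a two-column drug--disease pair table
#'
#' TSV with columns `drug_id`, `disease_id` (e.g. time-stamped new
#' positives).
#'
#' @param path path to the TSV file (header required).
#' @return data.frame with character columns drug_id, disease_id.
#' @export
read_pair_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  need <- c("drug_id", "disease_id")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("pair table '%s' must have columns %s",
                        path, paste(need, collapse = ", ")))
  }
  df[need]
}

#' Write an association score table as TSV
#'
#' @param scores data.frame of association scores ([score_all_pairs()]).
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association score table written by [write_scores()]
#'
#' @param path path to the TSV file.
#' @return data.frame of association scores.
#' @export
read_scores <- function(path) {
  read.delim(path, header = TRUE, sep = "\t",
             colClasses = c(method = "character", drug_id = "character",
                            disease_id = "character", direction = "character",
                            status = "character"))
}
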