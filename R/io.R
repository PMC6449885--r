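# Readers and writers for the plain-text interchange formats: 2-column TSV
# pair tables (optional single header line), miRBase-style GFF3 coordinates,
# and MeSH-style tree-number tables.

pair_header_vocab <- c(
  "mirna", "mir", "mirna_id", "disease", "disease_id", "disease_name",
  "source", "source_id", "target", "target_id", "gene", "gene_id", "mrna",
  "family", "family_id", "tree_number", "treenumber", "tree", "from", "to",
  "id", "name"
)

# Parse a 2-column tab-delimited file. Errors name the offending line.
read_pair_file <- function(path, col_names, allow_empty = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  idx <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  empty_result <- function() {
    out <- tibble::tibble(a = character(), b = character())
    names(out) <- col_names
    out
  }
  if (length(idx) == 0) {
    if (allow_empty) return(empty_result())
    stop("empty input file: ", path, call. = FALSE)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]]))
  if (length(first) == 2 && all(first %in% pair_header_vocab)) {
    fields <- fields[-1]
    idx <- idx[-1]
    if (length(fields) == 0) {
      if (allow_empty) return(empty_result())
      stop("empty input file (header only): ", path, call. = FALSE)
    }
  }
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated columns, found %d",
                 idx[bad], path, nf[bad]), call. = FALSE)
  }
  out <- tibble::tibble(
    a = trimws(vapply(fields, `[[`, character(1), 1L)),
    b = trimws(vapply(fields, `[[`, character(1), 2L))
  )
  names(out) <- col_names
  out
}

dedup_pairs <- function(df, what) {
  key <- paste(df[[1]], df[[2]], sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    warning(sum(dup), " duplicated ", what, " pair(s) removed", call. = FALSE)
  df[!dup, , drop = FALSE]
}

#' Read a miRNA-disease association table
#'
#' Parses a 2-column tab-delimited file of experimentally verified
#' miRNA-disease pairs (optional header). Identifiers are kept verbatim
#' (case-sensitive) in order of first appearance; duplicated pairs are
#' collapsed with a warning.
#'
#' @param path path to a TSV file with columns (miRNA id, disease id).
#' @return A tibble with columns `mirna` and `disease`, one row per unique
#'   association. Convert to the binary matrix with [as_assoc_matrix()].
#' @seealso [dataset_stats()], [mda_fit()]
#' @export
read_associations <- function(path) {
  dedup_pairs(read_pair_file(path, c("mirna", "disease")), "miRNA-disease association")
}

#' Read a bipartite interaction table
#'
#' Reads miRNA-mRNA (or disease-gene) interaction pairs from a 2-column TSV.
#' Duplicated pairs are removed with a warning; occurrence counts used by the
#' entropy kernel are always computed over the deduplicated set (see
#' [interaction_summary()]).
#'
#' @param path path to a TSV file with columns (source id, target id).
#' @return A tibble with columns `source` and `target`.
#' @export
read_interactions <- function(path) {
  dedup_pairs(read_pair_file(path, c("source", "target")), "interaction")
}

#' Summarise an interaction table
#'
#' @param pairs a two-column data frame of (source, target) pairs; duplicates
#'   are ignored.
#' @return A list with `n_interactions` (total unique pair count N) and
#'   `target_counts`, a tibble of per-target occurrence counts n(t) across all
#'   sources.
#' @examples
#' interaction_summary(toy10_bundle()$mirna_targets)
#' @export
interaction_summary <- function(pairs) {
  prof <- interaction_profile(pairs)
  counts <- tibble::tibble(target = names(prof$counts), n = as.integer(prof$counts))
  list(n_interactions = prof$n, target_counts = counts)
}

#' Read miRNA family assignments
#'
#' @param path path to a TSV file with columns (miRNA id, family id). An empty
#'   file is valid and denotes "no family information".
#' @return A tibble with columns `mirna` and `family`. A miRNA assigned to two
#'   different families raises an error.
#' @seealso [family_matrix()]
#' @export
read_family <- function(path) {
  df <- read_pair_file(path, c("mirna", "family"), allow_empty = TRUE)
  df <- df[!duplicated(paste(df$mirna, df$family, sep = "\r")), , drop = FALSE]
  multi <- unique(df$mirna[duplicated(df$mirna)])
  if (length(multi))
    stop("miRNA(s) assigned to more than one family: ",
         paste(head(multi, 5), collapse = ", "), call. = FALSE)
  df
}

#' Read miRNA genomic coordinates from a GFF3 file
#'
#' Imports miRBase-style GFF3 and keeps records of type `miRNA`. The miRNA
#' identifier is taken from the `Name` attribute, falling back to `ID`;
#' records carrying neither are skipped with a warning. If an identifier
#' occurs on several lines the first record wins (with a warning).
#'
#' @param path path to a GFF3 file.
#' @return A tibble with columns `mirna`, `chrom`, `start`, `end` (1-based,
#'   inclusive) and `strand`.
#' @seealso [cluster_matrix()]
#' @export
read_coordinates <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if ("type" %in% names(df)) df <- df[as.character(df$type) == "miRNA", , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no miRNA records found in ", path, call. = FALSE)
    return(tibble::tibble(mirna = character(), chrom = character(),
                          start = integer(), end = integer(), strand = character()))
  }
  nm <- if ("Name" %in% names(df)) as.character(df$Name) else rep(NA_character_, nrow(df))
  id <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  nm[is.na(nm) | !nzchar(nm)] <- id[is.na(nm) | !nzchar(nm)]
  drop <- is.na(nm) | !nzchar(nm)
  if (any(drop)) {
    warning(sum(drop), " record(s) without Name/ID attribute skipped", call. = FALSE)
    df <- df[!drop, , drop = FALSE]; nm <- nm[!drop]
  }
  dup <- duplicated(nm)
  if (any(dup)) {
    warning(sum(dup), " duplicate coordinate record(s) ignored (first kept)", call. = FALSE)
    df <- df[!dup, , drop = FALSE]; nm <- nm[!dup]
  }
  if (any(df$start > df$end)) stop("coordinate record with start > end", call. = FALSE)
  tibble::tibble(
    mirna = nm,
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
}

#' Read disease MeSH tree numbers
#'
#' @param path path to a TSV file with columns (disease name, tree number). A
#'   disease may have several rows, one per tree number.
#' @return A tibble with columns `disease` and `tree_number`. Tree numbers
#'   with empty dot-separated segments raise a parse error.
#' @seealso [disease_dag()], [semantic_similarity()]
#' @export
read_mesh_tree <- function(path) {
  df <- read_pair_file(path, c("disease", "tree_number"))
  segs <- strsplit(df$tree_number, ".", fixed = TRUE)
  bad <- vapply(segs, function(s) length(s) == 0 || any(!nzchar(trimws(s))), logical(1))
  bad <- bad | endsWith(df$tree_number, ".") | startsWith(df$tree_number, ".")
  if (any(bad))
    stop("malformed tree number: '", df$tree_number[which(bad)[1]], "'", call. = FALSE)
  df[!duplicated(paste(df$disease, df$tree_number, sep = "\r")), , drop = FALSE]
}

#' Global characteristics of an association network
#'
#' Computes the number of associations, entities, and the average (rounded to
#' two decimals), maximum and minimum degrees on each side of the bipartite
#' miRNA-disease network.
#'
#' @param associations a tibble of (mirna, disease) pairs or a binary
#'   association matrix.
#' @return A one-row tibble of summary statistics.
#' @examples
#' dataset_stats(toy10_bundle()$associations)
#' @export
dataset_stats <- function(associations) {
  m <- as_assoc_matrix(associations)
  if (sum(m) == 0) stop("association matrix has no associations", call. = FALSE)
  rd <- rowSums(m); cd <- colSums(m)
  tibble::tibble(
    n_associations = as.integer(sum(m)),
    n_mirnas = nrow(m),
    n_diseases = ncol(m),
    avg_mirna_degree = round(mean(rd), 2),
    max_mirna_degree = as.integer(max(rd)),
    min_mirna_degree = as.integer(min(rd)),
    avg_disease_degree = round(mean(cd), 2),
    max_disease_degree = as.integer(max(cd)),
    min_disease_degree = as.integer(min(cd))
  )
}

unknown_disease_error <- function(disease, known) {
  near <- tryCatch(
    agrep(disease, known, max.distance = 0.3, ignore.case = TRUE, value = TRUE),
    error = function(e) character()
  )
  stop("unknown disease '", disease, "'",
       if (length(near)) paste0("; close matches: ", paste(head(near, 5), collapse = ", ")),
       call. = FALSE)
}

#' Rank candidate miRNAs for a disease
#'
#' Returns the top-scoring miRNAs that are *not* already known to be
#' associated with the disease, ordered by descending prediction score with
#' ties broken by miRNA input order.
#'
#' @param fit an [mda_fit()] object.
#' @param disease a disease identifier (column of the association matrix).
#' @param top_k maximum number of candidates to return.
#' @return A tibble with columns `rank`, `mirna`, `score`.
#' @export
rank_candidates <- function(fit, disease, top_k = 50) {
  stopifnot(inherits(fit, "mda_fit"))
  ds <- colnames(fit$assoc)
  if (!disease %in% ds) unknown_disease_error(disease, ds)
  sc <- fit$scores[, disease]
  cand <- which(fit$assoc[, disease] == 0)
  ord <- cand[order(-sc[cand], cand)]
  ord <- head(ord, top_k)
  tibble::tibble(rank = seq_along(ord),
                 mirna = rownames(fit$assoc)[ord],
                 score = unname(sc[ord]))
}

#' Write a per-disease candidate ranking to TSV
#'
#' @inheritParams rank_candidates
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_rankings <- function(fit, disease, top_k = 50, path) {
  readr::write_tsv(rank_candidates(fit, disease, top_k), path)
  invisible(path)
}
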