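# Core containers: binary association / relation matrices and named
# similarity matrices with a role tag.

#' Build the binary association matrix
#'
#' @param x a tibble of (mirna, disease) pairs, or an already-built binary
#'   matrix with dimnames (validated and returned unchanged).
#' @return A binary matrix with miRNAs as rows and diseases as columns, in
#'   order of first appearance.
#' @export
as_assoc_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("association matrix must carry row and column names", call. = FALSE)
    if (!all(x %in% c(0, 1)))
      stop("association matrix entries must be 0 or 1", call. = FALSE)
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  mir <- as.character(x[[1]]); dis <- as.character(x[[2]])
  mirnas <- unique(mir); diseases <- unique(dis)
  m <- matrix(0, length(mirnas), length(diseases), dimnames = list(mirnas, diseases))
  m[cbind(match(mir, mirnas), match(dis, diseases))] <- 1
  m
}

zero_mat <- function(ids) {
  matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
}

#' Build the miRNA family co-membership matrix
#'
#' `FAM(i, j) = 1` exactly when `i != j` and both miRNAs are assigned to the
#' same family. The diagonal is forced to zero: the relation is defined for
#' pairs only, and a self-pair would double self-similarity in the family
#' boost. miRNAs absent from the family table belong to no family.
#'
#' @param family a tibble of (mirna, family) assignments, e.g. from
#'   [read_family()], or `NULL` for "no family information".
#' @param mirna_ids ordered character vector of miRNA identifiers defining
#'   the matrix. Assignments for miRNAs outside this set are ignored with a
#'   warning.
#' @return A symmetric binary matrix over `mirna_ids` with zero diagonal.
#' @export
family_matrix <- function(family, mirna_ids) {
  fam <- zero_mat(mirna_ids)
  if (is.null(family) || nrow(family) == 0) return(fam)
  mir <- as.character(family[[1]]); fid <- as.character(family[[2]])
  df <- unique(data.frame(mir, fid, stringsAsFactors = FALSE))
  multi <- unique(df$mir[duplicated(df$mir)])
  if (length(multi))
    stop("miRNA(s) assigned to more than one family: ",
         paste(head(multi, 5), collapse = ", "), call. = FALSE)
  outside <- setdiff(df$mir, mirna_ids)
  if (length(outside))
    warning(length(outside), " family assignment(s) for unknown miRNA(s) ignored",
            call. = FALSE)
  df <- df[df$mir %in% mirna_ids, , drop = FALSE]
  for (f in unique(df$fid)) {
    members <- df$mir[df$fid == f]
    if (length(members) >= 2) {
      fam[members, members] <- 1
    }
  }
  diag(fam) <- 0
  fam
}

#' Build the genomic-cluster co-membership matrix
#'
#' Two miRNAs are clustered when they lie on the same chromosome and the gap
#' between their genomic intervals, `max(0, max(start_i, start_j) -
#' min(end_i, end_j))`, is strictly below the threshold (overlapping
#' intervals have gap 0). Strand is ignored and the relation is pairwise: no
#' transitive closure is applied. miRNAs without coordinates get all-zero
#' rows.
#'
#' @param coordinates a tibble of genomic records as returned by
#'   [read_coordinates()].
#' @param mirna_ids ordered character vector of miRNA identifiers defining
#'   the matrix.
#' @param threshold_bp maximum gap in base pairs (default 20 kb).
#' @return A symmetric binary matrix over `mirna_ids` with zero diagonal.
#' @export
cluster_matrix <- function(coordinates, mirna_ids, threshold_bp = 20000) {
  if (!(is.numeric(threshold_bp) && threshold_bp > 0))
    stop("threshold_bp must be positive", call. = FALSE)
  clu <- zero_mat(mirna_ids)
  if (is.null(coordinates) || nrow(coordinates) == 0) return(clu)
  if (any(coordinates$start > coordinates$end))
    stop("coordinate record with start > end", call. = FALSE)
  co <- coordinates[coordinates$mirna %in% mirna_ids, , drop = FALSE]
  co <- co[!duplicated(co$mirna), , drop = FALSE]
  n <- nrow(co)
  if (n < 2) return(clu)
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      if (co$chrom[a] != co$chrom[b]) next
      gap <- max(0, max(co$start[a], co$start[b]) - min(co$end[a], co$end[b]))
      if (gap < threshold_bp) {
        clu[co$mirna[a], co$mirna[b]] <- 1
        clu[co$mirna[b], co$mirna[a]] <- 1
      }
    }
  }
  clu
}

# --- similarity matrix container ------------------------------------------

new_sim <- function(values, role) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, role = role, class = c("mda_sim", class(values)))
}

sim_values <- function(x) {
  y <- unclass(x)
  attr(y, "role") <- NULL
  y
}

sim_role <- function(x) attr(x, "role") %||% "similarity"

#' @export
print.mda_sim <- function(x, ...) {
  cat(sprintf("<%s similarity matrix: %d x %d>\n", sim_role(x), nrow(x), ncol(x)))
  print(sim_values(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Tidy a similarity matrix into long format
#'
#' @param x an `mda_sim` similarity matrix.
#' @param ... unused.
#' @return A tibble with columns `item1`, `item2`, `similarity`, `role`.
#' @export
tidy.mda_sim <- function(x, ...) {
  v <- sim_values(x)
  tibble::tibble(
    item1 = rownames(v)[row(v)[upper.tri(v, diag = TRUE)]],
    item2 = colnames(v)[col(v)[upper.tri(v, diag = TRUE)]],
    similarity = v[upper.tri(v, diag = TRUE)],
    role = sim_role(x)
  )
}

#' Heatmap of a similarity matrix
#'
#' @param object an `mda_sim` similarity matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mda_sim <- function(object, ...) {
  v <- sim_values(object)
  df <- tibble::tibble(
    item1 = factor(rownames(v)[row(v)], levels = rownames(v)),
    item2 = factor(colnames(v)[col(v)], levels = colnames(v)),
    similarity = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$item2, .data$item1, fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(1, v))) +
    ggplot2::labs(x = NULL, y = NULL, fill = sim_role(object)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
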