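# Disease semantic similarity from MeSH tree numbers, Wang-style: each
# ancestor of a disease contributes a weight that decays by a factor delta
# per DAG edge, taking the maximum over paths; the semantic value DV is the
# sum of contributions. Similarity of two diseases compares the
# contributions of their shared ancestors.

#' Build a disease DAG from MeSH tree numbers
#'
#' Tree numbers are dot-separated: the parent of `"a.b.c"` is `"a.b"`. An
#' edge links a disease to the disease owning its parent tree number; a
#' disease whose parent tree number is owned by nobody is a root. A disease
#' with several tree numbers has the union of the implied parents.
#'
#' @param mesh a tibble of (disease, tree_number) rows, e.g. from
#'   [read_mesh_tree()].
#' @return An object of class `disease_dag` with elements `nodes`, `parents`
#'   (named list of parent-id character vectors) and `tree` (the input
#'   table).
#' @export
disease_dag <- function(mesh) {
  stopifnot(is.data.frame(mesh), ncol(mesh) >= 2)
  d <- as.character(mesh[[1]])
  tn <- as.character(mesh[[2]])
  segs <- strsplit(tn, ".", fixed = TRUE)
  bad <- vapply(segs, function(s) length(s) == 0 || any(!nzchar(trimws(s))), logical(1))
  bad <- bad | endsWith(tn, ".") | startsWith(tn, ".")
  if (any(bad))
    stop("malformed tree number: '", tn[which(bad)[1]], "'", call. = FALSE)
  keep <- !duplicated(paste(d, tn, sep = "\r"))
  d <- d[keep]; tn <- tn[keep]; segs <- segs[keep]
  if (anyDuplicated(tn)) {
    i <- which(duplicated(tn))[1]
    stop("tree number '", tn[i], "' assigned to multiple diseases", call. = FALSE)
  }
  owner <- setNames(d, tn)
  nodes <- unique(d)
  parents <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_along(tn)) {
    s <- segs[[r]]
    if (length(s) < 2) next
    ptn <- paste(s[-length(s)], collapse = ".")
    if (ptn %in% names(owner)) {
      p <- unname(owner[[ptn]])
      if (p != d[r]) parents[[d[r]]] <- union(parents[[d[r]]], p)
    }
  }
  structure(list(nodes = nodes, parents = parents,
                 tree = tibble::tibble(disease = d, tree_number = tn)),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("<disease DAG: %d node(s), %d parent edge(s)>\n", length(x$nodes), n_edges))
  invisible(x)
}

#' Ancestor contributions and semantic value of a disease
#'
#' The disease itself contributes 1; an ancestor `t` contributes
#' `delta * D(c)` maximised over the children `c` of `t` lying on paths
#' towards the disease — equivalently, the maximum of `delta ^ path length`
#' over all upward paths from the disease to `t`. Computed by max-product
#' relaxation over parent links, which
#' terminates because contributions only increase and the prefix DAG is
#' acyclic. The semantic value `DV` is the sum of all contributions.
#'
#' @param dag a `disease_dag` object or a (disease, tree_number) tibble.
#' @param disease a disease identifier present in the DAG.
#' @param delta per-edge decay in (0, 1).
#' @return A list with `contributions` (named numeric vector over the
#'   ancestor set, including the disease itself) and `dv` (their sum).
#' @examples
#' mesh <- tibble::tibble(disease = c("R", "A", "B"),
#'                        tree_number = c("C01", "C01.100", "C01.100.200"))
#' ancestor_contributions(mesh, "B")
#' @export
ancestor_contributions <- function(dag, disease, delta = 0.5) {
  if (is.data.frame(dag)) dag <- disease_dag(dag)
  stopifnot(inherits(dag, "disease_dag"))
  if (!(is.numeric(delta) && length(delta) == 1 && delta > 0 && delta < 1))
    stop("delta must lie in (0, 1)", call. = FALSE)
  if (!disease %in% dag$nodes) stop("unknown disease: ", disease, call. = FALSE)
  contrib <- setNames(1, disease)
  frontier <- disease
  while (length(frontier)) {
    nxt <- character()
    for (node in frontier) {
      for (p in dag$parents[[node]]) {
        cand <- delta * contrib[[node]]
        cur <- contrib[p]
        if (is.na(cur) || cand > cur) {
          contrib[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(contributions = contrib, dv = sum(contrib))
}

#' Disease semantic similarity matrix
#'
#' For diseases A and B with ancestor sets `T_A`, `T_B` and contribution maps
#' `D_A`, `D_B`, the similarity is the sum of both diseases' contributions
#' over the shared ancestors divided by `2 * min(DV(A), DV(B))` (or
#' `DV(A) + DV(B)` with `denominator = "sum"`, the classical normalisation).
#' Any value exceeding 1 under the min denominator is clamped to 1 with a
#' warning. Diseases absent from the DAG score 0 against everything,
#' including themselves; in-DAG diseases have unit diagonal.
#'
#' @param mesh a (disease, tree_number) tibble or a prebuilt `disease_dag`.
#' @param ids ordered identifiers defining the matrix; may include diseases
#'   absent from the DAG. Defaults to the DAG's nodes.
#' @param delta per-edge contribution decay in (0, 1).
#' @param denominator `"min"` (default) or `"sum"`; see Details.
#' @return A symmetric `mda_sim` matrix with role `DD` and entries in
#'   \[0, 1\].
#' @examples
#' mesh <- tibble::tibble(disease = c("R", "A", "B"),
#'                        tree_number = c("C01", "C01.100", "C01.100.200"))
#' semantic_similarity(mesh)["A", "B"]
#' @export
semantic_similarity <- function(mesh, ids = NULL, delta = 0.5,
                                denominator = c("min", "sum")) {
  denominator <- match.arg(denominator)
  dag <- if (inherits(mesh, "disease_dag")) mesh else disease_dag(mesh)
  if (!(is.numeric(delta) && length(delta) == 1 && delta > 0 && delta < 1))
    stop("delta must lie in (0, 1)", call. = FALSE)
  if (is.null(ids)) ids <- dag$nodes
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids contain duplicates", call. = FALSE)
  contrib <- lapply(setNames(ids, ids), function(x) {
    if (x %in% dag$nodes) ancestor_contributions(dag, x, delta) else NULL
  })
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  clamped <- 0L
  for (a in seq_len(n)) {
    ca <- contrib[[a]]
    if (is.null(ca)) next
    S[a, a] <- 1
    if (a == n) next
    for (b in seq(a + 1, n)) {
      cb <- contrib[[b]]
      if (is.null(cb)) next
      shared <- intersect(names(ca$contributions), names(cb$contributions))
      if (!length(shared)) next
      num <- sum(ca$contributions[shared]) + sum(cb$contributions[shared])
      den <- if (denominator == "min") 2 * min(ca$dv, cb$dv) else ca$dv + cb$dv
      v <- num / den
      if (v > 1) { clamped <- clamped + 1L; v <- 1 }
      S[a, b] <- S[b, a] <- v
    }
  }
  if (clamped > 0)
    warning(clamped, " semantic similarity value(s) exceeded 1 and were clamped",
            call. = FALSE)
  new_sim(S, "DD")
}
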