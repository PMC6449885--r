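# Seeded synthetic data with planted block structure. The generator couples
# the three signal channels the recommender exploits — shared targets within
# a miRNA block, family co-membership, genomic clustering — to groups of
# diseases that share interaction genes and sit as siblings in a generated
# MeSH-style DAG. Each channel can be switched off independently.

sub_seed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u)) %% 65011L
  (as.integer(seed) %% 1000003L) * 2011L + h
}

with_stream <- function(seed, name, code) {
  withr::with_seed(sub_seed(seed, name), code)
}

#' Fixed worked-example dataset
#'
#' A deterministic micro-dataset used throughout the documentation and
#' tests: five miRNAs (A-E) targeting four mRNAs in ten unique interactions,
#' a three-disease MeSH chain (dR -> dA -> dB), a two-member family \{A, B\}
#' whose members also sit within 20 kb on chr1, a small disease-gene table
#' and a small association table. The same dataset ships as plain-text files
#' under `inst/extdata/toy10/`.
#'
#' @return An object of class `mda_bundle` (a list of tibbles plus the
#'   binary `assoc_matrix`).
#' @examples
#' toy10_bundle()$mirna_targets
#' @export
toy10_bundle <- function() {
  associations <- tibble::tibble(
    mirna = c("A", "B", "B", "C", "D"),
    disease = c("dA", "dA", "dB", "dB", "dR")
  )
  bundle <- structure(list(
    mirna_targets = tibble::tibble(
      mirna = c("A", "A", "B", "B", "C", "C", "C", "D", "D", "E"),
      mrna = c("g1", "g2", "g2", "g3", "g1", "g3", "g4", "g2", "g3", "g2")
    ),
    disease_genes = tibble::tibble(
      disease = c("dA", "dA", "dB", "dR"),
      gene = c("h1", "h2", "h2", "h3")
    ),
    associations = associations,
    assoc_matrix = as_assoc_matrix(associations),
    family = tibble::tibble(mirna = c("A", "B"), family = c("fam1", "fam1")),
    coordinates = tibble::tibble(
      mirna = c("A", "B", "C", "D", "E"),
      chrom = c("chr1", "chr1", "chr2", "chr1", "chr3"),
      start = c(1000L, 12000L, 5000L, 40000L, 1000L),
      end = c(1085L, 12085L, 5085L, 40085L, 1085L),
      strand = c("+", "+", "+", "+", "-")
    ),
    mesh = tibble::tibble(
      disease = c("dR", "dA", "dB"),
      tree_number = c("C05", "C05.100", "C05.100.200")
    ),
    truth = NULL,
    seed = NULL,
    config = list(name = "toy10")
  ), class = "mda_bundle")
  bundle
}

#' Generate a seeded planted-signal dataset
#'
#' miRNAs are partitioned into blocks and diseases into matching groups.
#' Within a block, miRNAs draw targets from a shared mRNA pool (controlled
#' by `target_overlap`) and are preferentially associated with the block's
#' disease group; diseases in a group share interaction genes and are
#' siblings in the generated MeSH-style DAG. A fraction of blocks are
#' additionally marked as miRNA families and laid out as genomic clusters
#' (consecutive loci within 20 kb). Finally `noise_rate` flips random
#' association cells; the pre-noise density is solved so that the expected
#' post-noise density equals `association_density` exactly. All draws come
#' from one seeded generator with per-component sub-streams, so adding a
#' component never perturbs the others and regeneration with the same seed
#' and configuration is bit-identical.
#'
#' @param seed integer seed.
#' @param n_mirnas,n_diseases,n_mrnas,n_genes entity counts.
#' @param n_blocks number of miRNA blocks / disease groups.
#' @param target_overlap probability that a target draw comes from the
#'   block's shared pool rather than the global pool, in \[0, 1\].
#' @param association_density expected overall fraction of 1s in the
#'   association matrix.
#' @param within_block_assoc cap on the within-block association
#'   probability; the effective value also respects the overall density.
#' @param family_rate,cluster_rate fraction of blocks marked as families /
#'   laid out as genomic clusters.
#' @param noise_rate probability of flipping each association cell.
#' @param targets_per_mirna,genes_per_disease draws per entity (duplicates
#'   collapse, so realised profile sizes can be smaller).
#' @return An object of class `mda_bundle`; element `truth` records the
#'   planted block structure.
#' @examples
#' b <- simulate_mda(seed = 1, n_mirnas = 10, n_diseases = 4, n_blocks = 2)
#' dataset_stats(b$assoc_matrix)
#' @export
simulate_mda <- function(seed,
                         n_mirnas = 50, n_diseases = 20,
                         n_mrnas = 200, n_genes = 150,
                         n_blocks = 5,
                         target_overlap = 0.7,
                         association_density = 0.15,
                         within_block_assoc = 0.7,
                         family_rate = 0.4,
                         cluster_rate = 0.4,
                         noise_rate = 0.02,
                         targets_per_mirna = 12,
                         genes_per_disease = 12) {
  if (n_blocks > n_mirnas || n_blocks > n_diseases)
    stop("more blocks than miRNAs or diseases", call. = FALSE)
  stopifnot(target_overlap >= 0, target_overlap <= 1,
            association_density > 0, association_density < 1,
            noise_rate >= 0, noise_rate <= 1)
  config <- list(
    n_mirnas = n_mirnas, n_diseases = n_diseases, n_mrnas = n_mrnas,
    n_genes = n_genes, n_blocks = n_blocks, target_overlap = target_overlap,
    association_density = association_density,
    within_block_assoc = within_block_assoc, family_rate = family_rate,
    cluster_rate = cluster_rate, noise_rate = noise_rate,
    targets_per_mirna = targets_per_mirna, genes_per_disease = genes_per_disease
  )
  mirnas <- sprintf("mir%03d", seq_len(n_mirnas))
  diseases <- sprintf("dis%03d", seq_len(n_diseases))
  mrnas <- sprintf("t%04d", seq_len(n_mrnas))
  genes <- sprintf("g%04d", seq_len(n_genes))
  block_m <- sort(rep_len(seq_len(n_blocks), n_mirnas))
  group_d <- sort(rep_len(seq_len(n_blocks), n_diseases))

  draw_pairs <- function(entities, membership, universe, per_entity, stream) {
    pool_size <- max(2L, floor(length(universe) / (n_blocks + 1)))
    pools <- lapply(seq_len(n_blocks), function(b) {
      universe[seq((b - 1) * pool_size + 1, b * pool_size)]
    })
    with_stream(seed, stream, {
      purrr::map2_dfr(entities, membership, function(e, b) {
        from_pool <- sum(stats::runif(per_entity) < target_overlap)
        picked <- c(
          sample(pools[[b]], size = min(from_pool, pool_size)),
          sample(universe, size = per_entity - from_pool)
        )
        tibble::tibble(source = e, target = unique(picked))
      })
    })
  }

  mirna_targets <- draw_pairs(mirnas, block_m, mrnas, targets_per_mirna, "mirna_targets")
  names(mirna_targets) <- c("mirna", "mrna")
  disease_genes <- draw_pairs(diseases, group_d, genes, genes_per_disease, "disease_genes")
  names(disease_genes) <- c("disease", "gene")

  # solve the pre-noise density so the expected post-noise density matches
  r <- noise_rate
  d0 <- if (1 - 2 * r > 0) (association_density - r) / (1 - 2 * r) else association_density
  d0 <- min(max(d0, 0), 1)
  f <- mean(outer(block_m, group_d, `==`))
  p_in <- min(within_block_assoc, if (f > 0) d0 / f else 0)
  p_out <- if (f < 1) max(0, (d0 - f * p_in) / (1 - f)) else 0
  as_mat <- with_stream(seed, "associations", {
    pmat <- outer(block_m, group_d, function(b, g) ifelse(b == g, p_in, p_out))
    m <- matrix(as.numeric(stats::runif(length(pmat)) < pmat),
                n_mirnas, n_diseases, dimnames = list(mirnas, diseases))
    if (r > 0) {
      flip <- stats::runif(length(pmat)) < r
      m[flip] <- 1 - m[flip]
    }
    m
  })
  idx <- which(as_mat == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  associations <- tibble::tibble(mirna = mirnas[idx[, 1]], disease = diseases[idx[, 2]])

  n_fam <- min(n_blocks, ceiling(family_rate * n_blocks))
  fam_blocks <- if (n_fam > 0) with_stream(seed, "family", sort(sample(n_blocks, n_fam))) else integer()
  in_fam <- block_m %in% fam_blocks
  family <- tibble::tibble(mirna = mirnas[in_fam],
                           family = paste0("fam", block_m[in_fam]))

  n_clu <- min(n_blocks, ceiling(cluster_rate * n_blocks))
  clu_blocks <- if (n_clu > 0) with_stream(seed, "cluster", sort(sample(n_blocks, n_clu))) else integer()
  coordinates <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    members <- which(block_m == b)
    step <- if (b %in% clu_blocks) 2000L else 1000000L
    start <- 1L + (seq_along(members) - 1L) * step
    tibble::tibble(mirna = mirnas[members], chrom = paste0("chr", b),
                   start = start, end = start + 79L, strand = "+")
  })

  group_idx <- ave(seq_along(group_d), group_d, FUN = seq_along)
  mesh <- dplyr::bind_rows(
    tibble::tibble(disease = "disease_root", tree_number = "C01"),
    tibble::tibble(disease = sprintf("branch%03d", seq_len(n_blocks)),
                   tree_number = sprintf("C01.%03d", seq_len(n_blocks))),
    tibble::tibble(disease = diseases,
                   tree_number = sprintf("C01.%03d.%03d", group_d, group_idx))
  )

  structure(list(
    mirna_targets = mirna_targets,
    disease_genes = disease_genes,
    associations = associations,
    assoc_matrix = as_mat,
    family = family,
    coordinates = coordinates,
    mesh = mesh,
    truth = list(
      mirna_blocks = tibble::tibble(mirna = mirnas, block = block_m),
      disease_groups = tibble::tibble(disease = diseases, group = group_d),
      family_blocks = fam_blocks,
      cluster_blocks = clu_blocks
    ),
    seed = as.integer(seed),
    config = config
  ), class = "mda_bundle")
}

#' @export
print.mda_bundle <- function(x, ...) {
  cat(sprintf("<synthetic miRNA-disease bundle: %d association(s), %d miRNA-target pair(s)>\n",
              nrow(x$associations), nrow(x$mirna_targets)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Fit the recommender to a data bundle
#'
#' Convenience wrapper: calls [mda_fit()] with every component of a bundle,
#' using the full binary matrix so that isolated entities are kept.
#'
#' @param bundle an `mda_bundle` from [simulate_mda()] or [toy10_bundle()].
#' @param params an [mda_params()] object.
#' @return An `mda_fit` object.
#' @export
fit_bundle <- function(bundle, params = mda_params()) {
  stopifnot(inherits(bundle, "mda_bundle"))
  mda_fit(bundle$assoc_matrix, bundle$mirna_targets,
          disease_genes = bundle$disease_genes, family = bundle$family,
          coordinates = bundle$coordinates, mesh = bundle$mesh,
          params = params)
}

#' Export a bundle to the plain-text interchange formats
#'
#' Writes every component in exactly the formats the readers parse: TSV pair
#' tables with a header line, a GFF3 coordinate file and a tree-number TSV,
#' plus `manifest.json` recording the seed, the configuration and an MD5
#' checksum per file.
#'
#' @param bundle an `mda_bundle`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mda_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    disease_genes = file.path(dir, "disease_genes.tsv"),
    family = file.path(dir, "family.tsv"),
    mesh = file.path(dir, "mesh.tsv"),
    coordinates = file.path(dir, "coordinates.gff3")
  )
  readr::write_tsv(bundle$associations, paths[["associations"]])
  readr::write_tsv(bundle$mirna_targets, paths[["mirna_targets"]])
  readr::write_tsv(bundle$disease_genes, paths[["disease_genes"]])
  readr::write_tsv(bundle$family, paths[["family"]])
  readr::write_tsv(bundle$mesh, paths[["mesh"]])
  co <- bundle$coordinates
  gff <- c("##gff-version 3",
           sprintf("%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   co$chrom, co$start, co$end, co$strand, co$mirna, co$mirna))
  writeLines(gff, paths[["coordinates"]])
  manifest <- list(
    seed = bundle$seed,
    config = bundle$config,
    files = as.list(unname(tools::md5sum(unname(paths)))) |>
      setNames(basename(unname(paths)))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = manifest_path))
}

#' Deterministic benchmark-scale association matrix (synthetic)
#'
#' Constructs, without randomness, a binary association matrix with
#' prescribed global characteristics: total association count, one miRNA
#' attaining the maximum miRNA degree, one disease attaining the maximum
#' disease degree, and every entity associated at least once. This is a
#' synthetic stand-in used to exercise [dataset_stats()] and the scoring
#' machinery at realistic scale; it carries no biological signal. The
#' default characteristics mirror a curated human miRNA-disease benchmark
#' network (5048 associations between 475 miRNAs and 334 diseases, degree
#' extremes 112 and 208).
#'
#' @param n_mirnas,n_diseases matrix dimensions.
#' @param n_associations total number of 1s.
#' @param max_mirna_degree,max_disease_degree planted degree maxima.
#' @return A binary matrix with dimnames.
#' @export
synthetic_benchmark_matrix <- function(n_mirnas = 475, n_diseases = 334,
                                       n_associations = 5048,
                                       max_mirna_degree = 112,
                                       max_disease_degree = 208) {
  stopifnot(max_mirna_degree <= n_diseases, max_disease_degree <= n_mirnas,
            n_associations <= n_mirnas * n_diseases)
  m <- matrix(0, n_mirnas, n_diseases,
              dimnames = list(sprintf("mir%03d", seq_len(n_mirnas)),
                              sprintf("dis%03d", seq_len(n_diseases))))
  m[1, seq_len(max_mirna_degree)] <- 1
  m[seq_len(max_disease_degree), 1] <- 1
  # give every remaining entity degree >= 1; the last row and column are
  # reserved at degree exactly 1 so the planted minima survive the fill
  need_row <- which(rowSums(m) == 0)
  if (length(need_row)) {
    cols <- 2L + (seq_along(need_row) - 1L) %% (n_diseases - 2L)
    m[cbind(need_row, cols)] <- 1
  }
  need_col <- which(colSums(m) == 0)
  if (length(need_col)) {
    rows <- 2L + (seq_along(need_col) - 1L) %% (n_mirnas - 2L)
    m[cbind(rows, need_col)] <- 1
  }
  # deterministic low-discrepancy walk fills the rest under the degree caps
  rd <- rowSums(m); cd <- colSums(m)
  total <- sum(m)
  k <- 0L
  while (total < n_associations) {
    k <- k + 1L
    i <- 2L + (k * 7L) %% (n_mirnas - 2L)
    j <- 2L + (k * 11L + (k %/% n_diseases)) %% (n_diseases - 2L)
    if (m[i, j] == 0 && rd[i] < max_mirna_degree - 1L && cd[j] < max_disease_degree - 1L) {
      m[i, j] <- 1
      rd[i] <- rd[i] + 1; cd[j] <- cd[j] + 1
      total <- total + 1L
    }
    if (k > 50L * n_mirnas * n_diseases)
      stop("could not place the requested number of associations", call. = FALSE)
  }
  m
}
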