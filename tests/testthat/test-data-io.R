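test_that("association reader builds a binary matrix in first-appearance order", {
  path <- write_tsv_fixture(c("mA\td1", "mA\td2", "mB\td1"))
  df <- read_associations(path)
  m <- as_assoc_matrix(df)
  expect_identical(rownames(m), c("mA", "mB"))
  expect_identical(colnames(m), c("d1", "d2"))
  expect_equal(unname(m), matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE))

  # duplicated pair collapses with a warning, matrix unchanged
  path2 <- write_tsv_fixture(c("mA\td1", "mA\td2", "mB\td1", "mA\td1"))
  expect_warning(df2 <- read_associations(path2), "duplicated")
  expect_equal(as_assoc_matrix(df2), m)

  # a header line is tolerated and skipped
  path3 <- write_tsv_fixture(c("mirna\tdisease", "mA\td1", "mA\td2", "mB\td1"))
  expect_equal(as_assoc_matrix(read_associations(path3)), m)
})

test_that("pair readers reject malformed and empty files", {
  bad <- write_tsv_fixture(c("mA\td1", "mB\td1\textra", "mC\td2"))
  expect_error(read_associations(bad), "line 2")
  empty <- write_tsv_fixture(character())
  expect_error(read_associations(empty), "empty")
  expect_error(read_interactions(empty), "empty")
  blank <- write_tsv_fixture(c("", "  "))
  expect_error(read_associations(blank), "empty")
})

test_that("interaction tables deduplicate and count target occurrences", {
  toy <- toy10_bundle()
  s <- interaction_summary(toy$mirna_targets)
  expect_equal(s$n_interactions, 10L)
  counts <- setNames(s$target_counts$n, s$target_counts$target)
  expect_equal(counts[c("g1", "g2", "g3", "g4")], c(g1 = 2L, g2 = 4L, g3 = 3L, g4 = 1L))

  one <- write_tsv_fixture("mA\tg1")
  s1 <- interaction_summary(read_interactions(one))
  expect_equal(s1$n_interactions, 1L)
  expect_equal(s1$target_counts$n, 1L)

  # a repeated pair leaves the table identical to the deduplicated one
  dup <- rbind(toy$mirna_targets, toy$mirna_targets[1, ])
  expect_equal(interaction_summary(dup), s)
})

test_that("family relations are symmetric, zero-diagonal and validated", {
  fam <- family_matrix(tibble::tibble(mirna = c("A", "B", "C"),
                                      family = c("fam1", "fam1", "fam2")),
                       c("A", "B", "C"))
  expect_equal(fam["A", "B"], 1)
  expect_equal(fam["B", "A"], 1)
  expect_equal(sum(fam), 2)
  expect_true(all(diag(fam) == 0))

  # empty file -> all-zero matrix
  empty <- write_tsv_fixture(character())
  expect_equal(sum(family_matrix(read_family(empty), c("A", "B"))), 0)

  # singleton family pairs with nobody
  expect_equal(sum(family_matrix(tibble::tibble(mirna = "A", family = "fam1"),
                                 c("A", "B", "C"))), 0)

  # ambiguous membership is an error, both at read and at matrix build
  two <- write_tsv_fixture(c("A\tfam1", "A\tfam2"))
  expect_error(read_family(two), "more than one family")
  expect_error(family_matrix(tibble::tibble(mirna = c("A", "A"),
                                            family = c("f1", "f2")), "A"),
               "more than one family")

  # assignments outside the id universe are dropped with a warning
  expect_warning(
    fam2 <- family_matrix(tibble::tibble(mirna = c("A", "B", "Z"),
                                         family = c("f", "f", "f")),
                          c("A", "B")),
    "unknown"
  )
  expect_equal(fam2["A", "B"], 1)
})

test_that("GFF coordinate records map to one row per miRNA", {
  gff <- write_tsv_fixture(c(
    "##gff-version 3",
    "chr1\t.\tmiRNA\t1000\t1085\t.\t+\t.\tID=m1;Name=m1",
    "chr1\t.\tmiRNA_primary_transcript\t900\t1200\t.\t+\t.\tID=pri1;Name=pri1",
    "chr2\t.\tmiRNA\t5000\t5085\t.\t-\t.\tID=MI999"
  ), ext = ".gff3")
  co <- read_coordinates(gff)
  expect_equal(nrow(co), 2L)  # primary transcript filtered out
  expect_equal(co$mirna, c("m1", "MI999"))  # ID fallback when Name absent
  expect_equal(co$chrom[1], "chr1")
  expect_equal(co$start[1], 1000L)
  expect_equal(co$end[1], 1085L)
  expect_equal(co$strand[2], "-")

  # duplicate id: first record kept, with a warning
  gff2 <- write_tsv_fixture(c(
    "##gff-version 3",
    "chr1\t.\tmiRNA\t1000\t1085\t.\t+\t.\tName=m1",
    "chr1\t.\tmiRNA\t2000\t2085\t.\t+\t.\tName=m1"
  ), ext = ".gff3")
  expect_warning(co2 <- read_coordinates(gff2), "duplicate")
  expect_equal(co2$start, 1000L)

  # no miRNA-type records -> empty table plus warning
  gff3 <- write_tsv_fixture(c(
    "##gff-version 3",
    "chr1\t.\tgene\t1\t10\t.\t+\t.\tID=g1"
  ), ext = ".gff3")
  expect_warning(co3 <- read_coordinates(gff3), "no miRNA records")
  expect_equal(nrow(co3), 0L)
})

test_that("genomic clustering follows the gap threshold pairwise", {
  co <- tibble::tibble(
    mirna = c("m1", "m2", "m3", "m4"),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(1000L, 12000L, 1000L, 40000L),
    end = c(1085L, 12085L, 1085L, 40085L),
    strand = c("+", "+", "+", "+")
  )
  ids <- co$mirna
  clu <- cluster_matrix(co, ids)
  expect_equal(clu["m1", "m2"], 1)  # gap 10915 < 20000
  expect_equal(clu["m1", "m4"], 0)  # gap 38915 >= 20000
  expect_equal(clu["m1", "m3"], 0)  # different chromosome
  expect_equal(clu, t(clu))
  expect_true(all(diag(clu) == 0))

  # strand flips and swapping which interval comes first do not matter
  co_flip <- co
  co_flip$strand <- c("-", "+", "-", "+")
  expect_equal(cluster_matrix(co_flip, ids), clu)
  expect_equal(cluster_matrix(co[rev(seq_len(nrow(co))), ], ids), clu)

  # m4 is 28 kb from m2: the relation is pairwise, no transitive closure
  expect_equal(clu["m2", "m4"], 0)
  # miRNAs without coordinates get zero rows
  clu5 <- cluster_matrix(co, c(ids, "m5"))
  expect_true(all(clu5["m5", ] == 0))
  expect_error(cluster_matrix(co, ids, threshold_bp = 0), "positive")
})

test_that("MeSH tree numbers define parent edges by prefix", {
  chain <- tibble::tibble(disease = c("R", "A", "B"),
                          tree_number = c("C01", "C01.100", "C01.100.200"))
  dag <- disease_dag(chain)
  expect_setequal(dag$parents$B, "A")
  expect_setequal(dag$parents$A, "R")
  expect_null(dag$parents$R)
  expect_setequal(names(ancestor_contributions(dag, "B")$contributions),
                  c("B", "A", "R"))

  sib <- tibble::tibble(disease = c("R", "A", "C"),
                        tree_number = c("C01", "C01.100", "C01.200"))
  dag2 <- disease_dag(sib)
  expect_setequal(dag2$parents$A, "R")
  expect_setequal(dag2$parents$C, "R")

  # a disease whose parent tree number is owned by nobody is a root
  orphan <- disease_dag(tibble::tibble(disease = "A", tree_number = "C01.100"))
  expect_null(orphan$parents$A)

  bad <- write_tsv_fixture(c("A\tC01..100"))
  expect_error(read_mesh_tree(bad), "malformed tree number")
  expect_error(disease_dag(tibble::tibble(disease = "A", tree_number = "C01.")),
               "malformed tree number")
})

test_that("dataset statistics are consistent with degree sums", {
  m <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("mA", "mB"), c("d1", "d2")))
  st <- dataset_stats(m)
  expect_equal(st$n_associations, 3L)
  expect_equal(st$avg_mirna_degree, 1.5)
  expect_equal(st$avg_disease_degree, 1.5)

  set.seed(11)
  r <- random_assoc(sprintf("m%d", 1:12), sprintf("d%d", 1:7), 0.4)
  st2 <- dataset_stats(r)
  expect_equal(st2$n_associations, sum(rowSums(r)))
  expect_equal(st2$n_associations, sum(colSums(r)))
  expect_error(dataset_stats(r * 0), "no associations")
})

test_that("rankings exclude known associations and break ties by id", {
  fit <- structure(list(
    assoc = matrix(c(1, 0, 0), 3, 1, dimnames = list(c("mA", "mB", "mC"), "d1")),
    scores = matrix(c(0.9, 0.5, 0.2), 3, 1,
                    dimnames = list(c("mA", "mB", "mC"), "d1"))
  ), class = "mda_fit")
  rk <- rank_candidates(fit, "d1", top_k = 2)
  expect_equal(rk$mirna, c("mB", "mC"))
  expect_equal(rk$score, c(0.5, 0.2))

  # top_k larger than the candidate pool clamps
  expect_equal(nrow(rank_candidates(fit, "d1", top_k = 10)), 2L)

  # equal scores order by miRNA input order
  fit$scores[, 1] <- c(0.9, 0.4, 0.4)
  expect_equal(rank_candidates(fit, "d1", 2)$mirna, c("mB", "mC"))

  expect_error(rank_candidates(fit, "dd1"), "unknown disease")

  out <- tempfile(fileext = ".tsv")
  write_rankings(fit, "d1", 2, out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(back$mirna, c("mB", "mC"))
})

test_that("matrices survive a write / re-read round trip", {
  set.seed(3)
  m <- random_assoc(sprintf("m%d", 1:6), sprintf("d%d", 1:4), 0.5)
  idx <- which(m == 1, arr.ind = TRUE)
  df <- tibble::tibble(mirna = rownames(m)[idx[, 1]], disease = colnames(m)[idx[, 2]])
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  back <- as_assoc_matrix(read_associations(path))
  expect_equal(back[rownames(m), colnames(m)], m)
})
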