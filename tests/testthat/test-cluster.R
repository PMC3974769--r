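# flip a base deterministically (A<->C, G<->T) at given 1-based positions
flip_at <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  map <- c(A = "C", C = "A", G = "T", T = "G")
  ch[positions] <- map[ch[positions]]
  paste(ch, collapse = "")
}

test_that("pairwise identity is computed over pairwise-deleted columns", {
  aln <- or_alignment(c(a = "ACGTAC", b = "ACGTAA", c = "AC--AC"), alphabet = "DNA")
  idm <- identity_matrix(aln)
  expect_equal(idm$identity["a", "b"], 5 / 6)
  expect_equal(idm$diff_counts["a", "b"], 1)
  expect_equal(idm$identity["a", "c"], 1)        # gap columns excluded
  expect_equal(idm$compared["a", "c"], 4)
  expect_equal(idm$gap_diffs["a", "c"], 2)
  expect_equal(diag(idm$identity), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(idm$identity))
})

test_that("sequencing variants collapse under the two-difference rule with transitive closure", {
  base <- random_cds(215, seed = 3)
  aln <- or_alignment(c(r1 = base, r2 = base,
                        two = flip_at(base, c(10, 20)),
                        three = flip_at(base, c(30, 40, 50))),
                      alphabet = "DNA")
  dd <- dedupe_identical(aln)
  expect_equal(sort(names(dd$alignment)), c("r1", "three"))
  expect_equal(dd$membership$representative[dd$membership$id == "two"], "r1")

  # chain a~b (2 diffs), b~c (2 diffs), a-c (4 diffs): one cluster by closure
  chain <- or_alignment(c(a = base, b = flip_at(base, c(1, 2)),
                          c = flip_at(base, c(1, 2, 3, 4))),
                        alphabet = "DNA")
  dd2 <- dedupe_identical(chain)
  expect_equal(names(dd2$alignment), "a")
  # brute-force union-find oracle over the pairwise difference matrix
  d <- identity_matrix(chain)$diff_counts
  parent <- seq_len(3)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:3) for (j in 1:3) if (d[i, j] <= 2) parent[find(i)] <- find(j)
  expect_equal(length(unique(vapply(1:3, find, integer(1)))), 1L)
})

test_that("base-vs-gap columns count as differences when collapsing reads", {
  base <- random_cds(215, seed = 4)
  # a 2-base deletion is within the collapse budget either way; a 3-base gap
  # run separates the reads only when gap columns count as differences
  del2 <- paste0(substr(base, 1, 99), "--", substr(base, 102, nchar(base)))
  del3 <- paste0(substr(base, 1, 99), "---", substr(base, 103, nchar(base)))
  aln2 <- or_alignment(c(x = base, y = del2), alphabet = "DNA")
  expect_equal(length(dedupe_identical(aln2, count_gaps = TRUE)$alignment), 1L)
  aln3 <- or_alignment(c(x = base, y = del3), alphabet = "DNA")
  expect_equal(length(dedupe_identical(aln3, count_gaps = TRUE)$alignment), 2L)
  expect_equal(length(dedupe_identical(aln3, count_gaps = FALSE)$alignment), 1L)
})

test_that("hierarchical identity thresholds gate allele merging by taxonomic relation", {
  base <- random_cds(215, seed = 6)
  md <- fixture_metadata()
  # 3 diffs / 645 = 99.5% identity; 33 diffs = 94.9%
  # disjoint flip positions so single-linkage cannot chain across the cut-off
  aln <- or_alignment(c(BJ1_A01 = base,
                        BJ1_A02 = flip_at(base, 1:3),
                        BJ2_A01 = flip_at(base, 20:27),    # 98.8%: below species cut
                        HG1_A01 = flip_at(base, 101:133)),
                      alphabet = "DNA")
  idm <- identity_matrix(aln)
  clus <- cluster_alleles(idm, parse_sequence_id(names(aln), md))
  grp <- function(id) which(vapply(clus$members, function(g) id %in% g, logical(1)))
  expect_equal(grp("BJ1_A01"), grp("BJ1_A02"))   # same species >= 99%
  expect_false(grp("BJ1_A01") == grp("BJ2_A01")) # same species < 99%
  expect_false(grp("BJ1_A01") == grp("HG1_A01")) # cross genus < 96%
  expect_error(cluster_alleles(idm, parse_sequence_id(names(aln)[1:3], md)),
               "no metadata")
})

test_that("clusters mixing functional status are split into separate genes", {
  base <- random_cds(215, seed = 7)
  ids <- c("BJ1_A01", "BJ1_A02")
  aln <- or_alignment(setNames(c(base, flip_at(base, 5)), ids), alphabet = "DNA")
  md <- fixture_metadata()
  parsed <- parse_sequence_id(ids, md)
  tree <- ape::read.tree(text = "(BJ1_A01,BJ1_A02);")
  clus <- cluster_alleles(identity_matrix(aln), parsed)
  expect_length(clus$members, 1L)
  final <- resolve_ambiguities(clus, tree,
                               c(BJ1_A01 = "FUNCTIONAL", BJ1_A02 = "PSEUDOGENE"),
                               parsed)
  expect_length(final, 2L)
})

test_that("non-transitive components are re-partitioned along the tree", {
  base <- random_cds(215, seed = 8)
  # A=B (4 diffs), B=C (4 diffs), A!=C (8 diffs) within one species
  ids <- c("BJ1_A01", "BJ1_A02", "BJ1_A03")     # A, B, C
  aln <- or_alignment(setNames(c(base, flip_at(base, 1:4), flip_at(base, 1:8)), ids),
                      alphabet = "DNA")
  md <- fixture_metadata()
  parsed <- parse_sequence_id(ids, md)
  # three alleles of one individual would also trigger the copy split, so
  # spread them over individuals: A,B from individual 1; C from individual 2
  ids2 <- c("BJ1_A01", "BJ1_A02", "BJ2_A01")
  aln <- or_alignment(setNames(unname(unclass(aln)), ids2), alphabet = "DNA")
  parsed <- parse_sequence_id(ids2, md)
  idm <- identity_matrix(aln)
  clus <- cluster_alleles(idm, parsed)
  expect_length(clus$members, 1L)               # single-linkage chains them
  expect_false(clus$edges["BJ1_A01", "BJ2_A01"])  # but A-C fails the cut-off

  tree <- ape::read.tree(text = "((BJ1_A01,BJ1_A02),BJ2_A01);")
  statuses <- setNames(rep("FUNCTIONAL", 3), ids2)
  final <- resolve_ambiguities(clus, tree, statuses, parsed)
  got <- lapply(final, sort)

  # oracle: enumerate the partitions of {A,B,C}; keep those whose groups all
  # satisfy the pairwise cut-offs; among them the tree-consistent maximal
  # grouping is {A,B},{C}
  parts <- list(list(c("BJ1_A01", "BJ1_A02", "BJ2_A01")),
                list(c("BJ1_A01", "BJ1_A02"), "BJ2_A01"),
                list(c("BJ1_A01", "BJ2_A01"), "BJ1_A02"),
                list(c("BJ1_A02", "BJ2_A01"), "BJ1_A01"),
                list("BJ1_A01", "BJ1_A02", "BJ2_A01"))
  ok_part <- Filter(function(p) all(vapply(p, function(g)
    all(clus$edges[g, g] | diag(length(g)) > 0), logical(1))), parts)
  sisters_AB <- list(sort(c("BJ1_A01", "BJ1_A02")), "BJ2_A01")
  expect_true(any(vapply(ok_part, function(p)
    identical(lapply(p, sort)[order(vapply(p, function(g) sort(g)[1], character(1)))],
              sisters_AB), logical(1))))
  expect_equal(got, sisters_AB)
})

test_that("more than two alleles in one individual split into gene copies", {
  base <- random_cds(215, seed = 9)
  ids <- c("HG1_A01", "HG1_A02", "HG1_A03")
  aln <- or_alignment(setNames(c(base, flip_at(base, 1), flip_at(base, 2)), ids),
                      alphabet = "DNA")
  md <- fixture_metadata()
  parsed <- parse_sequence_id(ids, md)
  tree <- ape::read.tree(text = "((HG1_A01,HG1_A02),HG1_A03);")
  statuses <- setNames(rep("FUNCTIONAL", 3), ids)
  clus <- cluster_alleles(identity_matrix(aln), parsed)
  expect_length(clus$members, 1L)
  final <- resolve_ambiguities(clus, tree, statuses, parsed)
  expect_length(final, 2L)
  expect_equal(sort(lengths(final)), c(1L, 2L))
  expect_error(resolve_ambiguities(clus, ape::read.tree(text = "(HG1_A01,HG1_A02);"),
                                   statuses, parsed),
               "missing from tree")
})

test_that("consensus calling is majority with alphabetical tie-break and gaps as residues", {
  expect_equal(consensus_sequence(c(x = "ACGT")), "ACGT")
  expect_equal(consensus_sequence(c(a = "ACGT", b = "ACGA", c = "ACGA")), "ACGA")
  expect_equal(consensus_sequence(c(a = "A", b = "C")), "A")       # tie -> alphabetical
  expect_equal(consensus_sequence(c(a = "A-GT", b = "A-GA", c = "ACGA")), "A-GA")
  expect_error(consensus_sequence(character(0)), "empty")
})

test_that("the final gene set partitions the input and never mixes statuses", {
  res <- default_pipeline()
  mem <- attr(res$genes, "membership")
  expect_setequal(mem$seq_id, setdiff(names(res$unique), default_sim()$outgroups))
  expect_equal(anyDuplicated(mem$seq_id), 0L)
  by_gene <- split(mem$status, mem$gene_id)
  expect_true(all(vapply(by_gene, function(s) length(unique(s)) == 1L, logical(1))))
  expect_equal(nrow(res$genes), length(unique(mem$gene_id)))
})

test_that("gene merging recovers the simulated gene partition", {
  sim <- default_sim()
  res <- default_pipeline()
  mem <- attr(res$genes, "membership")
  truth_gene <- sim$truth$gene[match(mem$seq_id, sim$truth$id)]
  ari <- mclust::adjustedRandIndex(mem$gene_id, truth_gene)
  expect_gte(ari, 0.9)
})
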