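test_that("TN93 distances are zero for identical pairs and match the closed formula", {
  a <- random_cds(100, seed = 41)
  aln <- or_alignment(c(x = a, y = a), alphabet = "DNA")
  expect_equal(unname(tn93_distance(aln)["x", "y"]), 0)

  # hand evaluation for one A->G transition in 300 sites
  b <- a
  pos <- regexpr("A", a)[1]
  substr(b, pos, pos) <- "G"
  aln2 <- or_alignment(c(x = a, y = b), alphabet = "DNA")
  d <- tn93_distance(aln2)
  n <- nchar(a)
  freq <- table(factor(strsplit(paste0(a, b), "")[[1]], levels = c("A","C","G","T"))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- 1 / n   # purine transition proportion
  P2 <- 0; Q <- 0
  k1 <- 2 * gA * gG / gR; k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  hand <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  expect_equal(unname(d["x", "y"]), unname(hand), tolerance = 1e-10)
})

test_that("neighbor joining recovers additive quartets and clamps negative branches", {
  # additive matrix on ((A,B),(C,D)) with internal branch 2
  dm <- matrix(0, 4, 4, dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  dm["A","B"] <- dm["B","A"] <- 2
  dm["C","D"] <- dm["D","C"] <- 2
  for (i in c("A","B")) for (j in c("C","D")) dm[i, j] <- dm[j, i] <- 5
  tr <- neighbor_joining(dm)
  # brute force over the three possible quartet splits
  split_of <- function(tree) {
    bp <- ape::prop.part(tree)
    sets <- lapply(bp, function(x) sort(tree$tip.label[x]))
    sets
  }
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))
  expect_true(all(tr$edge.length >= 0))
  # path lengths reproduce the additive matrix exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)
  # three taxa: the unique unrooted topology
  d3 <- dm[1:3, 1:3]
  expect_equal(ape::Ntip(neighbor_joining(d3)), 3L)
  dm[1, 2] <- dm[2, 1] <- NaN
  expect_error(neighbor_joining(dm), "non-finite")
})

test_that("bootstrap support is maximal for perfectly congruent splits and tracks rooting", {
  # two blocks of sequences separated by many sites, identical within block
  base <- random_cds(120, seed = 51)
  other <- local({
    ch <- strsplit(base, "")[[1]]
    set.seed(52)
    idx <- sample(length(ch), 80)
    for (i in idx) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
    paste(ch, collapse = "")
  })
  jig <- function(s, k, seed) {       # k private substitutions
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  aln <- or_alignment(c(a1 = jig(base, 3, 1), a2 = jig(base, 3, 2),
                        b1 = jig(other, 3, 3), b2 = jig(other, 3, 4)),
                      alphabet = "DNA")
  tr <- bootstrap_support(aln, n = 100, seed = 9)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup[!is.na(sup)] == 100))
  # supports are attached before rooting when rooting is requested
  tr2 <- bootstrap_support(aln, n = 100, seed = 9, root = c("b1", "b2"))
  expect_true(ape::is.rooted(tr2))
  expect_true(ape::is.monophyletic(tr2, c("a1", "a2")))
})

test_that("clade extraction labels maximal supported proper subtrees and leaves the rest UNASSIGNED", {
  # star tree: no internal structure, everything UNASSIGNED
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1,R:3);")
  star <- ape::root(star, "R", resolve.root = TRUE)
  star$node.label <- rep(100, star$Nnode)
  ca <- extract_clades(star, outgroups = "R")
  expect_true(all(ca$clade == "UNASSIGNED"))

  # two supported families under a weak ingroup node (labels in the newick)
  tr <- ape::read.tree(text = "(((a1:1,a2:1)99:2,(b1:1,b2:1)98:2)50:1,R:5);")
  ca <- extract_clades(tr, min_support = 97, outgroups = "R")
  got <- setNames(ca$clade, ca$leaf)
  expect_equal(unname(got[c("a1", "a2")]), c("A", "A"))
  expect_equal(unname(got[c("b1", "b2")]), c("B", "B"))
  expect_equal(unname(attr(ca, "supports")), c(99, 98))

  # the full ingroup never becomes a clade even at full support
  tr2 <- ape::read.tree(text = "(((a1:1,a2:1)10:2,(b1:1,b2:1)10:2)100:1,R:5);")
  ca2 <- extract_clades(tr2, min_support = 97, outgroups = "R")
  expect_true(all(ca2$clade == "UNASSIGNED"))

  expect_error(extract_clades(ape::read.tree(text = "(a:1,b:1,c:1);")), "rooted")
})

test_that("clade summaries reconcile counts and percentages", {
  assign <- structure(data.frame(leaf = c("x1", "x2", "x3", "y1"),
                                 clade = c("A", "A", "A", "UNASSIGNED"),
                                 stringsAsFactors = FALSE),
                      class = c("clade_assignment", "data.frame"))
  st <- c(x1 = "FUNCTIONAL", x2 = "FUNCTIONAL", x3 = "FUNCTIONAL", y1 = "PSEUDOGENE")
  cs <- clade_summary(assign, st)
  a <- cs[cs$clade == "A", ]
  expect_equal(a$percent_functional, 100)
  expect_equal(sum(cs$n_total), 4L)
  expect_equal(cs$n_functional + cs$n_pseudogene, cs$n_total)
  expect_error(clade_summary(assign, st[-1]), "missing status")
})

test_that("trait labeling marks exactly the foreground tips and round-trips", {
  md <- fixture_metadata()
  tr <- ape::read.tree(text = "((BJ1_A01:1,GC1_A01:1):1,(HG1_A01:1,CM1_A01:1):1);")
  lab <- label_partitions(tr, md, "sociality", foreground = "Social")
  expect_equal(lab$n_foreground, 2L)
  expect_equal(sum(grepl("#1$", lab$tree$tip.label)), 2L)
  expect_setequal(grep("#1$", lab$tree$tip.label, value = TRUE),
                  c("HG1_A01#1", "CM1_A01#1"))
  lab2 <- label_partitions(tr, md, "sociality", foreground = "Solitary")
  expect_setequal(grep("#1$", lab2$tree$tip.label, value = TRUE),
                  c("BJ1_A01#1", "GC1_A01#1"))
  # round-trip: written newick parses and strips back to the original topology
  f <- tempfile(fileext = ".nwk")
  writeLines(lab$newick, f)
  back <- strip_partition_labels(ape::read.tree(f))
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
})

test_that("bipartition supports are invariant to leaf order in the alignment", {
  sim <- simulate_codon_alignment(6, 80, omega = 0.5, mu = 0.15, seed = 61)
  t1 <- bootstrap_support(sim, n = 60, seed = 3)
  perm <- or_alignment(unclass(sim)[c(4, 2, 6, 1, 5, 3)], alphabet = "DNA")
  t2 <- bootstrap_support(perm, n = 60, seed = 3)
  key <- function(tr) {
    pp <- ape::prop.part(tr)
    sup <- suppressWarnings(as.numeric(tr$node.label))
    parts <- vapply(seq_along(pp), function(i)
      paste(sort(tr$tip.label[pp[[i]]]), collapse = "|"), character(1))
    setNames(sup, parts)
  }
  k1 <- key(t1); k2 <- key(t2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 2L)
  expect_equal(k1[shared], k2[shared])
})
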