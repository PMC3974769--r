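# independent brute-force oracles built directly on the genetic code
oracle_gc <- setNames(as.character(Biostrings::GENETIC_CODE),
                      names(Biostrings::GENETIC_CODE))
oracle_codons <- apply(expand.grid(b3 = c("A","C","G","T"), b2 = c("A","C","G","T"),
                                   b1 = c("A","C","G","T")), 1,
                       function(r) paste0(r[["b1"]], r[["b2"]], r[["b3"]]))
oracle_sense <- oracle_codons[oracle_gc[oracle_codons] != "*"]

oracle_sites <- function(codon) {
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0; n_valid <- 0
    for (b in setdiff(c("A","C","G","T"), substr(codon, pos, pos))) {
      mut <- codon; substr(mut, pos, pos) <- b
      if (oracle_gc[[mut]] == "*") next
      n_valid <- n_valid + 1
      if (oracle_gc[[mut]] == oracle_gc[[codon]]) n_syn <- n_syn + 1
    }
    if (n_valid > 0) syn <- syn + n_syn / n_valid
  }
  syn
}

# exhaustive pathway enumeration between two codons (all step orders), with
# stop-containing pathways dropped
oracle_paths <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else
    unique(combinat_perms(pos))
  res <- list()
  for (ord in perms) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_gc[[nxt]] == "*") { valid <- FALSE; break }
      if (oracle_gc[[cur]] == oracle_gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) res[[length(res) + 1]] <- c(sd = sd, nd = nd)
  }
  if (length(res) == 0) return(c(sd = NA_real_, nd = NA_real_))
  colMeans(do.call(rbind, res))
}
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (rest in combinat_perms(v[-i]))
    out[[length(out) + 1]] <- c(v[i], rest)
  out
}

test_that("synonymous site counts match enumeration of single-base mutants", {
  expect_equal(unname(ng_sites("TTT")[1]), 1 / 3)
  expect_equal(unname(ng_sites("ATG")[1]), 0)
  expect_gte(unname(ng_sites("GGG")[1]), 1)
  for (codon in oracle_sense) {
    s <- ng_sites(codon)
    expect_equal(unname(s[1]), oracle_sites(codon), tolerance = 1e-12)
    expect_equal(unname(sum(s)), 3)
  }
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("AXG"), "ACGT")
})

test_that("pairwise difference counting equals the exhaustive pathway oracle", {
  # spec worked examples
  pad <- "GGTACC"    # two invariant codons give the pair a usable denominator
  est <- ng_pairwise(paste0("TTT", pad), paste0("TTC", pad))
  expect_equal(est$Sd, 1); expect_equal(est$Nd, 0)
  est <- ng_pairwise(paste0("TTT", pad), paste0("TTA", pad))
  expect_equal(est$Nd, 1); expect_equal(est$Sd, 0)
  est <- ng_pairwise("TTTGGT", "TTTGGT")
  expect_equal(est$dN, 0); expect_equal(est$dS, 0)

  # all sense-codon pairs with <= 2 differences against the oracle
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  set.seed(1)
  c1s <- sample(oracle_sense, 25)
  for (c1 in c1s) for (c2 in oracle_sense) {
    h <- ham(c1, c2)
    if (h == 0 || h > 2) next
    o <- oracle_paths(c1, c2)
    est <- ng_pairwise(paste0(c1, pad), paste0(c2, pad))
    expect_equal(est$Sd, unname(o["sd"]), tolerance = 1e-12)
    expect_equal(est$Nd, unname(o["nd"]), tolerance = 1e-12)
    expect_equal(est$Sd + est$Nd, h)   # path-averaged counts sum to the differences
  }
})

test_that("pairwise estimates are symmetric and flag saturation", {
  a <- random_cds(100, seed = 21)
  set.seed(22)
  b <- local({
    ch <- strsplit(a, "")[[1]]
    idx <- sample(length(ch), 30)
    for (i in idx) {
      for (alt in sample(setdiff(c("A","C","G","T"), ch[i]))) {
        old <- ch[i]; ch[i] <- alt
        ci <- (i - 1) %/% 3 + 1
        codon <- paste(ch[(3 * ci - 2):(3 * ci)], collapse = "")
        if (!codon %in% c("TAA", "TAG", "TGA")) break
        ch[i] <- old
      }
    }
    paste(ch, collapse = "")
  })
  e1 <- ng_pairwise(a, b); e2 <- ng_pairwise(b, a)
  expect_equal(e1$dN, e2$dN); expect_equal(e1$dS, e2$dS)
  expect_equal(e1$Nd, e2$Nd); expect_equal(e1$Sd, e2$Sd)
  # gap codons drop pairwise
  ag <- paste0("---", substring(a, 4))
  expect_equal(ng_pairwise(ag, b)$n_codons, 99)
  expect_error(ng_pairwise(a, substring(b, 1, 99)), "codon-aligned")
})

test_that("the codon Z test is seeded, one-tailed, and degenerate on identical input", {
  a <- random_cds(120, seed = 31)
  aln <- or_alignment(c(s1 = a, s2 = a, s3 = a), alphabet = "DNA")
  expect_warning(z0 <- codon_z_test(aln, "PURIFYING", n_boot = 50, seed = 1),
                 "zero bootstrap variance")
  expect_equal(z0$p, 1)

  sim <- simulate_codon_alignment(8, 150, omega = 0.1, mu = 0.1, seed = 77)
  z1 <- codon_z_test(sim, "PURIFYING", n_boot = 200, seed = 5)
  z2 <- codon_z_test(sim, "PURIFYING", n_boot = 200, seed = 5)
  expect_identical(z1$Z, z2$Z)
  expect_true(z1$p >= 0 && z1$p <= 1)
  expect_error(codon_z_test(sim, "PURIFYING", n_boot = 10), "seed")
  # the POSITIVE alternative mirrors the statistic
  zp <- codon_z_test(sim, "POSITIVE", n_boot = 200, seed = 5)
  expect_equal(zp$statistic, -z1$statistic)
})

test_that("the per-codon scan classes invariant, synonymous-only and nonsynonymous codons", {
  # codon 1 invariant; codon 2 synonymous variation (GGT/GGC); codon 3
  # nonsynonymous variation (AAA/GAA)
  aln <- or_alignment(c(s1 = "ATGGGTAAA", s2 = "ATGGGCGAA", s3 = "ATGGGTAAA"),
                      alphabet = "DNA")
  scan <- per_codon_dnds_scan(aln)
  expect_equal(nrow(scan), 3L)
  expect_true(is.na(scan$class[1]))
  expect_equal(scan$class[2], "dN/dS<1")
  expect_equal(scan$class[3], "dN/dS>1")
  expect_equal(scan$Sd[2], 2)   # two of three pairs differ synonymously
})

test_that("ZZ statistic matches hand-computed r-squared on a three-site fixture", {
  # 4 haplotypes over 3 biallelic sites (columns 1, 3, 5); columns 2 and 4
  # are monomorphic padding, column 6 carries a gap so it must be excluded
  haps <- c(h1 = "ATATA-", h2 = "ATATAA", h3 = "GTATCA", h4 = "GTGTCA")
  aln <- or_alignment(haps, alphabet = "DNA")
  # site vectors: s1 = (A,A,G,G), s3 = (A,A,A,G), s5 = (A,A,C,C)
  r2 <- function(x, y) cor(x, y)^2
  s1 <- c(1, 1, 0, 0); s3 <- c(1, 1, 1, 0); s5 <- c(1, 1, 0, 0)
  ZnS_hand <- mean(c(r2(s1, s3), r2(s1, s5), r2(s3, s5)))
  Za_hand <- mean(c(r2(s1, s3), r2(s3, s5)))
  zz <- zz_statistic(aln)
  expect_equal(zz$n_sites, 3L)
  expect_equal(zz$ZnS, ZnS_hand)
  expect_equal(zz$Za, Za_hand)
  expect_equal(zz$ZZ, Za_hand - ZnS_hand)
  # two usable sites: adjacency covers all pairs, so ZZ = 0
  two <- or_alignment(c(a = "AA", b = "AT", c = "TA", d = "TT"), alphabet = "DNA")
  expect_equal(zz_statistic(two)$ZZ, 0)
  expect_error(zz_statistic(or_alignment(c(a = "AAA", b = "AAT"), alphabet = "DNA")),
               "biallelic")
  # row order invariance and range
  perm <- or_alignment(haps[c(3, 1, 4, 2)], alphabet = "DNA")
  expect_equal(zz_statistic(perm)$ZnS, zz$ZnS)
  expect_true(zz$ZnS >= 0 && zz$ZnS <= 1)
})

test_that("BH adjustment follows the step-up formula and q-values reduce to BH at pi0 = 1", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(9)
  p <- runif(40)
  expect_equal(storey_qvalues(p, pi0 = 1)$qvalues, bh_adjust(p))
})

test_that("the pi0 estimate is near 1 for uniform p-values and q-values are monotone in [0, 1]", {
  set.seed(101)
  p <- runif(500)
  q <- storey_qvalues(p)
  expect_gt(q$pi0, 0.8)
  expect_lte(q$pi0, 1)
  o <- order(p)
  expect_true(all(diff(q$qvalues[o]) >= -1e-12))
  expect_true(all(q$qvalues <= 1 & q$qvalues >= 0))
  expect_warning(qq <- storey_qvalues(p, lambda_grid = numeric(0)), "degenerate")
  expect_equal(qq$qvalues, bh_adjust(p))
})
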