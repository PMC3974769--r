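BASES <- c("A", "C", "G", "T")

.ng_cache <- new.env(parent = emptyenv())

all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

codon_aa <- function(codon) unname(genetic_code()[codon])

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the fraction of possible single-base changes
#' that leave the encoded amino acid unchanged; changes creating a stop
#' codon are disregarded (the classic counting convention), so the
#' fraction at a position is synonymous changes over non-stop changes.
#' Summed over the three positions the fractions give the codon's
#' synonymous sites; nonsynonymous sites are the complement to 3.
#'
#' @param codon three-letter string over ACGT, not a stop codon.
#' @return named numeric `c(syn_sites, nonsyn_sites)`.
#' @export
ng_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("codon must be three of ACGT", call. = FALSE)
  aa <- codon_aa(codon)
  if (aa == "*") stop("stop codons have no defined site counts", call. = FALSE)
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0L; n_valid <- 0L
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      mut_aa <- codon_aa(mut)
      if (mut_aa == "*") next
      n_valid <- n_valid + 1L
      if (mut_aa == aa) n_syn <- n_syn + 1L
    }
    if (n_valid > 0L) syn <- syn + n_syn / n_valid
  }
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

# path-averaged synonymous/nonsynonymous differences between two codons.
# All minimal mutational pathways are enumerated; pathways passing through a
# stop codon are excluded (unless that removes every pathway).
ng_pair_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else
    if (k == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  step_counts <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- codon_aa(cur); a2 <- codon_aa(nxt)
      if (a2 == "*" || a1 == "*") return(NULL)   # pathway through a stop
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, step_counts)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (length(ok) == 0L) {      # every pathway blocked by stops: keep all
    ok <- lapply(perms, function(order) {
      cur <- c1; sd <- nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, ok))
}

# cached lookup tables: per-codon site counts and 64x64 path-averaged
# difference counts (NA where either codon is a stop)
ng_tables <- function() {
  if (!is.null(.ng_cache$tab)) return(.ng_cache$tab)
  codons <- all_codons()
  aa <- codon_aa(codons)
  ok <- aa != "*"
  S <- rep(NA_real_, 64); N <- rep(NA_real_, 64)
  for (i in which(ok)) {
    s <- ng_sites(codons[i])
    S[i] <- s[["syn_sites"]]; N[i] <- s[["nonsyn_sites"]]
  }
  SD <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  ND <- SD
  for (i in which(ok)) for (j in which(ok)) {
    if (j < i) { SD[i, j] <- SD[j, i]; ND[i, j] <- ND[j, i]; next }
    cc <- ng_pair_counts(codons[i], codons[j])
    SD[i, j] <- cc[["sd"]]; ND[i, j] <- cc[["nd"]]
  }
  .ng_cache$tab <- list(codons = codons, S = setNames(S, codons),
                        N = setNames(N, codons), SD = SD, ND = ND)
  .ng_cache$tab
}

# codon index vector of a gapped nucleotide string; NA for codons containing
# gaps, ambiguity codes, or encoding stops
codon_index <- function(nt) {
  nt <- toupper(nt)
  n_codon <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  idx <- match(codons, all_codons())
  tab <- ng_tables()
  idx[!is.na(idx) & is.na(tab$S[idx])] <- NA_integer_   # stops
  idx
}

jc_correct <- function(p) {
  d <- ifelse(p < 3 / 4, -3 / 4 * log(1 - 4 / 3 * p), NaN)
  ifelse(p == 0, 0, d)
}

#' Nei-Gojobori pairwise dN and dS
#'
#' Counting method with equal (uniform) weighting of all minimal
#' mutational pathways between codons, pathways through stop codons
#' excluded, and Jukes-Cantor correction of the proportions. Codons
#' containing gaps or ambiguity codes in either sequence, or encoding a
#' stop, are dropped pairwise.
#'
#' @param seq1,seq2 codon-aligned nucleotide strings of equal length
#'   divisible by three.
#' @return list of class `dnds_estimate`: `dN`, `dS`, `omega` (dN/dS, NaN
#'   when dS is 0), `N_sites`, `S_sites`, `Nd`, `Sd`, `n_codons`
#'   (compared), `saturated` flag.
#' @export
ng_pairwise <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be codon-aligned", call. = FALSE)
  if (nchar(seq1) %% 3L != 0L) stop("alignment length must be divisible by 3", call. = FALSE)
  tab <- ng_tables()
  i1 <- codon_index(seq1); i2 <- codon_index(seq2)
  ok <- !is.na(i1) & !is.na(i2)
  if (!any(ok)) stop("no comparable codons", call. = FALSE)
  Sd <- sum(tab$SD[cbind(i1[ok], i2[ok])])
  Nd <- sum(tab$ND[cbind(i1[ok], i2[ok])])
  S <- sum((tab$S[i1[ok]] + tab$S[i2[ok]]) / 2)
  N <- sum((tab$N[i1[ok]] + tab$N[i2[ok]]) / 2)
  pS <- Sd / S; pN <- Nd / N
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  structure(list(dN = dN, dS = dS,
                 omega = if (!is.nan(dS) && dS > 0) dN / dS else NaN,
                 N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
                 n_codons = sum(ok), saturated = is.nan(dS) || is.nan(dN)),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN = %.4f, dS = %.4f, dN/dS = %.3f (%d codons)\n",
              x$dN, x$dS, x$omega, x$n_codons))
  invisible(x)
}

# per-pair, per-codon count matrices for an alignment (used by the Z test,
# the per-codon scan and the mean pairwise statistics)
ng_matrices <- function(aln) {
  tab <- ng_tables()
  ids <- names(aln)
  idx <- lapply(unclass(aln), codon_index)
  n_codon <- length(idx[[1]])
  prs <- combn(length(ids), 2)
  P <- ncol(prs)
  SD <- ND <- SS <- NS <- matrix(0, P, n_codon)
  for (p in seq_len(P)) {
    i1 <- idx[[prs[1, p]]]; i2 <- idx[[prs[2, p]]]
    ok <- !is.na(i1) & !is.na(i2)
    SD[p, ok] <- tab$SD[cbind(i1[ok], i2[ok])]
    ND[p, ok] <- tab$ND[cbind(i1[ok], i2[ok])]
    SS[p, ok] <- (tab$S[i1[ok]] + tab$S[i2[ok]]) / 2
    NS[p, ok] <- (tab$N[i1[ok]] + tab$N[i2[ok]]) / 2
  }
  list(pairs = prs, ids = ids, SD = SD, ND = ND, SS = SS, NS = NS)
}

#' Mean pairwise dN/dS of a codon alignment
#'
#' @param aln codon-aligned nucleotide `or_alignment`.
#' @return list `mean_omega` (mean over non-saturated pairs of dN/dS),
#'   `mean_dN`, `mean_dS`, `pooled_omega` (ratio of pooled dN to pooled
#'   dS), `n_pairs`.
#' @export
mean_pairwise_dnds <- function(aln) {
  mm <- ng_matrices(aln)
  pS <- rowSums(mm$SD) / rowSums(mm$SS)
  pN <- rowSums(mm$ND) / rowSums(mm$NS)
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  w <- dN / dS
  ok <- is.finite(w)
  list(mean_omega = mean(w[ok]), mean_dN = mean(dN, na.rm = TRUE),
       mean_dS = mean(dS, na.rm = TRUE),
       pooled_omega = jc_correct(sum(mm$ND) / sum(mm$NS)) /
         jc_correct(sum(mm$SD) / sum(mm$SS)),
       n_pairs = sum(ok))
}

#' Codon-based Z test of selection
#'
#' Tests the overall average of dS - dN (purifying alternative, dN < dS) or
#' dN - dS (positive alternative) across all sequence pairs. The variance
#' of the mean statistic is obtained by bootstrap over codon columns;
#' Z = mean / SE with a one-tailed normal p-value.
#'
#' @param aln codon-aligned nucleotide `or_alignment` with >= 2 sequences.
#' @param alternative `"PURIFYING"` (dN < dS) or `"POSITIVE"` (dN > dS).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed mandatory RNG seed for reproducibility.
#' @return list of class `z_test`: `Z`, `p`, `statistic` (observed mean),
#'   `se`, `alternative`, `n_boot`, `seed`.
#' @export
codon_z_test <- function(aln, alternative = c("PURIFYING", "POSITIVE"),
                         n_boot = 1000L, seed) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(aln) < 2L) stop("need at least two sequences", call. = FALSE)
  mm <- ng_matrices(aln)
  sign <- if (alternative == "PURIFYING") 1 else -1
  stat_from <- function(SDs, NDs, SSs, NSs) {
    dS <- jc_correct(SDs / SSs); dN <- jc_correct(NDs / NSs)
    mean(sign * (dS - dN), na.rm = TRUE)
  }
  obs <- stat_from(rowSums(mm$SD), rowSums(mm$ND), rowSums(mm$SS), rowSums(mm$NS))
  C <- ncol(mm$SD)
  set.seed(seed)
  W <- stats::rmultinom(n_boot, C, rep(1 / C, C))   # codon resampling weights
  bS <- mm$SD %*% W; bN <- mm$ND %*% W
  bSS <- mm$SS %*% W; bNS <- mm$NS %*% W
  dSb <- jc_correct(bS / bSS); dNb <- jc_correct(bN / bNS)
  stat_b <- colMeans(sign * (dSb - dNb), na.rm = TRUE)
  se <- sd(stat_b)
  if (!is.finite(se) || se == 0) {
    warning("zero bootstrap variance; no signal")
    return(structure(list(Z = 0, p = 1, statistic = obs, se = se,
                          alternative = alternative, n_boot = n_boot, seed = seed),
                     class = "z_test"))
  }
  Z <- obs / se
  structure(list(Z = Z, p = pnorm(Z, lower.tail = FALSE), statistic = obs,
                 se = se, alternative = alternative, n_boot = n_boot, seed = seed),
            class = "z_test")
}

#' @export
print.z_test <- function(x, ...) {
  cat(sprintf("codon Z test (%s): Z = %.3f, one-tailed p = %.4g (%d bootstraps)\n",
              x$alternative, x$Z, x$p, x$n_boot))
  invisible(x)
}

#' Counting-based per-codon selection scan
#'
#' Pools the path-averaged synonymous and nonsynonymous differences of
#' every sequence pair per codon column and compares the observed
#' proportions per site class. This is a descriptive counting scan, not a
#' likelihood codon model: it flags codons whose pooled nonsynonymous rate
#' exceeds (class `dN/dS>1`) or falls below (class `dN/dS<1`) the
#' synonymous rate; invariant codons are `NA`.
#'
#' @param aln codon-aligned nucleotide `or_alignment`.
#' @return data.frame: `codon` (1-based), `Nd`, `Sd`, `N_sites`, `S_sites`,
#'   `class`.
#' @export
per_codon_dnds_scan <- function(aln) {
  mm <- ng_matrices(aln)
  Nd <- colSums(mm$ND); Sd <- colSums(mm$SD)
  NS <- colSums(mm$NS); SS <- colSums(mm$SS)
  pN <- ifelse(NS > 0, Nd / NS, NA_real_)
  pS <- ifelse(SS > 0, Sd / SS, NA_real_)
  cls <- rep(NA_character_, length(Nd))
  has_sig <- (Nd + Sd) > 0 & !is.na(pN) & !is.na(pS)
  cls[has_sig & pN > pS] <- "dN/dS>1"
  cls[has_sig & pN < pS] <- "dN/dS<1"
  data.frame(codon = seq_along(Nd), Nd = Nd, Sd = Sd,
             N_sites = NS, S_sites = SS, class = cls,
             stringsAsFactors = FALSE)
}

#' ZZ linkage-disequilibrium statistic
#'
#' Computes r-squared between every pair of retained segregating sites
#' (biallelic, gap- and N-free columns). ZnS is the mean over all pairs,
#' Za the mean over physically adjacent retained sites, and ZZ = Za - ZnS;
#' positive ZZ indicates decay of LD with distance, a hallmark of
#' intragenic recombination.
#'
#' @param aln nucleotide `or_alignment`.
#' @return list of class `zz_stat`: `ZnS`, `Za`, `ZZ`, `n_sites` retained.
#' @export
zz_statistic <- function(aln) {
  m <- alignment_matrix(aln)
  usable <- apply(m, 2, function(col) {
    all(col %in% BASES) && length(unique(col)) == 2L
  })
  sites <- which(usable)
  if (length(sites) < 2L) stop("need at least two biallelic gap-free sites", call. = FALSE)
  X <- vapply(sites, function(j) as.numeric(m[, j] == sort(unique(m[, j]))[1]),
              numeric(nrow(m)))
  R <- suppressWarnings(cor(X))^2
  R[!is.finite(R)] <- 0        # monomorphic-after-encoding guard (cannot occur)
  all_pairs <- R[upper.tri(R)]
  adj <- R[cbind(seq_len(ncol(R) - 1L), seq_len(ncol(R) - 1L) + 1L)]
  ZnS <- mean(all_pairs)
  Za <- mean(adj)
  structure(list(ZnS = ZnS, Za = Za, ZZ = Za - ZnS, n_sites = length(sites)),
            class = "zz_stat")
}

#' @export
print.zz_stat <- function(x, ...) {
  cat(sprintf("ZnS = %.4f, Za = %.4f, ZZ = %.4f (%d segregating sites)\n",
              x$ZnS, x$Za, x$ZZ, x$n_sites))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, order preserving).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by averaging the grid estimates
#' `#\{p > lambda\} / (m (1 - lambda))` over the lambda grid (mean-of-
#' estimates smoother), then computes step-up q-values
#' `q(p_(i)) = min_(j >= i) pi0 m p_(j) / j`, clamped to 1. With pi0 = 1
#' this reduces to the Benjamini-Hochberg adjustment.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda_grid grid in `[0, 1)`; default `seq(0.05, 0.90, 0.05)`.
#' @param pi0 optionally force pi0 (e.g. 1 for the BH reduction).
#' @return list `qvalues` (input order), `pi0`.
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.90, by = 0.05), pi0 = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    if (length(lambda_grid) == 0L || any(lambda_grid < 0 | lambda_grid >= 1)) {
      warning("degenerate lambda grid; falling back to pi0 = 1 (BH-equivalent)")
      pi0 <- 1
    } else {
      est <- vapply(lambda_grid, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
      pi0 <- min(max(mean(est), 1 / m), 1)
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalues = q, pi0 = pi0)
}
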