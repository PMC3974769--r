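PREFERRED_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT", H = "CAT",
  I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT", P = "CCT", Q = "CAA",
  R = "CGT", S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Reference (ancestral) amplicon protein for a topology
#'
#' Deterministic template used as the root of simulations: transmembrane
#' domains are filled with hydrophobic residues and loops with polar ones,
#' the ligand-binding positions carry hydrophobic residues, and the two
#' diagnostic motifs (MAYDRFVAIC, KAFSTCASH) are planted at the end of TM3
#' and the start of TM6.
#'
#' @param topology a `receptor_topology`.
#' @return amino-acid string of length `max(topology$domains$end)`.
#' @export
or_reference_protein <- function(topology = read_topology()) {
  L <- max(topology$domains$end)
  tm_fill <- strsplit("LIVFAMWLVGIT", "")[[1]]
  loop_fill <- strsplit("GSTNEQKRHDP", "")[[1]]
  aa <- character(L)
  for (i in seq_len(nrow(topology$domains))) {
    d <- topology$domains[i, ]
    fill <- if (grepl("^TM", d$name)) tm_fill else loop_fill
    idx <- (d$start + 1L):d$end
    aa[idx] <- rep_len(fill, length(idx))
  }
  hyd <- default_hydrophobic()
  aa[topology$binding_positions + 1L] <-
    rep_len(hyd, length(topology$binding_positions))
  plant <- function(aa, motif, at) {
    m <- strsplit(motif, "")[[1]]
    aa[(at + 1L):(at + length(m))] <- m
    aa
  }
  tm3 <- topology$domains[topology$domains$name == "TM3", ]
  tm6 <- topology$domains[topology$domains$name == "TM6", ]
  aa <- plant(aa, "MAYDRFVAIC", tm3$end - 10L)
  aa <- plant(aa, "KAFSTCASH", tm6$start)
  paste(aa, collapse = "")
}

#' Reference amplicon coding sequence
#' @param topology a `receptor_topology`.
#' @return nucleotide string (3x protein length; frame offset 0).
#' @export
or_reference_cds <- function(topology = read_topology()) {
  aa <- strsplit(or_reference_protein(topology), "")[[1]]
  paste(PREFERRED_CODON[aa], collapse = "")
}

# amino-acid columns whose codons are held under strict constraint
# (the diagnostic motifs; omega forced to 0 there for functional genes)
motif_columns <- function(topology) {
  tm3 <- topology$domains[topology$domains$name == "TM3", ]
  tm6 <- topology$domains[topology$domains$name == "TM6", ]
  c((tm3$end - 10L):(tm3$end - 1L), tm6$start:(tm6$start + 8L))
}

#' Simulation configuration for the birth-and-death repertoire generator
#'
#' Defaults emulate a 14-species mole-rat-like radiation: a fixed species
#' tree with the named genus structure, four deeply diverged ancestral gene
#' lineages (the clade structure), duplication and pseudogenization along
#' branches, codon substitution under mixed omega site classes (rejection
#' sampling: the relative nonsynonymous:synonymous acceptance rate equals
#' the codon class omega), two sequenced individuals per species
#' with up to two alleles per gene copy differing by a few bases, two
#' clones per allele, up to one PCR error base per read, and three deeply
#' divergent outgroup sequences for rooting. Under the default rates,
#' within-species alleles of one gene stay above the 99% identity
#' threshold while orthologous copies in different species (and duplicate
#' copies within a species) fall below their merge thresholds, so the
#' observable gene entities of the truth table are species-local loci.
#'
#' @param species_tree newick file (default: packaged synthetic tree).
#' @param n_ancestral_genes founder gene lineages at the root.
#' @param duplication_rate duplications per gene per unit branch length.
#' @param pseudogenization_prob per-gene probability per unit branch
#'   length of losing function (stop codon or 1-2 base deletion).
#' @param substitution_rate proposed substitutions per site per unit
#'   branch length (realized rate is lower under purifying omega classes).
#' @param omega_classes data.frame `omega`, `proportion` of codon site
#'   classes (proportions sum to 1).
#' @param founder_divergence proposed substitutions per site separating
#'   each founder from the base sequence.
#' @param duplicate_divergence proposed substitutions per site applied to
#'   a newborn duplicate (models the divergence of retained copies).
#' @param individuals_per_species,alleles_per_individual,clones_per_allele
#'   sampling design at the tips.
#' @param allele_max_subs maximum private substitutions per allele.
#' @param pcr_error_bases maximum PCR/sequencing error bases per read (0-2).
#' @param n_outgroups divergent non-OR GPCR-like outgroup sequences
#'   emitted for rooting.
#' @param outgroup_divergence proposed substitutions per site separating
#'   each outgroup from the base sequence.
#' @param seed mandatory RNG seed.
#' @param topology `receptor_topology` defining the amplicon.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(species_tree = system.file("extdata", "bathyergid_tree_synthetic.nwk",
                                                         package = "olfactoR"),
                              n_ancestral_genes = 4L,
                              duplication_rate = 0.05,
                              pseudogenization_prob = 0.15,
                              substitution_rate = 0.04,
                              omega_classes = data.frame(omega = c(0.1, 0.5, 2),
                                                         proportion = c(0.6, 0.3, 0.1)),
                              founder_divergence = 0.40,
                              duplicate_divergence = 0.05,
                              individuals_per_species = 2L,
                              alleles_per_individual = 2L,
                              clones_per_allele = 2L,
                              allele_max_subs = 2L,
                              pcr_error_bases = 1L,
                              n_outgroups = 3L,
                              outgroup_divergence = 0.6,
                              seed = 1L,
                              topology = read_topology()) {
  if (abs(sum(omega_classes$proportion) - 1) > 1e-8)
    stop("omega class proportions must sum to 1", call. = FALSE)
  if (any(c(duplication_rate, pseudogenization_prob, substitution_rate,
            founder_divergence, duplicate_divergence) < 0))
    stop("rates must be non-negative", call. = FALSE)
  if (!pcr_error_bases %in% 0:2) stop("pcr_error_bases must be 0, 1 or 2", call. = FALSE)
  if (alleles_per_individual > 2L) stop("at most two alleles per gene copy", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  structure(list(species_tree = species_tree, n_ancestral_genes = n_ancestral_genes,
                 duplication_rate = duplication_rate,
                 pseudogenization_prob = pseudogenization_prob,
                 substitution_rate = substitution_rate, omega_classes = omega_classes,
                 founder_divergence = founder_divergence,
                 duplicate_divergence = duplicate_divergence,
                 individuals_per_species = individuals_per_species,
                 alleles_per_individual = alleles_per_individual,
                 clones_per_allele = clones_per_allele,
                 allele_max_subs = allele_max_subs,
                 pcr_error_bases = pcr_error_bases,
                 n_outgroups = as.integer(n_outgroups),
                 outgroup_divergence = outgroup_divergence,
                 seed = as.integer(seed),
                 topology = topology, omega_override = integer(0)),
            class = "sim_config")
}

#' Force an omega value at chosen codons
#'
#' Overrides the site-class omega at the listed codons, e.g. to plant a
#' positively selected codon the per-codon scan should recover.
#'
#' @param config a `sim_config`.
#' @param target_codons 1-based codon indices within the amplicon.
#' @param omega_target omega value for those codons.
#' @return modified `sim_config`.
#' @export
plant_selection <- function(config, target_codons, omega_target) {
  n_codon <- max(config$topology$domains$end)
  if (length(target_codons) == 0L) return(config)
  if (any(target_codons < 1L | target_codons > n_codon))
    stop("target codon index out of range", call. = FALSE)
  ov <- config$omega_override
  ov[as.character(target_codons)] <- omega_target
  config$omega_override <- ov
  config
}

# propose-and-accept substitution sweep on a character vector sequence.
# omega_codon: per-codon omega (functional sequences only); pseudogenes
# accept everything and may gain stops.
mutate_seq <- function(s, n_att, omega_codon, functional) {
  if (n_att == 0L) return(s)
  idx <- which(s != "-")
  if (length(idx) == 0L) return(s)
  gc <- genetic_code()
  for (k in seq_len(n_att)) {
    pos <- idx[sample.int(length(idx), 1L)]
    alt <- sample(setdiff(BASES, s[pos]), 1L)
    if (!functional) { s[pos] <- alt; next }
    ci <- (pos - 1L) %/% 3L + 1L
    cols <- (3L * ci - 2L):(3L * ci)
    codon <- s[cols]
    if (any(codon == "-")) next
    new_codon <- codon
    new_codon[cols == pos] <- alt
    aa_old <- gc[[paste(codon, collapse = "")]]
    aa_new <- gc[[paste(new_codon, collapse = "")]]
    if (is.null(aa_new) || aa_new == "*") next
    # relative nonsyn:syn acceptance equals omega on both sides of 1:
    # omega <= 1 thins nonsynonymous changes, omega > 1 thins synonymous ones
    w <- omega_codon[ci]
    p_acc <- if (aa_old == aa_new) min(1, 1 / max(w, 1e-12)) else min(1, w)
    if (runif(1) < p_acc) s[pos] <- alt
  }
  s
}

# add exactly n random substitutions (used for allele and PCR variation)
add_random_subs <- function(s, n, avoid_stops = FALSE, max_tries = 200L) {
  if (n == 0L) return(s)
  gc <- genetic_code()
  idx <- which(s != "-")
  done <- 0L; tries <- 0L
  while (done < n && tries < max_tries) {
    tries <- tries + 1L
    pos <- idx[sample.int(length(idx), 1L)]
    alt <- sample(setdiff(BASES, s[pos]), 1L)
    if (avoid_stops) {
      ci <- (pos - 1L) %/% 3L + 1L
      cols <- (3L * ci - 2L):(3L * ci)
      codon <- s[cols]
      if (!any(codon == "-")) {
        new_codon <- codon
        new_codon[cols == pos] <- alt
        aa <- gc[[paste(new_codon, collapse = "")]]
        if (is.null(aa) || aa == "*") next
      }
    }
    s[pos] <- alt
    done <- done + 1L
  }
  s
}

# plant a pseudogenizing lesion: premature stop codon (p = 0.6) or a
# 1-2 base deletion
plant_lesion <- function(s, n_codon) {
  if (runif(1) < 0.6) {
    repeat {
      ci <- sample(2:(n_codon - 1L), 1L)
      cols <- (3L * ci - 2L):(3L * ci)
      if (!any(s[cols] == "-")) break
    }
    s[cols] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
    attr(s, "event") <- sprintf("stop@codon%d", ci)
  } else {
    len <- sample(1:2, 1L)
    ungapped <- which(s != "-")
    start <- sample(seq_len(length(ungapped) - len), 1L)
    s[ungapped[start:(start + len - 1L)]] <- "-"
    attr(s, "event") <- sprintf("del%d@%d", len, ungapped[start] - 1L)
  }
  s
}

#' Simulate a ground-truthed OR repertoire
#'
#' Gene lineages evolve along the species tree by duplication,
#' codon-constrained substitution and pseudogenization; each tip species is
#' then sampled as in an amplicon study (individuals, alleles, clones, PCR
#' error). The output alignment shares the topology's coordinate system
#' (deletions appear as gaps), so it is consumed directly by the analysis
#' stages.
#'
#' @param config a `sim_config`.
#' @return list of class `or_simulation`: `alignment` (nucleotide
#'   `or_alignment`, outgroups included), `truth` (per-read data.frame:
#'   `id, gene, status, clade, events`; gene ids are species-local loci,
#'   outgroup rows labeled OUTGROUP), `outgroups` (their ids), `omega`
#'   (per-codon omega vector), `config`.
#' @export
simulate_repertoire <- function(config = simulation_config()) {
  set.seed(config$seed)
  tree <- if (inherits(config$species_tree, "phylo")) config$species_tree
          else ape::read.tree(config$species_tree)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("invalid species tree", call. = FALSE)
  topo <- config$topology
  n_codon <- max(topo$domains$end)
  base <- strsplit(or_reference_cds(topo), "")[[1]]

  # per-codon omega: site classes, motif codons pinned at 0, overrides last
  cls <- sample.int(nrow(config$omega_classes), n_codon, replace = TRUE,
                    prob = config$omega_classes$proportion)
  omega <- config$omega_classes$omega[cls]
  omega[motif_columns(topo) + 1L] <- 0
  if (length(config$omega_override) > 0L)
    omega[as.integer(names(config$omega_override))] <- config$omega_override

  founders <- lapply(seq_len(config$n_ancestral_genes), function(i) {
    list(gene = sprintf("F%d", i), clade = sprintf("F%d", i),
         seq = mutate_seq(base, round(config$founder_divergence * length(base)),
                          omega, TRUE),
         status = "FUNCTIONAL", events = character(0))
  })
  dup_counter <- new.env(parent = emptyenv()); dup_counter$n <- 0L

  evolve_edge <- function(genes, t) {
    out <- list()
    for (g in genes) {
      n_dup <- rpois(1L, config$duplication_rate * t)
      g$seq <- mutate_seq(g$seq, rpois(1L, config$substitution_rate * sum(g$seq != "-") * t),
                          omega, g$status == "FUNCTIONAL")
      if (g$status == "FUNCTIONAL" &&
          runif(1) < 1 - (1 - config$pseudogenization_prob)^t) {
        g$seq <- plant_lesion(g$seq, n_codon)
        g$events <- c(g$events, attr(g$seq, "event"))
        attr(g$seq, "event") <- NULL
        g$status <- "PSEUDOGENE"
      }
      out[[length(out) + 1L]] <- g
      for (k in seq_len(n_dup)) {
        dup_counter$n <- dup_counter$n + 1L
        d <- g
        d$gene <- sprintf("%s.d%d", g$gene, dup_counter$n)
        d$seq <- mutate_seq(d$seq, round(config$duplicate_divergence * sum(d$seq != "-")),
                            omega, d$status == "FUNCTIONAL")
        out[[length(out) + 1L]] <- d
      }
    }
    out
  }

  reads <- list(); truth <- list()
  sample_tip <- function(genes, code) {
    for (ind in seq_len(config$individuals_per_species)) {
      clone_k <- 0L
      for (g in genes) {
        for (a in seq_len(config$alleles_per_individual)) {
          allele <- add_random_subs(g$seq, sample.int(config$allele_max_subs + 1L, 1L) - 1L,
                                    avoid_stops = g$status == "FUNCTIONAL")
          for (cl in seq_len(config$clones_per_allele)) {
            clone_k <- clone_k + 1L
            read <- add_random_subs(allele,
                                    if (config$pcr_error_bases > 0L)
                                      sample.int(config$pcr_error_bases + 1L, 1L) - 1L else 0L,
                                    avoid_stops = FALSE)
            lab <- sprintf("%s%d_%s%02d", code, ind,
                           LETTERS[(clone_k - 1L) %/% 99L + 1L], (clone_k - 1L) %% 99L + 1L)
            reads[[lab]] <<- paste(read, collapse = "")
            truth[[lab]] <<- c(lab, sprintf("%s@%s", g$gene, code), g$status,
                               g$clade, paste(g$events, collapse = ";"))
          }
        }
      }
    }
  }

  recurse <- function(node, genes) {
    kids <- tree$edge[tree$edge[, 1] == node, , drop = FALSE]
    for (r in seq_len(nrow(kids))) {
      child <- kids[r, 2]
      t <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == child)]
      g2 <- evolve_edge(genes, t)
      if (child <= length(tree$tip.label)) sample_tip(g2, tree$tip.label[child])
      else recurse(child, g2)
    }
  }
  root <- length(tree$tip.label) + 1L
  recurse(root, founders)

  # deeply divergent GPCR-like outgroups for rooting
  og_ids <- character(0)
  if (config$n_outgroups > 0L) {
    og_anc <- mutate_seq(base, round(config$outgroup_divergence * length(base)),
                         rep(1, n_codon), TRUE)
    for (k in seq_len(config$n_outgroups)) {
      lab <- sprintf("OUT%d", k)
      og_ids <- c(og_ids, lab)
      og <- mutate_seq(og_anc, round(0.05 * length(base)), rep(1, n_codon), TRUE)
      reads[[lab]] <- paste(og, collapse = "")
      truth[[lab]] <- c(lab, "OUTGROUP", "FUNCTIONAL", "OUTGROUP", "")
    }
  }

  aln <- or_alignment(unlist(reads), alphabet = "DNA")
  tm <- do.call(rbind, unname(truth))
  truth_df <- data.frame(id = tm[, 1], gene = tm[, 2], status = tm[, 3],
                         clade = tm[, 4], events = tm[, 5],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(alignment = aln, truth = truth_df, outgroups = og_ids,
                 omega = omega, config = config),
            class = "or_simulation")
}

#' @export
print.or_simulation <- function(x, ...) {
  cat(sprintf("<or_simulation> %d reads, %d true genes (%.0f%% pseudogene reads), seed %d\n",
              nrow(x$truth), length(unique(x$truth$gene)),
              100 * mean(x$truth$status == "PSEUDOGENE"), x$config$seed))
  invisible(x)
}

#' Simulate a codon alignment under a single omega
#'
#' Star-phylogeny codon alignment: a random stop-free ancestor evolves
#' independently into `n_seq` sequences; substitution proposals are uniform
#' over sites and target bases, synonymous changes always accepted,
#' nonsynonymous accepted with probability min(1, omega). This matches the
#' uniform-pathway assumptions of the counting statistics and is the
#' generator used for their calibration tests.
#'
#' @param n_seq number of sequences.
#' @param n_codons codons per sequence.
#' @param omega nonsynonymous acceptance ratio (scalar or per-codon).
#' @param mu proposed substitutions per site per lineage.
#' @param seed RNG seed.
#' @return nucleotide `or_alignment`.
#' @export
simulate_codon_alignment <- function(n_seq, n_codons, omega, mu = 0.1, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  omega <- rep_len(omega, n_codons)
  codons <- all_codons()
  ok <- codon_aa(codons) != "*"
  anc <- strsplit(paste(sample(codons[ok], n_codons, replace = TRUE), collapse = ""),
                  "")[[1]]
  seqs <- vapply(seq_len(n_seq), function(i) {
    paste(mutate_seq(anc, rpois(1L, mu * 3 * n_codons), omega, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("S%03d", seq_len(n_seq))
  or_alignment(seqs, alphabet = "DNA")
}

#' Synthetic per-species ecogroup table
#'
#' Draws per-species pseudogene proportions around group truths with
#' Gaussian noise (clamped to [0, 1]); optionally realizes counts
#' binomially over `n_genes` genes per species. With `noise_sd = 0` and
#' `binomial = FALSE` the group means equal the truths exactly.
#'
#' @param n_species_per_group named integer vector (names = ecogroups).
#' @param true_props named numeric vector of true pseudogene proportions.
#' @param noise_sd standard deviation of the per-species deviation.
#' @param seed RNG seed.
#' @param n_genes genes per species (counts scale).
#' @param binomial realize counts binomially instead of deterministically.
#' @return data.frame `species, ecogroup, n_functional, n_pseudogene`.
#' @export
make_ecogroup_fixture <- function(n_species_per_group, true_props, noise_sd = 0.05,
                                  seed = 1L, n_genes = 100L, binomial = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (any(true_props < 0 | true_props > 1))
    stop("true proportions must lie in [0, 1]", call. = FALSE)
  stopifnot(all(names(n_species_per_group) %in% names(true_props)))
  set.seed(seed)
  rows <- list()
  for (g in names(n_species_per_group)) {
    for (i in seq_len(n_species_per_group[[g]])) {
      p <- min(max(true_props[[g]] + stats::rnorm(1, 0, noise_sd), 0), 1)
      npseudo <- if (binomial) rbinom(1, n_genes, p) else round(p * n_genes)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("%s_sp%02d", gsub("[^A-Za-z0-9]", "", g), i),
        ecogroup = g, n_functional = n_genes - npseudo, n_pseudogene = npseudo,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
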