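#' Pipeline run configuration
#'
#' Collects the file paths, thresholds and seeds of a full repertoire run.
#' `input` may be a FASTA path or an `or_alignment`; metadata and topology
#' default to the packaged fixtures.
#'
#' @param input aligned nucleotide FASTA path or `or_alignment`.
#' @param outdir output directory (created).
#' @param metadata `species_metadata` or TSV path.
#' @param topology `receptor_topology` or TSV path.
#' @param thresholds allele identity thresholds.
#' @param max_diff sequencing-variant collapse limit.
#' @param min_support,min_size clade extraction thresholds.
#' @param n_boot bootstrap replicates for the tree stage.
#' @param z_boot bootstrap replicates for the clade Z tests.
#' @param outgroups outgroup tip ids for rooting (midpoint fallback).
#' @param seed mandatory seed for all stochastic stages.
#' @param verbose log stage counts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, outdir, metadata = read_species_metadata(),
                            topology = read_topology(),
                            thresholds = default_thresholds(), max_diff = 2L,
                            min_support = 97, min_size = 2L, n_boot = 200L,
                            z_boot = 1000L, outgroups = character(0), seed,
                            verbose = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(attr(x, "class"))
  if (is_path(input) && !file.exists(input))
    stop(sprintf("input FASTA not found: %s", input), call. = FALSE)
  if (is_path(metadata) && !file.exists(metadata))
    stop(sprintf("metadata not found: %s", metadata), call. = FALSE)
  if (is_path(topology) && !file.exists(topology))
    stop(sprintf("topology not found: %s", topology), call. = FALSE)
  structure(list(input = input, outdir = outdir, metadata = metadata,
                 topology = topology, thresholds = thresholds,
                 max_diff = max_diff, min_support = min_support,
                 min_size = min_size, n_boot = n_boot, z_boot = z_boot,
                 outgroups = outgroups, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full repertoire analysis pipeline
#'
#' Stages, in dependency order: classify every read; collapse sequencing
#' variants; build the bootstrap NJ tree of unique sequences; merge alleles
#' into genes against the tree; extract well-supported clades and summarise
#' their functional composition; map variability and binding-pocket
#' statistics on the functional genes; run the clade Z tests and the ZZ
#' recombination check; tabulate per-species pseudogene proportions with
#' pairwise ecogroup tests; write trait-labeled trees. Every output is
#' written under `outdir` and listed in `manifest.json` with md5 checksums,
#' so a rerun with the same config and seed is byte-reproducible.
#'
#' @param config a `pipeline_config`.
#' @return list of class `pipeline_result` with the in-memory stage
#'   results and the manifest data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(attr(x, "class"))
  md <- if (is_path(config$metadata)) read_species_metadata(config$metadata)
        else config$metadata
  topo <- if (is_path(config$topology)) read_topology(config$topology)
          else config$topology
  aln <- if (is_path(config$input)) read_alignment(config$input, "DNA")
         else config$input
  outfile <- function(name) file.path(config$outdir, name)
  written <- character(0)
  put_tsv <- function(df, name) {
    write.table(df, outfile(name), sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, name)
  }
  put_json <- function(x, name) {
    jsonlite::write_json(x, outfile(name), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, name)
  }

  # classify -> dedupe
  classification <- classify_alignment(aln, topology = topo, verbose = config$verbose)
  put_tsv(classification, "classification.tsv")
  dd <- dedupe_identical(aln, max_diff = config$max_diff, verbose = config$verbose)
  put_tsv(dd$membership, "dedupe_membership.tsv")
  uniq <- dd$alignment
  statuses <- setNames(classification$status, classification$id)[names(uniq)]
  og <- intersect(config$outgroups, names(uniq))
  ingroup <- setdiff(names(uniq), og)

  # tree of unique sequences, rooted before support counting
  rooted <- bootstrap_support(uniq, n = config$n_boot, seed = config$seed,
                              root = if (length(og) > 0L) og else "midpoint")
  ape::write.tree(rooted, outfile("tree.nwk"))
  written <- c(written, "tree.nwk")

  # allele merging on the ingroup (outgroups serve rooting only)
  parsed <- parse_sequence_id(ingroup, md)
  genes <- merge_alleles(or_alignment(unclass(uniq)[ingroup], alphabet = "DNA"),
                         statuses[ingroup], parsed, rooted,
                         thresholds = config$thresholds, verbose = config$verbose)
  put_tsv(as.data.frame(genes), "genes.tsv")
  put_tsv(attr(genes, "membership"), "gene_membership.tsv")
  write_fasta(attr(genes, "consensus"), outfile("consensus.fasta"))
  written <- c(written, "consensus.fasta")

  # clades on the sequence tree; gene clade = clade of its members
  clades <- extract_clades(rooted, min_support = config$min_support,
                           min_size = config$min_size, outgroups = config$outgroups)
  put_tsv(as.data.frame(clades), "clades.tsv")
  membership <- attr(genes, "membership")
  leaf_clade <- setNames(clades$clade, clades$leaf)
  gene_clade <- vapply(split(membership$seq_id, membership$gene_id), function(ids) {
    tab <- table(leaf_clade[ids])
    names(tab)[which.max(tab)]
  }, character(1))
  gene_status <- setNames(genes$status, genes$gene_id)
  csum <- clade_summary(
    structure(data.frame(leaf = names(gene_clade), clade = unname(gene_clade),
                         stringsAsFactors = FALSE),
              supports = attr(clades, "supports"),
              class = c("clade_assignment", "data.frame")),
    gene_status)
  put_tsv(csum, "clade_summary.tsv")

  # variability on functional gene consensus sequences
  cons <- attr(genes, "consensus")
  fun_ids <- genes$gene_id[genes$status == "FUNCTIONAL"]
  stats_out <- list()
  if (length(fun_ids) >= 2L) {
    fun_aln <- or_alignment(cons[fun_ids], alphabet = "DNA")
    aa <- translate_alignment(fun_aln)
    profile <- site_variability(aa, topo)
    put_tsv(profile, "site_profile.tsv")
    bstats <- binding_site_stats(profile, topo)
    bstats$hydrophobic_fraction <-
      hydrophobic_fraction(aa, topo$binding_positions)
    motifs <- clade_binding_motifs(aa, gene_clade[fun_ids], topo)
    put_tsv(motifs$table, "clade_binding_motifs.tsv")
    bstats$n_cross_clade_conserved <- motifs$n_conserved
    put_json(bstats, "binding_stats.json")
    stats_out$binding <- bstats
    stats_out$profile <- profile
  }

  # selection: per-clade purifying Z tests on functional genes; ZZ check
  ztests <- list()
  for (lab in sort(unique(gene_clade))) {
    if (lab == "UNASSIGNED") next
    ids <- intersect(names(gene_clade)[gene_clade == lab], fun_ids)
    if (length(ids) < 2L) next
    zt <- codon_z_test(or_alignment(cons[ids], alphabet = "DNA"),
                       "PURIFYING", n_boot = config$z_boot, seed = config$seed)
    ztests[[lab]] <- data.frame(clade = lab, n_genes = length(ids),
                                Z = zt$Z, p = zt$p)
  }
  if (length(ztests) > 0L) put_tsv(do.call(rbind, ztests), "clade_ztests.tsv")
  zz <- tryCatch(zz_statistic(or_alignment(unclass(uniq)[ingroup], alphabet = "DNA")),
                 error = function(e) NULL)
  if (!is.null(zz)) put_json(zz[c("ZnS", "Za", "ZZ", "n_sites")], "zz.json")

  # ecogroup comparison from per-species gene counts
  sp_rows <- do.call(rbind, lapply(md$species_code, function(code) {
    has <- vapply(strsplit(genes$species_list, ","), function(s) code %in% s, logical(1))
    data.frame(species = code,
               n_functional = sum(has & genes$status == "FUNCTIONAL"),
               n_pseudogene = sum(has & genes$status == "PSEUDOGENE"),
               stringsAsFactors = FALSE)
  }))
  eco <- suppressWarnings(
    pseudogene_proportions(sp_rows[sp_rows$n_functional + sp_rows$n_pseudogene > 0, ],
                           data.frame(species = md$species_code,
                                      ecogroup = md$ecogroup)))
  put_tsv(eco$species, "ecogroup_species.tsv")
  put_tsv(eco$groups, "ecogroup_summary.tsv")
  tests <- if (nrow(eco$groups) >= 2L) pairwise_wilcoxon(eco) else NULL
  if (!is.null(tests)) put_tsv(tests$pairs, "ecogroup_tests.tsv")

  # trait-labeled trees (branch-site foreground dialect), both polarities
  ingroup_tree <- if (length(og) > 0L) ape::drop.tip(rooted, og) else rooted
  for (fg in c("Social", "Solitary")) {
    ok <- tryCatch({
      lp <- label_partitions(ingroup_tree, md, "sociality", fg)
      writeLines(lp$newick, outfile(sprintf("tree_foreground_%s.nwk", tolower(fg))))
      TRUE
    }, error = function(e) FALSE)
    if (ok) written <- c(written, sprintf("tree_foreground_%s.nwk", tolower(fg)))
  }

  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(file.path(config$outdir, written))),
                         stringsAsFactors = FALSE)
  put_json(manifest, "manifest.json")
  structure(list(classification = classification, unique = uniq, tree = rooted,
                 genes = genes, clades = clades, clade_summary = csum,
                 stats = stats_out, ztests = ztests, zz = zz, ecogroup = eco,
                 ecogroup_tests = tests, manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d reads -> %d unique -> %d genes (%d functional); %d clades\n",
              nrow(x$classification), length(x$unique), nrow(x$genes),
              sum(x$genes$status == "FUNCTIONAL"),
              length(attr(x$clades, "supports"))))
  invisible(x)
}
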