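#' Pairwise identity and difference-count matrices
#'
#' Identity is nucleotide identity over pairwise-deleted columns: a column
#' contributes to a pair only when both rows carry an unambiguous base
#' (gaps and N excluded). `diff_counts` counts the differing compared
#' columns; `gap_diffs` counts columns where exactly one row is gapped,
#' which matter when deciding whether two reads are sequencing variants of
#' the same molecule.
#'
#' @param aln nucleotide `or_alignment`.
#' @return list of class `or_identity` with `ids`, `identity`,
#'   `diff_counts`, `gap_diffs`, `compared`.
#' @export
identity_matrix <- function(aln) {
  m <- alignment_matrix(aln)
  V <- (m %in% c("A", "C", "G", "T")) + 0
  dim(V) <- dim(m)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    Ib <- (m == b) + 0
    matches <- matches + tcrossprod(Ib)
  }
  compared <- tcrossprod(V)
  G <- (m == "-") + 0
  gap_diffs <- tcrossprod(G, V) + tcrossprod(V, G)
  identity <- matches / compared
  identity[compared == 0] <- NA_real_
  diag(identity) <- 1
  diffs <- compared - matches
  dimnames(identity) <- dimnames(diffs) <- dimnames(gap_diffs) <-
    dimnames(compared) <- list(rownames(m), rownames(m))
  structure(list(ids = rownames(m), identity = identity,
                 diff_counts = diffs, gap_diffs = gap_diffs, compared = compared),
            class = "or_identity")
}

#' @export
print.or_identity <- function(x, ...) {
  cat(sprintf("<or_identity> %d sequences, mean identity %.3f\n",
              length(x$ids), mean(x$identity[upper.tri(x$identity)], na.rm = TRUE)))
  invisible(x)
}

# connected components of a logical adjacency matrix; returns integer labels
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Collapse sequencing variants into unique sequences
#'
#' Reads within `max_diff` differing sites of each other (transitive
#' closure) are treated as the same molecule, attributing the differences
#' to PCR or sequencing error. A column where one read has a base and the
#' other a gap counts as a difference, so short indel artifacts also
#' collapse. The surviving representative is the lexicographically first id
#' of each group.
#'
#' @param aln nucleotide `or_alignment`.
#' @param max_diff maximum differing sites treated as identity (default 2).
#' @param count_gaps count base-vs-gap columns as differences.
#' @param verbose log counts.
#' @return list with `alignment` (representatives, input order),
#'   `membership` (data.frame `id`, `representative`).
#' @export
dedupe_identical <- function(aln, max_diff = 2L, count_gaps = TRUE, verbose = FALSE) {
  idm <- identity_matrix(aln)
  d <- idm$diff_counts + if (count_gaps) idm$gap_diffs else 0
  comp <- adjacency_components(d <= max_diff)
  ids <- idm$ids
  rep_of <- vapply(split(ids, comp), function(g) sort(g)[1], character(1))
  membership <- data.frame(id = ids, representative = rep_of[as.character(comp)],
                           row.names = NULL, stringsAsFactors = FALSE)
  keep <- ids[ids %in% rep_of]
  or_log("dedupe", length(ids), length(keep),
         dropped = sprintf("%s merged into %s (<= %d differences)",
                           setdiff(ids, keep),
                           membership$representative[match(setdiff(ids, keep), membership$id)],
                           max_diff),
         verbose = verbose)
  list(alignment = or_alignment(unclass(aln)[keep], alphabet = "DNA"),
       membership = membership)
}

#' Default hierarchical identity thresholds for allele merging
#' @export
default_thresholds <- function() {
  c(same_species = 0.99, same_genus = 0.98, cross_genus = 0.96)
}

#' Provisional allele clusters under hierarchical identity cut-offs
#'
#' Two sequences are provisionally alleles of the same gene when their
#' pairwise identity reaches the threshold for their taxonomic relation:
#' 99% within a species, 98% between species of the same genus, 96% across
#' genera. Clusters are the connected components of this graph
#' (single-linkage), so non-transitive components are possible and are
#' resolved later against the tree.
#'
#' @param idm an `or_identity`.
#' @param parsed parsed identifiers (from [parse_sequence_id()]) covering
#'   every id in `idm`.
#' @param thresholds named vector, see [default_thresholds()].
#' @return list of class `or_clusters` with `members` (list of id vectors),
#'   `edges` (logical adjacency), `ids`.
#' @export
cluster_alleles <- function(idm, parsed, thresholds = default_thresholds()) {
  ids <- idm$ids
  miss <- setdiff(ids, parsed$id)
  if (length(miss) > 0L)
    stop(sprintf("no metadata for sequence(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  sp <- parsed$species_code[match(ids, parsed$id)]
  gen <- parsed$genus[match(ids, parsed$id)]
  same_sp <- outer(sp, sp, "==")
  same_gen <- outer(gen, gen, "==")
  thr <- matrix(thresholds[["cross_genus"]], length(ids), length(ids))
  thr[same_gen] <- thresholds[["same_genus"]]
  thr[same_sp] <- thresholds[["same_species"]]
  edges <- !is.na(idm$identity) & idm$identity >= thr
  diag(edges) <- TRUE
  comp <- adjacency_components(edges)
  members <- split(ids, comp)
  members <- members[order(vapply(members, function(g) sort(g)[1], character(1)))]
  structure(list(members = unname(members), edges = edges, ids = ids),
            class = "or_clusters")
}

#' @export
print.or_clusters <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("<or_clusters> %d sequences in %d clusters (max size %d)\n",
              length(x$ids), length(x$members), max(sizes)))
  invisible(x)
}

# maximal tree-consistent threshold-clique groups within a member set.
# Bottom-up: an internal node forms a group when all its descendant tips lie
# in the member set and satisfy all pairwise identity edges.
tree_clique_groups <- function(members, tree, edges) {
  if (length(members) == 1L) return(list(members))
  tips <- match(members, tree$tip.label)
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), type = "tips")
  is_clique <- function(g) all(edges[g, g] | diag(length(g)) > 0)
  cand <- list()
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    dt <- desc[[node]]
    if (all(dt %in% tips)) {
      g <- tree$tip.label[dt]
      if (is_clique(g)) cand[[length(cand) + 1L]] <- g
    }
  }
  cand <- cand[order(-lengths(cand))]
  taken <- character(0)
  groups <- list()
  for (g in cand) {
    if (!any(g %in% taken)) {
      groups[[length(groups) + 1L]] <- g
      taken <- c(taken, g)
    }
  }
  for (m in setdiff(members, taken)) groups[[length(groups) + 1L]] <- m
  groups
}

# split a member set recursively at the root of its induced subtree until no
# individual contributes more than two sequences (duplicate gene copies).
split_copies <- function(members, tree, individual_of) {
  over <- function(g) any(table(individual_of[g]) > 2L)
  if (!over(members) || length(members) < 2L) return(list(members))
  tips <- match(members, tree$tip.label)
  mrca <- ape::getMRCA(tree, tips)
  if (is.null(mrca)) return(list(members))
  kids <- tree$edge[tree$edge[, 1] == mrca, 2]
  desc <- phangorn::Descendants(tree, kids, type = "tips")
  grp <- lapply(desc, function(d) members[tips %in% d])
  grp <- grp[lengths(grp) > 0L]
  if (length(grp) < 2L) return(list(members))
  unlist(lapply(grp, split_copies, tree = tree, individual_of = individual_of),
         recursive = FALSE)
}

#' Resolve provisional clusters into final genes
#'
#' Applies, in order: (a) clusters mixing functional and pseudogene
#' sequences are split by status (a duplication followed by
#' pseudogenisation); (b) non-transitive components (A=B, B=C, A!=C) are
#' re-partitioned so that merged sequences form tree-consistent groups that
#' satisfy every pairwise identity edge; (c) when one individual
#' contributes more than two sequences to a gene, the gene is split into
#' two copies along the deepest split of the members' subtree.
#'
#' @param clusters an `or_clusters`.
#' @param tree `phylo` tree whose tips include every clustered id.
#' @param statuses named character vector id -> FUNCTIONAL/PSEUDOGENE.
#' @param parsed parsed identifiers (individual = species_code +
#'   individual number).
#' @return list of final member id vectors.
#' @export
resolve_ambiguities <- function(clusters, tree, statuses, parsed) {
  miss <- setdiff(clusters$ids, tree$tip.label)
  if (length(miss) > 0L)
    stop(sprintf("id(s) missing from tree: %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(clusters$ids %in% names(statuses)))
    stop("every clustered id needs a functional status", call. = FALSE)
  individual_of <- setNames(paste0(parsed$species_code, parsed$individual), parsed$id)

  is_clique <- function(g) all(clusters$edges[g, g] | diag(length(g)) > 0)
  final <- list()
  for (g in clusters$members) {
    by_status <- split(g, statuses[g])                       # (a)
    for (h in by_status) {
      # (b) applies only where transitivity failed; transitive clusters
      # are kept whole, as the identity rule alone settles them
      cliques <- if (is_clique(h)) list(h)
                 else tree_clique_groups(h, tree, clusters$edges)
      for (q in cliques) {
        final <- c(final, split_copies(q, tree, individual_of)) # (c)
      }
    }
  }
  final[order(vapply(final, function(g) sort(g)[1], character(1)))]
}

#' Majority-rule consensus of an aligned cluster
#'
#' Per-column majority residue, gaps counted as residues; ties broken by
#' the alphabetically first candidate (`-` sorts before `A`).
#'
#' @param seqs named character vector of aligned sequences (cluster rows).
#' @return single consensus string.
#' @export
consensus_sequence <- function(seqs) {
  if (length(seqs) == 0L) stop("empty cluster", call. = FALSE)
  if (length(seqs) == 1L) return(unname(unclass(seqs)[1]))
  m <- do.call(rbind, strsplit(toupper(unclass(seqs)), ""))
  paste(apply(m, 2, function(col) {
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]
  }), collapse = "")
}

#' Merge alleles into unique OR genes
#'
#' Runs the full merging stage: hierarchical-threshold clustering of the
#' deduplicated sequences, tree-based resolution of status mixtures,
#' non-transitive components and duplicate copies, and per-gene consensus
#' calling.
#'
#' @param aln deduplicated nucleotide `or_alignment`.
#' @param statuses named character vector id -> status.
#' @param parsed parsed identifiers.
#' @param tree `phylo` with all ids as tips.
#' @param thresholds identity thresholds, see [default_thresholds()].
#' @param verbose log counts.
#' @return object of class `or_genes`: data.frame `gene_id, status,
#'   n_members, species_list`, with `membership` (data.frame) and
#'   `consensus` (named character vector) attributes.
#' @export
merge_alleles <- function(aln, statuses, parsed, tree,
                          thresholds = default_thresholds(), verbose = FALSE) {
  idm <- identity_matrix(aln)
  clus <- cluster_alleles(idm, parsed, thresholds)
  final <- resolve_ambiguities(clus, tree, statuses, parsed)
  gene_id <- sprintf("ORG%03d", seq_along(final))
  cons <- vapply(final, function(g) consensus_sequence(unclass(aln)[g]), character(1))
  names(cons) <- gene_id
  sp <- function(g) paste(sort(unique(parsed$species_code[match(g, parsed$id)])),
                          collapse = ",")
  tab <- data.frame(
    gene_id = gene_id,
    status = vapply(final, function(g) unname(statuses[g[1]]), character(1)),
    n_members = lengths(final),
    species_list = vapply(final, sp, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  membership <- data.frame(
    seq_id = unlist(final),
    gene_id = rep(gene_id, lengths(final)),
    status = unname(statuses[unlist(final)]),
    row.names = NULL, stringsAsFactors = FALSE)
  or_log("cluster", length(aln), nrow(tab), verbose = verbose)
  structure(tab, membership = membership, consensus = cons,
            class = c("or_genes", "data.frame"))
}

#' @export
summary.or_genes <- function(object, ...) {
  cat(sprintf("%d genes from %d sequences: %d FUNCTIONAL, %d PSEUDOGENE\n",
              nrow(object), nrow(attr(object, "membership")),
              sum(object$status == "FUNCTIONAL"), sum(object$status == "PSEUDOGENE")))
  invisible(object)
}
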