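as_DNAbin <- function(aln) {
  m <- alignment_matrix(aln)
  ape::as.DNAbin(tolower(m))
}

#' Tamura-Nei (TN93) distance matrix
#'
#' Pairwise TN93 distances with empirical base frequencies; positions with
#' gaps or ambiguity codes are dropped per pair (pairwise deletion).
#' Saturated pairs yield `NaN` and are flagged.
#'
#' @param aln nucleotide `or_alignment` (>= 2 rows).
#' @param model `"TN93"` or `"P_DISTANCE"` (raw proportion of differences).
#' @param pairwise_deletion drop gapped positions per pair (default TRUE).
#' @return a `dist`-like square matrix with attribute `model`; `NaN`
#'   entries mark saturated pairs.
#' @export
tn93_distance <- function(aln, model = c("TN93", "P_DISTANCE"), pairwise_deletion = TRUE) {
  model <- match.arg(model)
  if (length(aln) < 2L) stop("need at least two sequences", call. = FALSE)
  d <- ape::dist.dna(as_DNAbin(aln), model = if (model == "TN93") "TN93" else "raw",
                     pairwise.deletion = pairwise_deletion, as.matrix = TRUE)
  attr(d, "model") <- model
  attr(d, "saturated") <- any(!is.finite(d))
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard NJ agglomeration; negative branch-length artifacts are clamped
#' to zero and the deficit transferred to the sibling branch, preserving
#' tip-to-tip path lengths where possible.
#'
#' @param d square distance matrix (finite entries).
#' @return unrooted `phylo`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d)))
    stop("distance matrix has non-finite entries; resolve saturated pairs first",
         call. = FALSE)
  if (nrow(d) < 3L) stop("need at least three taxa", call. = FALSE)
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0L)
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n` times; the support of each
#' internal edge is the percentage of replicate trees containing the same
#' bipartition, stored in `node.label`.
#'
#' Supports are counted on the tree as returned, so when rooting is
#' requested (outgroups or midpoint) it is applied to the reference tree
#' before counting; re-rooting a support-labeled tree afterwards would
#' scramble the label-to-node mapping.
#'
#' @param aln nucleotide `or_alignment`.
#' @param n bootstrap replicates (default 1000).
#' @param seed RNG seed (mandatory).
#' @param model distance model, see [tn93_distance()].
#' @param root how to root the reference tree before counting: `"none"`
#'   (leave unrooted), `"midpoint"`, or a character vector of outgroup tip
#'   labels.
#' @return `phylo` with numeric `node.label` support percentages (root
#'   label NA).
#' @export
bootstrap_support <- function(aln, n = 1000L, seed, model = "TN93", root = "none") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  m <- alignment_matrix(aln)
  dist_of <- function(mm) {
    d <- ape::dist.dna(ape::as.DNAbin(tolower(mm)), model = if (model == "TN93") "TN93" else "raw",
                       pairwise.deletion = TRUE, as.matrix = TRUE)
    if (any(!is.finite(d)))   # saturated resample: fall back to p-distance
      d <- ape::dist.dna(ape::as.DNAbin(tolower(mm)), model = "raw",
                         pairwise.deletion = TRUE, as.matrix = TRUE)
    d
  }
  ref <- neighbor_joining(dist_of(m))
  if (length(root) > 1L || !identical(root, "none")) {
    ref <- if (identical(root, "midpoint")) phangorn::midpoint(ref)
           else root_tree(ref, root)
  }
  set.seed(seed)
  reps <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    reps[[b]] <- neighbor_joining(dist_of(m[, cols, drop = FALSE]))
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(ref, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  ref$node.label <- round(100 * cnt / n, 1)
  ref
}

#' Root a tree on outgroups (midpoint fallback)
#'
#' @param tree `phylo`.
#' @param outgroups tip labels to root on; when none are present the tree
#'   is midpoint rooted with a warning.
#' @return rooted `phylo`.
#' @export
root_tree <- function(tree, outgroups = character(0)) {
  present <- intersect(outgroups, tree$tip.label)
  if (length(present) > 0L) {
    ape::root(tree, outgroup = present, resolve.root = TRUE)
  } else {
    if (length(outgroups) > 0L)
      warning("no outgroup tips present; midpoint rooting used")
    phangorn::midpoint(tree)
  }
}

#' Extract well-supported clades from a rooted tree
#'
#' Maximal non-nested clades whose bootstrap support meets `min_support`
#' and which contain at least `min_size` tips are labeled A, B, C, ... in
#' tree (cladewise) order; candidate clades must be proper subsets of the
#' non-outgroup tips. Remaining leaves are `UNASSIGNED`.
#'
#' @param tree rooted `phylo` with numeric `node.label` supports.
#' @param min_support support threshold in percent (default 97).
#' @param min_size minimum tips per clade (default 2).
#' @param outgroups tips excluded from clade membership.
#' @return object of class `clade_assignment`: data.frame `leaf`, `clade`;
#'   attribute `supports` names each clade's support value.
#' @export
extract_clades <- function(tree, min_support = 97, min_size = 2L,
                           outgroups = character(0)) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (root on the designated outgroups first)", call. = FALSE)
  n_tip <- length(tree$tip.label)
  ingroup <- setdiff(tree$tip.label, outgroups)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), type = "tips")
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  node_order <- unique(tree_cw$edge[, 1])          # parents, top-down
  node_order <- c(node_order, setdiff((n_tip + 1L):(n_tip + tree$Nnode), node_order))
  taken <- character(0)
  clades <- list()
  sup_out <- numeric(0)
  for (node in node_order) {
    tips <- tree$tip.label[desc[[node]]]
    if (any(tips %in% outgroups)) next
    if (length(tips) >= length(ingroup)) next      # trivial full-ingroup clade
    if (length(tips) < min_size) next
    s <- supports[node - n_tip]
    if (is.na(s) || s < min_support) next
    if (any(tips %in% taken)) next                 # nested inside an accepted clade
    lab <- LETTERS[length(clades) + 1L]
    clades[[lab]] <- tips
    sup_out[lab] <- s
    taken <- c(taken, tips)
  }
  assignment <- data.frame(
    leaf = ingroup,
    clade = vapply(ingroup, function(t) {
      hit <- names(clades)[vapply(clades, function(g) t %in% g, logical(1))]
      if (length(hit) == 0L) "UNASSIGNED" else hit[1]
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(assignment, supports = sup_out, class = c("clade_assignment", "data.frame"))
}

#' @export
print.clade_assignment <- function(x, ...) {
  tab <- table(x$clade)
  sup <- attr(x, "supports")
  cat(sprintf("<clade_assignment> %d leaves: %s\n", nrow(x),
              paste(sprintf("%s=%d%s", names(tab), tab,
                            ifelse(names(tab) %in% names(sup),
                                   sprintf(" (%.0f%%)", sup[names(tab)]), "")),
                    collapse = ", ")))
  invisible(x)
}

#' Per-clade functional composition
#'
#' @param assignment a `clade_assignment`.
#' @param statuses named vector leaf -> FUNCTIONAL/PSEUDOGENE.
#' @return data.frame `clade, n_functional, n_pseudogene, n_total,
#'   percent_functional, percent_pseudogene` (UNASSIGNED leaves summarised
#'   in their own row).
#' @export
clade_summary <- function(assignment, statuses) {
  miss <- setdiff(assignment$leaf, names(statuses))
  if (length(miss) > 0L)
    stop(sprintf("missing status for leaf(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  st <- statuses[assignment$leaf]
  out <- do.call(rbind, lapply(split(st, assignment$clade), function(s) {
    data.frame(n_functional = sum(s == "FUNCTIONAL"),
               n_pseudogene = sum(s == "PSEUDOGENE"),
               n_total = length(s))
  }))
  out$clade <- rownames(out)
  rownames(out) <- NULL
  out$percent_functional <- 100 * out$n_functional / out$n_total
  out$percent_pseudogene <- 100 * out$n_pseudogene / out$n_total
  out[, c("clade", "n_functional", "n_pseudogene", "n_total",
          "percent_functional", "percent_pseudogene")]
}

#' Label terminal branches by a species trait (CodeML foreground dialect)
#'
#' Appends `#1` to every tip whose species carries the foreground trait
#' value, producing the newick dialect used by branch-site codon models.
#'
#' @param tree `phylo` whose tips parse via [parse_sequence_id()].
#' @param metadata `species_metadata` table.
#' @param trait trait column (currently `"sociality"`).
#' @param foreground trait value marking foreground branches (e.g.
#'   `"Social"`).
#' @return list `newick` (labeled string), `tree` (phylo with labeled
#'   tips), `n_foreground`.
#' @export
label_partitions <- function(tree, metadata = read_species_metadata(),
                             trait = "sociality", foreground) {
  stopifnot(trait %in% c("sociality"))
  parsed <- parse_sequence_id(tree$tip.label, metadata)
  val <- metadata[[trait]][match(parsed$species_code, metadata$species_code)]
  fg <- val == foreground
  lab <- tree
  lab$tip.label <- paste0(tree$tip.label, ifelse(fg, "#1", ""))
  list(newick = ape::write.tree(lab), tree = lab, n_foreground = sum(fg))
}

#' Strip CodeML foreground labels from tip names
#' @param tree `phylo` with `#1`-suffixed tips.
#' @export
strip_partition_labels <- function(tree) {
  tree$tip.label <- sub("#1$", "", tree$tip.label)
  tree
}
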