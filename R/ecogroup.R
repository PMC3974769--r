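#' Per-species pseudogene proportions and ecogroup summaries
#'
#' Builds the species-level table of functional and pseudogene counts with
#' percent pseudogenes, and per-ecogroup mean and standard error of the
#' percentage (SE = sd / sqrt(k) over the k species of the group;
#' NA for single-species groups).
#'
#' @param counts data.frame with columns `species`, `n_functional`,
#'   `n_pseudogene` (one row per species), or a gene table plus `species`
#'   mapping.
#' @param metadata data.frame mapping `species` (or `species_code`) to
#'   `ecogroup`.
#' @param verbose log exclusions.
#' @return list of class `ecogroup_table`: `species` (per-species rows with
#'   `ecogroup` and `percent_pseudogene`), `groups` (per-ecogroup `mean`,
#'   `se`, `n_species`).
#' @export
pseudogene_proportions <- function(counts, metadata, verbose = FALSE) {
  need <- c("species", "n_functional", "n_pseudogene")
  if (!all(need %in% names(counts)))
    stop(sprintf("counts needs columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  key <- if ("species" %in% names(metadata)) "species" else "species_code"
  eg <- metadata$ecogroup[match(counts$species, metadata[[key]])]
  if (anyNA(eg))
    stop(sprintf("no ecogroup for species: %s",
                 paste(counts$species[is.na(eg)], collapse = ", ")), call. = FALSE)
  tot <- counts$n_functional + counts$n_pseudogene
  drop <- tot == 0
  if (any(drop)) {
    warning(sprintf("species with zero genes excluded: %s",
                    paste(counts$species[drop], collapse = ", ")))
    counts <- counts[!drop, , drop = FALSE]; eg <- eg[!drop]; tot <- tot[!drop]
  }
  species <- data.frame(species = counts$species, ecogroup = eg,
                        n_functional = counts$n_functional,
                        n_pseudogene = counts$n_pseudogene,
                        percent_pseudogene = 100 * counts$n_pseudogene / tot,
                        row.names = NULL, stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(species$percent_pseudogene, species$ecogroup),
                                  function(v) data.frame(mean = mean(v),
                                                         se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
                                                         n_species = length(v))))
  groups$ecogroup <- rownames(groups)
  rownames(groups) <- NULL
  or_log("ecogroup", nrow(counts) + sum(drop), nrow(species), verbose = verbose)
  structure(list(species = species,
                 groups = groups[, c("ecogroup", "mean", "se", "n_species")]),
            class = "ecogroup_table")
}

#' @export
print.ecogroup_table <- function(x, ...) {
  cat(sprintf("<ecogroup_table> %d species in %d ecogroups\n",
              nrow(x$species), nrow(x$groups)))
  print(x$groups)
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum tests between ecogroups
#'
#' Rank-sum test of per-species pseudogene percentages for every ecogroup
#' pair, using the exact distribution when both groups have fewer than 50
#' observations and no ties, and the normal approximation with continuity
#' and tie correction otherwise. Benjamini-Hochberg adjustment is applied
#' across all tested pairs; both raw and adjusted matrices are returned.
#'
#' @param table an `ecogroup_table` (or a data.frame with `ecogroup` and
#'   `percent_pseudogene` columns).
#' @param exact_max exact-branch sample-size limit (default 50).
#' @return list of class `ecogroup_tests`: `p_raw`, `p_adjusted`
#'   (lower-triangular matrices), `pairs` (long-format data.frame).
#' @export
pairwise_wilcoxon <- function(table, exact_max = 50L) {
  df <- if (inherits(table, "ecogroup_table")) table$species else table
  groups <- split(df$percent_pseudogene, df$ecogroup)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least two non-empty ecogroups", call. = FALSE)
  labs <- names(groups)
  k <- length(labs)
  p_raw <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in 2:k) for (j in 1:(i - 1)) {
    x <- groups[[i]]; y <- groups[[j]]
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- length(x) < exact_max && length(y) < exact_max && !ties
    p <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
    p_raw[i, j] <- if (is.finite(p)) p else 1   # degenerate comparison: no evidence
  }
  idx <- which(lower.tri(p_raw), arr.ind = TRUE)
  adj <- bh_adjust(p_raw[lower.tri(p_raw)])
  p_adj <- p_raw
  p_adj[lower.tri(p_adj)] <- adj
  pairs <- data.frame(group1 = labs[idx[, 1]], group2 = labs[idx[, 2]],
                      p_raw = p_raw[lower.tri(p_raw)], p_adjusted = adj,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(p_raw = p_raw, p_adjusted = p_adj, pairs = pairs),
            class = "ecogroup_tests")
}

#' @export
print.ecogroup_tests <- function(x, ...) {
  cat("Pairwise Wilcoxon rank-sum tests (BH-adjusted p-values below diagonal):\n")
  print(round(x$p_adjusted, 3))
  invisible(x)
}

#' Read an external ecogroup count table
#'
#' Schema: `species ecogroup n_functional n_pseudogene` (TSV). Used for
#' merging published whole-subgenome OR counts with the mole-rat rows; the
#' external table is a documented optional input and never bundled.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ecogroup_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "ecogroup", "n_functional", "n_pseudogene")
  if (!all(need %in% names(df)))
    stop(sprintf("ecogroup table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  df
}
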