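#' Default hydrophobic amino-acid set
#'
#' Standard hydropathy grouping used for the binding-pocket composition
#' statistic; configurable wherever it is consumed.
#' @export
default_hydrophobic <- function() c("A", "V", "L", "I", "M", "F", "W", "C", "Y")

variability_category <- function(count) {
  cut(count, breaks = c(-Inf, 1, 2, 4, Inf),
      labels = c("HIGHLY_CONSERVED", "CONSERVED", "VARIABLE", "HIGHLY_VARIABLE"))
}

#' Per-column amino-acid variability profile
#'
#' Counts the distinct residues observed at each alignment column of the
#' functional-gene amino-acid alignment (gaps and `X` excluded) and bins
#' them into the four conservation categories: highly conserved (1),
#' conserved (2), variable (3-4), highly variable (>= 5).
#'
#' @param aa_aln amino-acid `or_alignment` (functional genes only by
#'   contract; pass what you mean to profile).
#' @param topology optional `receptor_topology` used to annotate columns
#'   with their domain.
#' @return data.frame of class `site_profile`: `column` (0-based), `domain`
#'   (NA without topology), `count`, `category`, `is_binding`.
#' @export
site_variability <- function(aa_aln, topology = NULL) {
  m <- alignment_matrix(aa_aln)
  counts <- apply(m, 2, function(col) length(unique(col[!col %in% c("-", "X", "*")])))
  cols <- seq_len(ncol(m)) - 1L
  df <- data.frame(
    column = cols,
    domain = if (is.null(topology)) NA_character_ else domain_of(cols, topology$domains),
    count = as.integer(counts),
    category = as.character(variability_category(counts)),
    is_binding = if (is.null(topology)) FALSE else cols %in% topology$binding_positions,
    stringsAsFactors = FALSE)
  class(df) <- c("site_profile", "data.frame")
  df
}

#' Binding-pocket variability statistics
#'
#' A binding position is variable when at least two distinct residues are
#' observed there. The TM3-TM6 fraction is computed over the binding
#' positions falling in TM3-TM6 only, i.e. with the TM2 and TM7 binding
#' residues excluded.
#'
#' @param profile a `site_profile`.
#' @param topology a `receptor_topology`.
#' @return list `n_variable_binding`, `n_binding`,
#'   `frac_polymorphic_tm3_6`.
#' @export
binding_site_stats <- function(profile, topology) {
  bp <- topology$binding_positions
  if (any(!bp %in% profile$column))
    stop("binding position outside the alignment", call. = FALSE)
  counts <- profile$count[match(bp, profile$column)]
  core <- binding_positions_in(topology)
  core_counts <- profile$count[match(core, profile$column)]
  list(n_variable_binding = sum(counts >= 2L),
       n_binding = length(bp),
       frac_polymorphic_tm3_6 = mean(core_counts >= 2L))
}

#' Fraction of hydrophobic residues at binding positions
#'
#' Computed over residue observations: every non-gap, non-ambiguous residue
#' of every row at every binding position contributes one observation.
#'
#' @param aa_aln amino-acid `or_alignment`.
#' @param binding_positions 0-based columns.
#' @param hydrophobic_set residue set, see [default_hydrophobic()].
#' @return fraction in `[0, 1]`.
#' @export
hydrophobic_fraction <- function(aa_aln, binding_positions,
                                 hydrophobic_set = default_hydrophobic()) {
  if (length(binding_positions) == 0L) stop("empty binding-position set", call. = FALSE)
  m <- alignment_matrix(aa_aln)[, binding_positions + 1L, drop = FALSE]
  obs <- m[!m %in% c("-", "X", "*")]
  if (length(obs) == 0L) stop("no residue observations at binding positions", call. = FALSE)
  mean(obs %in% hydrophobic_set)
}

#' Per-clade residue motifs at the TM3-TM6 binding positions
#'
#' For each binding position in TM3-TM6, reports the residue set observed
#' in every clade. A position is conserved across clades when one single
#' residue is fixed in all clades; the remaining positions carry
#' clade-specific motifs.
#'
#' @param aa_aln amino-acid `or_alignment` of functional genes.
#' @param clades named character vector id -> clade label (UNASSIGNED rows
#'   are ignored).
#' @param topology a `receptor_topology`.
#' @return list of class `clade_motifs`: `table` (data.frame position x
#'   clade residue sets, plus `conserved`), `n_conserved`,
#'   `n_clade_specific`.
#' @export
clade_binding_motifs <- function(aa_aln, clades, topology) {
  core <- binding_positions_in(topology)
  cl <- clades[names(clades) %in% names(aa_aln)]
  cl <- cl[cl != "UNASSIGNED"]
  labs <- sort(unique(cl))
  if (length(labs) == 0L) stop("no clade-assigned sequences in alignment", call. = FALSE)
  m <- alignment_matrix(aa_aln)
  keep <- character(0)
  for (lab in labs) {
    rows <- names(cl)[cl == lab]
    sub <- m[rows, , drop = FALSE]
    if (all(sub %in% c("-", "X", "*"))) {
      warning(sprintf("clade %s has no usable residues; skipped", lab))
      next
    }
    keep <- c(keep, lab)
  }
  res_set <- function(rows, col) {
    r <- m[rows, col + 1L]
    sort(unique(r[!r %in% c("-", "X", "*")]))
  }
  tab <- data.frame(position = core, stringsAsFactors = FALSE)
  for (lab in keep)
    tab[[lab]] <- vapply(core, function(p)
      paste(res_set(names(cl)[cl == lab], p), collapse = "/"), character(1))
  tab$conserved <- apply(tab[, keep, drop = FALSE], 1, function(rr) {
    rr <- rr[nzchar(rr)]
    length(rr) == length(keep) && all(nchar(rr) == 1L) && length(unique(rr)) == 1L
  })
  structure(list(table = tab, n_conserved = sum(tab$conserved),
                 n_clade_specific = sum(!tab$conserved), clades = keep),
            class = "clade_motifs")
}

#' @export
print.clade_motifs <- function(x, ...) {
  cat(sprintf("<clade_motifs> %d binding positions, %d clades: %d cross-clade conserved, %d clade-specific\n",
              nrow(x$table), length(x$clades), x$n_conserved, x$n_clade_specific))
  invisible(x)
}

#' Overlap between two variability profiles
#'
#' Fractions are computed on the reference profile's position sets: the
#' share of the reference's highly conserved positions (count = 1) that are
#' also highly conserved in `profile`, and the share of the reference's
#' variable positions (count >= 3) that are also variable.
#'
#' @param profile,reference_profile `site_profile` objects on the same
#'   coordinate system.
#' @return list `shared_highly_conserved_frac`, `shared_variable_frac`.
#' @export
compare_profiles <- function(profile, reference_profile) {
  if (nrow(profile) != nrow(reference_profile))
    stop("profiles have different lengths", call. = FALSE)
  hc_ref <- reference_profile$column[reference_profile$count == 1L]
  var_ref <- reference_profile$column[reference_profile$count >= 3L]
  hc <- profile$column[profile$count == 1L]
  vv <- profile$column[profile$count >= 3L]
  list(shared_highly_conserved_frac =
         if (length(hc_ref) == 0L) NA_real_ else mean(hc_ref %in% hc),
       shared_variable_frac =
         if (length(var_ref) == 0L) NA_real_ else mean(var_ref %in% vv))
}
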