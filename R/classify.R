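STOP_CODONS <- c("TAA", "TAG", "TGA")

# translate one gapped, in-frame nucleotide string to a gapped aa string.
# codons fully gapped -> "-", partially gapped or containing N -> "X".
translate_gapped <- function(nt, frame_offset = 0L) {
  nt <- toupper(nt)
  if (frame_offset > 0L) nt <- substring(nt, frame_offset + 1L)
  n_codon <- nchar(nt) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- rep("X", n_codon)
  aa[codons == "---"] <- "-"
  clean <- !grepl("[-N]", codons)
  gc <- genetic_code()
  aa[clean] <- unname(gc[codons[clean]])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a nucleotide alignment codon-wise
#'
#' Columns are translated in the fixed reading frame shared by the run;
#' fully gapped codons become `-`, codons with partial gaps or ambiguity
#' codes become `X`.
#'
#' @param aln nucleotide `or_alignment`.
#' @param frame_offset 0, 1 or 2 leading bases to skip.
#' @return amino-acid `or_alignment`.
#' @export
translate_alignment <- function(aln, frame_offset = 0L) {
  stopifnot(attr(aln, "alphabet") == "DNA")
  aa <- vapply(unclass(aln), translate_gapped, character(1), frame_offset = frame_offset)
  or_alignment(aa, alphabet = "AA")
}

#' Default functional reference row for a run
#'
#' The reference anchors the reading frame and the indel calls. By default
#' it is the longest sequence in the alignment whose own translation has no
#' internal stop codon and which has no gaps, i.e. the best available
#' intact receptor.
#'
#' @param aln nucleotide `or_alignment`.
#' @param frame_offset reading frame offset.
#' @return the id of the chosen reference row.
#' @export
choose_reference <- function(aln, frame_offset = 0L) {
  ok <- vapply(names(aln), function(id) {
    s <- aln[[id]]
    aa <- translate_gapped(gsub("-", "", s), frame_offset)
    body <- substr(aa, 1L, nchar(aa) - 1L)
    !grepl("\\*", body) && !grepl("-", s, fixed = TRUE)
  }, logical(1))
  if (!any(ok)) stop("no disruption-free sequence available as reference; designate one explicitly",
                     call. = FALSE)
  cand <- names(aln)[ok]
  ng <- nchar(gsub("-", "", unclass(aln)[cand]))
  cand[order(-ng, cand)][1]
}

#' Find ORF disruptions in an aligned OR sequence
#'
#' Reports every in-frame premature stop codon (reading frame taken from
#' the designated functional reference row) and every insertion or deletion
#' run, relative to the reference, whose length is not a multiple of three.
#' In-frame indel runs (length divisible by 3) are reported with kind
#' `INFRAME_INDEL` so that length-variant sequences can be screened against
#' the binding pocket, but they are not ORF disruptions.
#'
#' @param seq gapped nucleotide string (one alignment row).
#' @param reference gapped nucleotide string of the functional reference row.
#' @param frame_offset reading-frame offset of the reference.
#' @return data.frame with columns `kind` (PREMATURE_STOP, FRAMESHIFT_INDEL,
#'   INFRAME_INDEL, AMBIGUOUS_CODON), `alignment_column` (0-based) and
#'   `detail`.
#' @export
find_disruptions <- function(seq, reference, frame_offset = 0L) {
  if (is.null(reference) || !nzchar(reference))
    stop("no functional reference row designated", call. = FALSE)
  s <- strsplit(toupper(seq), "")[[1]]
  r <- strsplit(toupper(reference), "")[[1]]
  if (length(s) != length(r)) stop("sequence and reference have different alignment lengths",
                                   call. = FALSE)
  out <- list()
  add <- function(kind, col, detail)
    out[[length(out) + 1L]] <<- data.frame(kind = kind, alignment_column = col,
                                           detail = detail, stringsAsFactors = FALSE)

  run_events <- function(mask, label) {
    if (any(mask)) {
      rl <- rle(mask)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        len <- rl$lengths[k]
        kind <- if (len %% 3L == 0L) "INFRAME_INDEL" else "FRAMESHIFT_INDEL"
        add(kind, starts[k] - 1L, sprintf("%s%d", label, len))
      }
    }
  }
  run_events(s == "-" & r != "-", "del")
  run_events(s != "-" & r == "-", "ins")

  # premature stops in the reference reading frame
  ref_cols <- which(r != "-")
  if (frame_offset > 0L) ref_cols <- ref_cols[-seq_len(frame_offset)]
  n_codon <- length(ref_cols) %/% 3L
  if (n_codon > 1L) {
    for (i in seq_len(n_codon - 1L)) {          # final codon not counted
      cols <- ref_cols[(3L * i - 2L):(3L * i)]
      codon <- paste(s[cols], collapse = "")
      if (grepl("-", codon, fixed = TRUE)) next # handled as indel
      if (grepl("N", codon, fixed = TRUE)) {
        add("AMBIGUOUS_CODON", cols[1] - 1L, codon)
      } else if (codon %in% STOP_CODONS) {
        add("PREMATURE_STOP", cols[1] - 1L, codon)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(kind = character(0), alignment_column = integer(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Default OR motif set
#'
#' The two diagnostic OR motifs checked for length-variant sequences:
#' MAYDRFVAIC at the end of TM3 and KAFSTCASH at the start of TM6.
#'
#' @param max_mismatch allowed mismatches per motif.
#' @return data.frame with columns `name`, `pattern`, `domain`, `max_mismatch`.
#' @export
default_motifs <- function(max_mismatch = 2L) {
  data.frame(name = c("MAYDRFVAIC", "KAFSTCASH"),
             pattern = c("MAYDRFVAIC", "KAFSTCASH"),
             domain = c("TM3", "TM6"),
             max_mismatch = as.integer(max_mismatch),
             stringsAsFactors = FALSE)
}

#' Scan for receptor motifs in a translated sequence
#'
#' Each motif is slid over the gap-stripped residues of its expected domain
#' window; the best (fewest-mismatch) placement is reported. `X` residues
#' count as mismatches.
#'
#' @param aa_seq gapped amino-acid string (one row of the translated
#'   alignment).
#' @param motif_set data.frame as produced by [default_motifs()].
#' @param topology a `receptor_topology` (amino-acid coordinates).
#' @param max_mismatch default mismatch budget when the motif set has no
#'   `max_mismatch` column.
#' @return data.frame `motif_name, mismatches, position, hit`; `position` is
#'   the 0-based offset of the best placement within the gap-stripped domain
#'   window (NA when the window is empty).
#' @export
detect_motifs <- function(aa_seq, motif_set = default_motifs(), topology = read_topology(),
                          max_mismatch = 2L) {
  if (!"max_mismatch" %in% names(motif_set)) motif_set$max_mismatch <- as.integer(max_mismatch)
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  res <- lapply(seq_len(nrow(motif_set)), function(i) {
    pat <- strsplit(motif_set$pattern[i], "")[[1]]
    dom <- topology$domains[topology$domains$name == motif_set$domain[i], ]
    if (nrow(dom) != 1L)
      stop(sprintf("motif domain '%s' not in topology", motif_set$domain[i]), call. = FALSE)
    win <- aa[(dom$start + 1L):dom$end]
    win <- win[win != "-"]
    if (length(pat) > dom$end - dom$start)
      stop(sprintf("motif %s longer than its domain window", motif_set$name[i]), call. = FALSE)
    if (length(win) < length(pat))
      return(data.frame(motif_name = motif_set$name[i], mismatches = NA_integer_,
                        position = NA_integer_, hit = FALSE, stringsAsFactors = FALSE))
    n_place <- length(win) - length(pat) + 1L
    mm <- vapply(seq_len(n_place), function(off) {
      sub <- win[off:(off + length(pat) - 1L)]
      sum(sub != pat | sub == "X")
    }, integer(1))
    best <- which.min(mm)
    data.frame(motif_name = motif_set$name[i], mismatches = mm[best],
               position = best - 1L, hit = mm[best] <= motif_set$max_mismatch[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify one aligned OR sequence as functional or pseudogene
#'
#' A sequence is a pseudogene if it carries any ORF disruption (premature
#' stop or frameshift indel relative to the functional reference). Length
#' variants (in-frame indels only) remain functional only if the required
#' receptor motifs are present within the mismatch budget and none of the
#' indels falls on a ligand-binding position.
#'
#' @param seq gapped nucleotide string.
#' @param id sequence id.
#' @param reference gapped nucleotide string of the reference row.
#' @param topology a `receptor_topology`.
#' @param motif_set motif table, see [default_motifs()].
#' @param frame_offset reading-frame offset.
#' @param require_all_motifs if `FALSE`, a single motif hit suffices for
#'   length variants.
#' @return list of class `or_functional_call` with elements `id`, `status`,
#'   `disruptions`, `motif_hits`.
#' @export
classify_status <- function(seq, id = "seq", reference, topology = read_topology(),
                            motif_set = default_motifs(), frame_offset = 0L,
                            require_all_motifs = TRUE) {
  ev <- find_disruptions(seq, reference, frame_offset)
  disr <- ev[ev$kind %in% c("PREMATURE_STOP", "FRAMESHIFT_INDEL"), , drop = FALSE]
  inframe <- ev[ev$kind == "INFRAME_INDEL", , drop = FALSE]
  aa <- translate_gapped(seq, frame_offset)
  hits <- detect_motifs(aa, motif_set, topology)
  status <- "FUNCTIONAL"
  if (nrow(disr) > 0L) {
    status <- "PSEUDOGENE"
  } else if (nrow(inframe) > 0L) {
    motifs_ok <- if (require_all_motifs) all(hits$hit) else any(hits$hit)
    indel_aa_cols <- unique((inframe$alignment_column - frame_offset) %/% 3L)
    pocket_hit <- any(indel_aa_cols %in% topology$binding_positions)
    if (!motifs_ok || pocket_hit) status <- "PSEUDOGENE"
  }
  structure(list(id = id, status = status, disruptions = disr,
                 inframe_indels = inframe,
                 ambiguous = ev[ev$kind == "AMBIGUOUS_CODON", , drop = FALSE],
                 motif_hits = hits),
            class = "or_functional_call")
}

#' @export
print.or_functional_call <- function(x, ...) {
  cat(sprintf("<%s> %s: %d disruption(s), %d/%d motif hit(s)\n",
              x$id, x$status, nrow(x$disruptions), sum(x$motif_hits$hit),
              nrow(x$motif_hits)))
  invisible(x)
}

#' Classify every sequence of an aligned run
#'
#' @param aln nucleotide `or_alignment`.
#' @param reference_id id of the functional reference row; default picks the
#'   longest disruption-free sequence via [choose_reference()].
#' @param topology,motif_set,frame_offset,require_all_motifs passed to
#'   [classify_status()].
#' @param verbose log per-stage counts.
#' @return data.frame of class `or_classification`: columns `id`, `status`,
#'   `n_disruptions`, `disruption_details`, `motif_summary`; the reference id
#'   is kept in attribute `reference_id` and the full per-sequence calls in
#'   attribute `calls`.
#' @export
classify_alignment <- function(aln, reference_id = NULL, topology = read_topology(),
                               motif_set = default_motifs(), frame_offset = 0L,
                               require_all_motifs = TRUE, verbose = FALSE) {
  if (is.null(reference_id)) reference_id <- choose_reference(aln, frame_offset)
  if (!reference_id %in% names(aln))
    stop(sprintf("reference id '%s' not in alignment", reference_id), call. = FALSE)
  ref <- aln[[reference_id]]
  calls <- lapply(names(aln), function(id)
    classify_status(aln[[id]], id = id, reference = ref, topology = topology,
                    motif_set = motif_set, frame_offset = frame_offset,
                    require_all_motifs = require_all_motifs))
  names(calls) <- names(aln)
  df <- data.frame(
    id = names(aln),
    status = vapply(calls, `[[`, character(1), "status"),
    n_disruptions = vapply(calls, function(x) nrow(x$disruptions), integer(1)),
    disruption_details = vapply(calls, function(x)
      paste(sprintf("%s@%d:%s", x$disruptions$kind, x$disruptions$alignment_column,
                    x$disruptions$detail), collapse = ";"), character(1)),
    motif_summary = vapply(calls, function(x)
      paste(sprintf("%s=%s", x$motif_hits$motif_name, x$motif_hits$mismatches),
            collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  or_log("classify", length(aln), nrow(df), verbose = verbose)
  structure(df, reference_id = reference_id, calls = calls,
            class = c("or_classification", "data.frame"))
}
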