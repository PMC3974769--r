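.gc_env <- new.env(parent = emptyenv())

# the standard genetic code as a plain named vector, fetched once
genetic_code <- function() {
  if (is.null(.gc_env$gc)) {
    g <- Biostrings::GENETIC_CODE
    .gc_env$gc <- setNames(as.character(g), names(g))
  }
  .gc_env$gc
}

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")

#' Construct an alignment object
#'
#' An alignment is a named character vector of equal-length upper-case
#' sequence strings with an `alphabet` attribute (`"DNA"` or `"AA"`).
#' Unaligned sequence sets use the same container with `aligned = FALSE`,
#' in which case rows may differ in length.
#'
#' @param seqs named character vector of sequences.
#' @param alphabet `"DNA"` or `"AA"`.
#' @param aligned logical; enforce equal row lengths and alphabet checks.
#' @return an object of class `or_alignment`.
#' @export
or_alignment <- function(seqs, alphabet = c("DNA", "AA"), aligned = TRUE) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0L) stop("alignment has no sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named", call. = FALSE)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (aligned && length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment: row lengths %s",
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  allowed <- if (alphabet == "DNA") DNA_ALPHABET else AA_ALPHABET
  bad <- regmatches(seqs, regexpr(sprintf("[^%s]", paste(allowed, collapse = "")), seqs))
  if (length(bad) > 0L) {
    i <- which(!vapply(gregexpr(sprintf("[^%s]", paste(allowed, collapse = "")), seqs),
                       function(m) m[1] == -1L, logical(1)))[1]
    pos <- regexpr(sprintf("[^%s]", paste(allowed, collapse = "")), seqs[[i]])
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(seqs[[i]], pos, pos), names(seqs)[i], pos), call. = FALSE)
  }
  structure(seqs, class = "or_alignment", alphabet = alphabet, aligned = aligned)
}

#' @export
print.or_alignment <- function(x, ...) {
  cat(sprintf("<or_alignment> %d %s sequences%s\n", length(x), attr(x, "alphabet"),
              if (isTRUE(attr(x, "aligned")))
                sprintf(", %d columns", nchar(x[[1]])) else " (unaligned)"))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = sites)
#' @param aln an `or_alignment`.
#' @return character matrix with sequence ids as row names.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(isTRUE(attr(aln, "aligned")))
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Matrix back to an alignment
#' @param m character matrix as produced by [alignment_matrix()].
#' @param alphabet `"DNA"` or `"AA"`.
#' @export
matrix_alignment <- function(m, alphabet = c("DNA", "AA")) {
  or_alignment(setNames(apply(m, 1, paste, collapse = ""), rownames(m)),
               alphabet = match.arg(alphabet))
}

#' Read sequences from a FASTA file
#'
#' Ids are the full header up to the first whitespace, preserved verbatim.
#' In aligned mode all records must have equal length.
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"` or `"AA"`.
#' @param aligned require equal-length rows.
#' @return an `or_alignment`.
#' @export
read_alignment <- function(path, alphabet = c("DNA", "AA"), aligned = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  or_alignment(seqs, alphabet = alphabet, aligned = aligned)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param aln an `or_alignment` (or named character vector).
#' @param path output file.
#' @export
write_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(unclass(aln))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read the species metadata table
#'
#' Tab-separated with header
#' `species_code species_name genus sociality ecogroup`. Sociality must be
#' Solitary/Social; ecogroup one of Aquatic, Semi-aquatic, Subterranean,
#' Terrestrial, Volant.
#'
#' @param path TSV file; default is the packaged 14-species mole-rat table.
#' @return data.frame of class `species_metadata`.
#' @export
read_species_metadata <- function(path = system.file("extdata", "bathyergid_species.tsv",
                                                     package = "olfactoR")) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_code", "species_name", "genus", "sociality", "ecogroup")
  if (!all(need %in% names(md)))
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(md$species_code))
    stop("duplicate species_code in metadata", call. = FALSE)
  if (!all(md$sociality %in% c("Solitary", "Social")))
    stop("sociality must be Solitary or Social", call. = FALSE)
  eg <- c("Aquatic", "Semi-aquatic", "Subterranean", "Terrestrial", "Volant")
  if (!all(md$ecogroup %in% eg))
    stop(sprintf("ecogroup must be one of: %s", paste(eg, collapse = ", ")), call. = FALSE)
  class(md) <- c("species_metadata", "data.frame")
  md
}

#' Parse a clone identifier into its taxonomic parts
#'
#' Identifiers follow `<species code><individual number>_<clone label>`,
#' e.g. `"BJ4_A12"` is clone A12 from individual 4 of *Bathyergus janetta*
#' (code BJ). The species code is matched (longest first) against the
#' metadata table, so codes of different lengths (BJ, CHH, ...) are
#' unambiguous.
#'
#' @param id clone identifier (vectorised).
#' @param metadata a `species_metadata` table.
#' @return data.frame with columns `id, species_code, genus, individual, clone`.
#' @export
parse_sequence_id <- function(id, metadata = read_species_metadata()) {
  codes <- metadata$species_code[order(-nchar(metadata$species_code),
                                       metadata$species_code)]
  parse1 <- function(x) {
    for (code in codes) {
      if (startsWith(x, code)) {
        rest <- substring(x, nchar(code) + 1L)
        m <- regmatches(rest, regexec("^([0-9]+)_([A-Za-z0-9]+)$", rest))[[1]]
        if (length(m) == 3L)
          return(c(code, metadata$genus[metadata$species_code == code], m[2], m[3]))
      }
    }
    stop(sprintf("cannot resolve species code in id '%s'", x), call. = FALSE)
  }
  parts <- t(vapply(id, parse1, character(4)))
  data.frame(id = id, species_code = parts[, 1], genus = parts[, 2],
             individual = parts[, 3], clone = parts[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a receptor topology definition
#'
#' The topology file is tab-separated with header `name start end` giving
#' 0-based half-open amino-acid alignment coordinates of the 7TM domains and
#' loops, plus a JSON sidecar (or `binding` argument) listing the
#' ligand-binding alignment positions. Domains must be ordered and
#' non-overlapping, and every binding position must fall inside a domain.
#'
#' @param path domain TSV.
#' @param binding_path JSON file containing an array `binding_positions`
#'   (0-based amino-acid columns); defaults to `<path>.json` convention used
#'   by the packaged fixture.
#' @return list of class `receptor_topology` with elements `domains`
#'   (data.frame) and `binding_positions` (integer vector).
#' @export
read_topology <- function(path = system.file("extdata", "topology_synthetic.tsv",
                                             package = "olfactoR"),
                          binding_path = NULL) {
  dom <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(dom)))
    stop("topology table needs columns name, start, end", call. = FALSE)
  if (is.null(binding_path))
    binding_path <- sub("\\.tsv$", ".json", path)
  bp <- as.integer(jsonlite::read_json(binding_path, simplifyVector = TRUE)$binding_positions)
  receptor_topology(dom, bp)
}

#' Construct (and validate) a receptor topology
#' @param domains data.frame with `name`, `start`, `end` (0-based half-open).
#' @param binding_positions integer vector of 0-based alignment columns.
#' @export
receptor_topology <- function(domains, binding_positions) {
  domains <- domains[order(domains$start), , drop = FALSE]
  if (any(domains$end <= domains$start))
    stop("empty or inverted domain interval", call. = FALSE)
  if (nrow(domains) > 1L && any(domains$start[-1] < domains$end[-nrow(domains)]))
    stop("overlapping domains", call. = FALSE)
  binding_positions <- sort(unique(as.integer(binding_positions)))
  dom_of <- domain_of(binding_positions, domains)
  if (anyNA(dom_of))
    stop(sprintf("binding position(s) outside all domains: %s",
                 paste(binding_positions[is.na(dom_of)], collapse = ", ")), call. = FALSE)
  structure(list(domains = domains, binding_positions = binding_positions),
            class = "receptor_topology")
}

#' @export
print.receptor_topology <- function(x, ...) {
  cat(sprintf("<receptor_topology> %d domains (%s), %d binding positions\n",
              nrow(x$domains), paste(range(x$domains$start), collapse = "-"),
              length(x$binding_positions)))
  invisible(x)
}

# domain name for each 0-based column (NA outside all domains)
domain_of <- function(cols, domains) {
  out <- rep(NA_character_, length(cols))
  for (i in seq_len(nrow(domains))) {
    hit <- cols >= domains$start[i] & cols < domains$end[i]
    out[hit] <- domains$name[i]
  }
  out
}

#' Binding positions restricted to a set of domains
#' @param topology a `receptor_topology`.
#' @param domains character vector of domain names (default TM3-TM6).
#' @export
binding_positions_in <- function(topology, domains = c("TM3", "TM4", "TM5", "TM6")) {
  bp <- topology$binding_positions
  bp[domain_of(bp, topology$domains) %in% domains]
}

# lightweight stage logging: count in, count out, per-record reasons
or_log <- function(stage, n_in, n_out, dropped = character(0), verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[%s] in=%d out=%d dropped=%d", stage, n_in, n_out, length(dropped)))
  for (d in dropped) message(sprintf("[%s]   - %s", stage, d))
  invisible(NULL)
}
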