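# shared fixture builders: everything is generated in code at test time

fixture_topology <- function() read_topology()
fixture_metadata <- function() read_species_metadata()

# a small aligned set of intact amplicons for classification tests:
# the reference coding sequence plus named per-sequence edits
amplicon_set <- function(edits = list()) {
  cds <- or_reference_cds(fixture_topology())
  seqs <- c(REF = cds)
  for (nm in names(edits)) seqs[[nm]] <- edits[[nm]](cds)
  or_alignment(seqs, alphabet = "DNA")
}

# edit helpers operating on a nucleotide string
edit_sub <- function(pos, base) function(s) { substr(s, pos, pos) <- base; s }
edit_codon <- function(codon_i, triplet) function(s) {
  substr(s, 3 * codon_i - 2, 3 * codon_i) <- triplet; s
}
edit_del <- function(pos, len) function(s) {
  paste0(substr(s, 1, pos - 1), strrep("-", len), substr(s, pos + len, nchar(s)))
}

# compose edits left to right
edit_chain <- function(...) {
  fs <- list(...)
  function(s) Reduce(function(x, f) f(x), fs, s)
}

# random stop-free codon string (test-local utility)
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  all64 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                             c("A","C","G","T")), 1, paste, collapse = "")
  ok <- !(all64 %in% c("TAA", "TAG", "TGA"))
  paste(sample(all64[ok], n_codons, replace = TRUE), collapse = "")
}

# a small deterministic simulation shared by several tests (cached per run)
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_repertoire(simulation_config(seed = 1))
  .sim_cache$sim
}
default_pipeline <- function() {
  if (is.null(.sim_cache$res)) {
    sim <- default_sim()
    .sim_cache$res <- run_pipeline(pipeline_config(
      input = sim$alignment, outdir = file.path(tempdir(), "olfactor_default_run"),
      n_boot = 100, z_boot = 300, outgroups = sim$outgroups, seed = 7))
  }
  .sim_cache$res
}
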