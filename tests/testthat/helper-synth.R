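# Shared synthetic fixtures, built once per test run.

synth_cache <- new.env(parent = emptyenv())

# two KIR-like genes at 0.90 pairwise identity plus their registry
base_pair <- function() {
  if (is.null(synth_cache$pair)) {
    genes <- kir_generate_gene_set(n_genes = 2L, divergence = 0.90, seed = 7L)
    synth_cache$pair <- list(genes = genes,
                             registry = kir_synth_registry(genes))
  }
  synth_cache$pair
}

packaged <- function() {
  if (is.null(synth_cache$reg))
    synth_cache$reg <- kir_registry_packaged()
  synth_cache$reg
}

good_meta <- function() {
  list(date = "2018-05-01",
       evidence = list(list(kind = "independent_pcr", label = "expA"),
                       list(kind = "independent_pcr", label = "expB")))
}

# independent tier oracle: whole-protein translation via Biostrings and
# direct string comparison of the coding and flanking blocks
oracle_translate <- function(s) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, 3L * (nchar(s) %/% 3L))),
    no.init.codon = TRUE))
}

oracle_tier <- function(novel, ref, ref_protein = oracle_translate(ref$cds)) {
  if (!identical(oracle_translate(novel$cds), ref_protein))
    return("non_synonymous")
  if (!identical(novel$cds, ref$cds)) return("synonymous")
  same_flanks <- identical(novel$flank5, ref$flank5) &&
    identical(novel$flank3, ref$flank3)
  if (!same_flanks) return("non_coding_only")
  "identical"
}
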