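# Seeded generator of KIR-like annotated coding sequences.
#
# The generator emulates the block structure of a KIR transcript (leader
# peptide, one to three Ig-like domains with conserved cysteine spacing, a
# stem, a transmembrane segment and a cytoplasmic tail) so that every
# other module can be exercised without any real sequence data.  It is not
# an evolutionary simulation: substitutions are uniform, with no rate
# model and no recombination hotspots.
#
# Seed contract: all randomness comes from R's Mersenne-Twister generator,
# (re)seeded with the supplied integer via set.seed(); the caller's RNG
# state is saved and restored, and identical seeds give byte-identical
# output.

SENSE_CODONS <- setdiff(names(GENETIC_CODE_TAB),
                        c("TAA", "TAG", "TGA"))

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed, kind = "Mersenne-Twister")
  }
  force(expr)
}

random_codons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

# exon block plan for a given domain count and cytoplasmic tail length
block_plan <- function(domain_count, cyt_codons) {
  doms <- c("D0", "D1", "D2")[seq_len(domain_count)]
  labels <- c("leader", doms, "stem", "TM", "cyt")
  codons <- c(21L, rep(96L, domain_count), 24L, 21L, cyt_codons + 1L)
  data.frame(label = labels, codons = codons, stringsAsFactors = FALSE)
}

build_ancestor <- function(domain_count, cyt_codons) {
  plan <- block_plan(domain_count, cyt_codons)
  blocks <- lapply(seq_len(nrow(plan)), function(i) {
    cod <- random_codons(plan$codons[i])
    if (plan$label[i] == "leader") cod[1] <- "ATG"
    if (plan$label[i] %in% c("D0", "D1", "D2")) {
      cod[10] <- "TGT"                     # Ig-fold cysteine pair spacing
      cod[85] <- "TGT"
    }
    if (plan$label[i] == "cyt") cod[length(cod)] <- "TAA"   # stop
    paste(cod, collapse = "")
  })
  ends <- cumsum(plan$codons * 3L)
  spans <- data.frame(label = plan$label, start = c(0L, ends[-length(ends)]),
                      end = ends, stringsAsFactors = FALSE)
  list(cds = paste(unlist(blocks), collapse = ""), spans = spans)
}

mutate_positions <- function(cds, n, protect = integer()) {
  chars <- strsplit(cds, "")[[1]]
  ncod <- length(chars) %/% 3L
  eligible <- setdiff(seq_along(chars), protect)
  pos <- sample(eligible, n)
  for (p in pos) {
    repeat {
      new <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      ci <- (p - 1L) %/% 3L
      codon <- chars[(ci * 3L + 1L):(ci * 3L + 3L)]
      codon[(p - 1L) %% 3L + 1L] <- new
      # avoid minting incidental stop codons except in the terminal codon
      if (ci == ncod - 1L ||
          !paste(codon, collapse = "") %in% c("TAA", "TAG", "TGA")) {
        chars[p] <- new
        break
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a set of diverged KIR-like genes
#'
#' Builds one ancestral sequence from labelled blocks and derives each
#' gene from it by substituting a fixed number of sites, chosen so that
#' the pairwise identity between any two genes is close to `divergence`.
#' Each gene also receives 5' and 3' untranslated flanks.
#'
#' @param n_genes Number of genes.
#' @param divergence Target pairwise identity between genes, in (0, 1).
#' @param domain_count Ig-like domains per gene (1-3).
#' @param cyt_codons Cytoplasmic tail length in codons.
#' @param flank_len Length (nt) of each untranslated flank.
#' @param seed Integer seed (see the seed contract above).
#' @return A named list of [kir_sequence()] objects (`gene01`, `gene02`,
#'   ...) with a `truth` attribute recording the generating parameters.
#' @export
kir_generate_gene_set <- function(n_genes = 3L, divergence = 0.90,
                                  domain_count = 3L, cyt_codons = 84L,
                                  flank_len = 120L, seed = 1L) {
  stopifnot(divergence > 0, divergence < 1, n_genes >= 1L)
  with_seed(seed, {
    anc <- build_ancestor(domain_count, cyt_codons)
    L <- nchar(anc$cds)
    m <- round(L * (1 - divergence) / 2)
    # beyond ~40% substitutions per gene, overlapping hits and chance
    # re-matches saturate and the requested pairwise identity cannot be
    # delivered within tolerance
    if (m > 0.4 * (L - 6L))
      kir_error("unsatisfiable divergence for this sequence length",
                "kir_synth_error")
    protect <- c(1:3, (L - 2):L)            # keep start and stop intact
    f5_anc <- paste(sample(c("A", "C", "G", "T"), flank_len, TRUE),
                    collapse = "")
    f3_anc <- paste(sample(c("A", "C", "G", "T"), flank_len, TRUE),
                    collapse = "")
    genes <- lapply(seq_len(n_genes), function(i) {
      cds <- if (n_genes == 1L) anc$cds else
        mutate_positions(anc$cds, m, protect)
      kir_sequence(cds, exon_spans = anc$spans,
                   flank5 = if (n_genes == 1L) f5_anc else
                     mutate_positions(f5_anc, max(1L, round(flank_len *
                                                              (1 - divergence) / 2))),
                   flank3 = if (n_genes == 1L) f3_anc else
                     mutate_positions(f3_anc, max(1L, round(flank_len *
                                                              (1 - divergence) / 2))))
    })
    names(genes) <- sprintf("gene%02d", seq_len(n_genes))
    attr(genes, "truth") <- list(domain_count = domain_count,
                                 cyt_codons = cyt_codons,
                                 divergence = divergence, seed = seed,
                                 n_sub_per_gene = m)
    genes
  })
}

# codon -> synonymous sense-codon alternatives, tabulated once
SYN_ALTS <- local({
  aa <- GENETIC_CODE_TAB[SENSE_CODONS]
  stats::setNames(lapply(seq_along(SENSE_CODONS), function(i)
    SENSE_CODONS[aa == aa[i] & SENSE_CODONS != SENSE_CODONS[i]]),
    SENSE_CODONS)
})

synonymous_alternatives <- function(codon) SYN_ALTS[[codon]]

#' Apply a controlled mutation to an annotated sequence
#'
#' Mutation classes: `synonymous` substitutes codons without changing the
#' protein (verified against the standard code); `nonsynonymous` changes
#' the encoded amino acid without creating a stop; `noncoding` touches
#' only the 3' (or, failing that, 5') flank; `stop` converts the codon at
#' fraction `stop_at` of the cds to TAA; `frameshift` deletes one
#' nucleotide mid-sequence.
#'
#' @param seq A [kir_sequence()].
#' @param class One of `"synonymous"`, `"nonsynonymous"`, `"noncoding"`,
#'   `"stop"`, `"frameshift"`.
#' @param count Number of sites to mutate (classes `stop` and
#'   `frameshift` always act once).
#' @param seed Integer seed.
#' @param stop_at Fraction of the coding length at which the premature
#'   stop is placed.
#' @return The mutated `kir_sequence`, with a `mutation` attribute.
#' @export
kir_mutate <- function(seq, class = c("synonymous", "nonsynonymous",
                                      "noncoding", "stop", "frameshift"),
                       count = 1L, seed = 1L, stop_at = 0.5) {
  class <- match.arg(class)
  with_seed(seed, {
    cds <- seq$cds
    ncod <- nchar(cds) %/% 3L
    codon_at <- function(i) substr(cds, i * 3L - 2L, i * 3L)
    set_codon <- function(i, codon) {
      substr(cds, i * 3L - 2L, i * 3L) <- codon
      cds
    }
    body_codons <- 2:(ncod - 1L)            # spare the start and stop codons
    if (class == "synonymous") {
      elig <- body_codons[vapply(body_codons, function(i)
        length(synonymous_alternatives(codon_at(i))) > 0L, TRUE)]
      if (length(elig) < count)
        kir_error("not enough codons with synonymous alternatives",
                  "kir_synth_error")
      for (i in sample(elig, count))
        cds <- set_codon(i, sample(synonymous_alternatives(codon_at(i)), 1L))
    } else if (class == "nonsynonymous") {
      if (length(body_codons) < count)
        kir_error("not enough eligible codons", "kir_synth_error")
      for (i in sample(body_codons, count)) {
        aa <- GENETIC_CODE_TAB[[codon_at(i)]]
        alts <- SENSE_CODONS[GENETIC_CODE_TAB[SENSE_CODONS] != aa]
        cds <- set_codon(i, sample(alts, 1L))
      }
    } else if (class == "noncoding") {
      target <- if (!is.null(seq$flank3)) "flank3"
                else if (!is.null(seq$flank5)) "flank5"
                else kir_error("no non-coding block to mutate",
                               "kir_synth_error")
      seq[[target]] <- mutate_positions(seq[[target]], count)
    } else if (class == "stop") {
      i <- max(2L, min(ncod - 1L, round(stop_at * ncod)))
      cds <- set_codon(i, "TAA")
    } else if (class == "frameshift") {
      p <- sample(4:(nchar(cds) - 3L), 1L)
      cds <- paste0(substr(cds, 1L, p - 1L),
                    substr(cds, p + 1L, nchar(cds)))
    }
    es <- seq$exon_spans
    if (nchar(cds) != nchar(seq$cds))       # frameshift shortens the cds
      es$end[nrow(es)] <- es$end[nrow(es)] - (nchar(seq$cds) - nchar(cds))
    out <- kir_sequence(cds, exon_spans = es, flank5 = seq$flank5,
                        flank3 = seq$flank3, introns = seq$introns,
                        complete = seq$complete,
                        genomic_exons = seq$genomic_exons)
    attr(out, "mutation") <- list(class = class, count = count)
    out
  })
}

#' Splice two parent sequences into a recombinant
#'
#' @param parentA,parentB [kir_sequence()] objects with identical exon
#'   structure and equal cds length.
#' @param breakpoint Fraction in (0, 1) of the cds taken from `parentA`.
#' @return A `kir_sequence` chimera (flanks from `parentA`).
#' @export
kir_chimera <- function(parentA, parentB, breakpoint) {
  stopifnot(breakpoint > 0, breakpoint < 1,
            nchar(parentA$cds) == nchar(parentB$cds))
  k <- round(breakpoint * nchar(parentA$cds))
  cds <- paste0(substr(parentA$cds, 1L, k),
                substr(parentB$cds, k + 1L, nchar(parentB$cds)))
  out <- kir_sequence(cds, exon_spans = parentA$exon_spans,
                      flank5 = parentA$flank5, flank3 = parentA$flank3,
                      complete = parentA$complete)
  attr(out, "breakpoint") <- k
  out
}

#' Build a synthetic registry from generated genes
#'
#' Registers each generated gene under a systematically numbered symbol
#' (tail class and domain count taken from its features) with the sequence
#' attached as allele `*001`.
#'
#' @param genes List from [kir_generate_gene_set()].
#' @param species Species code for the synthetic registry.
#' @param cfg A [kir_allocator_config()] (for feature extraction).
#' @return A `kir_registry`.
#' @export
kir_synth_registry <- function(genes, species = "Mamu",
                               cfg = kir_allocator_config()) {
  reg <- kir_registry_new()
  width <- species_gene_width(reg, species)
  for (i in seq_along(genes)) {
    feats <- kir_extract_features(genes[[i]], cfg)
    sym <- paste0(species, "-KIR", feats$domain_count, "D",
                  feats$tail_class, formatC(i, width = width, flag = "0"))
    reg <- kir_registry_add_gene(reg, sym)
    reg <- kir_registry_add_allele(reg, paste0(sym, "*001"),
                                   cds = genes[[i]]$cds,
                                   flank5 = genes[[i]]$flank5 %||%
                                     NA_character_,
                                   flank3 = genes[[i]]$flank3 %||%
                                     NA_character_)
  }
  reg
}
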