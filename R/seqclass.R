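# Structural features of annotated KIR coding sequences and tiered
# classification of differences between a candidate and a reference.
#
# Coordinates are 0-based half-open throughout; the reading frame is
# anchored at the first base of the cds.

EXON_LABELS <- c("leader", "D0", "D1", "D2", "stem", "TM", "cyt")

# standard genetic code, fetched once at namespace load
GENETIC_CODE_TAB <- Biostrings::GENETIC_CODE

#' Construct an annotated KIR-like coding sequence
#'
#' @param cds Nucleotide string (A/C/G/T; IUPAC ambiguity codes are
#'   tolerated up to 1 percent of positions downstream).
#' @param exon_spans Data frame with columns `label`, `start`, `end`
#'   (0-based half-open intervals over the cds) using labels from
#'   `leader`, `D0`, `D1`, `D2`, `stem`, `TM`, `cyt`.  Spans must tile the
#'   cds without overlap, and no domain label may appear twice.
#' @param flank5,flank3 Optional untranslated flanking blocks.
#' @param introns Optional named list of intron sequences.
#' @param complete Is the sequence full-length (annotated leader through
#'   stop)?  Incomplete sequences are compared over the shared annotated
#'   region only and naming decisions based on them are flagged.
#' @param genomic_exons Optional exon-label data frame describing the
#'   genomic gene content when the cds is a (possibly alternatively
#'   spliced) transcript; when present it, not the transcript annotation,
#'   determines the domain count.
#' @return An object of class `kir_sequence`.
#' @export
kir_sequence <- function(cds, exon_spans, flank5 = NULL, flank3 = NULL,
                         introns = NULL, complete = TRUE,
                         genomic_exons = NULL) {
  cds <- toupper(cds)
  if (is.null(exon_spans))
    kir_error("annotation required: exon_spans missing",
              "kir_annotation_error")
  es <- as.data.frame(exon_spans)
  if (!all(c("label", "start", "end") %in% names(es)))
    kir_error("exon_spans needs columns label, start, end",
              "kir_annotation_error")
  es <- es[order(es$start), ]
  bad <- setdiff(es$label, EXON_LABELS)
  if (length(bad))
    kir_error(sprintf("unknown exon label(s): %s", paste(bad, collapse = ", ")),
              "kir_annotation_error")
  if (anyDuplicated(es$label[es$label %in% c("D0", "D1", "D2")]))
    kir_error("ambiguous exon labels: duplicated domain label",
              "kir_annotation_error")
  if (es$start[1] != 0L || es$end[nrow(es)] != nchar(cds) ||
      (nrow(es) > 1L && any(es$start[-1] != es$end[-nrow(es)])))
    kir_error("exon spans must tile the cds without gaps or overlap",
              "kir_annotation_error")
  structure(list(cds = cds, exon_spans = es, flank5 = flank5,
                 flank3 = flank3, introns = introns, complete = complete,
                 genomic_exons = genomic_exons),
            class = "kir_sequence")
}

#' @export
print.kir_sequence <- function(x, ...) {
  cat("<kir_sequence> ", nchar(x$cds), " nt cds, exons: ",
      paste(x$exon_spans$label, collapse = "-"),
      if (!x$complete) " (partial)" else "", "\n", sep = "")
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codon-by-codon translation anchored at position 1; codons containing
#' IUPAC ambiguity characters translate to `X`, stop codons to `*`.  A
#' trailing partial codon is dropped.
#'
#' @param cds Nucleotide string.
#' @return Amino-acid string.
#' @export
kir_translate <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_TAB[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

ambiguity_fraction <- function(cds) {
  1 - nchar(gsub("[^ACGT]", "", cds)) / nchar(cds)
}

#' Derive structural features from an annotated sequence
#'
#' The Ig-domain count is annotation-driven: it is the number of domain
#' exons (`D0`, `D1`, `D2`) in the genomic annotation when one is attached,
#' otherwise in the transcript annotation -- so a gene whose transcript
#' splices out a domain exon still counts its genomic domain content.
#' Tail class is `L` when the cytoplasmic exon is at least
#' `tail_long_min_codons` codons long or its peptide carries an ITIM-like
#' motif, else `S`.
#'
#' @param seq A [kir_sequence()].
#' @param cfg An [kir_allocator_config()]; supplies the tail-length
#'   threshold, ITIM pattern and premature-stop fraction.
#' @return A list of class `kir_features`: `domain_count`, `tail_class`,
#'   `premature_stop`, `frameshift`, `start_lost`, `protein`.
#' @export
kir_extract_features <- function(seq, cfg = kir_allocator_config()) {
  if (!inherits(seq, "kir_sequence"))
    kir_error("expected a kir_sequence", "kir_annotation_error")
  lab_src <- if (!is.null(seq$genomic_exons)) as.data.frame(seq$genomic_exons)
             else seq$exon_spans
  domain_count <- sum(lab_src$label %in% c("D0", "D1", "D2"))

  cyt <- seq$exon_spans[seq$exon_spans$label == "cyt", ]
  if (nrow(cyt) == 1L) {
    cyt_nt <- substr(seq$cds, cyt$start + 1L, cyt$end)
    # translate the tail in the frame it occupies within the cds
    phase <- cyt$start %% 3L
    if (phase != 0L) cyt_nt <- substr(cyt_nt, 4L - phase, nchar(cyt_nt))
    cyt_aa <- kir_translate(cyt_nt)
    cyt_codons <- (cyt$end - cyt$start) %/% 3L
    long <- cyt_codons >= cfg$tail_long_min_codons ||
      grepl(cfg$itim_pattern, cyt_aa)
    tail_class <- if (long) "L" else "S"
  } else {
    tail_class <- "S"
  }

  prot_full <- kir_translate(seq$cds)
  stops <- gregexpr("*", prot_full, fixed = TRUE)[[1]]
  stops <- stops[stops > 0]
  n_codons <- nchar(prot_full)
  premature <- length(stops) > 0 &&
    min(stops) < cfg$premature_stop_fraction * n_codons
  frameshift <- seq$complete && nchar(seq$cds) %% 3L != 0L
  start_lost <- substr(seq$cds, 1L, 3L) != "ATG"
  protein <- if (length(stops)) substr(prot_full, 1L, min(stops) - 1L)
             else prot_full
  structure(list(domain_count = domain_count, tail_class = tail_class,
                 premature_stop = premature, frameshift = frameshift,
                 start_lost = start_lost, protein = protein),
            class = "kir_features")
}

#' @export
print.kir_features <- function(x, ...) {
  flags <- c("premature stop"[x$premature_stop], "frameshift"[x$frameshift],
             "start lost"[x$start_lost])
  cat("<kir_features> ", x$domain_count, " Ig domain(s), tail ",
      x$tail_class, ", protein ", nchar(x$protein), " aa",
      if (length(flags)) paste0(" [", paste(flags, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

# Global alignment of two cds strings.  Equal-length pairs are compared
# directly (substitution-only); otherwise a Needleman-Wunsch alignment
# with affine gaps (match 1, mismatch -1, open -4, extend -1).
align_cds <- function(a, b) {
  if (nchar(a) == nchar(b))
    return(list(pattern = a, subject = b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  list(pattern = as.character(Biostrings::alignedPattern(al)),
       subject = as.character(Biostrings::alignedSubject(al)))
}

aligned_identity <- function(pa, sa) {
  p <- strsplit(pa, "", fixed = TRUE)[[1]]
  s <- strsplit(sa, "", fixed = TRUE)[[1]]
  mean(p == s & p != "-")
}

count_block_diffs <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0L)     # compared only when both carry
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
    return(sum(av[keep] != bv[keep]))
  }
  al <- align_cds(a, b)
  p <- strsplit(al$pattern, "")[[1]]; s <- strsplit(al$subject, "")[[1]]
  sum(p != s)
}

#' Classify the differences between a novel and a reference sequence
#'
#' Globally aligns the two coding sequences, then walks reference-anchored
#' codons: a substitution is synonymous or non-synonymous according to
#' standard-code translation of the two codons, any codon touched by an
#' alignment gap escalates to the non-synonymous tier, and codons with an
#' ambiguity character in either sequence are excluded from the counts.
#' Intron and flank blocks are compared only when both sequences carry
#' them.  The tier is `identical`, `non_synonymous`, `synonymous` or
#' `non_coding_only` per the digit-tier rules: any non-synonymous change
#' dominates, then synonymous, then non-coding-only.
#'
#' @param novel,ref [kir_sequence()] objects.
#' @param cfg [kir_allocator_config()]; `comparability_floor` (default
#'   0.70 aligned identity) below which the pair is declared not
#'   comparable (wrong-gene comparison) instead of being tiered, and
#'   `max_ambiguity` (default 0.01) above which a sequence is rejected.
#' @return A list of class `kir_difference`: `tier`, `n_nonsyn`, `n_syn`,
#'   `n_noncoding`, `aligned_identity`, `n_ambiguous_excluded`,
#'   `partial_basis`.
#' @export
kir_classify_difference <- function(novel, ref,
                                    cfg = kir_allocator_config()) {
  for (s in list(novel, ref))
    if (ambiguity_fraction(s$cds) > cfg$max_ambiguity)
      kir_error(sprintf("sequence is %.1f%% ambiguous (limit %.0f%%)",
                        100 * ambiguity_fraction(s$cds),
                        100 * cfg$max_ambiguity), "kir_ambiguity_error")

  al <- align_cds(novel$cds, ref$cds)
  ident <- aligned_identity(al$pattern, al$subject)
  if (ident < cfg$comparability_floor)
    kir_error(sprintf(
      "aligned identity %.2f below comparability floor %.2f; likely a wrong-gene comparison",
      ident, cfg$comparability_floor), "kir_not_comparable")

  p <- strsplit(al$pattern, "")[[1]]   # novel
  s <- strsplit(al$subject, "")[[1]]   # reference
  acgt <- c("A", "C", "G", "T")
  if (nchar(novel$cds) == nchar(ref$cds)) {
    # substitution-only fast path: only differing codons need inspection
    ncod <- length(s) %/% 3L
    codon_of <- function(x, ci) paste(x[(ci * 3L - 2L):(ci * 3L)],
                                      collapse = "")
    diff_cod <- unique((which(p != s) - 1L) %/% 3L + 1L)
    diff_cod <- diff_cod[diff_cod <= ncod]
    n_nonsyn <- n_syn <- n_ambig <- 0L
    for (ci in diff_cod) {
      rng <- (ci * 3L - 2L):(ci * 3L)
      if (!all(c(p[rng], s[rng]) %in% acgt)) { n_ambig <- n_ambig + 1L; next }
      if (identical(kir_translate(codon_of(p, ci)),
                    kir_translate(codon_of(s, ci))))
        n_syn <- n_syn + 1L
      else
        n_nonsyn <- n_nonsyn + 1L
    }
  } else {
    # gapped path: walk alignment columns, reference-anchored
    ncod <- ceiling(sum(s != "-") / 3)
    gapped <- logical(ncod)
    nov_cod <- ref_cod <- vector("list", ncod)
    ref_pos <- 0L
    for (i in seq_along(s)) {
      ci <- min(ncod, ref_pos %/% 3L + 1L)
      if (s[i] == "-" || p[i] == "-") {
        gapped[ci] <- TRUE
      } else {
        ref_cod[[ci]] <- c(ref_cod[[ci]], s[i])
        nov_cod[[ci]] <- c(nov_cod[[ci]], p[i])
      }
      if (s[i] != "-") ref_pos <- ref_pos + 1L
    }
    n_nonsyn <- sum(gapped)
    n_syn <- 0L
    n_ambig <- 0L
    for (ci in which(!gapped)) {
      rc <- ref_cod[[ci]]; nc <- nov_cod[[ci]]
      if (length(rc) != 3L) next               # trailing partial codon
      if (!all(c(rc, nc) %in% acgt)) { n_ambig <- n_ambig + 1L; next }
      if (all(rc == nc)) next
      if (identical(kir_translate(paste(rc, collapse = "")),
                    kir_translate(paste(nc, collapse = ""))))
        n_syn <- n_syn + 1L
      else
        n_nonsyn <- n_nonsyn + 1L
    }
  }

  n_noncoding <- count_block_diffs(novel$flank5, ref$flank5) +
    count_block_diffs(novel$flank3, ref$flank3)
  if (!is.null(novel$introns) && !is.null(ref$introns))
    for (nm in intersect(names(novel$introns), names(ref$introns)))
      n_noncoding <- n_noncoding +
        count_block_diffs(novel$introns[[nm]], ref$introns[[nm]])

  tier <- if (n_nonsyn > 0L) "non_synonymous"
          else if (n_syn > 0L) "synonymous"
          else if (n_noncoding > 0L) "non_coding_only"
          else "identical"
  structure(list(tier = tier, n_nonsyn = n_nonsyn, n_syn = n_syn,
                 n_noncoding = n_noncoding, aligned_identity = ident,
                 n_ambiguous_excluded = n_ambig,
                 partial_basis = !novel$complete || !ref$complete),
            class = "kir_difference")
}

#' @export
print.kir_difference <- function(x, ...) {
  cat("<kir_difference> tier ", x$tier, " (", x$n_nonsyn, " non-syn, ",
      x$n_syn, " syn, ", x$n_noncoding, " non-coding; identity ",
      sprintf("%.3f", x$aligned_identity), ")",
      if (x$partial_basis) " [partial basis]", "\n", sep = "")
  invisible(x)
}

#' Read an annotation sidecar file
#'
#' The sidecar is JSON with an `exons` array of `{label, start, end}`
#' objects (0-based half-open over the cds), and optional `flank5`,
#' `flank3`, `introns` (object of name to sequence), `complete` and
#' `genomic_exons` entries.
#'
#' @param fasta Path to a single-record FASTA file with the cds.
#' @param annotation Path to the JSON sidecar.
#' @return A [kir_sequence()].
#' @export
kir_read_sequence <- function(fasta, annotation) {
  dna <- Biostrings::readDNAStringSet(fasta)
  if (length(dna) != 1L)
    kir_error("expected exactly one FASTA record", "kir_annotation_error")
  ann <- jsonlite::read_json(annotation, simplifyVector = TRUE)
  if (is.null(ann$exons))
    kir_error("annotation required: no 'exons' entry", "kir_annotation_error")
  kir_sequence(as.character(dna[[1]]),
               exon_spans = as.data.frame(ann$exons),
               flank5 = ann$flank5, flank3 = ann$flank3,
               introns = as.list(ann$introns),
               complete = ann$complete %||% TRUE,
               genomic_exons = if (!is.null(ann$genomic_exons))
                 as.data.frame(ann$genomic_exons))
}

#' Write a sequence and its annotation sidecar
#'
#' @param seq A [kir_sequence()].
#' @param name FASTA record name.
#' @param fasta,annotation Output paths.
#' @return `invisible(NULL)`.
#' @export
kir_write_sequence <- function(seq, name, fasta, annotation) {
  writeLines(c(paste0(">", name), seq$cds), fasta)
  obj <- list(exons = seq$exon_spans, complete = seq$complete)
  if (!is.null(seq$flank5)) obj$flank5 <- seq$flank5
  if (!is.null(seq$flank3)) obj$flank3 <- seq$flank3
  if (!is.null(seq$introns)) obj$introns <- seq$introns
  if (!is.null(seq$genomic_exons)) obj$genomic_exons <- seq$genomic_exons
  jsonlite::write_json(obj, annotation, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(NULL)
}
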