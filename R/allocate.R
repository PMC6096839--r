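# The naming engine: decide whether a novel sequence is an existing
# allele, a new allele at one of the three digit tiers, or a provisional
# (workshop) new gene; apply the recombinant majority-locus rule; append
# the null suffix when expression-destroying lesions are detected.

#' Configuration for the naming engine
#'
#' Houses every free parameter the nomenclature leaves qualitative, with
#' reproducible defaults.
#'
#' @param new_gene_identity_threshold Best-identity floor below which a
#'   candidate is proposed as a new (workshop) gene rather than an allele
#'   of an existing one.  Stands in for a phylogenetic divergence call.
#' @param window_size,window_step Width and stride (nt) of the windows
#'   used for the recombinant majority-locus vote.
#' @param comparability_floor Aligned identity below which two sequences
#'   are declared not comparable at all.
#' @param premature_stop_fraction An in-frame stop before this fraction of
#'   the annotated protein length flags the allele as null.
#' @param tail_long_min_codons Cytoplasmic exon length (codons) at or
#'   above which the tail is typed Long.
#' @param itim_pattern Regular expression for an ITIM-like motif in the
#'   cytoplasmic peptide; a match also types the tail Long.
#' @param max_ambiguity Maximum tolerated fraction of IUPAC-ambiguous
#'   positions in a coding sequence.
#' @param majority_margin Resolution band of the majority-locus call: when
#'   the leading locus owns no more than `0.5 + majority_margin` of the
#'   sequence under the refined two-segment fit, the recombinant is
#'   declared ambiguous and referred to manual review rather than named.
#' @return A list of class `kir_config`.
#' @export
kir_allocator_config <- function(new_gene_identity_threshold = 0.96,
                                 window_size = 100L,
                                 window_step = 50L,
                                 comparability_floor = 0.70,
                                 premature_stop_fraction = 0.90,
                                 tail_long_min_codons = 60L,
                                 itim_pattern = "[ILVS].Y..[LV]",
                                 max_ambiguity = 0.01,
                                 majority_margin = 0.02) {
  stopifnot(new_gene_identity_threshold > 0, new_gene_identity_threshold < 1,
            comparability_floor > 0, comparability_floor < 1,
            premature_stop_fraction > 0, premature_stop_fraction < 1,
            window_step <= window_size, window_step >= 1,
            majority_margin >= 0, majority_margin < 0.5)
  structure(list(new_gene_identity_threshold = new_gene_identity_threshold,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 comparability_floor = comparability_floor,
                 premature_stop_fraction = premature_stop_fraction,
                 tail_long_min_codons = as.integer(tail_long_min_codons),
                 itim_pattern = itim_pattern,
                 max_ambiguity = max_ambiguity,
                 majority_margin = majority_margin),
            class = "kir_config")
}

# Resolve the registry species a query species is named against: satellite
# species (Mafa, Mane) are assigned against the rhesus registry but keep
# their own prefix on output.
effective_species <- function(reg, species) {
  i <- match(species, reg$species_config$species)
  if (!is.na(i) && !is.na(reg$species_config$proxy_species[i]))
    reg$species_config$proxy_species[i]
  else species
}

species_gene_width <- function(reg, species) {
  i <- match(species, reg$species_config$species)
  if (is.na(i)) 1L else reg$species_config$gene_id_width[i]
}

# Window grid over the novel cds: regular stride plus a final window flush
# with the 3' end, so the whole sequence is covered and the vote is not
# biased toward the 5' side by an uncovered tail.
window_starts <- function(novel_len, cfg) {
  last <- max(0L, novel_len - cfg$window_size)
  unique(c(seq(0L, last, by = cfg$window_step), last))
}

# Per-position match vector of the novel sequence against one aligned
# allele, on novel cds coordinates.
match_profile <- function(novel_len, aln) {
  p <- strsplit(aln$pattern, "")[[1]]
  s <- strsplit(aln$subject, "")[[1]]
  keep <- p != "-"
  m <- logical(novel_len)
  m[cumsum(p != "-")[keep & s != "-" & p == s]] <- TRUE
  m
}

# Fraction of the novel sequence owned by locus A under the best
# two-segment partition (A then B, or B then A) of per-position matches
# against the two loci's nearest alleles.
ownership_fraction <- function(novel_len, aln_a, aln_b) {
  ma <- match_profile(novel_len, aln_a)
  mb <- match_profile(novel_len, aln_b)
  d <- cumsum(as.integer(ma) - as.integer(mb))
  # A-first: matches = sum(mb) + max over b of d[b]; B-first: sum(ma) - min d
  c0 <- c(0L, d)
  a_first_score <- sum(mb) + max(c0)
  b_first_score <- sum(ma) - min(c0)
  # the optimum is a plateau between informative (locus-discriminating)
  # sites; its midpoint is the unbiased breakpoint estimate
  plateau_mid <- function(idx) mean(range(idx)) - 1
  if (a_first_score >= b_first_score) {
    plateau_mid(which(c0 == max(c0))) / novel_len
  } else {
    1 - plateau_mid(which(c0 == min(c0))) / novel_len
  }
}

# Per-window identity between the novel sequence and one aligned allele.
# Windows are fixed on novel cds coordinates; each alignment's columns are
# mapped back to novel positions so gapped alignments vote correctly.
window_identities <- function(novel_len, aln, cfg) {
  starts <- window_starts(novel_len, cfg)
  p <- strsplit(aln$pattern, "")[[1]]   # novel
  s <- strsplit(aln$subject, "")[[1]]
  novel_pos <- cumsum(p != "-") - 1L    # 0-based novel position per column
  vapply(starts, function(st) {
    sel <- novel_pos >= st & novel_pos < st + cfg$window_size & p != "-"
    if (!any(sel)) return(NA_real_)
    mean(p[sel] == s[sel])
  }, 0)
}

#' Assign a novel sequence to a locus by windowed majority vote
#'
#' Aligns the candidate against every registered allele that carries a
#' sequence, then slides windows across the candidate cds; each window
#' votes for the gene of its nearest allele, and the gene collecting a
#' strict majority of votes wins.  Recombinants are thereby named for the
#' locus providing the majority of their sequence.  If no registered
#' allele reaches the new-gene identity threshold the candidate is
#' returned as a provisional workshop gene proposal instead.
#'
#' @param novel A [kir_sequence()].
#' @param reg A `kir_registry` whose alleles carry cds sequences.
#' @param species Species code of the candidate (satellite macaque species
#'   are matched against the rhesus registry).
#' @param cfg A [kir_allocator_config()].
#' @return A list: either `new_gene = FALSE` with `gene` (winning gene
#'   designation), `window_votes` (data frame of per-window winners) and
#'   `nearest` (per-allele global identities, best first), or
#'   `new_gene = TRUE` with a `proposal` gene symbol, `best_identity` and
#'   the [kir_features()] of the candidate.  A vote with no strict
#'   majority raises an `ambiguous recombinant` error for manual review.
#' @export
kir_assign_locus <- function(novel, reg, species,
                             cfg = kir_allocator_config()) {
  esp <- effective_species(reg, species)
  cand <- reg$alleles[reg$alleles$species == esp & !is.na(reg$alleles$cds), ,
                      drop = FALSE]
  if (!nrow(cand))
    return(new_gene_proposal(novel, reg, species, NA_real_, cfg))

  alns <- lapply(cand$cds, function(ref) align_cds(novel$cds, ref))
  ident <- vapply(alns, function(a) aligned_identity(a$pattern, a$subject), 0)
  comparable <- ident >= cfg$comparability_floor
  nearest <- data.frame(designation = cand$designation, gene = cand$gene,
                        identity = ident, stringsAsFactors = FALSE)
  nearest <- nearest[order(-nearest$identity, nearest$designation), ]
  rownames(nearest) <- NULL

  if (!any(comparable))
    return(new_gene_proposal(novel, reg, species, max(ident), cfg,
                             nearest = nearest))

  starts <- window_starts(nchar(novel$cds), cfg)
  wid <- vapply(alns[comparable],
                function(a) window_identities(nchar(novel$cds), a, cfg),
                numeric(length(starts)))
  wid <- matrix(wid, ncol = sum(comparable))
  genes <- cand$gene[comparable]

  # New-gene test on the windowed mosaic identity: each window is scored
  # against its own nearest allele, so a recombinant of two known genes
  # (locally near-identical to each parent) is never mistaken for a new
  # gene, while a uniformly divergent sequence falls below the threshold
  # in every window.
  mosaic <- mean(apply(wid, 1L, max, na.rm = TRUE))
  if (mosaic < cfg$new_gene_identity_threshold)
    return(new_gene_proposal(novel, reg, species, mosaic, cfg,
                             nearest = nearest))
  vote <- character(nrow(wid))
  for (w in seq_len(nrow(wid))) {
    row <- wid[w, ]
    if (all(is.na(row))) { vote[w] <- NA_character_; next }
    best <- max(row, na.rm = TRUE)
    winners <- unique(genes[!is.na(row) & row == best])
    vote[w] <- if (length(winners) == 1L) winners else NA_character_
  }
  cast <- vote[!is.na(vote)]
  if (!length(cast))
    kir_error("ambiguous recombinant: no window could vote",
              "kir_ambiguous_recombinant")
  tab <- sort(table(cast), decreasing = TRUE)
  if (length(tab) == 1L) {
    win_gene <- names(tab)[1]
  } else {
    # Window votes nominate the two leading loci; the majority call is
    # then refined at nucleotide resolution with an optimal two-segment
    # fit between each locus's nearest allele.  A leading share within
    # `majority_margin` of an even split is below the method's resolution
    # and is surfaced as ambiguous rather than decided.
    top2 <- names(tab)[1:2]
    best_aln <- lapply(top2, function(g) {
      sel <- which(cand$gene == g & comparable)
      alns[[sel[which.max(ident[sel])]]]
    })
    own <- ownership_fraction(nchar(novel$cds), best_aln[[1]], best_aln[[2]])
    if (abs(own - 0.5) <= cfg$majority_margin)
      kir_error(sprintf(
        "ambiguous recombinant: leading locus owns %.1f%% of the sequence (within the %.0f%% resolution band); manual review required",
        100 * max(own, 1 - own), 100 * cfg$majority_margin),
        "kir_ambiguous_recombinant")
    win_gene <- if (own > 0.5) top2[1] else top2[2]
  }
  list(new_gene = FALSE,
       gene = paste0(esp, "-", win_gene),
       output_species = species,
       window_votes = data.frame(start = starts,
                                 end = pmin(starts + cfg$window_size,
                                            nchar(novel$cds)),
                                 gene = vote, stringsAsFactors = FALSE),
       nearest = nearest)
}

new_gene_proposal <- function(novel, reg, species, best_identity, cfg,
                              nearest = NULL) {
  feats <- kir_extract_features(novel, cfg)
  esp <- effective_species(reg, species)
  syms <- reg$genes[reg$genes$species == esp, "designation"]
  nums <- vapply(syms, function(d) {
    p <- kir_parse(d)
    # the divergent-X series is numbered separately; skip it and the
    # number-free degenerate forms when continuing the main sequence
    if (p$x_lineage != "none" || !nzchar(p$gene_id)) return(NA_integer_)
    as.integer(p$gene_id)
  }, 0L)
  nxt <- max(c(0L, nums), na.rm = TRUE) + 1L
  width <- species_gene_width(reg, species)
  sym <- paste0(species, "-KIR", feats$domain_count, "D", feats$tail_class,
                "W", formatC(nxt, width = width, flag = "0"))
  list(new_gene = TRUE, proposal = sym, best_identity = best_identity,
       features = feats, output_species = species, nearest = nearest)
}

check_evidence <- function(evidence) {
  if (is.null(evidence) || !length(evidence)) return(FALSE)
  if (is.data.frame(evidence)) {
    kinds <- evidence$kind; labels <- evidence$label
  } else {
    kinds <- vapply(evidence, `[[`, "", "kind")
    labels <- vapply(evidence, `[[`, "", "label")
  }
  n_ind <- length(unique(labels[kinds == "individual"]))
  n_pcr <- length(unique(labels[kinds == "independent_pcr"]))
  n_ind >= 2L || n_pcr >= 2L
}

#' Assign a standards-conformant name to a novel sequence
#'
#' Full naming pipeline: submission checks (full-length where the species
#' mandates it; replication evidence from at least two individuals or two
#' independent PCR/cloning experiments), locus assignment by windowed
#' majority vote, then tier classification against every sequenced allele
#' of the winning gene.  A sequence identical to a registered allele over
#' the full shared region keeps that allele's name; a coding-synonymous
#' variant extends the nearest matching allele's name at the second digit
#' field; a variant differing only in non-coding blocks extends it at the
#' third; anything with a protein-level difference receives the next free
#' first-field number.  Expression-destroying lesions (premature stop,
#' frameshift, lost start) append the `N` suffix.  The `L`, `S`, `C`, `A`
#' and `Q` suffixes encode expression measurements and are never inferred
#' from sequence; they are curator metadata only.
#'
#' @param novel A [kir_sequence()].
#' @param reg A `kir_registry` with cds attached to its alleles.
#' @param species Species code of the submission.
#' @param meta List with `date` (scalar), `evidence` (list of
#'   `list(kind = "individual"|"independent_pcr", label = ...)`) and
#'   optionally `completeness` (`"full"` or `"partial"`, default taken
#'   from the sequence's `complete` flag).
#' @param cfg A [kir_allocator_config()].
#' @return A `kir_decision`: `status` (one of `existing_allele`,
#'   `new_tier1`, `new_tier2`, `new_tier3`, `new_gene_workshop`,
#'   `rejected`), `assigned` (designation string, `NA` when rejected),
#'   `nearest`, `window_votes`, `suffix_triggers`, `checks` and `notes`
#'   (including the incumbent's canonical long form when a bare name is
#'   first extended to a longer one).
#' @export
kir_assign_name <- function(novel, reg, species, meta,
                            cfg = kir_allocator_config()) {
  completeness <- meta$completeness %||%
    (if (isTRUE(novel$complete)) "full" else "partial")
  i <- match(species, reg$species_config$species)
  flm <- !is.na(i) && reg$species_config$full_length_mandatory[i]
  checks <- list(
    full_length = if (!flm) "waived"
                  else if (identical(completeness, "full")) "pass" else "fail",
    evidence = if (check_evidence(meta$evidence)) "pass" else "fail")
  if (checks$full_length == "fail" || checks$evidence == "fail") {
    failed <- names(checks)[unlist(checks) == "fail"]
    return(kir_decision("rejected", NA_character_, checks = checks,
                        notes = sprintf("failed check(s): %s",
                                        paste(failed, collapse = ", "))))
  }

  feats <- kir_extract_features(novel, cfg)
  triggers <- c("premature_stop"[feats$premature_stop],
                "frameshift"[feats$frameshift],
                "start_lost"[feats$start_lost])
  nullsfx <- if (length(triggers)) "N" else ""

  locus <- kir_assign_locus(novel, reg, species, cfg)
  if (locus$new_gene) {
    assigned <- paste0(locus$proposal, "*001", nullsfx)
    return(kir_decision("new_gene_workshop", assigned,
                        nearest = locus$nearest,
                        suffix_triggers = triggers, checks = checks,
                        notes = sprintf("best identity %.3f below threshold %.3f",
                                        locus$best_identity,
                                        cfg$new_gene_identity_threshold)))
  }

  esp <- effective_species(reg, species)
  gene_sym <- sub("^[A-Za-z]{4}-", "", locus$gene)
  out_gene <- paste0(species, "-", gene_sym)
  gene_alleles <- reg$alleles[reg$alleles$species == esp &
                              reg$alleles$gene == gene_sym &
                              !is.na(reg$alleles$cds), , drop = FALSE]
  diffs <- vector("list", nrow(gene_alleles))
  for (k in seq_len(nrow(gene_alleles))) {
    # tier classification is cds- and flank-driven, so a registered allele
    # needs no exon annotation: a single covering span suffices
    ref <- kir_sequence(gene_alleles$cds[k],
                        exon_spans = data.frame(
                          label = "leader", start = 0L,
                          end = nchar(gene_alleles$cds[k])),
                        flank5 = if (!is.na(gene_alleles$flank5[k]))
                          gene_alleles$flank5[k],
                        flank3 = if (!is.na(gene_alleles$flank3[k]))
                          gene_alleles$flank3[k])
    diffs[[k]] <- tryCatch(kir_classify_difference(novel, ref, cfg),
                           kir_not_comparable = function(e) NULL)
  }
  ok <- !vapply(diffs, is.null, TRUE)
  gene_alleles <- gene_alleles[ok, , drop = FALSE]
  diffs <- diffs[ok]
  tiers <- vapply(diffs, `[[`, "", "tier")
  idents <- vapply(diffs, `[[`, 0, "aligned_identity")
  ord <- order(-idents, match(gene_alleles$designation,
                              kir_sort(gene_alleles$designation)))
  nearest_df <- data.frame(designation = gene_alleles$designation[ord],
                           identity = idents[ord], tier = tiers[ord],
                           stringsAsFactors = FALSE)

  pick <- function(tier) {
    sel <- which(tiers == tier)
    if (!length(sel)) return(NA_integer_)
    sel[order(-idents[sel])][1]
  }

  partial_note <- if (!novel$complete) "partial-basis comparison" else NULL

  k <- pick("identical")
  if (!is.na(k))
    return(kir_decision("existing_allele", gene_alleles$designation[k],
                        nearest = nearest_df, window_votes = locus$window_votes,
                        suffix_triggers = triggers, checks = checks,
                        notes = partial_note))

  k <- pick("synonymous")
  if (!is.na(k)) {
    parent <- gene_alleles$designation[k]
    pn <- kir_parse(parent)
    f2 <- kir_next_available(reg, locus$gene, 2L, parent = parent)
    assigned <- paste0(out_gene, "*", pn$field1, ":", f2, nullsfx)
    note <- if (is.na(pn$field2))
      sprintf("incumbent '%s' keeps its short form as an alias; canonical long form '%s*%s:01'",
              parent, out_gene, pn$field1)
    return(kir_decision("new_tier2", assigned, nearest = nearest_df,
                        window_votes = locus$window_votes,
                        suffix_triggers = triggers, checks = checks,
                        notes = c(note, partial_note)))
  }

  k <- pick("non_coding_only")
  if (!is.na(k)) {
    parent <- gene_alleles$designation[k]
    pn <- kir_parse(parent)
    f2 <- if (is.na(pn$field2)) "01" else pn$field2
    f3 <- kir_next_available(reg, locus$gene, 3L, parent = parent)
    assigned <- paste0(out_gene, "*", pn$field1, ":", f2, ":", f3, nullsfx)
    note <- if (is.na(pn$field3))
      sprintf("incumbent '%s' keeps its short form as an alias; canonical long form '%s*%s:%s:01'",
              parent, out_gene, pn$field1, f2)
    return(kir_decision("new_tier3", assigned, nearest = nearest_df,
                        window_votes = locus$window_votes,
                        suffix_triggers = triggers, checks = checks,
                        notes = c(note, partial_note)))
  }

  f1 <- kir_next_available(reg, locus$gene, 1L)
  assigned <- paste0(out_gene, "*", f1, nullsfx)
  kir_decision("new_tier1", assigned, nearest = nearest_df,
               window_votes = locus$window_votes,
               suffix_triggers = triggers, checks = checks,
               notes = partial_note)
}

kir_decision <- function(status, assigned, nearest = NULL,
                         window_votes = NULL, suffix_triggers = character(),
                         checks = NULL, notes = NULL) {
  structure(list(status = status, assigned = assigned, nearest = nearest,
                 window_votes = window_votes,
                 suffix_triggers = suffix_triggers, checks = checks,
                 notes = notes),
            class = "kir_decision")
}

#' @export
print.kir_decision <- function(x, ...) {
  cat("<kir_decision> ", x$status,
      if (!is.na(x$assigned)) paste0(": ", x$assigned), "\n", sep = "")
  if (!is.null(x$nearest) && nrow(x$nearest))
    cat("  nearest: ", x$nearest$designation[1],
        sprintf(" (identity %.3f)", x$nearest$identity[1]), "\n", sep = "")
  if (length(x$suffix_triggers))
    cat("  suffix triggers:", paste(x$suffix_triggers, collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Record an accepted naming decision in the registry
#'
#' A no-op for `existing_allele` decisions (idempotent resubmission); for
#' new names, registers the gene (workshop proposals) and/or allele with
#' the submitted sequence attached.
#'
#' @param reg A `kir_registry`.
#' @param decision A `kir_decision` from [kir_assign_name()].
#' @param novel The submitted [kir_sequence()].
#' @param meta The submission metadata used for the decision.
#' @return The updated registry.
#' @export
kir_registry_commit <- function(reg, decision, novel, meta = list()) {
  if (decision$status %in% c("existing_allele", "rejected"))
    return(reg)
  gene <- sub("\\*.*$", "", decision$assigned)
  if (!gene %in% reg$genes$designation)
    reg <- kir_registry_add_gene(reg, gene)
  kir_registry_add_allele(reg, decision$assigned, cds = novel$cds,
                          flank5 = novel$flank5 %||% NA_character_,
                          flank3 = novel$flank3 %||% NA_character_,
                          submission_date = meta$date %||% NA_character_)
}
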