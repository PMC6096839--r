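# Resolution of previous (pre-standardization) designations to current
# ones.  Legacy names are opaque keys: many of them ("KIR3DH1",
# "Pt-KIR3DL1/2", "2DL501NK") do not parse under the current grammar, so
# matching is by normalized string lookup, never by structural parsing.

normalize_legacy <- function(s) {
  s <- trimws(s)
  s <- sub("^[A-Z][a-z]{3}-", "", s)         # optional 4-char species prefix
  tolower(s)
}

#' Build the legacy-name lookup table for a registry
#'
#' Indexes every previous designation in the registry (gene- and
#' allele-level).  Compound names containing `/` are indexed whole and
#' additionally split on `/`, keeping only parts long enough to be names
#' in their own right (the published orangutan tables mix the whole-name
#' and split conventions).
#'
#' @param reg A `kir_registry`.
#' @return Data frame with columns `species`, `key` (normalized previous
#'   designation), `target` (current designation) and `accessions`.
#' @export
kir_legacy_index <- function(reg) {
  rows <- list()
  add <- function(species, target, prevs, accessions) {
    for (p in prevs) {
      keys <- p
      if (grepl("/", p, fixed = TRUE)) {
        parts <- strsplit(p, "/", fixed = TRUE)[[1]]
        keys <- c(keys, parts[nchar(parts) >= 3L])
      }
      for (k in unique(normalize_legacy(keys)))
        rows[[length(rows) + 1L]] <<- list(species = species, key = k,
                                           target = target,
                                           accessions = accessions)
    }
  }
  for (i in seq_len(nrow(reg$genes)))
    add(reg$genes$species[i], reg$genes$designation[i],
        reg$genes$previous[[i]], character())
  for (i in seq_len(nrow(reg$alleles)))
    add(reg$alleles$species[i], reg$alleles$designation[i],
        reg$alleles$previous[[i]], reg$alleles$accessions[[i]])
  idx <- if (!length(rows)) {
    data.frame(species = character(), key = character(),
               target = character(), accessions = I(list()))
  } else {
    data.frame(species = vapply(rows, `[[`, "", "species"),
               key = vapply(rows, `[[`, "", "key"),
               target = vapply(rows, `[[`, "", "target"),
               accessions = I(lapply(rows, `[[`, "accessions")),
               stringsAsFactors = FALSE)
  }
  # normalized current designations, for idempotent self-resolution
  attr(idx, "current") <- data.frame(
    species = c(reg$genes$species, reg$alleles$species),
    target = c(reg$genes$designation, reg$alleles$designation),
    key = normalize_legacy(c(reg$genes$designation,
                             reg$alleles$designation)),
    accessions = I(c(rep(list(character()), nrow(reg$genes)),
                     reg$alleles$accessions)),
    stringsAsFactors = FALSE)
  idx
}

#' Resolve a legacy KIR designation to current designations
#'
#' Looks the query up among all previous designations recorded in the
#' registry (both gene- and allele-level), after normalization that trims
#' whitespace, strips an optional four-character species prefix and folds
#' case.  Genuine ambiguity is preserved: a legacy symbol that was applied
#' to several current genes or alleles returns all of them, and supplying
#' an accession narrows -- never widens -- the candidate set.  A current
#' designation resolves to itself.
#'
#' @param reg A `kir_registry`.
#' @param query Legacy (or current) designation string.
#' @param species Optional species code filter.
#' @param accession Optional accession identifier; keeps only allele
#'   targets whose accession list contains it.
#' @param index Prebuilt lookup table from [kir_legacy_index()]; supply it
#'   when resolving many queries against the same registry.
#' @return A list with `status` (`"ok"` or `"no_mapping"` -- distinct from
#'   a parse error, which legacy queries never raise) and `targets`, a
#'   data frame with columns `species` and `designation` in canonical
#'   order.
#' @examples
#' reg <- kir_registry_packaged()
#' kir_resolve_legacy(reg, "KIR3DL5", species = "Mamu")
#' @export
kir_resolve_legacy <- function(reg, query, species = NULL,
                               accession = NULL,
                               index = kir_legacy_index(reg)) {
  if (!nzchar(trimws(query)))
    kir_error("empty legacy query", "kir_legacy_error")
  idx <- index
  key <- normalize_legacy(query)
  hit <- idx[idx$key == key, , drop = FALSE]

  # idempotence: a current designation is its own resolution
  cur <- attr(idx, "current")
  self <- cur[cur$key == key, , drop = FALSE]
  if (nrow(self))
    hit <- rbind(hit[, c("species", "target", "accessions")],
                 self[, c("species", "target", "accessions")])
  if (!is.null(species))
    hit <- hit[hit$species == species, , drop = FALSE]
  if (!is.null(accession))
    hit <- hit[vapply(hit$accessions, function(a) accession %in% a, TRUE),
               , drop = FALSE]
  targets <- unique(hit[, c("species", "target")])
  names(targets)[2] <- "designation"
  if (!nrow(targets))
    return(list(status = "no_mapping",
                targets = data.frame(species = character(),
                                     designation = character())))
  targets <- targets[order(targets$species,
                           match(targets$designation,
                                 kir_sort(targets$designation))), ]
  rownames(targets) <- NULL
  list(status = "ok", targets = targets)
}
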