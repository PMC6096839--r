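# Grammar for non-human KIR gene and allele designations.
#
# A designation is, in order:
#   [Xxxx-]  four-character species prefix (e.g. "Mamu", "Bota"), optional
#   KIR      literal acronym
#   <symbol> gene symbol body: number of Ig-like domains (1-3), "D",
#            optional "X" (cattle-style divergent-lineage marker before the
#            tail letter), tail letter L/S/P, optional "W" (workshop),
#            optional "X" (macaque-style divergent marker after the tail
#            letter), then a 1-2 digit gene number.  Two degenerate forms
#            exist: "1D" with no tail letter and no gene number, and "DP"
#            (pseudogene) with no domain count and no gene number.
#   *fff[:ss[:tt]][suffix]  optional allele fields: a 3-digit protein-level
#            field, a 2-digit synonymous-difference field, a 2-digit
#            non-coding-difference field, and an expression suffix from
#            {N,L,S,C,A,Q}.
#
# Zero-padding of the gene number is data, not formatting: the macaque
# series is deliberately two-digit ("3DL01") while ape and cattle numbers
# are unpadded ("3DL1"), so the printed form is preserved and equality on
# gene_id is string equality.

kir_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kir_error")))
}

#' Parse a KIR designation string
#'
#' Decomposes a gene or allele designation such as `"Mamu-KIR3DL01*019:02"`
#' into its structural parts.  Unknown species prefixes are accepted: the
#' set of valid prefixes is registry data, not grammar.
#'
#' @param designation A single designation string.  Surrounding whitespace
#'   is trimmed; matching is otherwise case-sensitive.
#' @return An object of class `kir_name`: a list with elements
#'   `species` (4-character prefix or `NA`), `domain_count` (1-3 or `NA`),
#'   `x_lineage` (`"none"`, `"pre_tail"` or `"post_tail"`),
#'   `tail_class` (`"L"`, `"S"`, `"P"` or `"none"`), `workshop` (logical),
#'   `dp_form` (logical, `TRUE` for the "KIRDP" pseudogene form),
#'   `gene_id` (gene number as printed, possibly `""`),
#'   `field1`/`field2`/`field3` (digit strings or `NA`),
#'   `suffix` (`"none"` or one of N, L, S, C, A, Q) and `raw`.
#' @seealso [kir_format()], [kir_compare()]
#' @examples
#' kir_parse("Mamu-KIR3DL01*019:02")
#' kir_parse("Bota-KIR3DXL6*001N")
#' @export
kir_parse <- function(designation) {
  if (length(designation) != 1L || !is.character(designation))
    kir_error("designation must be a single character string",
              "kir_parse_error")
  s <- trimws(designation)
  if (!nzchar(s))
    kir_error("empty designation", "kir_parse_error")

  rest <- s
  species <- NA_character_
  m <- regmatches(rest, regexec("^([A-Z][a-z]{3})-", rest))[[1]]
  if (length(m)) {
    species <- m[2]
    rest <- substr(rest, 6L, nchar(rest))
  }
  if (!startsWith(rest, "KIR"))
    kir_error(sprintf("expected 'KIR' acronym at position %d in '%s'",
                      if (is.na(species)) 1L else 6L, s),
              "kir_parse_error")
  rest <- substr(rest, 4L, nchar(rest))

  star <- regexpr("*", rest, fixed = TRUE)
  if (star > 0) {
    symbol <- substr(rest, 1L, star - 1L)
    allele <- substr(rest, star + 1L, nchar(rest))
  } else {
    symbol <- rest
    allele <- NULL
  }

  g <- parse_symbol(symbol, s)
  a <- parse_allele_fields(allele, s)

  out <- structure(c(list(species = species), g, a, list(raw = s)),
                   class = "kir_name")
  check_name_invariants(out)
  out
}

parse_symbol <- function(symbol, full) {
  if (!nzchar(symbol))
    kir_error(sprintf("missing gene symbol in '%s'", full), "kir_parse_error")
  if (symbol == "DP")
    return(list(domain_count = NA_integer_, x_lineage = "none",
                tail_class = "P", workshop = FALSE, dp_form = TRUE,
                gene_id = ""))
  dm <- regmatches(symbol, regexec("^([0-9])D", symbol))[[1]]
  if (!length(dm))
    kir_error(sprintf("malformed symbol '%s': expected domain count digit then 'D'",
                      symbol), "kir_parse_error")
  domain <- as.integer(dm[2])
  if (domain < 1L || domain > 3L)
    kir_error(sprintf("domain count %d out of range 1-3 in '%s'",
                      domain, full), "kir_parse_error")
  body <- substr(symbol, 3L, nchar(symbol))

  if (!nzchar(body)) {                       # "KIR1D" tailless form
    if (domain != 1L)
      kir_error(sprintf("tailless symbol '%s' is only legal with one Ig domain",
                        symbol), "kir_parse_error")
    return(list(domain_count = domain, x_lineage = "none",
                tail_class = "none", workshop = FALSE, dp_form = FALSE,
                gene_id = ""))
  }

  x_lineage <- "none"
  if (startsWith(body, "X")) {
    x_lineage <- "pre_tail"
    body <- substr(body, 2L, nchar(body))
  }
  tail <- substr(body, 1L, 1L)
  if (!tail %in% c("L", "S", "P"))
    kir_error(sprintf("invalid tail letter '%s' in '%s' (expected L, S or P)",
                      tail, full), "kir_parse_error")
  body <- substr(body, 2L, nchar(body))
  workshop <- FALSE
  if (startsWith(body, "W")) {
    workshop <- TRUE
    body <- substr(body, 2L, nchar(body))
  }
  if (startsWith(body, "X")) {
    if (x_lineage != "none")
      kir_error(sprintf("double 'X' marker in '%s'", full), "kir_parse_error")
    x_lineage <- "post_tail"
    body <- substr(body, 2L, nchar(body))
  }
  if (!nzchar(body))
    kir_error(sprintf("missing gene number in '%s'", full), "kir_parse_error")
  if (!grepl("^[0-9]+$", body))
    kir_error(sprintf("malformed gene number '%s' in '%s'", body, full),
              "kir_parse_error")
  if (nchar(body) > 2L)
    kir_error(sprintf("gene number '%s' longer than two digits in '%s'",
                      body, full), "kir_parse_error")
  list(domain_count = domain, x_lineage = x_lineage, tail_class = tail,
       workshop = workshop, dp_form = FALSE, gene_id = body)
}

parse_allele_fields <- function(allele, full) {
  empty <- list(field1 = NA_character_, field2 = NA_character_,
                field3 = NA_character_, suffix = "none")
  if (is.null(allele))
    return(empty)
  if (!nzchar(allele))
    kir_error(sprintf("empty allele part after '*' in '%s'", full),
              "kir_parse_error")
  suffix <- "none"
  last <- substr(allele, nchar(allele), nchar(allele))
  if (grepl("[A-Za-z]", last)) {
    if (!last %in% c("N", "L", "S", "C", "A", "Q"))
      kir_error(sprintf("suffix '%s' outside {N,L,S,C,A,Q} in '%s'",
                        last, full), "kir_parse_error")
    suffix <- last
    allele <- substr(allele, 1L, nchar(allele) - 1L)
  }
  toks <- strsplit(allele, ":", fixed = TRUE)[[1]]
  if (length(toks) < 1L || length(toks) > 3L)
    kir_error(sprintf("too many colon-separated fields in '%s'", full),
              "kir_parse_error")
  if (!grepl("^[0-9]{3}$", toks[1]))
    kir_error(sprintf("first allele field '%s' is not 3 digits in '%s'",
                      toks[1], full), "kir_parse_error")
  for (k in seq_along(toks)[-1])
    if (!grepl("^[0-9]{2}$", toks[k]))
      kir_error(sprintf("allele field %d ('%s') is not 2 digits in '%s'",
                        k, toks[k], full), "kir_parse_error")
  list(field1 = toks[1],
       field2 = if (length(toks) >= 2L) toks[2] else NA_character_,
       field3 = if (length(toks) >= 3L) toks[3] else NA_character_,
       suffix = suffix)
}

check_name_invariants <- function(x) {
  if (!is.na(x$field2) && is.na(x$field1))
    kir_error("second allele field without a first", "kir_invariant_error")
  if (!is.na(x$field3) && is.na(x$field2))
    kir_error("third allele field without a second", "kir_invariant_error")
  if (x$suffix != "none" && is.na(x$field1))
    kir_error("expression suffix on a gene-level name", "kir_invariant_error")
  if (x$tail_class == "none" &&
      (is.na(x$domain_count) || x$domain_count != 1L))
    kir_error("tailless symbol requires exactly one Ig domain",
              "kir_invariant_error")
  if (x$workshop && !x$tail_class %in% c("L", "S", "P"))
    kir_error("workshop flag requires a tail letter", "kir_invariant_error")
  if (x$dp_form && (!is.na(x$domain_count) || nzchar(x$gene_id)))
    kir_error("pseudogene 'DP' form carries no domain count or gene number",
              "kir_invariant_error")
  invisible(x)
}

#' Format a parsed KIR name back to its designation string
#'
#' Inverse of [kir_parse()]: `kir_format(kir_parse(s))` reproduces `s`
#' byte-for-byte for every designation in the packaged registry.  Names
#' violating the grammar invariants are refused.
#'
#' @param name A `kir_name` object.
#' @return The canonical designation string (plain text; italicization of
#'   gene symbols is typographic and out of band).
#' @export
kir_format <- function(name) {
  if (!inherits(name, "kir_name"))
    kir_error("expected a kir_name object", "kir_format_error")
  check_name_invariants(name)
  sym <- if (name$dp_form) {
    "DP"
  } else {
    paste0(name$domain_count, "D",
           if (name$x_lineage == "pre_tail") "X" else "",
           if (name$tail_class == "none") "" else name$tail_class,
           if (name$workshop) "W" else "",
           if (name$x_lineage == "post_tail") "X" else "",
           name$gene_id)
  }
  allele <- if (!is.na(name$field1)) {
    paste0("*", name$field1,
           if (!is.na(name$field2)) paste0(":", name$field2) else "",
           if (!is.na(name$field3)) paste0(":", name$field3) else "",
           if (name$suffix != "none") name$suffix else "")
  } else ""
  paste0(if (!is.na(name$species)) paste0(name$species, "-") else "",
         "KIR", sym, allele)
}

#' @export
print.kir_name <- function(x, ...) {
  cat("<kir_name> ", x$raw, "\n", sep = "")
  cat("  species:     ", if (is.na(x$species)) "(none)" else x$species, "\n")
  cat("  domains:     ", if (is.na(x$domain_count)) "(none)" else
        x$domain_count, "\n")
  cat("  tail:        ", x$tail_class,
      if (x$workshop) " (workshop)" else "", "\n", sep = "")
  if (x$x_lineage != "none")
    cat("  X marker:    ", x$x_lineage, "\n")
  cat("  gene number: ", if (nzchar(x$gene_id)) x$gene_id else "(none)", "\n")
  if (!is.na(x$field1))
    cat("  allele:      ", paste(stats::na.omit(
      c(x$field1, x$field2, x$field3)), collapse = ":"),
      if (x$suffix != "none") paste0(" suffix ", x$suffix) else "",
      "\n", sep = "")
  invisible(x)
}

suffix_rank <- c(none = 0, N = 1, L = 2, S = 3, C = 4, A = 5, Q = 6)
tail_rank <- c(none = 0, L = 1, S = 2, P = 3)
xlin_rank <- c(none = 0, pre_tail = 1, post_tail = 2)

# Numeric sort key used by both kir_compare and kir_sort; one row per name.
name_sort_key <- function(names) {
  df <- data.frame(
    species = vapply(names, function(n)
      if (is.na(n$species)) "" else n$species, ""),
    domain = vapply(names, function(n)
      if (is.na(n$domain_count)) -1L else n$domain_count, 0L),
    dp = vapply(names, function(n) as.integer(n$dp_form), 0L),
    tail = vapply(names, function(n) tail_rank[[n$tail_class]], 0),
    workshop = vapply(names, function(n) as.integer(n$workshop), 0L),
    xlin = vapply(names, function(n) xlin_rank[[n$x_lineage]], 0),
    gene = vapply(names, function(n)
      if (nzchar(n$gene_id)) as.integer(n$gene_id) else -1L, 0L),
    f1 = vapply(names, function(n)
      if (is.na(n$field1)) -1L else as.integer(n$field1), 0L),
    f2 = vapply(names, function(n)
      if (is.na(n$field2)) -1L else as.integer(n$field2), 0L),
    f3 = vapply(names, function(n)
      if (is.na(n$field3)) -1L else as.integer(n$field3), 0L),
    suffix = vapply(names, function(n) suffix_rank[[n$suffix]], 0),
    stringsAsFactors = FALSE)
  df
}

#' Compare two KIR names under the canonical total order
#'
#' Orders by species (lexicographic), then gene symbol (domain count, tail
#' class, workshop flag, numeric gene number), then the three allele fields
#' numerically with absent fields sorting before present ones, then suffix.
#'
#' @param a,b `kir_name` objects or designation strings.
#' @return -1, 0 or 1.
#' @export
kir_compare <- function(a, b) {
  if (is.character(a)) a <- kir_parse(a)
  if (is.character(b)) b <- kir_parse(b)
  k <- name_sort_key(list(a, b))
  for (col in names(k)) {
    if (k[1, col] < k[2, col]) return(-1L)
    if (k[1, col] > k[2, col]) return(1L)
  }
  0L
}

#' Sort designation strings in canonical order
#'
#' @param designations Character vector of parseable designations.
#' @return The input, reordered; a stable sort (ties keep input order).
#' @export
kir_sort <- function(designations) {
  names <- lapply(designations, kir_parse)
  k <- name_sort_key(names)
  designations[do.call(order, k)]
}
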