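test_that("published designations decompose into their structural parts", {
  x <- kir_parse("Mamu-KIR3DL01*019:02")
  expect_equal(x$species, "Mamu")
  expect_equal(x$domain_count, 3L)
  expect_equal(x$tail_class, "L")
  expect_equal(x$gene_id, "01")
  expect_equal(x$field1, "019")
  expect_equal(x$field2, "02")
  expect_true(is.na(x$field3))
  expect_equal(x$suffix, "none")

  x <- kir_parse("Poab-KIRDP*001")
  expect_equal(x$species, "Poab")
  expect_true(is.na(x$domain_count))
  expect_true(x$dp_form)
  expect_equal(x$tail_class, "P")
  expect_equal(x$field1, "001")

  x <- kir_parse("Bota-KIR3DXL6*001N")
  expect_equal(x$species, "Bota")
  expect_equal(x$domain_count, 3L)
  expect_equal(x$x_lineage, "pre_tail")
  expect_equal(x$tail_class, "L")
  expect_equal(x$gene_id, "6")
  expect_equal(x$suffix, "N")

  x <- kir_parse("Mamu-KIR3DSW08*010")
  expect_true(x$workshop)
  expect_equal(x$tail_class, "S")
  expect_equal(x$gene_id, "08")

  # the two divergent-lineage marker positions stay distinct
  expect_equal(kir_parse("Mamu-KIR3DLX1")$x_lineage, "post_tail")
  expect_equal(kir_parse("Bota-KIR3DXL1")$x_lineage, "pre_tail")

  # tailless one-domain form
  x <- kir_parse("Mamu-KIR1D*002")
  expect_equal(x$tail_class, "none")
  expect_equal(x$domain_count, 1L)
})

test_that("malformed designations are rejected with a named token", {
  expect_error(kir_parse("KIR4DQ1"), "out of range", class = "kir_parse_error")
  expect_error(kir_parse("KIR3DM1"), "tail letter", class = "kir_parse_error")
  expect_error(kir_parse("Mamu-KIR3DL01*01"), "not 3 digits",
               class = "kir_parse_error")
  expect_error(kir_parse("Mamu-KIR3DL01*001:002"), "not 2 digits",
               class = "kir_parse_error")
  expect_error(kir_parse("Mamu-KIR3DL01*001Z"), "suffix",
               class = "kir_parse_error")
  expect_error(kir_parse("Mamu-KIR3DL123"), "two digits",
               class = "kir_parse_error")
  expect_error(kir_parse("KIR2D"), "one Ig domain", class = "kir_parse_error")
  expect_error(kir_parse(""), "empty", class = "kir_parse_error")
  expect_error(kir_parse("Mamu-KIR3DXLX1"), "double",
               class = "kir_parse_error")
})

test_that("format round-trips every designation in the packaged registry", {
  reg <- packaged()
  all_names <- c(reg$genes$designation, reg$alleles$designation)
  expect_gt(length(all_names), 350)
  round <- vapply(all_names, function(s) kir_format(kir_parse(s)), "")
  expect_identical(unname(round), all_names)
})

test_that("format composes minimal names and refuses invariant violations", {
  expect_equal(kir_format(kir_parse("KIR3DL01*001")), "KIR3DL01*001")
  expect_equal(kir_format(kir_parse("Popy-KIR3DL1*002:01")),
               "Popy-KIR3DL1*002:01")
  bad <- kir_parse("Mamu-KIR3DL01*001:01")
  bad$field1 <- NA_character_              # field2 without field1
  expect_error(kir_format(bad), class = "kir_invariant_error")
  expect_error(kir_format(list(a = 1)), class = "kir_format_error")
})

test_that("grammar closure: any random well-formed name reparses to itself", {
  set.seed(42)
  species <- c(NA, "Mamu", "Patr", "Bota", "Zzzz")
  for (i in 1:200) {
    sp <- sample(species, 1)
    dom <- sample(1:3, 1)
    tail <- sample(c("L", "S", "P"), 1)
    w <- sample(c("", "W"), 1)
    gid <- sample(c("1", "7", "01", "20"), 1)
    f1 <- sprintf("%03d", sample(0:999, 1))
    f2 <- if (runif(1) < 0.5) sprintf(":%02d", sample(0:99, 1)) else ""
    f3 <- if (nzchar(f2) && runif(1) < 0.5)
      sprintf(":%02d", sample(0:99, 1)) else ""
    sfx <- sample(c("", "N", "L", "Q"), 1)
    s <- paste0(if (!is.na(sp)) paste0(sp, "-"), "KIR", dom, "D", tail, w,
                gid, "*", f1, f2, f3, sfx)
    expect_identical(kir_format(kir_parse(s)), s)
  }
})

test_that("comparison is a total order consistent with a tuple-sort oracle", {
  expect_equal(kir_compare("Mamu-KIR3DL01*001", "Mamu-KIR3DL01*002"), -1L)
  expect_equal(kir_compare("Mamu-KIR3DL01*019:01", "Mamu-KIR3DL01*019:02"),
               -1L)
  expect_equal(kir_compare("Mamu-KIR3DL01*001", "Mamu-KIR3DL01*001"), 0L)
  expect_equal(kir_compare("Mamu-KIR3DL02*001", "Mamu-KIR3DL01*002"), 1L)
  # gene-level name sorts before its alleles; suffix breaks final ties
  expect_equal(kir_compare("Mamu-KIR3DL01", "Mamu-KIR3DL01*001"), -1L)
  expect_equal(kir_compare("Mamu-KIR3DL01*001", "Mamu-KIR3DL01*001N"), -1L)

  reg <- packaged()
  mamu <- reg$alleles$designation[reg$alleles$species == "Mamu"]
  sorted <- kir_sort(mamu)
  expect_setequal(sorted, mamu)            # permutation: no loss, no dupes
  # brute-force oracle: decompose to plain tuples and order those
  key <- t(vapply(mamu, function(s) {
    p <- kir_parse(s)
    c(dom = ifelse(is.na(p$domain_count), -1, p$domain_count),
      tail = match(p$tail_class, c("none", "L", "S", "P")),
      w = as.integer(p$workshop),
      x = match(p$x_lineage, c("none", "pre_tail", "post_tail")),
      gid = ifelse(nzchar(p$gene_id), as.integer(p$gene_id), -1),
      f1 = ifelse(is.na(p$field1), -1, as.integer(p$field1)),
      f2 = ifelse(is.na(p$field2), -1, as.integer(p$field2)),
      f3 = ifelse(is.na(p$field3), -1, as.integer(p$field3)),
      sfx = match(p$suffix, c("none", "N", "L", "S", "C", "A", "Q")))
  }, numeric(9)))
  oracle <- mamu[do.call(order, as.data.frame(key))]
  expect_identical(sorted, oracle)

  # antisymmetry and transitivity on sampled triples
  set.seed(1)
  for (i in 1:50) {
    tri <- sample(mamu, 3)
    ab <- kir_compare(tri[1], tri[2])
    ba <- kir_compare(tri[2], tri[1])
    expect_equal(ab, -ba)
    bc <- kir_compare(tri[2], tri[3])
    if (ab <= 0 && bc <= 0)
      expect_lte(kir_compare(tri[1], tri[3]), 0L)
  }
})
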