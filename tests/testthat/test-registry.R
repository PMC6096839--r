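test_that("the packaged tables load with zero integrity problems", {
  reg <- packaged()
  expect_s3_class(reg, "kir_registry")
  expect_length(kir_registry_validate(reg), 0)
  expect_equal(nrow(reg$genes), 75)
  expect_equal(nrow(reg$alleles), 289)
  # accessions may legitimately be shared across alleles
  shared <- reg$alleles$designation[vapply(reg$alleles$accessions,
                                           function(a) "AY728189" %in% a,
                                           TRUE)]
  expect_setequal(shared, c("Mamu-KIR3DL08*001:01", "Mamu-KIR3DL08*005"))
})

test_that("census statistics reproduce the published counts", {
  reg <- packaged()
  expect_equal(kir_registry_stats(reg, "Patr")$n_genes, 13)
  st <- kir_registry_stats(reg, "orangutan", combined = TRUE)
  expect_equal(st$n_genes, 11)
  expect_equal(st$n_pseudogenes, 1)
  # per-species orangutan views stay available
  expect_equal(kir_registry_stats(reg, "Poab")$n_pseudogenes, 1)
  expect_equal(kir_registry_stats(reg, "Popy")$n_alleles, 5)
  # cattle: the tables print 17 distinct genes (2 pseudogenes among them)
  stc <- kir_registry_stats(reg, "Bota")
  expect_equal(stc$n_genes + stc$n_pseudogenes, 17)
  expect_match(reg$metadata$cattle_gene_count_note, "16")
  # configured species without records: all zeros
  st0 <- kir_registry_stats(reg, "Mafa")
  expect_equal(st0$n_genes, 0)
  expect_equal(st0$n_alleles, 0)
  expect_error(kir_registry_stats(reg, "Xxxx"), class = "kir_registry_error")
})

test_that("canonical JSON save and load round-trips the registry", {
  reg <- packaged()
  path <- withr::local_tempfile(fileext = ".json")
  kir_registry_write(reg, path)
  back <- kir_registry_read(path)
  expect_identical(back$genes$designation, reg$genes$designation)
  expect_identical(back$alleles$designation, reg$alleles$designation)
  expect_identical(lapply(back$alleles$previous, identity),
                   lapply(reg$alleles$previous, identity))
  expect_identical(lapply(back$alleles$accessions, identity),
                   lapply(reg$alleles$accessions, identity))
  expect_identical(back$alleles$breed, reg$alleles$breed)
  expect_identical(back$species_config, reg$species_config)
})

test_that("loader reports duplicates, bad rows and handles empty files", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tgene\tdesignation\tprevious_designations\taccessions\tbreed\treference",
               "Mamu\tKIR3DL01\tMamu-KIR3DL01*001\t\tAF334616\t\tx",
               "Mamu\tKIR3DL01\tMamu-KIR3DL01*001\t\tAF334617\t\tx"), tsv)
  expect_error(kir_registry_read(tsv), "Mamu-KIR3DL01\\*001",
               class = "kir_integrity_error")

  writeLines(c("species\tgene\tdesignation\tprevious_designations\taccessions\tbreed\treference",
               "Mamu\tKIR3DL01\tMamu-KIR9XL01*001\t\tAF334616\t\tx"), tsv)
  expect_error(kir_registry_read(tsv), "row 1", class = "kir_load_error")

  writeLines(character(), tsv)
  empty <- kir_registry_read(tsv)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$alleles), 0)

  # validate() collects problems instead of stopping at the first
  reg <- kir_registry_new()
  reg <- kir_registry_add_gene(reg, "Mamu-KIR3DL01")
  reg <- kir_registry_add_allele(reg, "Mamu-KIR3DL01*001")
  reg$alleles <- rbind(reg$alleles, reg$alleles)      # forced corruption
  probs <- kir_registry_validate(reg)
  expect_true(any(grepl("duplicate allele", probs)))
})

test_that("allele records enforce gene existence and accession shape", {
  reg <- kir_registry_new()
  expect_error(kir_registry_add_allele(reg, "Mamu-KIR3DL01*001"),
               "not registered", class = "kir_integrity_error")
  reg <- kir_registry_add_gene(reg, "Mamu-KIR3DL01")
  expect_error(kir_registry_add_allele(reg, "Mamu-KIR3DL01*001",
                                       accessions = "AF-334616"),
               "malformed accession", class = "kir_registry_error")
  reg <- kir_registry_add_allele(reg, "Mamu-KIR3DL01*001",
                                 accessions = "AF334616")
  expect_error(kir_registry_add_allele(reg, "Mamu-KIR3DL01*001"),
               class = "kir_integrity_error")
})

test_that("next_available is max-plus-one and never refills gaps", {
  reg <- packaged()
  # the 2DL04 series runs to *020 with *009 missing: gaps stay holes
  f1 <- vapply(reg$alleles$designation[reg$alleles$gene == "KIR2DL04"],
               function(d) kir_parse(d)$field1, "")
  expect_false("009" %in% f1)
  expect_equal(max(as.integer(f1)), 20L)
  expect_equal(kir_next_available(reg, "Mamu-KIR2DL04", 1), "021")
  # *008 has :01 and :02, so the next synonymous variant is :03
  expect_equal(kir_next_available(reg, "Mamu-KIR2DL04", 2,
                                  parent = "Mamu-KIR2DL04*008:01"), "03")
  # a bare incumbent scopes as :01
  expect_equal(kir_next_available(reg, "Mamu-KIR2DL04", 2,
                                  parent = "Mamu-KIR2DL04*004"), "02")
  expect_equal(kir_next_available(reg, "Mamu-KIR2DL04", 3,
                                  parent = "Mamu-KIR2DL04*004"), "02")
  expect_error(kir_next_available(reg, "Mamu-KIR2DL04", 2),
               class = "kir_allocation_error")

  fresh <- kir_registry_add_gene(kir_registry_new(), "Mamu-KIR3DL91")
  expect_equal(kir_next_available(fresh, "Mamu-KIR3DL91", 1), "001")
  # strictly monotone under repeated allocation
  r <- fresh
  got <- character(5)
  for (i in 1:5) {
    got[i] <- kir_next_available(r, "Mamu-KIR3DL91", 1)
    r <- kir_registry_add_allele(r, paste0("Mamu-KIR3DL91*", got[i]))
  }
  expect_equal(got, c("001", "002", "003", "004", "005"))
  # series exhaustion is an error, not a wraparound
  r2 <- kir_registry_add_allele(fresh, "Mamu-KIR3DL91*999")
  expect_error(kir_next_available(r2, "Mamu-KIR3DL91", 1),
               class = "kir_allocation_error")
})

test_that("sequences attach by designation and genes can be renamed", {
  pair <- base_pair()
  reg <- packaged()
  reg <- kir_registry_attach_cds(
    reg, c("Mamu-KIR2DL04*020" = pair$genes[[1]]$cds))
  i <- match("Mamu-KIR2DL04*020", reg$alleles$designation)
  expect_equal(reg$alleles$cds[i], pair$genes[[1]]$cds)
  expect_error(kir_registry_attach_cds(reg, c("Mamu-KIR9DL99*001" = "ACGT")),
               class = "kir_registry_error")

  reg2 <- kir_rename_gene(reg, "Mamu-KIR3DLW03", "Mamu-KIR3DL21")
  expect_false("Mamu-KIR3DLW03" %in% reg2$genes$designation)
  expect_true("Mamu-KIR3DL21*001" %in% reg2$alleles$designation)
  # renamed designations resolve through the legacy path
  hit <- kir_resolve_legacy(reg2, "Mamu-KIR3DLW03*001")
  expect_true("Mamu-KIR3DL21*001" %in% hit$targets$designation)
})
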