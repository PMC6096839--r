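test_that("an exact copy of a registered allele wins every window", {
  pair <- base_pair()
  loc <- kir_assign_locus(pair$genes[[1]], pair$registry, "Mamu")
  expect_false(loc$new_gene)
  expect_equal(loc$gene, "Mamu-KIR3DL01")
  cast <- loc$window_votes$gene[!is.na(loc$window_votes$gene)]
  expect_true(all(cast == "KIR3DL01"))
  expect_equal(loc$nearest$identity[1], 1.0)
})

test_that("recombinants go to the majority parent; the vote is auditable", {
  pair <- base_pair()
  ch <- kir_chimera(pair$genes[[1]], pair$genes[[2]], 0.7)
  loc <- kir_assign_locus(ch, pair$registry, "Mamu")
  expect_equal(loc$gene, "Mamu-KIR3DL01")
  # oracle: count windows by direct nearest-parent comparison on the
  # constructed chimera, independent of the engine's vote bookkeeping
  L <- nchar(ch$cds)
  cfg <- kir_allocator_config()
  starts <- unique(c(seq(0, L - cfg$window_size, by = cfg$window_step),
                     L - cfg$window_size))
  cv <- strsplit(ch$cds, "")[[1]]
  av <- strsplit(pair$genes[[1]]$cds, "")[[1]]
  bv <- strsplit(pair$genes[[2]]$cds, "")[[1]]
  oracle_votes <- vapply(starts, function(st) {
    w <- (st + 1):(st + cfg$window_size)
    ia <- mean(cv[w] == av[w]); ib <- mean(cv[w] == bv[w])
    if (ia > ib) "KIR3DL01" else if (ib > ia) "KIR3DL02" else NA_character_
  }, "")
  expect_gt(sum(oracle_votes == "KIR3DL01", na.rm = TRUE),
            sum(oracle_votes == "KIR3DL02", na.rm = TRUE))
  expect_equal(loc$window_votes$gene, oracle_votes)
})

test_that("the majority parent wins across the whole breakpoint sweep", {
  pair <- base_pair()
  for (bp in seq(0.55, 0.95, by = 0.1)) {
    loc <- kir_assign_locus(kir_chimera(pair$genes[[1]], pair$genes[[2]],
                                        bp), pair$registry, "Mamu")
    expect_equal(loc$gene, "Mamu-KIR3DL01", info = sprintf("bp %.2f", bp))
    loc <- kir_assign_locus(kir_chimera(pair$genes[[2]], pair$genes[[1]],
                                        bp), pair$registry, "Mamu")
    expect_equal(loc$gene, "Mamu-KIR3DL02", info = sprintf("rev bp %.2f", bp))
  }
  expect_error(kir_assign_locus(kir_chimera(pair$genes[[1]],
                                            pair$genes[[2]], 0.5),
                                pair$registry, "Mamu"),
               class = "kir_ambiguous_recombinant")
})

test_that("uniformly divergent sequences become workshop proposals", {
  genes <- kir_generate_gene_set(n_genes = 2L, divergence = 0.88, seed = 99L)
  reg <- kir_synth_registry(genes[1])
  loc <- kir_assign_locus(genes[[2]], reg, "Mamu")
  expect_true(loc$new_gene)
  expect_equal(loc$proposal, "Mamu-KIR3DLW02")   # continues the number series
  expect_lt(loc$best_identity, 0.96)
  dec <- kir_assign_name(genes[[2]], reg, "Mamu", good_meta())
  expect_equal(dec$status, "new_gene_workshop")
  expect_equal(dec$assigned, "Mamu-KIR3DLW02*001")
  expect_true(kir_parse(dec$assigned)$workshop)
})

test_that("the naming pipeline places variants at the right tier", {
  pair <- base_pair()
  reg <- pair$registry
  g <- pair$genes[[1]]
  meta <- good_meta()

  same <- kir_assign_name(g, reg, "Mamu", meta)
  expect_equal(same$status, "existing_allele")
  expect_equal(same$assigned, "Mamu-KIR3DL01*001")

  t1 <- kir_assign_name(kir_mutate(g, "nonsynonymous", 2, seed = 31),
                        reg, "Mamu", meta)
  expect_equal(t1$status, "new_tier1")
  expect_equal(t1$assigned, "Mamu-KIR3DL01*002")

  t2 <- kir_assign_name(kir_mutate(g, "synonymous", 2, seed = 32),
                        reg, "Mamu", meta)
  expect_equal(t2$status, "new_tier2")
  expect_equal(t2$assigned, "Mamu-KIR3DL01*001:02")
  expect_match(paste(t2$notes, collapse = " "),
               "Mamu-KIR3DL01\\*001:01")     # incumbent's canonical long form

  t3 <- kir_assign_name(kir_mutate(g, "noncoding", 2, seed = 33),
                        reg, "Mamu", meta)
  expect_equal(t3$status, "new_tier3")
  expect_equal(t3$assigned, "Mamu-KIR3DL01*001:01:02")

  stopped <- kir_assign_name(kir_mutate(g, "stop", seed = 34, stop_at = 0.4),
                             reg, "Mamu", meta)
  expect_equal(stopped$status, "new_tier1")
  expect_match(stopped$assigned, "N$")
  expect_true("premature_stop" %in% stopped$suffix_triggers)
})

test_that("tier-1 numbering continues past the highest published allele", {
  pair <- base_pair()
  reg <- packaged()
  # give the 2DL04 series (which tops out at *020) a reference sequence
  reg <- kir_registry_attach_cds(
    reg, c("Mamu-KIR2DL04*020" = pair$genes[[1]]$cds))
  novel <- kir_mutate(pair$genes[[1]], "nonsynonymous", 2, seed = 41)
  dec <- kir_assign_name(novel, reg, "Mamu", good_meta())
  expect_equal(dec$status, "new_tier1")
  expect_equal(dec$assigned, "Mamu-KIR2DL04*021")
})

test_that("submission checks reject under-evidenced or partial entries", {
  pair <- base_pair()
  g <- pair$genes[[1]]
  one_pcr <- list(date = "2018-05-01",
                  evidence = list(list(kind = "independent_pcr",
                                       label = "only")))
  dec <- kir_assign_name(g, pair$registry, "Mamu", one_pcr)
  expect_equal(dec$status, "rejected")
  expect_equal(dec$checks$evidence, "fail")
  expect_true(is.na(dec$assigned))

  partial <- g
  partial$complete <- FALSE
  dec <- kir_assign_name(partial, pair$registry, "Mamu", good_meta())
  expect_equal(dec$status, "rejected")     # full length mandatory for Mamu
  expect_equal(dec$checks$full_length, "fail")

  # two individuals are sufficient evidence
  two_ind <- list(date = "2018-05-01",
                  evidence = list(list(kind = "individual", label = "a1"),
                                  list(kind = "individual", label = "a2")))
  dec <- kir_assign_name(g, pair$registry, "Mamu", two_ind)
  expect_equal(dec$status, "existing_allele")
})

test_that("allocation is deterministic, monotone and idempotent", {
  pair <- base_pair()
  meta <- good_meta()
  v <- kir_mutate(pair$genes[[1]], "nonsynonymous", 2, seed = 51)
  d1 <- kir_assign_name(v, pair$registry, "Mamu", meta)
  d2 <- kir_assign_name(v, pair$registry, "Mamu", meta)
  expect_identical(d1, d2)

  reg <- pair$registry
  assigned <- character(12)
  for (i in seq_along(assigned)) {
    mut <- kir_mutate(pair$genes[[1]], "nonsynonymous", 2, seed = 600 + i)
    dec <- kir_assign_name(mut, reg, "Mamu", meta)
    expect_equal(dec$status, "new_tier1")
    assigned[i] <- dec$assigned
    reg <- kir_registry_commit(reg, dec, mut, meta)
  }
  fields <- as.integer(vapply(assigned, function(d) kir_parse(d)$field1, ""))
  expect_equal(fields, 2:13)               # strictly consecutive

  # resubmitting a registered sequence changes nothing
  resub <- kir_assign_name(mut, reg, "Mamu", meta)
  expect_equal(resub$status, "existing_allele")
  expect_equal(resub$assigned, assigned[length(assigned)])
  expect_identical(kir_registry_commit(reg, resub, mut, meta), reg)
})

test_that("null suffix obeys the premature-stop fraction boundary", {
  pair <- base_pair()
  g <- pair$genes[[1]]
  meta <- good_meta()
  for (at in c(0.2, 0.5, 0.8)) {
    dec <- kir_assign_name(kir_mutate(g, "stop", seed = 70, stop_at = at),
                           pair$registry, "Mamu", meta)
    expect_match(dec$assigned, "N$", info = sprintf("stop at %.1f", at))
  }
  for (at in c(0.92, 0.97)) {
    dec <- kir_assign_name(kir_mutate(g, "stop", seed = 70, stop_at = at),
                           pair$registry, "Mamu", meta)
    expect_false(grepl("N$", dec$assigned),
                 info = sprintf("stop at %.2f", at))
  }
})

test_that("satellite macaque species are named against the rhesus registry", {
  pair <- base_pair()
  mut <- kir_mutate(pair$genes[[1]], "nonsynonymous", 2, seed = 81)
  dec <- kir_assign_name(mut, pair$registry, "Mafa", good_meta())
  expect_equal(dec$status, "new_tier1")
  expect_match(dec$assigned, "^Mafa-KIR3DL01\\*")
})

test_that("ambiguous recombinants surface as errors from the pipeline", {
  pair <- base_pair()
  ch <- kir_chimera(pair$genes[[1]], pair$genes[[2]], 0.5)
  expect_error(kir_assign_name(ch, pair$registry, "Mamu", good_meta()),
               class = "kir_ambiguous_recombinant")
})
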