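# nhkir

Nomenclature engine for the killer-cell immunoglobulin-like receptor
(KIR) genes of non-human species: rhesus macaque (Mamu), chimpanzee
(Patr), both orangutan species (Poab/Popy) and cattle (Bota).

KIR loci are highly polymorphic, vary in gene content between
haplotypes, and recombine freely, so the literature accumulated many
incompatible names for the same sequences.  The standardized
nomenclature names each allele

```
Mamu-KIR3DL01*019:02N
└┬─┘    │││ │  │   │└ expression suffix (N = null; L/S/C/A/Q reserved)
 │      │││ │  │   └─ 3rd field: non-coding (intron/UTR) differences
 │      │││ │  └───── 2nd field: synonymous coding differences
 │      │││ └──────── 1st field: protein-level (non-synonymous) allele
 │      ││└────────── gene number (two-digit in macaques)
 │      │└─────────── tail class: L(ong), S(hort), P(seudogene);
 │      │             W after it flags a provisional "workshop" gene
 │      └──────────── number of Ig-like domains (1-3), then "D"
 └─────────────────── four-character species prefix
```

Cattle genes of the deeply divergent KIR3DX lineage carry an `X` before
the tail letter (`Bota-KIR3DXL1`); the divergent macaque gene carries it
after (`Mamu-KIR3DLX1`).  The three digit fields form a hierarchy:
alleles differing non-synonymously get distinct first fields, alleles
differing only synonymously share it and get distinct second fields, and
alleles differing only in introns/UTRs are separated at the third field.

This package provides, for curators and immunogeneticists:

* **Grammar** — `kir_parse()`, `kir_format()`, `kir_compare()`,
  `kir_sort()`: lossless parsing, printing and canonical ordering of
  designations.
* **Registry** — the full published tables (75 genes, 289 alleles, with
  previous designations and accessions) as `kir_registry_packaged()`;
  JSON/TSV I/O, integrity validation, census statistics and
  max-plus-one series allocation (`kir_next_available()`).
* **Legacy resolution** — `kir_resolve_legacy()` maps any
  pre-standardization name to its current designation(s), preserving
  genuine ambiguity and using accessions to disambiguate.
* **Sequence classification** — `kir_extract_features()` (Ig-domain
  count, tail class, null-allele lesions) and
  `kir_classify_difference()` (tiered non-synonymous / synonymous /
  non-coding comparison of a candidate against a reference).
* **Naming engine** — `kir_assign_name()`: submission checks (full
  length, replication evidence), locus assignment by windowed
  majority vote with a changepoint-refined recombinant rule, tier
  placement, null-suffix detection, workshop proposals for divergent
  sequences, and `kir_registry_commit()` to record accepted names.
* **Synthetic data** — `kir_generate_gene_set()`, `kir_mutate()`,
  `kir_chimera()`: seeded KIR-like sequences with controlled mutation
  classes, so everything is testable offline.
* **CLI** — an `nhkir` script (installed under `exec/`) exposing
  `parse`, `validate`, `stats`, `resolve`, `features`, `assign` and
  `synth` with `--json` output.

## Worked example

```r
library(nhkir)

kir_parse("Mamu-KIR3DL01*019:02")
#> <kir_name> Mamu-KIR3DL01*019:02
#>   species:      Mamu
#>   domains:      3
#>   tail:        L
#>   gene number:  01
#>   allele:      019:02

reg <- kir_registry_packaged()
kir_registry_stats(reg, "Patr")$n_genes
#> [1] 13

# what is the macaque sequence once published as "KIR3DL5"?
kir_resolve_legacy(reg, "KIR3DL5", species = "Mamu")$targets
#>   species       designation
#> 1    Mamu     Mamu-KIR3DL01
#> 2    Mamu Mamu-KIR3DL01*005
```

It is now allele 005 of Mamu-KIR3DL01 — it turned out to be a
recombinant whose sequence majority comes from that locus.  Naming a
novel sequence end to end:

```r
genes <- kir_generate_gene_set(n_genes = 2, divergence = 0.90, seed = 7)
reg   <- kir_synth_registry(genes)
novel <- kir_mutate(genes[[1]], "synonymous", count = 2, seed = 22)
kir_assign_name(novel, reg, "Mamu",
                meta = list(date = "2018-05-01",
                            evidence = list(
                              list(kind = "independent_pcr", label = "A"),
                              list(kind = "independent_pcr", label = "B"))))
#> <kir_decision> new_tier2: Mamu-KIR3DL01*001:02
#>   nearest: Mamu-KIR3DL01*001 (identity 0.998)
#>   note: incumbent 'Mamu-KIR3DL01*001' keeps its short form as an alias;
#>         canonical long form 'Mamu-KIR3DL01*001:01'
```

The candidate differs from allele 001 only synonymously, so it extends
that allele's name at the second digit field, and the incumbent's
canonical long form becomes `*001:01`.

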