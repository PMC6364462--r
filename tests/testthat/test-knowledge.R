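make_variant_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "chrom\tpos\tref\talt\tgene\tsignificance\treview_flag\tdiseases"
  writeLines(c(header, rows), path)
  path
}

test_that("variant table parsing applies the curation filters", {
  path <- make_variant_tsv(c(
    "chr1\t100\tA\tG\tGENE1\tPathogenic\t\tOMIM:2;OMIM:1",
    "1\t200\tC\tT\tGENE1\tBenign\t\t",
    "1\t300\tG\tA\tGENE1;GENE2\tPathogenic\t\tOMIM:1",
    "1\t400\tT\t\tGENE3\tPathogenic\t\tOMIM:1",
    "1\t500\tA\tC\tGENE3\tPathogenic\tconflicting\tOMIM:1",
    "1\t600\tA\tC\tGENE3\tUncertain\t\tOMIM:1"))
  expect_warning(read_variant_table(path), "Uncertain")
  got <- suppressWarnings(read_variant_table(path))
  expect_identical(nrow(got$pathogenic), 1L)
  expect_identical(got$pathogenic$chrom, "1")  # chr prefix stripped
  expect_identical(got$pathogenic$diseases[[1]], c("OMIM:1", "OMIM:2"))
  expect_identical(nrow(got$benign), 1L)
  expect_identical(unname(got$dropped["multi_gene"]), 1L)
  expect_identical(unname(got$dropped["missing_allele"]), 1L)
  expect_identical(unname(got$dropped["conflicting"]), 1L)
})

test_that("empty variant table yields empty sets and zero drops", {
  got <- read_variant_table(make_variant_tsv(character(0)))
  expect_identical(nrow(got$pathogenic), 0L)
  expect_identical(nrow(got$benign), 0L)
  expect_true(all(got$dropped == 0L))
})

test_that("variant tables round-trip through the simulated study files", {
  dir <- withr::local_tempdir()
  params <- sim_params(n_terms = 30L, root_branching = 4L, n_genes = 10L,
                       n_diseases = 6L, n_pathogenic = 25L, n_benign = 15L,
                       n_background_pool = 50L, seed = 31L)
  st <- suppressMessages(sim_study(params, dir = dir))
  reparsed <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_identical(reparsed$pathogenic, st$pathogenic)
  expect_identical(reparsed$benign, st$benign)
  # generator bookkeeping: all emitted rows are clean
  expect_identical(nrow(reparsed$pathogenic), 25L)
  expect_identical(nrow(reparsed$benign), 15L)
  expect_true(all(reparsed$dropped == 0L))
})

test_that("score lookups are cache-first with a lazily probed fallback", {
  dir <- withr::local_tempdir()
  fallback <- tibble::tibble(
    chrom = "1", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
    cadd = c(1, 2, 3), dann = c(0.1, 0.2, NA), gwava = c(0.5, NA, 0.7))
  fb_path <- write_tsv_plain(fallback, file.path(dir, "scores.tsv"))
  cache <- fallback[1, ]
  cache$cadd <- 1  # cache and fallback agree on shared keys
  store <- score_store(cache = cache, fallback_path = fb_path)

  hit <- lookup_scores(tibble::tibble(chrom = "1", pos = 10L,
                                      ref = "A", alt = "G"), store)
  expect_identical(hit$cadd, 1)
  expect_identical(fallback_probes(store), 0L)

  miss <- lookup_scores(tibble::tibble(chrom = "1", pos = 20L,
                                       ref = "A", alt = "G"), store)
  expect_identical(miss$cadd, 2)
  expect_true(is.na(miss$gwava))
  expect_identical(fallback_probes(store), 1L)

  none <- lookup_scores(tibble::tibble(chrom = "9", pos = 1L,
                                       ref = "A", alt = "G"), store)
  expect_true(all(is.na(none[c("cadd", "dann", "gwava")])))
})

test_that("cache-first results agree with a fallback-only scan on random keys", {
  st <- small_study()
  scores <- st$store$fallback %||% NULL
  fb_path <- st$store$fallback_path
  full <- phenorank:::.read_score_table(fb_path)
  store <- score_store(cache = full[seq_len(100L), ], fallback_path = fb_path)

  withr::with_seed(909L, {
    queries <- dplyr::bind_rows(
      full[sample.int(nrow(full), 500L, replace = TRUE),
           c("chrom", "pos", "ref", "alt")],
      tibble::tibble(chrom = "1", pos = sample.int(10L, 100L, replace = TRUE),
                     ref = "A", alt = "C"))
  })
  got <- lookup_scores(queries, store)
  want_idx <- match(phenorank:::.variant_key(queries),
                    phenorank:::.variant_key(full))
  for (col in c("cadd", "dann", "gwava")) {
    expect_identical(got[[col]], full[[col]][want_idx])
  }
})

test_that("nearest gene handles containment, distance and the tie rule", {
  kb <- knowledge_base(
    gene_profiles = tibble::tibble(entity = character(), term = character()),
    disease_profiles = tibble::tibble(entity = character(), term = character()),
    disease_moi = tibble::tibble(disease = character(), moi = character()),
    gene_intervals = tibble::tibble(
      gene = c("GB", "GA", "GC"), chrom = c("1", "1", "2"),
      start = c(1000L, 1600L, 10L), end = c(1400L, 2400L, 20L)),
    benign = tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            gene = character()))

  expect_identical(nearest_gene(tibble::tibble(chrom = "1", pos = 1200L), kb),
                   "GB")
  # equidistant (d = 100) between GB's end and GA's start -> smaller ID wins
  expect_identical(nearest_gene(tibble::tibble(chrom = "1", pos = 1500L), kb),
                   "GA")
  expect_identical(nearest_gene(tibble::tibble(chrom = "3", pos = 5L), kb),
                   NA_character_)

  # random positions against a brute-force per-interval scan
  withr::with_seed(111L, {
    pos <- sample.int(3000L, 200L, replace = TRUE)
  })
  got <- nearest_gene(tibble::tibble(chrom = "1", pos = pos), kb)
  iv <- kb$gene_intervals[kb$gene_intervals$chrom == "1", ]
  want <- vapply(pos, function(p) {
    d <- vapply(seq_len(nrow(iv)), function(j) {
      if (p >= iv$start[j] && p <= iv$end[j]) 0L else
        min(abs(p - iv$start[j]), abs(p - iv$end[j]))
    }, integer(1))
    sort(iv$gene[d == min(d)])[1]
  }, character(1))
  expect_identical(got, want)
})

test_that("VCF reading decomposes genotypes per ALT allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1",
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0",
    "1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t./.",
    "1\t500\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2",
    "1\t600\t.\tA\tG,T\t.\tPASS\t.\tGT\t2/2"), path)
  got <- read_vcf(path)
  expect_identical(nrow(got), 5L)
  expect_identical(got$zygosity[got$pos == 100L], "HET")
  expect_identical(got$chrom[got$pos == 100L], "1")
  expect_identical(got$zygosity[got$pos == 200L], "HOM")
  multi <- got[got$pos == 500L, ]
  expect_identical(sort(multi$alt), c("G", "T"))
  expect_identical(multi$zygosity, c("HET", "HET"))
  expect_identical(got[got$pos == 600L, ]$alt, "T")
  expect_identical(got[got$pos == 600L, ]$zygosity, "HOM")
  # never inflates past the per-row ALT count
  expect_lte(nrow(got), 1L + 1L + 0L + 0L + 2L + 2L)
})
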