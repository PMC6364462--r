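# Worked examples from the curated knowledge: a variant annotated with two
# diseases yields two pairs; zygosity expansion follows the disease's mode
# of inheritance; benign variants expand to both zygosities.

worked_kb <- function() {
  knowledge_base(
    gene_profiles = tibble::tibble(entity = "TMEM216", term = "HP:0000002"),
    disease_profiles = tibble::tibble(
      entity = c("OMIM:608091", "OMIM:603194", "OMIM:613647", "OMIM:100300",
                 "OMIM:252010", "OMIM:604625"),
      term = "HP:0000002"),
    disease_moi = tibble::tibble(
      disease = c("OMIM:608091", "OMIM:603194", "OMIM:613647", "OMIM:100300",
                  "OMIM:252010"),
      moi = c("RECESSIVE", "RECESSIVE", "RECESSIVE", "DOMINANT", "RECESSIVE")),
    gene_intervals = tibble::tibble(gene = c("TMEM216", "AP5Z1", "ARHGAP31",
                                             "FOXRED1"),
                                    chrom = c("11", "7", "3", "11"),
                                    start = c(1L, 1L, 1L, 5000L),
                                    end = c(100L, 100L, 100L, 6000L)),
    benign = tibble::tibble(chrom = "11", pos = 5500L, ref = "A", alt = "G",
                            gene = "FOXRED1"))
}

variant_row <- function(gene, diseases, chrom = "1", pos = 1L) {
  tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
                 diseases = list(diseases))
}

test_that("a variant with n diseases yields n variant-disease pairs", {
  # rs201108965-style record: two annotated diseases
  pathogenic <- variant_row("TMEM216", c("OMIM:608091", "OMIM:603194"))
  pairs <- build_pairs(pathogenic)
  expect_identical(nrow(pairs), 2L)
  expect_identical(pairs$disease, c("OMIM:603194", "OMIM:608091"))  # sorted

  single <- build_pairs(variant_row("AP5Z1", "OMIM:613647"))
  expect_identical(nrow(single), 1L)

  # pair count equals the sum of disease-list lengths on a random fixture
  st <- small_study()
  pairs_all <- build_pairs(st$pathogenic)
  expect_identical(nrow(pairs_all), sum(lengths(st$pathogenic$diseases)))
})

test_that("zygosity expansion follows the mode of inheritance", {
  kb <- worked_kb()
  # rs397704705-style: recessive disease -> single homozygous triple
  rec <- expand_zygosity(build_pairs(variant_row("AP5Z1", "OMIM:613647")), kb)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$zygosity, "HOM")
  expect_identical(rec$label, "POSITIVE")

  # rs387907031-style: dominant disease -> HOM and HET triples
  dom <- expand_zygosity(build_pairs(variant_row("ARHGAP31", "OMIM:100300")), kb)
  expect_identical(nrow(dom), 2L)
  expect_identical(sort(dom$zygosity), c("HET", "HOM"))

  # unknown inheritance expands like non-recessive
  unk <- expand_zygosity(build_pairs(variant_row("X", "OMIM:999999")), kb)
  expect_identical(nrow(unk), 2L)
})

test_that("benign variants expand to two zygosity instances each", {
  benign1 <- tibble::tibble(chrom = "11", pos = 5500L, ref = "A", alt = "G",
                            gene = "FOXRED1")
  got <- expand_benign(benign1)
  expect_identical(nrow(got), 2L)
  expect_identical(sort(got$zygosity), c("HET", "HOM"))
  expect_true(all(is.na(got$disease)))

  many <- benign1[rep(1L, 250L), ]
  many$pos <- seq_len(250L)
  expect_identical(nrow(expand_benign(many)), 500L)
  expect_identical(nrow(expand_benign(benign1[0L, ])), 0L)
})

test_that("negative sampling uses both strategies as specified", {
  kb <- worked_kb()
  # rs267606829-style positive: FOXRED1 variant, recessive disease, HOM
  pos <- tibble::tibble(chrom = "11", pos = 5800L, ref = "C", alt = "T",
                        gene = "FOXRED1", disease = "OMIM:252010",
                        zygosity = "HOM", label = "POSITIVE",
                        neg_strategy = "NONE")
  negs <- withr::with_seed(5L, sample_negatives(pos[rep(1L, 200L), ], kb))
  b <- negs[negs$neg_strategy == "BENIGN_SAME_GENE", ]
  w <- negs[negs$neg_strategy == "WRONG_DISEASE", ]
  expect_gt(nrow(b), 0L); expect_gt(nrow(w), 0L)
  # strategy 1: the benign FOXRED1 variant, positive's disease kept
  expect_true(all(b$gene == "FOXRED1" & b$pos == 5500L))
  expect_true(all(b$disease == "OMIM:252010"))
  # strategy 2: same variant, different disease, same zygosity
  expect_true(all(w$pos == 5800L & w$zygosity == "HOM"))
  expect_true(all(w$disease != "OMIM:252010"))
  expect_true(all(negs$label == "NEGATIVE"))
})

test_that("strategy choice is an unbiased coin over many draws", {
  kb <- worked_kb()
  pos <- tibble::tibble(chrom = "11", pos = 5800L, ref = "C", alt = "T",
                        gene = "FOXRED1", disease = "OMIM:252010",
                        zygosity = "HOM", label = "POSITIVE",
                        neg_strategy = "NONE")
  n <- 10000L
  negs <- withr::with_seed(17L, sample_negatives(pos[rep(1L, n), ], kb))
  frac <- mean(negs$neg_strategy == "BENIGN_SAME_GENE")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("genes without benign variants fall back to wrong-disease sampling", {
  kb <- worked_kb()
  pos <- tibble::tibble(chrom = "3", pos = 50L, ref = "C", alt = "T",
                        gene = "ARHGAP31", disease = "OMIM:100300",
                        zygosity = "HET", label = "POSITIVE",
                        neg_strategy = "NONE")
  negs <- withr::with_seed(23L, sample_negatives(pos[rep(1L, 50L), ], kb))
  expect_true(all(negs$neg_strategy == "WRONG_DISEASE"))
  expect_gt(attr(negs, "fallbacks"), 0L)
})

test_that("built training sets are balanced, leak-free and deterministic", {
  st <- small_study()
  ts <- build_training_set(st$kb, st$pathogenic, st$benign, seed = 99L)

  expect_identical(sum(ts$label == "POSITIVE"), sum(ts$label == "NEGATIVE"))

  # positive count recomputed from the MoI table
  pairs <- build_pairs(st$pathogenic)
  moi <- disease_moi(pairs$disease, st$kb)
  expect_identical(sum(ts$label == "POSITIVE"),
                   sum(ifelse(moi == "RECESSIVE", 1L, 2L)))

  key <- paste(ts$chrom, ts$pos, ts$ref, ts$alt, ts$disease, ts$zygosity)
  expect_length(intersect(key[ts$label == "POSITIVE"],
                          key[ts$label == "NEGATIVE"]), 0L)

  # wrong-disease negatives never carry a disease annotated to the variant
  w <- ts[ts$neg_strategy == "WRONG_DISEASE", ]
  vk <- paste(w$chrom, w$pos, w$ref, w$alt)
  annotated <- stats::setNames(st$pathogenic$diseases,
                               paste(st$pathogenic$chrom, st$pathogenic$pos,
                                     st$pathogenic$ref, st$pathogenic$alt))
  expect_false(any(mapply(function(k, d) d %in% annotated[[k]], vk, w$disease)))

  ts2 <- build_training_set(st$kb, st$pathogenic, st$benign, seed = 99L)
  expect_identical(as.data.frame(ts), as.data.frame(ts2))
  ts3 <- build_training_set(st$kb, st$pathogenic, st$benign, seed = 100L)
  expect_false(identical(as.data.frame(ts), as.data.frame(ts3)))
})

test_that("training sets round-trip through TSV with their seed", {
  st <- small_study()
  ts <- build_training_set(st$kb, st$pathogenic, st$benign, seed = 42L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_training_set(ts, path)
  back <- read_training_set(path)
  expect_identical(attr(back, "seed"), 42L)
  expect_equal(as.data.frame(back), as.data.frame(ts), ignore_attr = TRUE)
})
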