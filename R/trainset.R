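#' Expand pathogenic variants into variant-disease pairs
#'
#' A pathogenic variant annotated with n diseases contributes n
#' variant-disease pairs, one per disease, diseases in sorted ID order within
#' each variant.
#'
#' @param pathogenic Tibble from [read_variant_table()]`$pathogenic` (columns
#'   chrom, pos, ref, alt, gene and a `diseases` list-column).
#' @return A tibble with one row per (variant, disease): the variant columns
#'   plus `disease`.
#' @export
build_pairs <- function(pathogenic) {
  stopifnot(all(lengths(pathogenic$diseases) > 0L))
  out <- tidyr::unnest(
    dplyr::mutate(pathogenic, disease = lapply(.data$diseases, sort)),
    "disease"
  )
  dplyr::select(out, -"diseases")
}

#' Expand variant-disease pairs into zygosity triples
#'
#' Zygosity is assigned from the disease's mode of inheritance: a recessive
#' disease yields a single homozygous triple; any other mode (dominant,
#' X-linked, unknown) yields both a homozygous and a heterozygous triple.
#' All triples are positive training instances.
#'
#' @param pairs Tibble from [build_pairs()].
#' @param kb A [knowledge_base()] supplying disease modes of inheritance.
#' @return Instance tibble: variant columns, `disease`, `zygosity`, `label =
#'   "POSITIVE"`, `neg_strategy = "NONE"`.
#' @export
expand_zygosity <- function(pairs, kb) {
  moi <- disease_moi(pairs$disease, kb)
  reps <- ifelse(moi == "RECESSIVE", 1L, 2L)
  out <- pairs[rep(seq_len(nrow(pairs)), reps), , drop = FALSE]
  zyg <- unlist(lapply(reps, function(r) if (r == 1L) "HOM" else c("HOM", "HET")))
  dplyr::mutate(out, zygosity = zyg, label = "POSITIVE", neg_strategy = "NONE")
}

#' Expand benign variants into the candidate negative pool
#'
#' Benign variants carry no disease or mode of inheritance, so each is
#' treated as both a homozygote and a heterozygote, giving two
#' variant-zygosity instances per benign variant.
#'
#' @param benign Tibble of benign variants (chrom, pos, ref, alt, gene).
#' @return Instance tibble with `disease = NA`, two rows per input variant.
#' @export
expand_benign <- function(benign) {
  if (nrow(benign) == 0L) {
    return(dplyr::mutate(benign, disease = character(), zygosity = character()))
  }
  out <- benign[rep(seq_len(nrow(benign)), each = 2L), , drop = FALSE]
  dplyr::mutate(out, disease = NA_character_,
                zygosity = rep(c("HOM", "HET"), nrow(benign)))
}

#' Sample one negative instance per positive triple
#'
#' For each positive (variant V, disease D, zygosity Z), one of two
#' strategies is chosen with equal probability:
#' \describe{
#'   \item{BENIGN_SAME_GENE}{a benign variant drawn uniformly from V's gene,
#'     with zygosity drawn uniformly from HOM/HET. The positive's disease is
#'     kept as the phenotype context, so the pair differs from the positive
#'     only in its pathogenicity profile.}
#'   \item{WRONG_DISEASE}{(V, D', Z) with D' drawn uniformly from the
#'     knowledge base's profiled diseases, excluding every disease annotated
#'     to V — a pathogenic but non-causative instance.}
#' }
#' If V's gene holds no benign variant, the draw falls back to WRONG_DISEASE
#' (counted in the result's `fallbacks` attribute).
#'
#' @param positives Instance tibble from [expand_zygosity()]. Variants with
#'   `NA` gene must be resolved (e.g. via [nearest_gene()]) beforehand.
#' @param kb A [knowledge_base()].
#' @return Instance tibble of the same length, `label = "NEGATIVE"`, with the
#'   realized strategy in `neg_strategy` and attributes `fallbacks` and
#'   `strategy_counts`. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
sample_negatives <- function(positives, kb) {
  diseases <- sort(unique(kb$disease_profiles$entity))
  if (length(diseases) < 2L) stop("need at least 2 profiled diseases")
  variant_diseases <- split(positives$disease, .variant_key(positives))

  n <- nrow(positives)
  pick_benign <- stats::runif(n) < 0.5
  fallbacks <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- positives[i, ]
    benign_pool <- kb$benign_by_gene[[pos$gene]]
    use_benign <- pick_benign[i] && !is.null(benign_pool) && nrow(benign_pool) > 0L
    if (pick_benign[i] && !use_benign) fallbacks <- fallbacks + 1L
    if (use_benign) {
      b <- benign_pool[sample.int(nrow(benign_pool), 1L), ]
      b$disease <- pos$disease
      b$zygosity <- sample(c("HOM", "HET"), 1L)
      b$label <- "NEGATIVE"
      b$neg_strategy <- "BENIGN_SAME_GENE"
      rows[[i]] <- b
    } else {
      excl <- variant_diseases[[.variant_key(pos)]]
      cand <- setdiff(diseases, excl)
      if (length(cand) == 0L) stop("no alternative disease available for ",
                                   .variant_key(pos))
      neg <- pos
      neg$disease <- cand[sample.int(length(cand), 1L)]
      neg$label <- "NEGATIVE"
      neg$neg_strategy <- "WRONG_DISEASE"
      rows[[i]] <- neg
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, fallbacks = fallbacks,
            strategy_counts = table(out$neg_strategy))
}

#' Build the balanced training set
#'
#' Runs the full construction: variant-disease pairs, zygosity expansion by
#' mode of inheritance, gene assignment for intergenic variants via
#' [nearest_gene()], and one sampled negative per positive — yielding a
#' balanced set (#POSITIVE = #NEGATIVE), deterministic for a given seed.
#'
#' @param kb A [knowledge_base()].
#' @param pathogenic,benign Tibbles from [read_variant_table()].
#' @param seed Integer seed governing all negative-sampling randomness.
#' @return A `training_set` tibble of instances with attributes `seed` and
#'   `counts` (pairs, triples, benign instances, negatives by strategy,
#'   fallbacks).
#' @export
build_training_set <- function(kb, pathogenic, benign, seed = 1L) {
  pairs <- build_pairs(pathogenic)
  positives <- expand_zygosity(pairs, kb)
  no_gene <- is.na(positives$gene)
  if (any(no_gene)) {
    positives$gene[no_gene] <- nearest_gene(positives[no_gene, ], kb)
  }
  benign_pool <- expand_benign(benign)
  negatives <- withr::with_seed(seed, sample_negatives(positives, kb))
  instances <- dplyr::bind_rows(positives, negatives)
  counts <- c(pairs = nrow(pairs), triples = nrow(positives),
              benign_instances = nrow(benign_pool),
              negatives = nrow(negatives),
              benign_same_gene = sum(negatives$neg_strategy == "BENIGN_SAME_GENE"),
              wrong_disease = sum(negatives$neg_strategy == "WRONG_DISEASE"),
              fallbacks = attr(negatives, "fallbacks"))
  structure(tibble::as_tibble(instances), seed = seed, counts = counts,
            class = c("training_set", class(tibble::tibble())))
}

#' @export
print.training_set <- function(x, ...) {
  cts <- attr(x, "counts")
  cat("<training_set> ", nrow(x), " instances (",
      sum(x$label == "POSITIVE"), " positive / ",
      sum(x$label == "NEGATIVE"), " negative), seed ", attr(x, "seed"),
      "\n  negatives: ", cts[["benign_same_gene"]], " benign-same-gene, ",
      cts[["wrong_disease"]], " wrong-disease (",
      cts[["fallbacks"]], " fallback draws)\n", sep = "")
  NextMethod()
}

#' Write / read a training set as TSV
#'
#' One instance per row; the seed is recorded in a `#` header comment so a
#' re-read round-trips the construction metadata.
#'
#' @param ts A `training_set`.
#' @param path Output path.
#' @return `path`, invisibly (writer); a `training_set` (reader).
#' @export
write_training_set <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed=", attr(ts, "seed")), con)
  utils::write.table(as.data.frame(ts), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  header <- readLines(path, n = 1L)
  seed <- as.integer(sub("^# seed=", "", header))
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(), disease = readr::col_character(),
    zygosity = readr::col_character(), label = readr::col_character(),
    neg_strategy = readr::col_character()
  ), progress = FALSE)
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  structure(tbl, seed = seed,
            class = c("training_set", class(tibble::tibble())))
}
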