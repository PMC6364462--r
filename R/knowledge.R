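#' Read a ClinVar-like pathogenic/benign variant table
#'
#' Splits a variant knowledge table into pathogenic variants (with their
#' associated disease lists) and benign variants, applying the standard
#' curation filters: rows flagged with conflicting interpretation are
#' excluded, rows mapped to more than one gene or missing a ref/alt allele
#' are dropped (and counted), and rows with any other clinical significance
#' are skipped with a warning.
#'
#' @param path Path to a TSV with header columns
#'   `chrom, pos, ref, alt, gene, significance, review_flag, diseases`
#'   (`gene` and `diseases` may hold several IDs separated by `;`;
#'   `review_flag` is `conflicting` or empty).
#' @return A list with tibbles `pathogenic` (columns chrom, pos, ref, alt,
#'   gene, diseases list-column) and `benign` (chrom, pos, ref, alt, gene),
#'   plus `dropped`, a named count of rows removed by each filter.
#' @export
read_variant_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(), significance = readr::col_character(),
    review_flag = readr::col_character(), diseases = readr::col_character()
  ), progress = FALSE)
  if (nrow(tbl) == 0L) {
    empty <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            gene = character())
    return(list(pathogenic = dplyr::mutate(empty, diseases = list()),
                benign = empty,
                dropped = c(multi_gene = 0L, missing_allele = 0L,
                            conflicting = 0L, other_significance = 0L)))
  }
  bad_pos <- which(is.na(tbl$pos) | tbl$pos < 1)
  if (length(bad_pos)) {
    stop("malformed row(s) at line ", paste(bad_pos + 1L, collapse = ", "),
         ": missing or non-positive position")
  }
  tbl$chrom <- sub("^chr", "", tbl$chrom)

  multi_gene <- grepl(";", tbl$gene %||% "")
  missing_allele <- is.na(tbl$ref) | is.na(tbl$alt) | tbl$ref == "" |
    tbl$alt == "" | tbl$ref == tbl$alt
  conflicting <- !is.na(tbl$review_flag) & tbl$review_flag == "conflicting"
  keep <- !multi_gene & !missing_allele & !conflicting

  sig <- tolower(tbl$significance)
  other <- keep & !sig %in% c("pathogenic", "benign")
  if (any(other)) {
    warning("skipped ", sum(other), " row(s) with unknown significance: ",
            paste(unique(tbl$significance[other]), collapse = ", "))
  }

  base_cols <- c("chrom", "pos", "ref", "alt", "gene")
  path_tbl <- tbl[keep & sig == "pathogenic", , drop = FALSE]
  pathogenic <- tibble::as_tibble(path_tbl[base_cols])
  pathogenic$diseases <- lapply(path_tbl$diseases, function(d) {
    if (is.na(d) || d == "") character(0) else sort(strsplit(d, ";")[[1]])
  })
  benign <- tibble::as_tibble(tbl[keep & sig == "benign", base_cols])

  list(pathogenic = pathogenic, benign = benign,
       dropped = c(multi_gene = sum(multi_gene),
                   missing_allele = sum(missing_allele & !multi_gene),
                   conflicting = sum(conflicting & !multi_gene & !missing_allele),
                   other_significance = sum(other)))
}

#' Assemble a variant knowledge base
#'
#' Bundles the annotation resources the prioritizer consults: gene and
#' disease phenotype profiles, disease modes of inheritance, gene intervals,
#' and benign variants grouped by gene (the candidate pool for same-gene
#' negative sampling).
#'
#' @param gene_profiles,disease_profiles Data frames with columns
#'   `entity`, `term`.
#' @param disease_moi Data frame with columns `disease`, `moi`; `moi` one of
#'   `RECESSIVE`, `DOMINANT`, `X_LINKED`, `OTHER_UNKNOWN`. Diseases absent
#'   from the table default to `OTHER_UNKNOWN` on lookup.
#' @param gene_intervals Data frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param benign Tibble of benign variants (chrom, pos, ref, alt, gene).
#' @return A `knowledge_base` object.
#' @export
knowledge_base <- function(gene_profiles, disease_profiles, disease_moi,
                           gene_intervals, benign) {
  disease_moi <- tibble::as_tibble(disease_moi)
  bad <- setdiff(disease_moi$moi, moi_levels())
  if (length(bad)) stop("unknown mode of inheritance: ", paste(bad, collapse = ", "))
  gene_intervals <- tibble::as_tibble(gene_intervals)
  gene_intervals$chrom <- sub("^chr", "", gene_intervals$chrom)
  if (any(gene_intervals$end < gene_intervals$start)) {
    stop("degenerate gene interval(s)")
  }
  benign <- tibble::as_tibble(benign)
  structure(list(
    gene_profiles = tibble::as_tibble(gene_profiles),
    disease_profiles = tibble::as_tibble(disease_profiles),
    disease_moi = stats::setNames(disease_moi$moi, disease_moi$disease),
    gene_intervals = gene_intervals,
    benign_by_gene = split(benign, benign$gene)
  ), class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> ",
      length(unique(x$gene_profiles$entity)), " annotated genes, ",
      length(unique(x$disease_profiles$entity)), " annotated diseases, ",
      nrow(x$gene_intervals), " gene intervals, ",
      sum(vapply(x$benign_by_gene, nrow, 0L)), " benign variants\n", sep = "")
  invisible(x)
}

#' Recognized mode-of-inheritance categories
#' @return Character vector of the four categories, in feature-schema order.
#' @export
moi_levels <- function() c("RECESSIVE", "DOMINANT", "X_LINKED", "OTHER_UNKNOWN")

#' Mode of inheritance for a disease
#' @param disease Disease ID(s).
#' @param kb A [knowledge_base()].
#' @return Character vector; `OTHER_UNKNOWN` where no annotation exists.
#' @export
disease_moi <- function(disease, kb) {
  m <- unname(kb$disease_moi[disease])
  m[is.na(m)] <- "OTHER_UNKNOWN"
  m
}

#' Phenotype profile of an entity
#' @param entity Gene or disease ID.
#' @param profiles Annotation tibble (`entity`, `term`).
#' @return Character vector of term IDs (length 0 if unannotated).
#' @export
entity_profile <- function(entity, profiles) {
  sort(unique(profiles$term[profiles$entity == entity]))
}

# ---- pathogenicity score store --------------------------------------------

#' Pathogenicity score store with cache-first lookup
#'
#' Holds a pre-annotated in-memory cache of (chrom, pos, ref, alt) ->
#' (cadd, dann, gwava) triples for fast retrieval of common variants, plus an
#' on-disk fallback score table consulted only on cache misses (loaded lazily
#' and indexed by variant key on first use). A variant absent from both is a
#' full miss and returns all-missing scores; misses are data, never errors.
#'
#' @param cache A data frame with columns `chrom, pos, ref, alt, cadd, dann,
#'   gwava` (missing scores as `NA`), or `NULL` for an empty cache.
#' @param fallback_path Path to a TSV with the same columns (empty cells =
#'   missing), or `NULL` for no fallback.
#' @return A `score_store` object (environment-backed so the lazy fallback
#'   load and the probe counter persist across lookups).
#' @export
score_store <- function(cache = NULL, fallback_path = NULL) {
  e <- new.env(parent = emptyenv())
  e$cache <- .key_scores(cache)
  e$fallback_path <- fallback_path
  e$fallback <- NULL       # loaded on first miss
  e$fallback_probes <- 0L
  structure(e, class = "score_store")
}

.variant_key <- function(tbl) {
  paste(sub("^chr", "", tbl$chrom), tbl$pos, tbl$ref, tbl$alt, sep = ":")
}

.key_scores <- function(tbl) {
  if (is.null(tbl) || nrow(tbl) == 0L) {
    return(tibble::tibble(key = character(), cadd = double(),
                          dann = double(), gwava = double()))
  }
  tbl <- tibble::as_tibble(tbl)
  out <- tibble::tibble(key = .variant_key(tbl),
                        cadd = as.numeric(tbl$cadd),
                        dann = as.numeric(tbl$dann),
                        gwava = as.numeric(tbl$gwava))
  dplyr::distinct(out, .data$key, .keep_all = TRUE)
}

.read_score_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    cadd = readr::col_double(), dann = readr::col_double(),
    gwava = readr::col_double()
  ), progress = FALSE, na = c("", "NA"))
}

#' Look up pathogenicity scores for variants
#'
#' Cache-first: the in-memory cache is consulted for every variant; the
#' fallback table is probed only for keys the cache does not hold.
#'
#' @param variants Data frame with columns `chrom, pos, ref, alt`.
#' @param store A [score_store()].
#' @return `variants` with `cadd`, `dann`, `gwava` columns appended
#'   (`NA` = missing).
#' @export
lookup_scores <- function(variants, store) {
  stopifnot(inherits(store, "score_store"))
  variants <- tibble::as_tibble(variants)
  key <- .variant_key(variants)
  hit <- match(key, store$cache$key)
  out <- tibble::tibble(cadd = store$cache$cadd[hit],
                        dann = store$cache$dann[hit],
                        gwava = store$cache$gwava[hit])
  miss <- is.na(hit)
  if (any(miss) && !is.null(store$fallback_path)) {
    if (is.null(store$fallback)) {
      store$fallback <- .key_scores(.read_score_table(store$fallback_path))
    }
    store$fallback_probes <- store$fallback_probes + sum(miss)
    fhit <- match(key[miss], store$fallback$key)
    out$cadd[miss] <- store$fallback$cadd[fhit]
    out$dann[miss] <- store$fallback$dann[fhit]
    out$gwava[miss] <- store$fallback$gwava[fhit]
  }
  dplyr::bind_cols(variants, out)
}

#' Number of fallback probes a store has served
#' @param store A [score_store()].
#' @return Integer count of cache misses sent to the fallback table.
#' @export
fallback_probes <- function(store) store$fallback_probes

# ---- gene mapping ----------------------------------------------------------

#' Map variants to their nearest gene
#'
#' A variant inside a gene interval maps to that gene; an intergenic variant
#' maps to the gene minimizing the distance to the nearer interval boundary.
#' Ties break to the lexicographically smaller gene ID. Chromosomes with no
#' gene yield `NA`.
#'
#' @param variants Data frame with columns `chrom`, `pos`.
#' @param kb A [knowledge_base()].
#' @return Character vector of gene IDs, one per row of `variants`.
#' @export
nearest_gene <- function(variants, kb) {
  iv <- kb$gene_intervals
  chrom <- sub("^chr", "", variants$chrom)
  vapply(seq_len(nrow(variants)), function(i) {
    g <- iv[iv$chrom == chrom[i], ]
    if (nrow(g) == 0L) return(NA_character_)
    d <- pmax(g$start - variants$pos[i], variants$pos[i] - g$end, 0)
    cand <- g$gene[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

# ---- VCF -------------------------------------------------------------------

#' Read a single-sample VCF into per-allele variant records
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and decomposes each row into one
#' record per ALT allele carried by the sample's genotype. Genotypes are read
#' from the GT subfield: an ALT allele present on both haplotypes is
#' homozygous (`HOM`), on one haplotype heterozygous (`HET`); phased `|`
#' separators are treated as unphased. Rows with genotype `0/0` or `./.` are
#' dropped. A multi-allelic genotype such as `1/2` yields one HET record per
#' ALT allele.
#'
#' @param path Path to a VCF file.
#' @param sample Sample name or index (default: first sample).
#' @return A tibble with columns `chrom` (without `chr` prefix), `pos`,
#'   `ref`, `alt`, `zygosity` (`HOM`/`HET`).
#' @export
read_vcf <- function(path, sample = 1L) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf, getINFO = FALSE))
  if (nrow(fix) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          zygosity = character()))
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_mat)) stop("VCF has no GT genotype field")
  gt <- gt_mat[, sample]

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    g <- gt[i]
    if (is.na(g)) return(NULL)
    alleles <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    alleles <- alleles[!is.na(alleles) & alleles > 0L]
    if (length(alleles) == 0L) return(NULL)
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    counts <- table(alleles)
    idx <- as.integer(names(counts))
    tibble::tibble(
      chrom = sub("^chr", "", fix$CHROM[i]),
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = unname(alts[idx]),
      zygosity = ifelse(as.integer(counts) >= 2L, "HOM", "HET")
    )
  })
  dplyr::bind_rows(rows)
}
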