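#' Filter variants by minor allele frequency
#'
#' Removes variants whose population allele frequency exceeds the threshold
#' (strictly greater; a variant at exactly the threshold is kept). Variants
#' absent from the frequency table are treated as rare and kept.
#'
#' @param variants Data frame with columns `chrom, pos, ref, alt`.
#' @param freq_table Data frame with columns `chrom, pos, ref, alt, freq`,
#'   or `NULL` (no filtering).
#' @param threshold MAF cutoff in `[0, 1]`; default 0.01.
#' @return The surviving rows of `variants`, with the number removed in the
#'   `n_removed` attribute.
#' @export
maf_filter <- function(variants, freq_table, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 1)
  variants <- tibble::as_tibble(variants)
  if (is.null(freq_table) || nrow(variants) == 0L) {
    return(structure(variants, n_removed = 0L))
  }
  freq <- freq_table$freq[match(.variant_key(variants),
                                .variant_key(freq_table))]
  keep <- is.na(freq) | freq <= threshold
  structure(variants[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Rank the variants of a patient by causative-variant score
#'
#' The end-to-end prioritization: read the patient's VCF (or take an
#' already-parsed variant tibble), optionally remove common variants
#' (MAF > `maf`), encode every surviving variant against the patient's
#' phenotype profile and mode of inheritance, score with the trained model,
#' and rank by descending score. Equal scores break ties by
#' (chrom, pos, ref, alt) so output is byte-stable across runs. Variants in
#' genes without phenotype annotation are scored (similarity imputed and
#' flagged), not dropped.
#'
#' @param patient Path to a VCF file, or a tibble with columns
#'   `chrom, pos, ref, alt, zygosity`.
#' @param phenotypes Character vector of the patient's phenotype term IDs
#'   (must exist in the ontology).
#' @param moi The patient's mode of inheritance (see [moi_levels()];
#'   lower-case synonyms `recessive`, `dominant`, `x-linked`, `unknown`
#'   accepted).
#' @param model A `pvp_model` from [fit_pvp()] or [read_pvp()].
#' @param kb,store,onto,ic Knowledge resources consistent with the model's
#'   schema.
#' @param freq_table Optional allele-frequency table for [maf_filter()].
#' @param maf MAF threshold (default 0.01).
#' @param moi_filter If `TRUE`, additionally drop heterozygous variants when
#'   `moi` is recessive. Off by default.
#' @return A `ranked_variants` tibble: `rank, chrom, pos, ref, alt, gene,
#'   zygosity, score, sim, cadd, dann, gwava` plus the missing-value flag
#'   columns; accounting counts in the `accounting` attribute.
#' @export
prioritize <- function(patient, phenotypes, moi, model, kb, store, onto, ic,
                       freq_table = NULL, maf = 0.01, moi_filter = FALSE) {
  stopifnot(inherits(model, "pvp_model"))
  moi <- .canonical_moi(moi)
  bad <- setdiff(phenotypes, onto$terms)
  if (length(bad)) {
    stop("phenotype term(s) not in ontology: ", paste(bad, collapse = ", "))
  }
  variants <- if (is.character(patient)) read_vcf(patient) else
    tibble::as_tibble(patient)
  n_input <- nrow(variants)
  variants <- maf_filter(variants, freq_table, maf)
  n_maf <- attr(variants, "n_removed")
  n_moi <- 0L
  if (moi_filter && moi == "RECESSIVE") {
    n_moi <- sum(variants$zygosity == "HET")
    variants <- variants[variants$zygosity == "HOM", , drop = FALSE]
  }
  if (nrow(variants) == 0L) stop("no variants left after filtering")

  if (!"gene" %in% names(variants)) variants$gene <- NA_character_
  no_gene <- is.na(variants$gene)
  if (any(no_gene)) {
    variants$gene[no_gene] <- nearest_gene(variants[no_gene, , drop = FALSE], kb)
  }
  x <- encode_variants(variants, phenotypes, variants$zygosity, moi, kb,
                       store, onto, ic, model$imputation, model$schema)
  score <- predict(model, x)

  out <- dplyr::bind_cols(
    variants[, c("chrom", "pos", "ref", "alt", "gene", "zygosity")],
    tibble::tibble(score = score),
    tibble::as_tibble(x[, c("sim", "cadd", "dann", "gwava",
                            model$schema$flags), drop = FALSE])
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$chrom,
                        .data$pos, .data$ref, .data$alt)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1L)
  message("prioritize: ", n_input, " input variants, ", n_maf,
          " removed by MAF filter, ", n_moi, " removed by MoI filter, ",
          nrow(out), " ranked")
  structure(out, accounting = c(input = n_input, maf_removed = n_maf,
                                moi_removed = n_moi, ranked = nrow(out)),
            class = c("ranked_variants", class(out)))
}

.canonical_moi <- function(moi) {
  map <- c(recessive = "RECESSIVE", dominant = "DOMINANT",
           "x-linked" = "X_LINKED", x_linked = "X_LINKED",
           unknown = "OTHER_UNKNOWN", other = "OTHER_UNKNOWN")
  out <- if (tolower(moi) %in% names(map)) map[[tolower(moi)]] else moi
  if (!out %in% moi_levels()) stop("unknown mode of inheritance: ", moi)
  out
}
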