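#' Parameters for the synthetic study generator
#'
#' Defines the study conditions every synthetic input is drawn under. The
#' defaults describe a desk-scale rare-disease cohort: a 120-term phenotype
#' ontology with 8 top-level categories, 50 genes tiling one synthetic
#' chromosome, 30 diseases with 6-term phenotype profiles, 120 pathogenic and
#' 100 benign knowledge variants, pathogenicity scores separated by class
#' (pathogenic ~ Beta(8, 2), benign/background ~ Beta(2, 8); CADD on a 0-100
#' scale), 5% missingness per score, and 200 background variants sampled per
#' patient from a 1000-variant population pool in which 30% of variants are
#' rare (MAF < 1%) and the rest common.
#'
#' @param n_terms Total ontology terms (including root).
#' @param root_branching Number of the root's direct children (top-level
#'   categories).
#' @param n_genes,n_diseases Gene and disease counts.
#' @param terms_per_profile Terms per disease profile.
#' @param profile_noise Fraction of a causative gene's profile terms replaced
#'   by random terms (decoupling gene from disease annotation).
#' @param n_pathogenic,n_benign Variant counts in the knowledge table.
#' @param multi_disease_fraction Fraction of pathogenic variants annotated
#'   with two diseases.
#' @param score_dists Beta shape parameters per class, list with `pathogenic`
#'   and `benign` entries of `(shape1, shape2)`.
#' @param missing_rate Per-score probability of a missing value.
#' @param n_background_variants Background variants per patient VCF.
#' @param n_background_pool Size of the shared background population pool.
#' @param background_rare_fraction Fraction of pool variants with MAF below
#'   1% (the rest are common and removed by the MAF filter).
#' @param het_fraction Heterozygote fraction among background genotypes.
#' @param moi_distribution Named probabilities over [moi_levels()].
#' @param chrom Synthetic chromosome name.
#' @param seed Master seed; every generator stage derives its stream from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_terms = 120L, root_branching = 8L, n_genes = 50L,
                       n_diseases = 30L, terms_per_profile = 6L,
                       profile_noise = 0.1, n_pathogenic = 120L,
                       n_benign = 100L, multi_disease_fraction = 0.1,
                       score_dists = list(pathogenic = c(8, 2),
                                          benign = c(2, 8)),
                       missing_rate = 0.05, n_background_variants = 200L,
                       n_background_pool = 1000L,
                       background_rare_fraction = 0.3, het_fraction = 0.5,
                       moi_distribution = c(RECESSIVE = 0.35, DOMINANT = 0.35,
                                            X_LINKED = 0.1,
                                            OTHER_UNKNOWN = 0.2),
                       chrom = "1", seed = 1L) {
  stopifnot(n_terms >= root_branching + 1L, profile_noise >= 0,
            profile_noise <= 1, missing_rate >= 0, missing_rate <= 1,
            multi_disease_fraction >= 0, multi_disease_fraction <= 1,
            background_rare_fraction >= 0, background_rare_fraction <= 1,
            abs(sum(moi_distribution) - 1) < 1e-9,
            all(names(moi_distribution) %in% moi_levels()))
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

.term_id <- function(i) sprintf("HP:%07d", i)

#' Generate a random phenotype ontology
#'
#' Root plus `root_branching` direct children; each remaining term attaches
#' below with one or two parents drawn from previously placed non-root
#' terms, giving a DAG by construction.
#'
#' @param params A [sim_params()].
#' @param dir If non-NULL, the edge list is written to `dir/ontology.tsv`.
#' @return A [phenotype_ontology()].
#' @export
sim_ontology <- function(params, dir = NULL) {
  withr::with_seed(params$seed + 1L, {
    root <- .term_id(1L)
    kids <- .term_id(1L + seq_len(params$root_branching))
    edges <- tibble::tibble(child = kids, parent = root)
    for (i in seq_len(params$n_terms - params$root_branching - 1L) +
           params$root_branching + 1L) {
      placed <- .term_id(2L:(i - 1L))
      n_par <- sample(1:2, 1L)
      parents <- sample(placed, min(n_par, length(placed)))
      edges <- dplyr::bind_rows(edges,
                                tibble::tibble(child = .term_id(i),
                                               parent = parents))
    }
  })
  if (!is.null(dir)) {
    utils::write.table(as.data.frame(edges), file.path(dir, "ontology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  phenotype_ontology(edges)
}

#' Generate a synthetic knowledge base
#'
#' Diseases get random `terms_per_profile`-term profiles; each disease is
#' linked to a causative gene whose profile is the union of its diseases'
#' profiles with `profile_noise` of the terms replaced at random; remaining
#' genes get random profiles. Modes of inheritance are drawn from
#' `moi_distribution`; gene intervals tile the synthetic chromosome
#' (5 kb genes separated by 5 kb gaps).
#'
#' @param onto The ontology from [sim_ontology()].
#' @param params A [sim_params()].
#' @param dir If non-NULL, writes gene_annotations.tsv,
#'   disease_annotations.tsv, disease_moi.tsv, gene_intervals.tsv.
#' @return List: `kb` (a [knowledge_base()] without benign variants yet),
#'   `disease_gene` (tibble disease -> gene ground truth), components.
#' @export
sim_knowledge_base <- function(onto, params, dir = NULL) {
  terms <- setdiff(onto$terms, onto$root)
  genes <- sprintf("GENE%03d", seq_len(params$n_genes))
  diseases <- sprintf("OMIM:6%05d", seq_len(params$n_diseases))

  withr::with_seed(params$seed + 2L, {
    disease_profiles <- dplyr::bind_rows(lapply(diseases, function(d) {
      tibble::tibble(entity = d,
                     term = sample(terms, params$terms_per_profile))
    }))
    disease_gene <- tibble::tibble(
      disease = diseases,
      gene = sample(genes[seq_len(max(2L, floor(params$n_genes * 0.6)))],
                    params$n_diseases, replace = TRUE))
    noisy <- function(profile) {
      k <- floor(params$profile_noise * length(profile))
      if (k == 0L) return(profile)
      drop <- sample(seq_along(profile), k)
      unique(c(profile[-drop], sample(setdiff(terms, profile), k)))
    }
    gene_profiles <- dplyr::bind_rows(lapply(genes, function(g) {
      dz <- disease_gene$disease[disease_gene$gene == g]
      profile <- if (length(dz)) {
        noisy(unique(disease_profiles$term[disease_profiles$entity %in% dz]))
      } else {
        sample(terms, params$terms_per_profile)
      }
      tibble::tibble(entity = g, term = profile)
    }))
    moi <- tibble::tibble(
      disease = diseases,
      moi = sample(names(params$moi_distribution), params$n_diseases,
                   replace = TRUE, prob = params$moi_distribution))
  })
  intervals <- tibble::tibble(
    gene = genes, chrom = params$chrom,
    start = (seq_along(genes) - 1L) * 10000L + 1L,
    end = (seq_along(genes) - 1L) * 10000L + 5000L)

  if (!is.null(dir)) {
    wr <- function(x, f) utils::write.table(
      as.data.frame(x), file.path(dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(gene_profiles, "gene_annotations.tsv")
    wr(disease_profiles, "disease_annotations.tsv")
    wr(moi, "disease_moi.tsv")
    wr(intervals, "gene_intervals.tsv")
  }
  list(gene_profiles = gene_profiles, disease_profiles = disease_profiles,
       disease_moi = moi, gene_intervals = intervals,
       disease_gene = disease_gene)
}

.random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

.draw_scores <- function(n, shapes, missing_rate) {
  draw <- function(scale = 1) {
    v <- scale * stats::rbeta(n, shapes[1], shapes[2])
    v[stats::runif(n) < missing_rate] <- NA_real_
    v
  }
  tibble::tibble(cadd = draw(100), dann = draw(), gwava = draw())
}

#' Generate variants, score tables and allele frequencies
#'
#' Pathogenic variants are placed inside their disease's causative gene with
#' scores from the pathogenic Beta distributions and rare allele
#' frequencies; benign variants land in random genes with benign-class
#' scores; a background population pool (for patient VCFs) gets benign-class
#' scores and a rare/common frequency mixture. Positions are unique. The
#' score store's in-memory cache holds the background pool and benign
#' variants (the "common variant" library); the fallback table on disk holds
#' everything.
#'
#' @param kbparts Output of [sim_knowledge_base()].
#' @param params A [sim_params()].
#' @param dir If non-NULL, writes variants.tsv, scores_cache.tsv,
#'   scores.tsv, freqs.tsv.
#' @return List: `variant_table` (ClinVar-like tibble), `scores` (full score
#'   tibble), `cache` (subset for the in-memory cache), `freqs`,
#'   `background_pool` (tibble with zygosity-free variant records).
#' @export
sim_variants <- function(kbparts, params, dir = NULL) {
  iv <- kbparts$gene_intervals
  withr::with_seed(params$seed + 3L, {
    n_total <- params$n_pathogenic + params$n_benign + params$n_background_pool
    chrom_len <- max(iv$end) + 10000L
    pos_pool <- sample.int(chrom_len, n_total)

    # pathogenic: inside the causative gene of a (randomly drawn) disease
    dz <- sample(kbparts$disease_gene$disease, params$n_pathogenic,
                 replace = TRUE)
    gene <- kbparts$disease_gene$gene[match(dz, kbparts$disease_gene$disease)]
    g_iv <- iv[match(gene, iv$gene), ]
    pos_path <- g_iv$start + (pos_pool[seq_len(params$n_pathogenic)] %% 5000L)
    second <- stats::runif(params$n_pathogenic) < params$multi_disease_fraction
    diseases <- vapply(seq_len(params$n_pathogenic), function(i) {
      if (!second[i]) return(dz[i])
      same_gene <- setdiff(
        kbparts$disease_gene$disease[kbparts$disease_gene$gene == gene[i]],
        dz[i])
      extra <- if (length(same_gene)) sample(same_gene, 1L) else
        sample(setdiff(kbparts$disease_gene$disease, dz[i]), 1L)
      paste(sort(c(dz[i], extra)), collapse = ";")
    }, "")
    al_p <- .random_alleles(params$n_pathogenic)
    pathogenic <- tibble::tibble(
      chrom = params$chrom, pos = as.integer(pos_path), ref = al_p$ref,
      alt = al_p$alt, gene = gene, significance = "Pathogenic",
      review_flag = "", diseases = diseases)

    # benign: random genes
    bg_gene <- sample(iv$gene, params$n_benign, replace = TRUE)
    b_iv <- iv[match(bg_gene, iv$gene), ]
    idx_b <- params$n_pathogenic + seq_len(params$n_benign)
    al_b <- .random_alleles(params$n_benign)
    benign <- tibble::tibble(
      chrom = params$chrom,
      pos = as.integer(b_iv$start + (pos_pool[idx_b] %% 5000L)),
      ref = al_b$ref, alt = al_b$alt, gene = bg_gene,
      significance = "Benign", review_flag = "", diseases = "")

    # background population pool: anywhere on the chromosome
    idx_g <- params$n_pathogenic + params$n_benign +
      seq_len(params$n_background_pool)
    al_g <- .random_alleles(params$n_background_pool)
    background <- tibble::tibble(
      chrom = params$chrom, pos = as.integer(pos_pool[idx_g]),
      ref = al_g$ref, alt = al_g$alt)

    # deduplicate coordinates across the three sets
    all_pos <- c(pathogenic$pos, benign$pos, background$pos)
    dup <- duplicated(all_pos)
    if (any(dup)) {
      free <- setdiff(seq_len(chrom_len), all_pos)
      all_pos[dup] <- sample(free, sum(dup))
      pathogenic$pos <- all_pos[seq_len(params$n_pathogenic)]
      benign$pos <- all_pos[idx_b]
      background$pos <- all_pos[idx_g]
    }

    scores <- dplyr::bind_rows(
      dplyr::bind_cols(pathogenic[c("chrom", "pos", "ref", "alt")],
                       .draw_scores(params$n_pathogenic,
                                    params$score_dists$pathogenic,
                                    params$missing_rate)),
      dplyr::bind_cols(benign[c("chrom", "pos", "ref", "alt")],
                       .draw_scores(params$n_benign,
                                    params$score_dists$benign,
                                    params$missing_rate)),
      dplyr::bind_cols(background,
                       .draw_scores(params$n_background_pool,
                                    params$score_dists$benign,
                                    params$missing_rate)))

    rare <- stats::runif(params$n_background_pool) <
      params$background_rare_fraction
    freqs <- dplyr::bind_rows(
      dplyr::mutate(pathogenic[c("chrom", "pos", "ref", "alt")],
                    freq = stats::runif(params$n_pathogenic, 0, 0.009)),
      dplyr::mutate(benign[c("chrom", "pos", "ref", "alt")],
                    freq = stats::runif(params$n_benign, 0.011, 0.5)),
      dplyr::mutate(background,
                    freq = ifelse(rare,
                                  stats::runif(params$n_background_pool, 0, 0.009),
                                  stats::runif(params$n_background_pool, 0.011, 0.5))))
  })
  variant_table <- dplyr::bind_rows(pathogenic, benign)
  cache <- scores[scores$pos %in% c(benign$pos, background$pos), ]

  if (!is.null(dir)) {
    wr <- function(x, f) utils::write.table(
      as.data.frame(x), file.path(dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "")
    wr(variant_table, "variants.tsv")
    wr(scores, "scores.tsv")
    wr(cache, "scores_cache.tsv")
    wr(freqs, "freqs.tsv")
  }
  list(variant_table = variant_table, scores = scores, cache = cache,
       freqs = freqs, background_pool = background)
}

#' Write a background patient VCF
#'
#' Samples `n` variants from the background pool, assigns genotypes
#' (heterozygous with probability `het_fraction`, else homozygous
#' alternate), and writes a minimal single-sample VCF 4.2.
#'
#' @param background_pool Tibble from [sim_variants()].
#' @param params A [sim_params()].
#' @param path Output VCF path.
#' @param n Number of variants (default `params$n_background_variants`).
#' @param seed Seed for this draw (patients differ; default derives from
#'   `params$seed`).
#' @return Tibble of the sampled variants (chrom, pos, ref, alt, zygosity);
#'   the file is written as a side effect.
#' @export
sim_background_vcf <- function(background_pool, params, path,
                               n = params$n_background_variants,
                               seed = params$seed + 4L) {
  stopifnot(n <= nrow(background_pool))
  vars <- withr::with_seed(seed, {
    rows <- if (n > 0L) {
      background_pool[sample.int(nrow(background_pool), n), ]
    } else background_pool[0L, ]
    dplyr::mutate(dplyr::arrange(rows, .data$pos),
                  zygosity = ifelse(stats::runif(n) < params$het_fraction,
                                    "HET", "HOM"))
  })
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", params$chrom, ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "SAMPLE1", sep = "\t"))
  body <- if (nrow(vars)) {
    paste(vars$chrom, vars$pos, ".", vars$ref, vars$alt, ".", "PASS", ".",
          "GT", ifelse(vars$zygosity == "HET", "0/1", "1/1"), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(vars)
}

#' Generate a complete synthetic study
#'
#' Orchestrates [sim_ontology()], [sim_knowledge_base()] and
#' [sim_variants()], parses the emitted variant table through
#' [read_variant_table()], and assembles the live objects the pipeline
#' consumes, together with a ground-truth manifest.
#'
#' @param params A [sim_params()].
#' @param dir Optional directory; when given, every input file is emitted
#'   there (ontology.tsv, annotations, variants.tsv, scores.tsv, freqs.tsv,
#'   manifest.json).
#' @return A `sim_study` list: `onto`, `ic`, `kb`, `pathogenic`, `benign`,
#'   `store`, `freqs`, `background_pool`, `disease_gene`, `params`,
#'   `dropped`.
#' @export
sim_study <- function(params = sim_params(), dir = NULL) {
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  onto <- sim_ontology(params, dir)
  kbparts <- sim_knowledge_base(onto, params, dir)
  vars <- sim_variants(kbparts, params, dir)

  tmp <- if (is.null(dir)) tempfile(fileext = ".tsv") else
    file.path(dir, "variants.tsv")
  if (is.null(dir)) {
    utils::write.table(as.data.frame(vars$variant_table), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  parsed <- read_variant_table(tmp)
  if (is.null(dir)) unlink(tmp)

  kb <- knowledge_base(kbparts$gene_profiles, kbparts$disease_profiles,
                       kbparts$disease_moi, kbparts$gene_intervals,
                       parsed$benign)
  corpus <- dplyr::bind_rows(kbparts$gene_profiles, kbparts$disease_profiles)
  ic <- suppressMessages(compute_ic(corpus, onto))

  fallback_path <- if (is.null(dir)) tempfile(fileext = ".tsv") else
    file.path(dir, "scores.tsv")
  if (is.null(dir)) {
    utils::write.table(as.data.frame(vars$scores), fallback_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  store <- score_store(cache = vars$cache, fallback_path = fallback_path)

  if (!is.null(dir)) {
    manifest <- list(
      params = params[setdiff(names(params), "score_dists")],
      score_dists = params$score_dists,
      n_terms = length(onto$terms), root = onto$root,
      disease_gene = kbparts$disease_gene,
      n_pathogenic_rows = nrow(parsed$pathogenic),
      n_benign_rows = nrow(parsed$benign), dropped = as.list(parsed$dropped))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(onto = onto, ic = ic, kb = kb,
                 pathogenic = parsed$pathogenic, benign = parsed$benign,
                 store = store, freqs = vars$freqs,
                 background_pool = vars$background_pool,
                 disease_gene = kbparts$disease_gene, params = params,
                 dropped = parsed$dropped),
            class = "sim_study")
}

#' Generate a cohort of spike-in synthetic patients
#'
#' Draws positive triples from held-out diseases (or all diseases), builds
#' one MAF-filtered background per patient from the population pool, and
#' spikes the causative variant in.
#'
#' @param study A [sim_study()].
#' @param triples Positive instance tibble to draw causatives from.
#' @param n_patients Cohort size.
#' @param seed Seed for patient construction.
#' @return List of [make_synthetic_patient()] objects.
#' @export
sim_patient_cohort <- function(study, triples, n_patients = 50L, seed = 1L) {
  stopifnot(nrow(triples) > 0L)
  withr::with_seed(seed, {
    picks <- sample.int(nrow(triples), n_patients, replace = TRUE)
    bg_seeds <- sample.int(.Machine$integer.max / 2, n_patients)
  })
  lapply(seq_len(n_patients), function(i) {
    bg <- withr::with_seed(bg_seeds[i], {
      rows <- study$background_pool[
        sample.int(nrow(study$background_pool),
                   study$params$n_background_variants), ]
      dplyr::mutate(rows,
                    zygosity = ifelse(stats::runif(nrow(rows)) <
                                        study$params$het_fraction,
                                      "HET", "HOM"))
    })
    make_synthetic_patient(bg, triples[picks[i], ], study$kb, study$freqs)
  })
}
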