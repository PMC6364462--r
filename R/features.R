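#' Feature schema for variant encoding
#'
#' Fixes the order and dimensionality of the feature vector: four continuous
#' features (cadd, dann, gwava, phenotype similarity), one missing-value flag
#' per continuous feature, a zygosity bit (HET = 0, HOM = 1), a one-hot mode
#' of inheritance, and one high-level phenotype indicator per top-level
#' ontology category (root's direct children, lexicographic order). The
#' schema is frozen when a model is trained; the input layer width equals
#' `total_dim`.
#'
#' @param onto A [phenotype_ontology()]; its root children define the
#'   high-level categories.
#' @return A `feature_schema` object with `continuous`, `flags`,
#'   `moi_categories`, `highlevel_categories`, `names` (full column order)
#'   and `total_dim`.
#' @export
feature_schema <- function(onto) {
  continuous <- c("cadd", "dann", "gwava", "sim")
  flags <- paste0("miss_", continuous)
  highlevel <- onto$children[[onto$root]]
  nm <- c(continuous, flags, "zygosity",
          paste0("moi_", moi_levels()), paste0("hl_", highlevel))
  structure(list(continuous = continuous, flags = flags,
                 moi_categories = moi_levels(),
                 highlevel_categories = highlevel,
                 names = nm, total_dim = length(nm)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", x$total_dim, " features: 4 scores + 4 flags + ",
      "zygosity + ", length(x$moi_categories), " MoI + ",
      length(x$highlevel_categories), " high-level categories\n", sep = "")
  invisible(x)
}

# Raw (un-imputed) feature matrix: continuous slots keep NA where the score
# or similarity is missing; flags mark those slots. `profiles` is a
# list-column-like list of term-ID vectors, one per instance (the phenotype
# context used for the similarity and high-level features).
.encode_raw <- function(variants, profiles, zygosity, moi, kb, store,
                        onto, ic, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  n <- nrow(variants)
  stopifnot(length(profiles) == n, length(zygosity) == n)
  moi <- if (length(moi) == 1L) rep(moi, n) else moi
  bad_moi <- setdiff(unique(moi), schema$moi_categories)
  if (length(bad_moi)) stop("unknown MoI category: ", paste(bad_moi, collapse = ", "))
  .check_terms(unique(unlist(profiles)), onto)

  scored <- lookup_scores(variants, store)

  # phenotype similarity: patient/disease profile vs the variant's gene
  # profile; memoized per (gene, profile) pair since profiles repeat heavily
  gene <- if ("gene" %in% names(variants)) variants$gene else
    rep(NA_character_, n)
  no_gene <- is.na(gene)
  if (any(no_gene)) gene[no_gene] <- nearest_gene(variants[no_gene, ], kb)
  prof_key <- vapply(profiles, function(p) paste(sort(unique(p)), collapse = ","),
                     character(1))
  memo <- new.env(parent = emptyenv())
  sim <- vapply(seq_len(n), function(i) {
    if (is.na(gene[i])) return(NA_real_)
    k <- paste0(gene[i], "|", prof_key[i])
    if (!is.null(memo[[k]])) return(memo[[k]])
    gp <- entity_profile(gene[i], kb$gene_profiles)
    v <- if (length(gp) == 0L) NA_real_ else
      profile_similarity(profiles[[i]], gp, onto, ic)
    memo[[k]] <- v
    v
  }, double(1))

  cont <- cbind(cadd = scored$cadd, dann = scored$dann,
                gwava = scored$gwava, sim = sim)
  flags <- matrix(as.numeric(is.na(cont)), n, 4,
                  dimnames = list(NULL, schema$flags))

  hl_memo <- new.env(parent = emptyenv())
  hl <- t(vapply(seq_len(n), function(i) {
    k <- prof_key[i]
    if (is.null(hl_memo[[k]])) {
      hl_memo[[k]] <- as.numeric(high_level_profile(profiles[[i]], onto))
    }
    hl_memo[[k]]
  }, double(length(schema$highlevel_categories))))
  if (length(schema$highlevel_categories) == 1L) hl <- matrix(hl, ncol = 1L)

  moi_oh <- outer(moi, schema$moi_categories, `==`) * 1
  x <- cbind(cont, flags, zygosity = as.numeric(zygosity == "HOM"), moi_oh, hl)
  colnames(x) <- schema$names
  x
}

#' Fit the mean-imputation model
#'
#' Missing continuous features (cadd, dann, gwava, similarity) are imputed
#' with their training-set means over observed values. A feature never
#' observed in training gets mean 0 with a warning; its missing flag still
#' marks it at encode time.
#'
#' @param x_raw Raw feature matrix from the training instances (internal
#'   layout; produced by [encode_training()] machinery), or any numeric
#'   matrix whose first columns match the schema's continuous features.
#' @param schema A [feature_schema()].
#' @return An `imputation_model`: named means per continuous feature.
#' @export
fit_imputation <- function(x_raw, schema) {
  if (nrow(x_raw) == 0L) stop("empty training set")
  means <- vapply(schema$continuous, function(f) {
    v <- x_raw[, f]
    if (all(is.na(v))) {
      warning("feature '", f, "' never observed in training; imputing 0")
      0
    } else mean(v, na.rm = TRUE)
  }, double(1))
  structure(list(means = means), class = "imputation_model")
}

.apply_imputation <- function(x, imputation, schema) {
  for (f in schema$continuous) {
    v <- x[, f]
    v[is.na(v)] <- imputation$means[[f]]
    x[, f] <- v
  }
  stopifnot(!anyNA(x))
  x
}

#' Encode variants as feature vectors
#'
#' Produces the fixed-order numeric matrix the classifier consumes. Each row
#' combines the variant's pathogenicity scores (imputed where missing, with
#' flags), the best-match-average similarity between the phenotype profile
#' and the variant's gene profile (missing and flagged when the gene is
#' unannotated), the zygosity bit, the mode-of-inheritance one-hot, and the
#' high-level phenotype indicators of the profile.
#'
#' @param variants Data frame with columns `chrom, pos, ref, alt` and
#'   optionally `gene` (resolved via [nearest_gene()] where absent).
#' @param profiles A list of term-ID vectors (one per variant) or a single
#'   term-ID vector recycled to all variants (the patient's profile).
#' @param zygosity Character vector `HOM`/`HET` (recycled if length 1).
#' @param moi Mode-of-inheritance category (recycled if length 1).
#' @param kb,store,onto,ic Knowledge base, [score_store()], ontology and IC
#'   table.
#' @param imputation An [fit_imputation()] model.
#' @param schema A [feature_schema()].
#' @return Numeric matrix, one row per variant, `schema$total_dim` columns.
#' @export
encode_variants <- function(variants, profiles, zygosity, moi, kb, store,
                            onto, ic, imputation, schema) {
  n <- nrow(variants)
  if (!is.list(profiles)) profiles <- rep(list(profiles), n)
  if (length(zygosity) == 1L) zygosity <- rep(zygosity, n)
  x <- .encode_raw(variants, profiles, zygosity, moi, kb, store, onto, ic,
                   schema)
  .apply_imputation(x, imputation, schema)
}

#' Encode a training set, fitting imputation on it
#'
#' Encodes every instance of a training set (the phenotype profile of each
#' instance is its disease's profile) and fits the mean-imputation model on
#' the same instances, as done at training time.
#'
#' @param ts A `training_set` (or any instance tibble with variant columns,
#'   `disease`, `zygosity`, `label`).
#' @param kb,store,onto,ic Knowledge resources.
#' @param schema A [feature_schema()].
#' @param imputation Optional pre-fitted [fit_imputation()] model; fitted on
#'   `ts` when `NULL`.
#' @return List: `x` (imputed feature matrix), `y` (0/1 labels), `groups`
#'   (disease IDs for stratification), `imputation`, `schema`, `x_raw`.
#' @export
encode_training <- function(ts, kb, store, onto, ic, schema,
                            imputation = NULL) {
  profiles <- lapply(ts$disease, function(d) {
    entity_profile(d, kb$disease_profiles)
  })
  empty <- lengths(profiles) == 0L
  if (any(empty)) {
    stop("instance disease(s) without phenotype profile: ",
         paste(unique(ts$disease[empty]), collapse = ", "))
  }
  moi <- disease_moi(ts$disease, kb)
  x_raw <- .encode_raw(ts, profiles, ts$zygosity, moi, kb, store, onto, ic,
                       schema)
  if (is.null(imputation)) imputation <- fit_imputation(x_raw, schema)
  x <- .apply_imputation(x_raw, imputation, schema)
  list(x = x, y = as.numeric(ts$label == "POSITIVE"), groups = ts$disease,
       imputation = imputation, schema = schema, x_raw = x_raw)
}

#' Serialize / restore a feature schema as JSON
#' @param schema A [feature_schema()]. For restore, `path` only.
#' @param path File path.
#' @return `path` invisibly; reader returns a `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$total_dim <- as.integer(x$total_dim)
  structure(x, class = "feature_schema")
}
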