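#' Assemble a spike-in synthetic patient
#'
#' Takes a background variant set (a stand-in for a population exome),
#' filters it at 1% MAF, and inserts one known causative variant: a positive
#' (variant, disease, zygosity) triple. The causative zygosity follows the
#' disease's mode of inheritance — homozygous for recessive diseases, the
#' triple's own zygosity otherwise — and the patient's phenotype profile is
#' the disease's annotation profile. A background record at the causative
#' coordinates is replaced, not duplicated.
#'
#' @param background Tibble of background variants
#'   (chrom, pos, ref, alt, zygosity).
#' @param triple One-row positive instance tibble (variant columns,
#'   `disease`, `zygosity`).
#' @param kb A [knowledge_base()].
#' @param freq_table Allele-frequency table for the MAF filter (or `NULL`).
#' @param maf MAF threshold applied to the background (default 0.01).
#' @return A `synthetic_patient`: list with `variants` (tibble including the
#'   causative), `causative` (one row), `phenotypes`, `moi`, `disease`.
#' @export
make_synthetic_patient <- function(background, triple, kb, freq_table = NULL,
                                   maf = 0.01) {
  stopifnot(nrow(triple) == 1L)
  phenotypes <- entity_profile(triple$disease, kb$disease_profiles)
  if (length(phenotypes) == 0L) {
    stop("disease ", triple$disease, " has no phenotype profile")
  }
  moi <- disease_moi(triple$disease, kb)
  zyg <- if (moi == "RECESSIVE") "HOM" else triple$zygosity

  background <- maf_filter(tibble::as_tibble(background), freq_table, maf)
  clash <- .variant_key(background) == .variant_key(triple)
  background <- background[!clash, , drop = FALSE]
  causative <- tibble::tibble(chrom = sub("^chr", "", triple$chrom),
                              pos = triple$pos, ref = triple$ref,
                              alt = triple$alt, zygosity = zyg)
  structure(list(
    variants = dplyr::bind_rows(background[, names(causative)], causative),
    causative = causative, phenotypes = phenotypes, moi = moi,
    disease = triple$disease
  ), class = "synthetic_patient")
}

#' Evaluate prioritization over a cohort of synthetic patients
#'
#' Runs [prioritize()] for each patient, records the rank of the inserted
#' causative variant, and summarizes recovery: top-1 and top-10 counts and
#' fractions, plus ROC AUC and AUPR computed on the (score, is-causative)
#' pairs pooled across all patients' variants.
#'
#' @param patients List of [make_synthetic_patient()] objects.
#' @param model,kb,store,onto,ic Fitted model and knowledge resources.
#' @return An `eval_report`: list with `n`, `top1`, `top10`, `top1_fraction`,
#'   `top10_fraction`, `roc_auc`, `aupr`, `ranks` (per-patient tibble) and
#'   `pooled` (all scored variants with `causative` labels).
#' @export
evaluate_patients <- function(patients, model, kb, store, onto, ic) {
  stopifnot(length(patients) > 0L)
  per <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    ranked <- suppressMessages(
      prioritize(p$variants, p$phenotypes, p$moi, model, kb, store, onto,
                 ic, freq_table = NULL)
    )
    hit <- .variant_key(ranked) == .variant_key(p$causative)
    if (sum(hit) != 1L) {
      stop("causative variant of patient ", i,
           " missing from the ranked output")
    }
    list(rank = tibble::tibble(patient = i, disease = p$disease,
                               rank = ranked$rank[hit],
                               n_variants = nrow(ranked)),
         pooled = tibble::tibble(patient = i, score = ranked$score,
                                 causative = as.integer(hit[order(ranked$rank)])))
  })
  ranks <- dplyr::bind_rows(lapply(per, `[[`, "rank"))
  pooled <- dplyr::bind_rows(lapply(per, `[[`, "pooled"))
  n <- nrow(ranks)
  structure(list(
    n = n, top1 = sum(ranks$rank <= 1L), top10 = sum(ranks$rank <= 10L),
    top1_fraction = mean(ranks$rank <= 1L),
    top10_fraction = mean(ranks$rank <= 10L),
    roc_auc = roc_auc(pooled$causative, pooled$score),
    aupr = aupr(pooled$causative, pooled$score),
    ranks = ranks, pooled = pooled
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n, " synthetic patients\n",
      "  top-1: ", x$top1, " (", sprintf("%.2f%%", 100 * x$top1_fraction),
      ")   top-10: ", x$top10, " (",
      sprintf("%.2f%%", 100 * x$top10_fraction), ")\n",
      "  pooled ROC AUC ", sprintf("%.3f", x$roc_auc),
      ", AUPR ", sprintf("%.3f", x$aupr), "\n", sep = "")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the summary as JSON and as a one-row TSV
#' (top hit, top 10 hits, total, ROC AUC, AUPR), and the per-patient ranks
#' as TSV.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(top_hit = report$top1, top10_hits = report$top10,
                  total = report$n, top1_fraction = report$top1_fraction,
                  top10_fraction = report$top10_fraction,
                  roc_auc = report$roc_auc, aupr = report$aupr)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(tibble::as_tibble(summary), file.path(dir, "report.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$ranks, file.path(dir, "ranks.tsv"),
                   progress = FALSE)
  invisible(dir)
}

# ---- nested disease-stratified cross-validation ---------------------------

.partition_groups <- function(groups, k) {
  ug <- sort(unique(groups))
  if (length(ug) < k) stop("too few groups (", length(ug), ") for ", k, " folds")
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(ug)),
                             sample(ug))
  unname(fold_of[groups])
}

#' Nested disease-stratified cross-validation
#'
#' Splits the training instances into `outer` folds whose disease sets are
#' pairwise disjoint; within each outer training portion, a further `inner`
#' disjoint-disease split (outer x inner inner splits in total) drives
#' hyperparameter selection; the selected configuration is refit on the full
#' outer training portion (with imputation refit there too) and evaluated on
#' the untouched outer test portion — accuracy at a 0.5 threshold, ROC AUC
#' and AUPR.
#'
#' @param kb A [knowledge_base()].
#' @param pathogenic,benign Variant tables as for [build_training_set()].
#' @param store,onto,ic Knowledge resources.
#' @param outer,inner Fold counts (default 5 and 5).
#' @param seed Master seed: training-set construction, fold assignment and
#'   model fits all derive from it.
#' @param config Base [model_config()] used when `trials = 0` and as the
#'   epoch/rate template for tuned configurations.
#' @param trials Hyperparameter draws per outer fold (0 = no tuning, use
#'   `config`).
#' @param tune_epochs Epochs per tuning trial.
#' @return A `cv_result`: list with `metrics` (per-outer-fold tibble),
#'   `predictions` (per-instance tibble: fold, disease, label, score),
#'   `outer_folds` (disease -> fold tibble), `inner_folds` (fold, disease,
#'   inner split), `configs` (selected per fold).
#' @export
nested_cv <- function(kb, pathogenic, benign, store, onto, ic,
                      outer = 5L, inner = 5L, seed = 1L,
                      config = model_config(), trials = 0L,
                      tune_epochs = 10L) {
  ts <- build_training_set(kb, pathogenic, benign, seed = seed)
  schema <- feature_schema(onto)
  enc <- encode_training(ts, kb, store, onto, ic, schema)
  groups <- enc$groups

  fold <- withr::with_seed(seed, .partition_groups(groups, outer))
  inner_assign <- vector("list", outer)
  metrics <- vector("list", outer)
  preds <- vector("list", outer)
  configs <- vector("list", outer)

  for (f in seq_len(outer)) {
    tr <- fold != f
    te <- !tr
    inner_fold <- withr::with_seed(seed + f,
                                   .partition_groups(groups[tr], inner))
    inner_assign[[f]] <- tibble::tibble(outer_fold = f,
                                        disease = groups[tr],
                                        inner_fold = inner_fold)
    cfg <- config
    if (trials > 0L) {
      # candidate configs scored by mean loss over the inner disjoint-disease
      # splits: train on inner-train, evaluate on the inner held-out split
      draws <- .sample_search_space(trials, seed + 100L + f)
      x_raw_tr <- enc$x_raw[tr, , drop = FALSE]
      y_tr <- enc$y[tr]
      inner_loss <- vapply(seq_len(trials), function(i) {
        cand <- model_config(hidden_units = draws[[i]]$hidden_units,
                             batch_size = draws[[i]]$batch_size,
                             epochs = tune_epochs,
                             validation_fraction = 0,
                             seed = seed + i)
        mean(vapply(seq_len(inner), function(j) {
          itr <- inner_fold != j
          imp_j <- fit_imputation(x_raw_tr[itr, , drop = FALSE], schema)
          x_itr <- .apply_imputation(x_raw_tr[itr, , drop = FALSE], imp_j, schema)
          x_ite <- .apply_imputation(x_raw_tr[!itr, , drop = FALSE], imp_j, schema)
          fit_j <- train_mlp(x_itr, y_tr[itr], groups[tr][itr], cand)
          .bce(predict(fit_j, x_ite), y_tr[!itr])
        }, double(1)))
      }, double(1))
      best <- draws[[which.min(inner_loss)]]
      cfg <- model_config(hidden_units = best$hidden_units,
                          batch_size = best$batch_size,
                          epochs = config$epochs,
                          dropout_rate = config$dropout_rate,
                          learning_rate = config$learning_rate,
                          validation_fraction = config$validation_fraction,
                          seed = config$seed)
    }
    configs[[f]] <- cfg
    imp <- fit_imputation(enc$x_raw[tr, , drop = FALSE], schema)
    x_tr <- .apply_imputation(enc$x_raw[tr, , drop = FALSE], imp, schema)
    x_te <- .apply_imputation(enc$x_raw[te, , drop = FALSE], imp, schema)
    fit <- train_mlp(x_tr, enc$y[tr], groups[tr], cfg)
    score <- predict(fit, x_te)
    metrics[[f]] <- tibble::tibble(
      fold = f, n_test = sum(te),
      accuracy = mean((score >= 0.5) == (enc$y[te] == 1)),
      roc_auc = roc_auc(enc$y[te], score),
      aupr = aupr(enc$y[te], score))
    preds[[f]] <- tibble::tibble(fold = f, disease = groups[te],
                                 label = enc$y[te], score = score)
  }

  structure(list(
    metrics = dplyr::bind_rows(metrics),
    predictions = dplyr::bind_rows(preds),
    outer_folds = tibble::tibble(disease = groups, fold = fold),
    inner_folds = dplyr::bind_rows(inner_assign),
    configs = configs, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat("<cv_result> ", nrow(m), " outer folds (disease-disjoint)\n",
      "  mean accuracy ", sprintf("%.3f", mean(m$accuracy)),
      ", ROC AUC ", sprintf("%.3f", mean(m$roc_auc)),
      ", AUPR ", sprintf("%.3f", mean(m$aupr)), "\n", sep = "")
  invisible(x)
}
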