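test_that("ROC AUC matches the Mann-Whitney identity and handles ties", {
  withr::with_seed(404L, {
    for (i in 1:20) {
      labels <- rep(c(0, 1), times = c(30L, 10L))
      scores <- round(stats::runif(40L), 2)  # rounding forces ties
      expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores),
                   tolerance = 1e-12)
    }
  })
  expect_identical(roc_auc(c(0, 1, 0, 1), rep(0.4, 4L)), 0.5)
})

test_that("average precision handles ties and bounds", {
  # hand-enumerated: labels (1,0,1,0) by descending score
  expect_equal(aupr(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # all tied: one block, precision = prevalence
  expect_equal(aupr(c(1, 0, 0, 0), rep(0.5, 4L)), 0.25, tolerance = 1e-12)
  # perfect separation
  expect_identical(aupr(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_error(aupr(c(0, 0), c(0.1, 0.2)), "no positive")
})

test_that("synthetic patients carry MoI-consistent causatives and profiles", {
  st <- small_study()
  ts <- build_training_set(st$kb, st$pathogenic, st$benign, seed = 3L)
  pos <- ts[ts$label == "POSITIVE", ]

  rec_dz <- names(st$kb$disease_moi[st$kb$disease_moi == "RECESSIVE"])
  rec <- pos[pos$disease %in% rec_dz, ][1, ]
  bg <- dplyr::mutate(st$background_pool[1:50, ], zygosity = "HET")
  p <- make_synthetic_patient(bg, rec, st$kb, st$freqs)
  expect_identical(p$causative$zygosity, "HOM")
  expect_identical(p$moi, "RECESSIVE")
  expect_setequal(p$phenotypes,
                  entity_profile(rec$disease, st$kb$disease_profiles))
  k <- phenorank:::.variant_key(p$variants)
  expect_identical(sum(k == phenorank:::.variant_key(p$causative)), 1L)

  dom_dz <- names(st$kb$disease_moi[st$kb$disease_moi != "RECESSIVE"])
  dom <- pos[pos$disease %in% dom_dz & pos$zygosity == "HET", ][1, ]
  p2 <- make_synthetic_patient(bg, dom, st$kb, st$freqs)
  expect_identical(p2$causative$zygosity, "HET")

  # a background record at the causative coordinates is replaced
  bg_clash <- dplyr::bind_rows(
    bg[1:10, ],
    tibble::tibble(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                   alt = rec$alt, zygosity = "HET"))
  p3 <- make_synthetic_patient(bg_clash, rec, st$kb, freq_table = NULL)
  k3 <- phenorank:::.variant_key(p3$variants)
  expect_identical(sum(k3 == phenorank:::.variant_key(rec)), 1L)
  expect_identical(nrow(p3$variants), 11L)
  expect_identical(
    p3$variants$zygosity[k3 == phenorank:::.variant_key(rec)], "HOM")
})

test_that("cohort evaluation pools ranks and matches the rank-sum oracle", {
  st <- small_study()
  ts <- build_training_set(st$kb, st$pathogenic, st$benign, seed = 3L)
  fit <- fit_pvp(ts, st$kb, st$store, st$onto, st$ic,
                 model_config(hidden_units = c(16L, 8L), epochs = 30L,
                              batch_size = 64L, seed = 2L))
  triples <- ts[ts$label == "POSITIVE", ]
  patients <- sim_patient_cohort(st, triples, n_patients = 10L, seed = 15L)
  rep <- evaluate_patients(patients, fit, st$kb, st$store, st$onto, st$ic)

  expect_identical(rep$n, 10L)
  expect_lte(rep$top1, rep$top10)
  expect_lte(rep$top10, rep$n)
  # every patient got exactly one causative rank within 1..n_variants
  expect_identical(nrow(rep$ranks), 10L)
  expect_true(all(rep$ranks$rank >= 1L & rep$ranks$rank <= rep$ranks$n_variants))
  # pooled metrics equal independent recomputation
  expect_equal(rep$roc_auc,
               oracle_auc(rep$pooled$causative, rep$pooled$score),
               tolerance = 1e-12)
  expect_gte(rep$aupr, mean(rep$pooled$causative))
  expect_identical(sum(rep$pooled$causative), 10L)

  g <- glance(rep)
  expect_identical(g$top1, rep$top1)
  expect_identical(nrow(tidy(rep)), 10L)

  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  back <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(back$roc_auc, rep$roc_auc, tolerance = 1e-12)
})

test_that("a constant scorer yields chance AUC under the tie convention", {
  pooled_labels <- rep(c(1, 0), times = c(5L, 95L))
  expect_identical(roc_auc(pooled_labels, rep(0.7, 100L)), 0.5)
})

test_that("nested CV partitions diseases without leakage and metrics recompute", {
  st <- small_study()
  cfg <- model_config(hidden_units = c(12L, 6L), epochs = 6L,
                      batch_size = 64L, seed = 2L)
  cv <- nested_cv(st$kb, st$pathogenic, st$benign, st$store, st$onto,
                  st$ic, outer = 5L, inner = 5L, seed = 19L, config = cfg)

  # outer folds partition the disease set
  dz_fold <- dplyr::distinct(cv$outer_folds)
  expect_identical(anyDuplicated(dz_fold$disease), 0L)
  expect_setequal(unique(cv$outer_folds$fold), 1:5)

  # inner splits: 25 total, never touching the outer test diseases
  for (f in 1:5) {
    outer_test <- dz_fold$disease[dz_fold$fold == f]
    inner_f <- cv$inner_folds[cv$inner_folds$outer_fold == f, ]
    expect_setequal(unique(inner_f$inner_fold), 1:5)
    expect_length(intersect(inner_f$disease, outer_test), 0L)
  }
  expect_identical(
    nrow(dplyr::distinct(cv$inner_folds[c("outer_fold", "inner_fold")])), 25L)

  # reported accuracy equals a recount from the saved predictions
  for (f in 1:5) {
    pr <- cv$predictions[cv$predictions$fold == f, ]
    expect_equal(cv$metrics$accuracy[cv$metrics$fold == f],
                 mean((pr$score >= 0.5) == (pr$label == 1)),
                 tolerance = 1e-12)
    expect_equal(cv$metrics$roc_auc[cv$metrics$fold == f],
                 oracle_auc(pr$label, pr$score), tolerance = 1e-12)
  }
  expect_identical(nrow(cv$predictions),
                   nrow(build_training_set(st$kb, st$pathogenic, st$benign,
                                           seed = 19L)))
  g <- glance(cv)
  expect_equal(g$accuracy, mean(cv$metrics$accuracy), tolerance = 1e-12)
})

test_that("nested CV with tuning stays inside the search space", {
  st <- small_study()
  cfg <- model_config(hidden_units = 8L, epochs = 4L, batch_size = 64L,
                      seed = 2L)
  cv <- nested_cv(st$kb, st$pathogenic, st$benign, st$store, st$onto,
                  st$ic, outer = 3L, inner = 2L, seed = 19L, config = cfg,
                  trials = 2L, tune_epochs = 2L)
  units_space <- c(32L, 64L, 67L, 128L, 134L, 201L, 256L, 512L)
  for (c in cv$configs) {
    expect_true(length(c$hidden_units) %in% 2:4)
    expect_true(all(c$hidden_units %in% units_space))
  }
  expect_identical(nrow(cv$metrics), 3L)
})
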