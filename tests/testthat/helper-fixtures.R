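# Shared fixture machinery: small deterministic study objects, cached per
# session, plus brute-force oracles kept independent of the package's
# implementation paths.

.fixture_cache <- new.env(parent = emptyenv())

# Small random ontology (default 20 terms) for similarity oracle tests.
small_onto <- function(n_terms = 20L, seed = 101L) {
  key <- paste0("onto_", n_terms, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- sim_ontology(
      sim_params(n_terms = n_terms, root_branching = 4L, seed = seed))
  }
  .fixture_cache[[key]]
}

# Random annotation corpus over a given ontology.
small_corpus <- function(onto, n_entities = 10L, terms_each = 3L,
                         seed = 202L) {
  withr::with_seed(seed, {
    non_root <- setdiff(onto$terms, onto$root)
    dplyr::bind_rows(lapply(seq_len(n_entities), function(i) {
      tibble::tibble(entity = sprintf("E%02d", i),
                     term = sample(non_root, terms_each))
    }))
  })
}

# Reduced synthetic study reused across test files (cheap enough to be the
# default for anything that needs a full pipeline).
small_study <- function(seed = 7L) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressMessages(sim_study(sim_params(
      n_terms = 60L, root_branching = 5L, n_genes = 20L, n_diseases = 12L,
      n_pathogenic = 40L, n_benign = 30L, n_background_pool = 300L,
      n_background_variants = 80L, seed = seed)))
  }
  .fixture_cache[[key]]
}

# ---- oracles ---------------------------------------------------------------

# Ancestor closure by exhaustive path-walking DFS (re-derives reachability
# without the package's precomputed closures).
oracle_ancestors <- function(term, onto) {
  seen <- character(0)
  walk <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    for (p in onto$parents[[t]]) walk(p)
  }
  walk(term)
  sort(seen)
}

# IC by independent per-entity closure recount.
oracle_ic <- function(corpus, onto) {
  closures <- lapply(split(corpus$term, corpus$entity), function(ts) {
    unique(unlist(lapply(unique(ts), oracle_ancestors, onto = onto)))
  })
  N <- length(closures)
  vapply(onto$terms, function(t) {
    n_t <- sum(vapply(closures, function(cl) t %in% cl, TRUE))
    if (n_t == 0L) NA_real_ else -log(n_t / N)
  }, double(1))
}

# Pairwise similarity by enumerating common ancestors.
oracle_pairwise <- function(t1, t2, onto, ic_vec, max_ic) {
  common <- intersect(oracle_ancestors(t1, onto), oracle_ancestors(t2, onto))
  vals <- ic_vec[common]
  vals[is.na(vals)] <- 0
  max(vals) / max_ic
}

# BMA profile similarity by exhaustive double loop.
oracle_profile <- function(p, q, onto, ic_vec, max_ic) {
  m <- outer(p, q, Vectorize(function(a, b)
    oracle_pairwise(a, b, onto, ic_vec, max_ic)))
  0.5 * (mean(apply(m, 1, max)) + mean(apply(m, 2, max)))
}

# ROC AUC via the Mann-Whitney rank-sum identity with midranks.
oracle_auc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

write_tsv_plain <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names, na = "")
  path
}
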