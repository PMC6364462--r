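#' Build a phenotype ontology from an is-a edge list
#'
#' Constructs a validated phenotype ontology (a rooted is-a DAG such as HPO or
#' MP) from child/parent term pairs. The ontology must have exactly one root,
#' no cycles, and no edge pointing at an undeclared term.
#'
#' @param edges A data frame with columns `child` and `parent` (opaque term
#'   IDs, e.g. `HP:0000118`), or a path to a two-column TSV (child, parent)
#'   without a header.
#' @return A `phenotype_ontology` object: a list with `terms` (character),
#'   `parents` / `children` (named lists of character vectors), `root`
#'   (term ID) and `ancestors` (named list; each term's ancestor closure,
#'   including the term itself).
#' @examples
#' onto <- phenotype_ontology(data.frame(
#'   child = c("HP:2", "HP:3"), parent = c("HP:1", "HP:1")
#' ))
#' onto$root
#' @export
phenotype_ontology <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.table(edges, sep = "\t", header = FALSE,
                               col.names = c("child", "parent"),
                               colClasses = "character", quote = "")
  }
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges <- dplyr::distinct(tibble::as_tibble(edges)[, c("child", "parent")])
  if (any(edges$child == edges$parent)) {
    stop("self-loop edge(s): ", paste(edges$child[edges$child == edges$parent],
                                      collapse = ", "))
  }
  terms <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  parents <- lapply(parents, function(p) sort(unique(p)))
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) == 0L) stop("cycle detected: no root term")
  if (length(roots) > 1L) {
    stop("multiple roots: ", paste(roots, collapse = ", "))
  }
  children <- split(edges$child, factor(edges$parent, levels = terms))
  children <- lapply(children, function(ch) sort(unique(ch)))

  onto <- structure(
    list(terms = terms, parents = parents, children = children, root = roots),
    class = "phenotype_ontology"
  )
  onto$ancestors <- .ancestor_closures(onto)
  onto
}

# Closure (term + all is-a ancestors) for every term; Kahn order doubles as
# the cycle check.
.ancestor_closures <- function(onto) {
  terms <- onto$terms
  indeg <- lengths(onto$parents)
  order <- character(0)
  queue <- terms[indeg == 0L]
  indeg <- stats::setNames(indeg, terms)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in onto$children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(terms)) {
    stop("cycle detected among terms: ",
         paste(setdiff(terms, order), collapse = ", "))
  }
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in order) {
    anc[[t]] <- sort(unique(c(t, unlist(anc[onto$parents[[t]]], use.names = FALSE))))
  }
  anc
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat("<phenotype_ontology> ", length(x$terms), " terms, root ", x$root,
      ", ", length(x$children[[x$root]]), " top-level categories\n", sep = "")
  invisible(x)
}

.check_terms <- function(terms, onto) {
  bad <- setdiff(terms, onto$terms)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Information content of ontology terms from an annotation corpus
#'
#' Computes the information content IC(t) = -ln(n_t / N), where N is the
#' number of annotated entities (genes and/or diseases) in the corpus and
#' n_t the number whose annotation ancestor-closure contains t. The root is
#' always contained in every closure, so IC(root) = 0, and IC is monotone
#' non-decreasing from root to leaves. Terms that no entity's closure touches
#' have undefined IC: they are kept as `NA` and flagged, and downstream
#' similarity treats them as carrying zero information.
#'
#' @param corpus A data frame with columns `entity` and `term`, one row per
#'   annotation (an entity may have many terms).
#' @param onto A [phenotype_ontology()].
#' @return An `ic_table`: list with `ic` (named numeric, `NA` = unobserved),
#'   `max_ic` (largest finite IC, used for normalization) and `n_entities`.
#' @export
compute_ic <- function(corpus, onto) {
  stopifnot(inherits(onto, "phenotype_ontology"))
  corpus <- tibble::as_tibble(corpus)
  stopifnot(all(c("entity", "term") %in% names(corpus)))
  if (nrow(corpus) == 0L) stop("empty annotation corpus")
  .check_terms(unique(corpus$term), onto)

  closures <- lapply(split(corpus$term, corpus$entity), function(ts) {
    unique(unlist(onto$ancestors[unique(ts)], use.names = FALSE))
  })
  n_entities <- length(closures)
  counts <- table(unlist(closures, use.names = FALSE))
  ic <- stats::setNames(rep(NA_real_, length(onto$terms)), onto$terms)
  ic[names(counts)] <- -log(as.numeric(counts) / n_entities)
  max_ic <- suppressWarnings(max(ic, na.rm = TRUE))
  n_unobserved <- sum(is.na(ic))
  if (n_unobserved > 0) {
    message(n_unobserved, " term(s) unobserved in the corpus closure; ",
            "treated as zero information content in similarities")
  }
  structure(list(ic = ic, max_ic = max_ic, n_entities = n_entities),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("<ic_table> ", length(x$ic), " terms from ", x$n_entities,
      " entities; max IC ", format(x$max_ic, digits = 4), " nats\n", sep = "")
  invisible(x)
}

#' @rdname compute_ic
#' @param x An `ic_table`.
#' @param ... Unused.
#' @export
tidy.ic_table <- function(x, ...) {
  tibble::tibble(term = names(x$ic), ic = unname(x$ic),
                 observed = !is.na(x$ic))
}

.ic0 <- function(ic, terms) {
  v <- ic$ic[terms]
  v[is.na(v)] <- 0
  v
}

#' Normalized Resnik similarity between two ontology terms
#'
#' The most-informative common ancestor's IC, divided by the corpus-wide
#' maximum IC so the result lies in `[0, 1]`. Symmetric;
#' `term_similarity(t, t)` is `ic(t)/max_ic` and any term's similarity to the
#' root is 0.
#'
#' @param t1,t2 Term IDs.
#' @param onto A [phenotype_ontology()].
#' @param ic An `ic_table` from [compute_ic()].
#' @return A number in `[0, 1]`.
#' @export
term_similarity <- function(t1, t2, onto, ic) {
  .check_terms(c(t1, t2), onto)
  stopifnot(ic$max_ic > 0)
  common <- intersect(onto$ancestors[[t1]], onto$ancestors[[t2]])
  max(.ic0(ic, common)) / ic$max_ic
}

# Pairwise similarity matrix between two term vectors (rows = p, cols = q).
.sim_matrix <- function(p, q, onto, ic) {
  m <- matrix(0, length(p), length(q), dimnames = list(p, q))
  for (i in seq_along(p)) {
    anc_p <- onto$ancestors[[p[i]]]
    for (j in seq_along(q)) {
      common <- intersect(anc_p, onto$ancestors[[q[j]]])
      m[i, j] <- max(.ic0(ic, common))
    }
  }
  m / ic$max_ic
}

#' Best-match-average similarity between two phenotype profiles
#'
#' Symmetric best-match-average (BMA) over normalized Resnik pairwise
#' similarities: each term of one profile is matched to its best counterpart
#' in the other, the per-profile means are averaged. This is the standard
#' measure for comparing a patient's phenotype profile to a gene's or
#' disease's annotation profile.
#'
#' @param p,q Non-empty character vectors of term IDs.
#' @inheritParams term_similarity
#' @return A number in `[0, 1]`.
#' @export
profile_similarity <- function(p, q, onto, ic) {
  if (length(p) == 0L || length(q) == 0L) stop("empty phenotype profile")
  p <- unique(p); q <- unique(q)
  .check_terms(c(p, q), onto)
  m <- .sim_matrix(p, q, onto, ic)
  0.5 * (mean(apply(m, 1, max)) + mean(apply(m, 2, max)))
}

#' High-level phenotypic characterization of a profile
#'
#' One binary indicator per top-level phenotype category (the root's direct
#' children, in lexicographic term-ID order): 1 if any term of the profile
#' descends from (or is) that category.
#'
#' @param p Non-empty character vector of term IDs.
#' @param onto A [phenotype_ontology()].
#' @return A named 0/1 integer vector over the root's direct children.
#' @export
high_level_profile <- function(p, onto) {
  if (length(p) == 0L) stop("empty phenotype profile")
  .check_terms(p, onto)
  cats <- onto$children[[onto$root]]  # already sorted
  closure <- unique(unlist(onto$ancestors[unique(p)], use.names = FALSE))
  stats::setNames(as.integer(cats %in% closure), cats)
}
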