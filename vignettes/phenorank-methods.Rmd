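---
title: "Methods: phenotype-driven variant prioritization in phenorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-driven variant prioritization in phenorank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorank)
```

## The problem

A rare-disease exome carries tens of thousands of variants, and even after
frequency filtering many are predicted damaging. Pathogenicity alone is not
enough: healthy individuals carry pathogenic variants, so the clinically
useful question is which variant is *causative* — both damaging and in a
gene whose phenotypes match the patient. phenorank scores each variant in a
patient's VCF by combining per-variant pathogenicity scores (CADD, DANN and
GWAVA-style lookup tables) with the semantic similarity between the
patient's phenotype profile and the variant's gene profile, plus zygosity
and the disease's mode of inheritance, feeding everything into a small
feed-forward neural network trained on curated pathogenic/benign variant
knowledge.

## Phenotype similarity

The ontology is an is-a DAG of phenotype terms (HPO/MP-style identifiers;
gene profiles from human and model organisms are assumed pre-mapped into
one ontology — no cross-species bridging is performed). Term specificity is
measured by information content over an annotation corpus,

$$\mathrm{IC}(t) = -\ln \frac{n_t}{N},$$

where $N$ is the number of annotated entities and $n_t$ counts entities
whose annotation ancestor-closure contains $t$. The root is in every
closure, so $\mathrm{IC}(\mathrm{root}) = 0$, and IC is monotone
non-decreasing from root to leaf. Terms outside every closure have no
defined frequency; they are kept as `NA`, reported once per run, and
treated as carrying zero information when they appear as candidate common
ancestors. This is deliberate: inventing a large sentinel IC for unseen
terms would let two profiles look maximally similar through a term the
corpus knows nothing about.

Pairwise similarity is normalized Resnik — the maximum IC over common
ancestors, divided by the corpus-wide maximum IC so values lie in
$[0, 1]$ — and profiles are compared by symmetric best-match-average:

$$\mathrm{sim}(P, Q) = \frac{1}{2}\left[
  \frac{1}{|P|}\sum_{p \in P} \max_{q \in Q} s(p, q) +
  \frac{1}{|Q|}\sum_{q \in Q} \max_{p \in P} s(p, q)\right].$$

Resnik + BMA is the standard pairing for phenotype-profile comparison and,
unlike path-based measures, is directly checkable against a brute-force
enumeration oracle, which the test suite does to $10^{-12}$ on small random
DAGs. The measure sits behind the `profile_similarity()` contract and can
be swapped without touching the rest of the pipeline.

The high-level characterization of a profile is one indicator per direct
child of the root (sorted by term ID so the feature layout is
reproducible): 1 when any profile term descends from that category.

## Training-set construction

From a ClinVar-like table, records flagged with conflicting interpretation,
mapped to more than one gene, or missing an allele are excluded (and
counted). Each pathogenic variant with $n$ associated diseases yields $n$
variant–disease pairs. Zygosity then follows the disease's mode of
inheritance: recessive diseases produce a single homozygous triple; every
other mode (dominant, X-linked, unknown) produces both a homozygous and a
heterozygous triple. Benign variants carry no disease, so each contributes
a homozygous and a heterozygous instance to the candidate negative pool.

For every positive triple $(V, D, Z)$ one negative is drawn, choosing with
equal probability between two strategies:

* **benign, same gene** — a benign variant drawn uniformly from $V$'s gene,
  with uniform zygosity. The positive's disease $D$ is retained as the
  phenotype context: a benign variant has no disease of its own, yet the
  feature vector needs a profile, and keeping $D$ preserves the point of
  the design — the negative matches the positive on phenotype similarity
  (same gene) and must be separated on pathogenicity alone.
* **wrong disease** — $(V, D', Z)$ with $D'$ drawn uniformly from the
  profiled diseases excluding *every* disease annotated to $V$, not only
  $D$; otherwise a multi-disease variant could generate a "negative" that
  is literally one of its positives.

When a gene holds no benign variant the draw falls back to the
wrong-disease strategy and the fallback is counted, so the realized
strategy ratio is always reportable. The resulting set is exactly balanced
and bit-reproducible for a given seed. Intergenic variants are assigned to
their nearest gene (interval distance, ties to the smaller gene ID) before
sampling.

## Feature encoding

The vector layout is: four continuous features (CADD, DANN, GWAVA,
phenotype similarity), one missing flag per continuous feature, a zygosity
bit (HET = 0, HOM = 1), a four-way one-hot mode of inheritance, and one
high-level indicator per top-level ontology category. The dimension is
schema-derived (13 + number of root children) and frozen into a trained
model. Scores are used raw — DANN/GWAVA already live in $[0,1]$ and CADD's
phred scale passes through — since the classifier sees consistent scales at
train and predict time. Missing continuous values are mean-imputed from the
training instances' observed values, with the flag set to 1; a feature
never observed in training imputes to 0 with a warning. The similarity
feature compares the instance's phenotype profile (the disease's profile in
training, the patient's at prediction) with the variant's gene profile and
is itself imputed-and-flagged when the gene has no annotation, so variants
in novel genes are scored rather than dropped.

Score lookups are cache-first: an in-memory pre-annotated table is
consulted for every variant and an on-disk fallback table only on misses
(loaded lazily and indexed by variant key on first use); a full miss is
data (all-missing triple), never an error.

## The classifier

A feed-forward network with rectified-linear hidden layers and a single
logistic output, trained with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) on binary cross-entropy. The default architecture is
67–32–256 hidden units, learning rate 0.001, batch size 2500, 100 epochs.
Dropout (default rate 0.5) is applied between the last hidden layer and the
output, during training only, with inverted scaling. The per-epoch
validation loss is computed on a 20% holdout drawn over *disease groups*,
not rows, so no disease straddles the split — the same disjointness rule
the cross-validation uses. Benign-variant instances, which have no disease,
are grouped per variant for this purpose. The implementation is vectorized
base-R matrix algebra; its backpropagation is verified against
finite-difference gradients in the test suite, and training is
deterministic for a given seed under single-threaded BLAS.

Hyperparameter search samples from the reference space — 2–4 hidden
layers, widths in {32, 64, 67, 128, 134, 201, 256, 512}, batch size in
{2500, 5000, 10000, 15000, 20000} — and keeps the configuration with the
best validation loss. The default sampler is seeded uniform random search;
the sampler is a pluggable argument, so a model-based sampler can be
substituted without changing the space.

## Prioritization and evaluation

`prioritize()` reads the patient VCF (one record per ALT allele carried;
`0/0` and `./.` genotypes dropped; phased separators treated as unphased),
optionally removes variants with MAF strictly above 1% (variants absent
from the frequency table count as rare), encodes every survivor with the
patient's profile, its own zygosity and the patient's global mode of
inheritance, and ranks by descending score with a coordinate tie-break so
output is byte-stable. MoI is a feature, not a filter, by default; an
optional `moi_filter` drops heterozygotes under a recessive model for users
who want the harder constraint.

Spike-in evaluation plants one positive triple into a MAF-filtered
background variant set; the causative zygosity follows the disease's mode
of inheritance (recessive ⇒ homozygous) and the patient's phenotypes are
the disease profile. Reported metrics are top-1 and top-10 recovery and
ROC AUC / AUPR computed on the (score, is-causative) pairs pooled across
all patients' variants — pooling, rather than per-patient averaging,
matches reporting a single AUC over a cohort of cases. AUC uses the
midrank convention (a constant scorer gets exactly 0.5, verified against
the Mann–Whitney identity); AUPR is average precision with tied scores
handled as blocks. Accuracy in cross-validation uses a 0.5 threshold.

Nested cross-validation partitions diseases into five disjoint outer folds;
each outer training portion is re-partitioned into five disjoint inner
folds (25 inner splits) that drive hyperparameter selection; imputation is
refit inside every fold. The untouched outer 20% provides the reported
metrics, and the saved per-instance predictions let every metric be
recomputed independently.

## The synthetic study generator

`sim_study()` generates every input the pipeline consumes, so the package
builds and tests without any external download. Its defaults are the
conditions the test suite and acceptance run use:

| parameter | default | rationale |
|---|---|---|
| ontology | 120 terms, 8 top-level categories | deep enough for informative IC, small enough for oracle tests |
| genes / diseases | 50 / 30 | several diseases per causative gene, plus unannotated genes |
| disease profiles | 6 terms | typical size of a curated phenotype annotation |
| profile noise | 10% | causative-gene profiles imperfectly mirror disease profiles |
| pathogenic / benign variants | 120 / 100 | a few benign variants per gene for same-gene negatives |
| scores | pathogenic ~ Beta(8,2), benign ~ Beta(2,8); CADD ×100 | strongly separated classes: the planted signal is meant to be recoverable |
| score missingness | 5% per score | exercises imputation and flags |
| background | 200 variants/patient from a 1000-variant pool | desk-scale stand-in for a filtered exome |
| MoI mix | 35% recessive, 35% dominant, 10% X-linked, 20% unknown | a plausible rare-disease census |

Background-pool allele frequencies are a mixture: 30% rare (MAF < 1%) and
70% common. Common population variants are exactly what the 1% MAF filter
exists to remove, so what matters downstream is the post-filter rare
remainder (~60 of 200 sampled variants); an all-common pool would leave
patients nearly empty and make rank recovery vacuous. Pathogenic variants
are always rare.

What the generator does *not* emulate: realistic allele-frequency spectra,
linkage, sequence context, multi-chromosome structure, or ontologies at
HPO scale. Passing the synthetic acceptance thresholds (top-1 fraction
≥ 0.7, pooled ROC AUC ≥ 0.9 with training diseases disjoint from patient
diseases) therefore shows the pipeline recovers a strongly planted signal
end to end — it says nothing quantitative about performance on real
clinical exomes.

## Numerical choices and degenerate inputs

* Predicted probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ inside
  the loss only; predictions themselves are raw logistic outputs.
* Weights: He initialization for ReLU layers, Glorot for the output.
* Ties: equal ranks break by (chrom, pos, ref, alt); equal nearest-gene
  distances by gene ID; root children are ordered lexicographically.
* Degenerate inputs fail loudly — empty corpus, empty profile, single-class
  labels, cycle or multi-root edge lists, unknown terms or MoI categories —
  while missing scores and unannotated genes are ordinary data.
* Problem sizes in the test suite (60-term ontologies, ~40 pathogenic
  variants, 10–50 patients, reduced epochs) were chosen as the smallest
  sizes at which every property is still meaningfully exercised.

## Limitations

The similarity measure underlying the original system's phenotype score is
not published in detail; normalized Resnik + BMA is this package's choice
and other measures may rank differently. The 67-feature layout of the
original tool is not reproduced verbatim — the dimension here follows the
configured ontology. Trio/pedigree reasoning, structural variants, full
VCF INFO semantics and score computation itself are out of scope; scores
are consumed as lookup tables.
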