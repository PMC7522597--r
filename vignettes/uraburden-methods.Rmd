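---
title: "Ultra-rare variant burden testing in case-only cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-rare variant burden testing in case-only cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uraburden)
```

## The problem

Rare-variant burden tests for sequencing studies usually rely either on
parental genomes (to call variants *de novo*) or on matched controls (for
case-control collapsing tests). Many cohorts — particularly for rare and
under-funded conditions — have neither. `uraburden` implements a burden
framework for such *case-only* cohorts. It rests on one observation:
**ultra-rare variants** (variants seen in exactly one cohort subject and
never in large population references such as 1000 Genomes, ExAC and
gnomAD) are enriched for *de novo* and recent mutations, so the per-gene
*de novo* mutation expectation machinery can be adapted to them by a
global rescaling.

## The model

### From raw calls to carrier indicators

A filter cascade (`run_filter_cascade()`) reduces an annotated per-subject
variant table to per-gene, per-subject carrier indicators, in a fixed
order:

1. **Ultra-rare selection** — keep variants with in-cohort allele count 1
   and no frequency in any population reference (a missing annotation or a
   literal 0 both count as "absent").
2. **Low-quality filter** — remove calls with depth $DP \le 10$;
   heterozygous calls with alternate-read fraction $< 0.3$ or $GQ < 99$;
   homozygous calls with fraction $< 0.8$ or $GQ \le 25$. The heterozygous
   genotype-quality rule deserves a note: a removal rule of
   "$GQ \le 99$" is unsatisfiable under the common caller convention that
   caps GQ at 99, so the implemented (and configurable) rule removes
   het calls *below* 99, i.e. keeps only capped-quality calls.
3. **Frameshift-indel collapse** (truncating class only) — when one
   subject carries several frameshift indels in one gene, they are all
   removed if their cumulative signed size (insertions $+$, deletions $-$)
   is a multiple of 3, because the shifts cancel to an in-frame net
   effect; otherwise one deterministic representative (smallest
   chromosome, position) is kept. The sign convention is configurable
   (`size_mode = "absolute"`) because a cumulative-size rule can be read
   either way; the signed reading is the default since $+4$ and $-1$
   genuinely restore the reading frame.
4. **Principal-transcript filter** — only variants affecting the gene's
   principal isoform (APPRIS-style map) are retained.
5. **Splice-insertion rescue** (truncating only) — an insertion annotated
   as hitting a canonical splice dinucleotide is demoted to
   non-truncating if, after applying the insertion to the local reference
   context, a canonical GT (donor) / AG (acceptor) on the annotated
   strand is still present at exactly the annotated offset. Records
   without annotation are conservatively retained as truncating. The
   reconstruction window is the supplied context (typically ±10 bp).
6. **Per-gene per-subject collapse** — at most one variant of a class
   counts per gene per subject, so the per-gene count
   $N_{\mathrm{Obs},g}$ equals the number of distinct carrier subjects.

Each filter only removes (or reclassifies) records, so stage counts are
non-increasing and each stage is idempotent — both are tested properties.

### Rescaling mutation probabilities

Let $p_g$ be the per-gene *de novo* mutation probability of the class
(truncating or missense) for each gene in the universe $G$ of genes with
a defined probability, $N_S$ the number of subjects, and
$N_{\mathrm{Obs}}$ the total observed ultra-rare variant count of the
class. The global scaling factor is

$$ SF = \frac{N_{\mathrm{Obs}}}{N_S \sum_{g \in G} p_g}, \qquad
   P_{\mathrm{success},g} = p_g \, SF, $$

so that the expected and observed totals match exactly:
$N_S \sum_g P_{\mathrm{success},g} = N_{\mathrm{Obs}}$ — a conservation
identity asserted to $10^{-9}$ relative tolerance in the tests. Because
$SF$ absorbs any global factor, the probabilities are used exactly as
supplied (no diploid $\times 2$).

When the analysis is restricted to **constrained genes** (observed /
expected ratio strictly below 0.35 for truncating, 0.75 for missense —
thresholds chosen to admit moderately constrained genes given incomplete
penetrance), restriction happens *first* and $N_{\mathrm{Obs}}$ is also
restricted to variants in constrained genes, so the conservation identity
holds within the analysis universe. Whether the observed total should
also be restricted is genuinely ambiguous in a case-only design; we chose
the reading that preserves conservation, and expose
`n_obs = "all"` for the alternative. Genes missing from the constraint
table are excluded from the constrained universe.

### Gene burden test

Each gene is tested one-sided against its rescaled expectation:
$p_g = P(X \ge N_{\mathrm{Obs},g})$, $X \sim
\mathrm{Binomial}(N_S, P_{\mathrm{success},g})$; zero-carrier genes get
$p = 1$. BH-FDR is computed per class over the full defined-probability
universe (zero-carrier genes entering at $p = 1$; an `unobserved = "omit"`
mode restricts to observed genes, which is indistinguishable at top ranks
but changes the universe size). The Bonferroni correction is joint across
the truncating and missense universes,
$\min(1, p \,(m_T + m_M))$.

### Gene-set burden, de-correlation and resampling FDR

Gene-sets (GMT format; GO/pathways or mouse-phenotype resources) are
intersected with the probability universe and kept when they have more
than 5 and fewer than 100 members (small sets lack power; large sets are
overly general, accumulate heterogeneous probabilities, and can be
dragged to significance by one extreme gene). In constrained analyses,
sets with fewer than two constrained genes are dropped. The set test
pools probabilities, $P_{\mathrm{success}} = \sum_{g \in \mathrm{set}}
P_{\mathrm{success},g}$, and caps observations per subject,
$N_{\mathrm{success}} = \sum_s \min\!\big(\sum_{g \in \mathrm{set}}
N_{\mathrm{Obs},g,s},\, 1\big)$, before the same one-sided binomial test.

Overlapping gene-sets are highly correlated, which breaks naive multiple
testing. `greedy_stepdown_select()` de-correlates them: repeatedly select
the most significant remaining set, absorb every remaining set whose
**Jaccard similarity exceeds 0.5**, and continue with the rest.
Similarity is computed on *variant sets* — the (gene, subject) carrier
entries of member genes — rather than member gene lists, so two sets are
correlated only insofar as they share observed signal; this is
data-dependent by design. Ties in the p-value sort are broken
lexicographically by set name for determinism.

The FDR of the selected representatives is estimated by resampling: the
observed total is redistributed over genes,
$\mathrm{Multinomial}(N_{\mathrm{Obs}}, P_{\mathrm{success}} /
\sum P_{\mathrm{success}})$, subjects assigned uniformly at random
(duplicate draws within a gene-subject pair are retained as counts and
only capped by the per-set rule), the set tests and the greedy selection
are re-run in full, and for each representative threshold $p$

$$ \mathrm{FDR}_p = \frac{\mathrm{mean}_{i}\,
   N^{\mathrm{perm}_i}_{gs}(p)}{N^{\mathrm{real}}_{gs}(p)}, $$

over 1000 iterations by default, clamped to $[0,1]$ and monotonized
(cumulative minimum from the least to the most significant threshold).
Re-running the greedy selection inside each permutation — rather than
freezing the real-data selection — is the default because the selection
step is part of the statistic; `perm_selection = "fixed"` preserves the
other reading.

### Exact-test enrichment machinery

Three analyses use 2×2 exact tests (`fisher_exact()`, backed by the
standard hypergeometric test with the conditional maximum-likelihood odds
ratio, which can be $+\infty$ when the appropriate cell is empty; the
sample odds ratio $ad/bc$ is reported alongside):

* **Reference-singleton comparison**: cohort ultra-rare variants in a
  gene vs all other genes, against reference singleton counts in the
  same split; two-sided, restricted to genes with at least one reference
  truncating *and* one missense singleton (to avoid genes masked out of
  the reference), BH-FDR across tested genes.
* **Protein-region enrichment**: cohort vs reference variant positions
  inside vs outside a named region (e.g. a receptor's extracellular
  domain), one-sided.
* **Residue-class enrichment**: the same construction for variants
  altering a named residue class (e.g. disulfide-bond cysteines),
  one-sided.

The two-sided p-value uses the minimum-likelihood rule (all tables with
probability no larger than the observed one), which is what the standard
R implementation computes; mid-p and doubling variants exist but are not
offered.

### Power

Prospective power uses the one-sample proportion test with the arcsine
effect size $h = 2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_0}$:
$\mathrm{power} = \Phi(h\sqrt{n} - z_{1-\alpha})$, with
`required_n()` inverting it and verifying minimality at the returned
integer. $p_0$ is the gene's rescaled success probability, $p_1$ the
observed carrier proportion, and $\alpha$ is typically $0.05$ divided by
the joint Bonferroni universe size. Only the one-sided greater direction
is offered, matching the burden alternative. The normal approximation is
checked against exact-binomial Monte Carlo (within 0.02 absolute for
$n \ge 200$ on the tested grid).

## The synthetic-data generator

`simulate_cohort()` exists so that every stage can be exercised and
calibrated without access to protected genomes. Its defaults are the
study conditions the package is calibrated under: **231 subjects, 642
clean ultra-rare truncating and 3,293 clean ultra-rare missense
variants**, drawn multinomially over an **18,500-gene** universe with
per-gene probabilities log-uniform on $[10^{-7}, 10^{-4}]$ — the
approximate size and dynamic range of published per-gene mutation
probability tables. Within a gene, carriers are assigned to distinct
subjects so clean totals survive the per-gene per-subject collapse
exactly. On top of the null the generator can plant:

* **burden injections** — $k$ extra clean variants in distinct carriers
  of a chosen gene (the strongest published configuration, 7 carriers of
  231, is the recovery benchmark);
* **QC violations** — records violating exactly one filter each (low
  depth, low alternate fraction, reference frequency hits, non-principal
  transcripts, in-cohort recurrence, frameshift-indel pairs with
  cumulative size 3).

Truth labels live in a side channel (`$truth`), never in the variant
table, so the pipeline cannot peek. What the generator does *not*
emulate: sequence-context realism (positions and alleles are schematic),
linkage and relatedness, batch or caller artifacts, and genuine
annotation noise. Passing calibration tests therefore demonstrate the
statistical machinery is correct under its stated null — not that real
call sets are free of the artifacts the filters exist to remove.

## Numerical choices and degenerate inputs

* Binomial tails come from the regularized incomplete beta
  (`pbinom(..., lower.tail = FALSE)`), cross-checked against direct pmf
  summation at $10^{-12}$ relative tolerance on $n \le 50$ grids.
* $P_{\mathrm{success}}$ above 1 (pathological inputs only) is clamped
  with a warning naming the gene; pooled set probabilities likewise.
* An all-zero 2×2 table, an empty constrained universe, an empty
  gene-set after universe intersection, a zero observed total and an
  empty cluster selection are errors, not silent results.
* Resampling and simulation accept explicit integer seeds; identical
  seeds reproduce results bit-for-bit, and pipeline runs with identical
  config and seed write byte-identical tables.

## Problem sizes used in the checks

The shipped tests calibrate at the full study scale where it matters —
200 null cohorts and 200 injection replicates at 231 subjects over the
18,500-gene universe, and 1000-iteration resampling FDRs — and at
reduced scale (a few hundred to a couple of thousand genes) for
structural properties, where size adds nothing. The acceptance script
re-runs the study-scale checks with 100 replicates per property.

## Known limitations

* The cascade assumes effects are already annotated and mapped onto the
  controlled vocabulary; it does not re-annotate, lift over, phase, or
  handle compound heterozygotes or sex-chromosome ploidy.
* Structural variants are out of scope: there is no accepted
  probabilistic expectation model for their burden.
* Constraint-based restriction treats constraint as a gene-level
  property; regional missense constraint is not modeled.
* The multinomial resampling null holds totals fixed and treats genes
  independently; it does not model subject-level covariates.
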