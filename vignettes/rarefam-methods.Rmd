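---
title: "Models and methods behind rarefam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rarefam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarefam)
```

`rarefam` implements a two-stage familial rare-variant analysis: private
segregating variant discovery in multiplex pedigrees, followed by gene-based
case-control burden testing, sibling transmission-disequilibrium testing and
gene-set overrepresentation analysis. This vignette explains the models,
the parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Variant-of-interest prioritization

The discovery stage applies three independent predicates to each annotated
variant, per family:

1. **Functional class.** Keep protein-altering classes — nonsynonymous,
   splice, stop-gain, stop-loss. Synonymous, UTR, non-splice intronic and
   intergenic variants are removed. The class comes from the annotation
   table; by convention the upstream annotator labels intronic variants
   within ±2 bp of an exon boundary as `splice` (the `splice_window` field
   of `filter_config()` documents that expectation but is not itself a
   filter).
2. **Privateness.** Keep variants absent from all three interrogated
   population resources (dbSNP, 1000 Genomes European, ESP European
   American). The presence flags are tri-state: `NA` means "not looked
   up". Under the default `treat_absent` policy an `NA` counts as absent,
   because an allele a database has never seen cannot be marked present;
   the `fail_variant` policy is available for strict audits.
3. **Segregation.** Keep variants carried (allele count ≥ 1) by *every*
   affected member of the family. Carrier status rather than genotype is
   required because a dominant-acting rare allele may appear het or hom.
   A missing genotype in an affected member rejects the variant by default
   (`fail_variant`): dropout should not create false VOIs. The
   `ignore_individual` policy scores the remaining affecteds instead.

Because the three predicates are independent, their composition is
monotone and order-invariant; the test suite asserts both. Deleteriousness
scores (SIFT, PolyPhen-2, GERP, CADD) are carried through and reported but
never filtered on — in the study design they inform downstream manual gene
selection, which is judgement, not computation.

Genotype tables are *sparse* long tibbles: a (sample, variant) pair with no
row means zero copies, an `NA` row means a missing call, and a sample absent
from the table entirely means "never genotyped" and is an error where the
analysis requires that sample. This keeps 2000-sample cohorts cheap while
preserving the distinction the missing-data policies need.

## Gene-based burden association

For each gene, qualifying variants are those both **rare** — 1000 Genomes
European allele frequency strictly below 0.01, with a missing frequency
treated as 0 (unobserved) — and protein-altering. The default unit of
counting is the **carrier**: an individual with at least one qualifying
allele in the gene counts once, however many qualifying variants they hold.
Carrier counting is the default because the sample cross-product ratio of
the carrier table reproduces the reference results this package mirrors
better than allele counting; allele counting (2 chromosomes per individual)
is available via `count_mode = "allele"`. Missing genotypes count as
non-carriers in burden denominators — the panel samples were sequenced, so
sporadic missingness should deflate, not inflate, evidence — unlike the
conservative VOI-stage policy; both choices are deliberate and documented.

The test is the one-sided Fisher exact test: conditional on both margins,
the case-carrier count is hypergeometric and the p-value is the upper tail
$P(X \ge a)$, the direction "greater burden in cases" fixed by design. The
odds-ratio point estimate is the conditional MLE — the $\psi$ solving
$E_\psi[X] = a$ under the noncentral hypergeometric likelihood
$P_\psi(x) \propto \binom{n_1}{x}\binom{n_2}{K-x}\psi^x$ — computed by
bracketed root-finding on $\psi$ (tolerance 1e−10). Tables whose observed
cell sits at the support boundary give 0 or $\infty$; a table with no
carriers anywhere carries no information about the odds ratio and returns
`NA`.

Two confidence intervals are offered:

* `"woolf"` (default): the asymptotic logit interval
  $\exp(\log\widehat{OR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$ with a
  Haldane 0.5 correction for zero cells. This is the convention of the
  standard association toolkits, and it is the convention consistent with
  the reference intervals this package reproduces — which is why it is the
  default rather than the exact interval.
* `"exact"`: inversion of the noncentral hypergeometric tails at 0.025 per
  side, the `fisher.test` convention, for users who want guaranteed
  coverage at the cost of width (the suite verifies ≥95% empirical
  coverage).

A Bonferroni column over the genes scanned is appended as a clearly
labelled extension; raw p is the primary quantity. When the comparison
group is a public database that publishes only an allele frequency,
`compare_to_reference_af()` reconstructs the reference allele count as
`round(af × n_alleles)` — the allele number must be supplied, not guessed —
and applies the same machinery on allele counts.

## Transmission-disequilibrium burden

The TDT stage uses the sibling-sharing formulation: for each proband
carrying a qualifying variant, every *affected full sibling* genotyped at
that variant contributes one event, transmitted if the sibling carries the
allele. Parental phase is never needed. Under Mendelian segregation a rare
heterozygous allele reaches a sibling with probability ½, so with $T$
transmitted and $U$ untransmitted events,

$$\chi^2 = \frac{(\max(|T-U|-1,\,0))^2}{T+U}$$

on 1 df, with the Yates continuity correction truncated at zero so that
$|T-U| \le 1$ yields exactly 0 rather than a spurious positive statistic.
Events are counted per sibling-variant pair; with one qualifying variant
per family (the typical situation) this reduces to per-sibling counting.
Because the χ²(1) tail is an approximation for small event counts, the
exact two-sided binomial p at ½ is reported alongside. Siblings with a
missing call contribute no event rather than a false non-transmission.

## Overrepresentation analysis

`run_enrichment()` is a hypergeometric ORA: with a universe of $N$ genes,
a set of effective size $C = |S \cap U|$, an input list of $k$ universe
genes and overlap $O$, it reports $E = Ck/N$, the enrichment ratio
$R = O/E$, and $p = P(X \ge O)$. Sets are first bounded to effective sizes
in [500, 1500] — broad-category sizes matching the scale of the expected
polygenic gene count — and BH FDR is computed across all tested sets (a
per-branch stratification would also be defensible; across-all is the
default because the set collection supplied to the function is the unit of
analysis). Symbols are matched upper-cased; unmatched input genes are
excluded from $k$ and reported.

The default universe is the union of all genes in the supplied GMT. This
is an explicit, reproducible choice — but every p-value depends on it, so
analyses meant to be compared should pass the same explicit universe. The
enrichment *ratio* $R$ is far less sensitive to the universe than $p$,
which is why the worked examples anchor on $R$.

## The synthetic data generator

The generator's defaults describe the emulated study design and are fixed:
26 families ascertained for an affected first-cousin pair (three
generations: shared grandparental couple, two sibling parents with
married-in founders, one affected child each); a 13-gene panel resequenced
in 1004 cases and 1127 controls with one risk gene whose heterozygous
carriers arise at 18/1004 in cases and 2/1127 in controls, spread over 8
distinct variants; 37 sibling transmission events at probability ½ under
the null. Background genes carry 20 rare protein-altering variants each at
allele frequency 0.002 — about the per-gene variant yield of a targeted
panel of this size, comfortably under the 0.01 rarity threshold — at
identical rates in both arms, plus one common and one synonymous decoy per
gene so the filters have something to reject.

Family genotypes are generated by *gene dropping*: each parental allele is
transmitted with probability count/2, independently across meioses, which
is exact Mendelian transmission for a bi-allelic locus. Planted VOIs are
produced by conditioning a drop from a founder ancestral to all affecteds
on full segregation (rejection sampling), so a planted variant qualifies by
construction and ground truth is recorded at generation time. The
analytically known first-cousin co-inheritance probability of 1/16 for an
allele heterozygous in one shared grandparent is verified by Monte Carlo in
the suite.

The case-control simulation is deliberately *marginal* — independent
Bernoulli carrier status per individual — because the burden stage uses one
unrelated case per family; pedigree realism lives in the family stage. All
planted cohort variants are heterozygous SNVs, matching the observation
tables this emulates. What the generator does **not** emulate: linkage
disequilibrium and haplotype structure, site-specific call-rate
variation, population stratification, genotyping error, and indel
normalization issues. Consequently, passing tests demonstrate the
correctness and calibration of the *statistics and filters*, not
robustness to those real-data artefacts; in particular the burden test's
clean type-I error here says nothing about confounding by ancestry, which
the method itself does not correct for.

A master seed drives deterministic per-stage sub-streams, so each stage can
be re-run independently and `run_pipeline()` output is byte-identical
across runs with the same seed.

## Numerical choices and degenerate inputs

* Hypergeometric tails use `stats::phyper`; the test suite pins them to
  brute-force enumeration from binomial coefficients on all tables with
  margins ≤ 8 (tolerance 1e−12).
* Root-finding for $\psi$ expands a geometric bracket until the sign
  changes, then uses `uniroot` at tolerance 1e−10; the equations are
  monotone in $\psi$.
* An all-zero table gives p = 1; `T + U = 0` gives an `NA` χ²; an empty
  p-value vector adjusts to an empty vector; an empty family cohort yields
  an empty VOI result, while an empty *input gene list* for enrichment is
  an error (it is always a caller mistake).
* Ties in the burden ranking are broken alphabetically for reproducible
  output; multi-allelic VCF records are split into independent bi-allelic
  variants *before* any filtering; coordinates are 1-based end to end; no
  indel left-normalization is performed (a documented requirement on the
  annotation input).
* Problem sizes used by the simulation-based tests — 200 replicates for
  ranking properties, 1000 for burden type-I error, 2000 for TDT size,
  100000 gene drops for the 1/16 check — were chosen to keep Monte-Carlo
  standard errors small relative to the tolerances being asserted.

## Known limitations

* Hemizygous chromosome-X genotypes are taken as given and flagged, not
  re-modelled; the carrier definition (count ≥ 1) is unaffected.
* The burden test conditions on margins and uses no covariates; population
  stratification must be handled upstream by design (matched ancestry), as
  in the emulated study.
* The sibling TDT formulation assumes the proband's variant is ascertained
  independently of sibling genotypes; it is not a classical trio TDT and
  should not be compared to one numerically.
* Exact reproduction of published enrichment p-values requires the
  original tool's reference universe, which is generally not recoverable;
  the enrichment ratio is the stable quantity.
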