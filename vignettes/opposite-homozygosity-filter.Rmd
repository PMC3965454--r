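---
title: "Opposite-homozygosity filtering for IBD candidate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opposite-homozygosity filtering for IBD candidate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdscreen)
```

## The screening problem

Two individuals who co-inherited a chromosomal segment from a common
ancestor (identity by descent, IBD) carry at least one identical allele at
every marker of that segment. At a biallelic SNP this forbids *opposite
homozygosity*: one individual homozygous for the major allele while the
other is homozygous for the minor allele. Exact IBD inference methods model
genotype likelihoods over all pairs of individuals and scale poorly to
cohorts of thousands; this package implements the complementary strategy of
*screening*: cheaply discard the (individual, segment) pairs that cannot
plausibly be IBD with a query individual, and hand only the small surviving
fraction to an exact method. The screen is deliberately one-sided — it is
designed never to lose true IBD segments (sensitivity first), while the
false positives it keeps are someone else's problem downstream.

## The filter

**Indexing.** For each marker $j$ of an $n \times m$ unphased genotype
panel (coded as minor-allele counts $g \in \{0, 1, 2\}$, `NA` = missing) two
sets are stored: $S^{\mathrm{maj}}_j$, the individuals with $g = 0$
(homozygous major), and $S^{\mathrm{min}}_j$, those with $g = 2$. A missing
call places an individual in neither set, so absence of evidence can never
eliminate a candidate. Building the index is one $O(nm)$ pass
(`build_index()`), and the sets are persisted as packed bitsets
(`save_index()` / `load_index()`), so a growing study can index once and
query each newly genotyped sample against the cohort.

**Query scan.** A window of `window_cm` (default $w = 3.5$ cM) slides along
the genetic map in steps of `step_cm` (default $s = 0.5$ cM). Within a
window, the *Major Filter* selects the markers where the query is observed
homozygous minor ($g_q = 2$) and counts, per indexed individual, how many of
those markers place it in $S^{\mathrm{maj}}_j$ — each such marker is an
observed opposite homozygote. The *Minor Filter* mirrors this
($g_q = 0$ vs. $S^{\mathrm{min}}_j$). An individual survives the window only
if its count is within tolerance under **both** filters; the defaults
$w = 3.5$, $s = 0.5$ suit a target IBD length of `target_cm` $= L = 4$ cM,
since any segment of length $\ge w + s$ must fully contain at least one
planned window.

**Reporting.** A segment of length $L$ that fully contains a surviving
window $[a, b)$ can end at most $L - w$ beyond either window edge, so the
window is extended by $L - w$ cM on both sides (clamped to the mapped
chromosome range) before overlapping or touching extensions are merged per
individual into candidate segments (`run_query()`). The *candidate
fraction* is the retained share of the database, defined as total candidate
cM over $n \times$ (mapped genetic length); its reciprocal is the *speedup*
an exact downstream method would enjoy.

## Tolerating genotyping errors

Every panel contains genotyping errors, and a single erroneous
opposite-homozygote would otherwise kill a true IBD segment. Let
$\varepsilon$ be the per-allele error rate: each allele of a diploid call is
read correctly with probability $1 - \varepsilon$ and flipped otherwise,
independently, giving the observation model `obs_given_true()` (e.g.
$P(o = 0 \mid t = 2) = \varepsilon^2$,
$P(o = 1 \mid t = 1) = (1-\varepsilon)^2 + \varepsilon^2$).

For a marker selected by the Major Filter, the probability $p_e$ that a
*truly IBD* indexed individual shows an observed opposite homozygote is
computed under a generative sharing model: the pair shares one allele
(minor with probability $f$, the marker's MAF), each individual's other
allele is an independent population draw at frequency $f$ (so marginal
genotypes are Hardy–Weinberg), and all four observed alleles flip
independently with probability $\varepsilon$. Then

$$p_e = P(o_x = 0 \mid o_q = 2, \text{IBD}),$$

with the Minor Filter as the mirror image ($o_q = 0$, $o_x = 2$). Because
the shared allele makes true opposite homozygosity impossible, *every*
observed opposite homozygote under this model is a false rejection. The
closed form in `false_opphom_prob()` is validated in the test suite against
a brute-force Monte-Carlo implementation of exactly this generative story;
the simulation, not the algebra, is the arbiter of correctness.

With $c$ selected markers in a window, the number of error-induced opposite
homozygotes is approximated as $\mathrm{Binomial}(c, p_e)$ — selected
markers are treated as independent, a deliberate approximation that avoids
the expensive exact computation. `solve_tolerance()` returns the smallest
$k$ with

$$P(X > k) \le p_{\mathrm{th}}, \qquad X \sim \mathrm{Binomial}(c, p_e),$$

and individuals with more than $k$ observed opposite homozygotes are
eliminated. Note the direction: a *smaller* $p_{\mathrm{th}}$ demands a
stronger guarantee against false elimination, hence a *larger* $k$ and a
more tolerant (more sensitive, less aggressive) filter; $p_{\mathrm{th}} = 1$
gives $k = 0$, the strict error-free filter. Because $c$ and the MAFs of
the selected markers change from window to window, $k$ is recomputed for
every window.

Within a window a single conservative MAF stands in for all selected
markers: the *minimum* selected MAF for the Major Filter and the *maximum*
for the Minor Filter — in each case the direction that maximises $p_e$ and
therefore $k$, erring on the side of sensitivity. Since rare minor alleles
make the Major Filter's $p_e$ explode (an observed $g_q = 2$ at a rare
allele is more likely an error than real), markers with
`maf < maf_cutoff` (default 0.05, a conventional rare-variant cutoff; the
value is exposed as a flag) are excluded from the Major Filter altogether.
They still participate fully in the Minor Filter, including its label
structure.

## Pruning redundant markers

Dense panels are locally correlated (linkage disequilibrium), so
neighbouring markers often index nearly the same homozygote sets and add
little pruning power. During indexing, markers are greedily grouped into
runs along each chromosome: a marker joins the current run iff the Jaccard
index between its set and the set of the run's *first* marker exceeds
`J_th` (default 0.9); identical sets always share a label, and two empty
sets have Jaccard index 1 by convention. Separate label sequences are kept
for the two filters. At query time (`use_pruning = TRUE`, the default) only
the first in-window selected marker of each label contributes, halving the
work on correlated panels at a modest cost in candidate size; pruning is
switchable off when maximal pruning power matters more than speed. The
aggregation rule (greedy runs against the run's first marker) is a design
choice: the criterion itself only defines when a *pair* of markers is
redundant, and a sequential single-pass rule respects the local structure
of LD while staying deterministic.

## The synthetic cohort generator

No real genotyping-array cohort ships with the package, so the simulator
(`simulate_panel()`, `simulate_queries()`) emulates one end to end:

* markers placed uniformly on a `length_cm` (default 180) cM map with MAFs
  drawn from U(`maf_min`, `maf_max`) = U(0.05, 0.5), a flat spectrum typical
  of array panels after rare-variant QC;
* $2n$ haplotypes drawn marker by marker through a latent-quantile chain
  whose carry-over probability `rho` controls first-order LD (`rho = 0`,
  the default, is linkage equilibrium; marginal frequencies match the drawn
  MAFs exactly either way);
* each query individual assembled from two *composite haplotypes* — mosaics
  of 0.2 cM blocks copied from randomly chosen panel haplotypes — so that a
  query shares plenty of short-range material with everyone but no long
  segment with anyone, breaking latent relatedness;
* one IBD segment of `ibd_cm` (default 4) cM injected by copying a random
  indexed individual's haplotype over the query's first haplotype at a
  uniform location (`inject_ibd()` records the ground truth);
* per-allele errors at rate `eps_sim` (default 0.005, matching the modeled
  $\varepsilon$) applied to the query's haplotypes (`inject_errors()`).

Everything is deterministic given the master seed; per-query child seeds
are derived by a fixed counter scheme so any query can be regenerated in
isolation.

What the generator does *not* emulate: realistic block-structured LD and
recombination hotspots (a first-order chain at best), allele-frequency
spectra skewed toward rare variants, missing genotype calls, population
structure, or errors in the *panel* (only the query is perturbed, mirroring
the evaluation protocol). Passing tests therefore demonstrate the
correctness of the machinery and the direction of the performance trends,
not absolute performance figures for any particular real cohort — on real
panels the LD structure raises marker redundancy and shifts the
sensitivity/candidate-fraction trade-off.

For close-relative screening, `simulate_cousin_queries()` injects a segment
of the expected shared length for $d$-th cousins,
$L_d = 100 / (2(d+1))$ cM (a pair of $d$-th cousins is separated by
$2(d+1)$ meioses), and derives the window size by the rule
$w = L_d - s$ rounded up to the closest half cM.

## Evaluation harness

`score_candidates()` reports *overall sensitivity* as the fraction of
markers inside injected segments that are covered by candidate segments of
the **correct** indexed partner (a candidate naming the wrong individual
does not count), and *full-coverage sensitivity* as the fraction of
segments covered entirely. The candidate fraction is averaged per query
(equivalent to pooling when all queries share one map, which they do here).
`sweep_thresholds()` scans the genome once per query and re-applies the
per-window tolerances for every $(p_{\mathrm{th}}, p'_{\mathrm{th}})$ pair
of a grid — the counts do not depend on the thresholds, which makes the
two-dimensional sweep cheap. `pareto_frontier()` extracts the
non-dominated points; with two thresholds the performance picture is a
family of ROC curves and the frontier is their left envelope.

## Numerical and boundary conventions

* Window intervals are half-open $[a, a + w)$; the last window of each
  chromosome is closed on the right so the final marker is reachable, and a
  tail window anchored at (last marker $- w$) is appended when the step grid
  does not land there — otherwise segments at the end of the scanned arm
  would be undetectable. A chromosome shorter than $w$ gets a single
  whole-span window.
* Candidate intervals that merely touch are merged along with overlapping
  ones.
* "Pass both filters" is evaluated per window (the conjunction of the two
  survivor sets), the stricter of the readings the phrase admits.
* cM positions for VCF input come from a 3-column genetic map with linear
  interpolation between map points and constant extrapolation beyond the
  ends; bp coordinates are 1-based.
* Allele coding: genotypes count minor alleles relative to *database*
  frequencies; at MAF exactly 0.5 the lexicographically smaller allele
  symbol is the major allele (a documented tie-break). Queries are mapped
  onto the index's coding (`align_query()`), and a query allele pair absent
  from the index is an error rather than a silent mismatch.
* A query's missing call at marker $j$ means $j$ is never selected; an
  indexed individual's missing call keeps it out of both sets at $j$. Both
  conventions follow the sensitivity-first contract: missing data never
  rejects a candidate.
* Monomorphic markers keep `maf = 0` and simply never select.

## Problem sizes used by the test suite

The shipped tests exercise a scaled-down protocol chosen to keep a full run
comfortably on a laptop: the main scenario uses $n = 500$ individuals,
$m = 5000$ markers on one 180 cM chromosome and 500 queries with one 4 cM
injected segment each ($\varepsilon_{\mathrm{sim}} = 0.005$), swept over a
5×5 logarithmic threshold grid $\{10^{-4}, 10^{-3}, 5\cdot10^{-3},
2\cdot10^{-2}, 10^{-1}\}^2$. Trend experiments (marker density, step size,
single-filter contributions, cousin degrees) reuse that scenario with 150 -
250 queries and a 3×3 sub-grid; oracle-equivalence checks run on panels of
up to 100 individuals and 1000 markers where a naive per-pair, per-window
recount is feasible. The acceptance script (`scripts/acceptance.R`) re-runs
the main scenario end to end at full 500-query size.

## Known limitations

* The binomial error-tolerance bound treats selected markers as
  independent; under strong LD it is conservative in an uncontrolled way.
* The filter bounds detectable segments below by $w$: segments shorter than
  $w + s$ may not contain a full window and can only be caught by luck of
  alignment.
* Candidate fraction, not wall-clock time, is the primary performance
  measure; absolute timings depend on hardware and are only asserted to
  scale linearly in database size.
* Multi-allelic sites, binary PLINK files, phasing and the downstream IBD
  inference itself are out of scope; the candidate report is the hand-off
  point.
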