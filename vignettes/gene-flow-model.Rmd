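---
title: "Pedigree-aware haplotype correction with a parent-child gene-flow HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware haplotype correction with a parent-child gene-flow HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinphase)
```

## The problem

Population phasing engines estimate haplotypes from genotypes by modelling
linkage disequilibrium and haplotype sharing, ignoring explicit family
structure. Their output is highly accurate but contains occasional *switch
errors*: positions after which the two estimated haplotypes of an individual
are swapped. When a genotyped parent is available, most of these errors are
detectable, because the child must carry one complete parental haplotype per
chromosome (up to a handful of recombination events). kinphase formalizes
this with a four-state hidden Markov model of gene flow in each parent-child
duo, and uses the fitted model to correct switch errors, call recombination
events with posterior probabilities, and flag genotyping errors. Processing
duos independently keeps the computation linear in the number of meioses and
markers, in contrast to exact pedigree HMMs over inheritance vectors, whose
state space grows exponentially with pedigree size.

## Model

For ordered parental haplotypes $P = (P^1, P^2)$ and child haplotypes
$C = (C^1, C^2)$ over $L$ sites, the hidden state $S_\ell = (i, j)$ asserts
that $P^i$ and $C^j$ are identical by descent at site $\ell$; there are four
states, labelled A-D. Three point processes move the state along the
chromosome:

* a true recombination in the parent, with per-interval probability
  $\rho_\ell$ derived from the genetic map;
* a switch error in the parental haplotypes, rate $\theta_p$ per interval;
* a switch error in the child haplotypes, rate $\theta_c$ per interval.

A parental switch error and a recombination both toggle the parent index,
and when they coincide they cancel, so the parent-index change probability
is the exclusive-or composition
$q_\ell = \theta_p(1-\rho_\ell) + \rho_\ell(1-\theta_p)$ (an additive
composition is available via `q_mode = "additive"` for sensitivity checks).
The child index toggles with probability $\theta_c$. The sixteen transition
probabilities therefore fall into four sets: T1 (no change,
$(1-q_\ell)(1-\theta_c)$), T2 (parent index, $q_\ell(1-\theta_c)$), T3
(child index, $(1-q_\ell)\theta_c$) and T4 (both, $q_\ell\theta_c$).
Emissions compare the IBD allele pair: $1-\epsilon$ on a match, $\epsilon$
on a mismatch, and 1 when either allele is missing — missing data are
treated as uninformative rather than imputed. The initial distribution is
uniform over the four states: there is no information about gene flow before
the first marker.

### Parameters

| parameter | meaning | default / origin |
|---|---|---|
| $\rho_\ell$ | recombination probability per interval | genetic map; Haldane $\rho = (1-e^{-2d})/2$, $d$ in Morgans |
| $\theta_p$ | parental switch-error rate per interval | estimated per duo, clamped to $[10^{-7}, 0.5]$ |
| $\theta_c$ | child switch-error rate per interval | estimated per duo, same clamp |
| $\epsilon$ | per-locus emission (genotyping) error | estimated per duo, same clamp |
| `male_scale` | male/female map-length ratio | 0.605 (family-based map estimate for an X-like map) |

For SNP-array spacings ($d \ll 0.01$ M) the Haldane and linear map functions
agree to first order; the choice matters only for very sparse maps. Maps are
read in cM (HapMap-style columns: position, rate in cM/Mb, cumulative cM)
and converted to Morgans internally; physical coordinates are 1-based.
Sex-specific maps are obtained by scaling the female/averaged map so the
total length matches the target; scaling preserves relative spacing exactly.

Estimation runs a single expectation/maximization update from a weak
initialization ($10^{-3}$ for all three rates): $\theta_c$ is the mean
posterior T3/T4 transition mass per interval, $\theta_p$ the mean posterior
T2/T4 mass *in excess of the map expectation* $\overline{\rho}$, and
$\epsilon$ the mean posterior emission-mismatch mass per locus. Because the
state path is almost deterministic given data, one iteration is adequate for
convergence; estimation is per duo and never pooled. $\rho_\ell$ is fixed by
the map and never re-estimated. The subtraction of $\overline{\rho}$ is how
the model disentangles parental switch errors from recombinations in rate;
at any single interval the two are distinguished only through $\rho_\ell$
itself, which is why a hotspot-resolved map is essential for confident
event calling (below).

### Recombination posteriors

A crossover can only be resolved to the interval between consecutive
parent-heterozygous markers, since parent-homozygous loci in between emit
identically for both parental indices. For each such interval the posterior
probability that at least one recombination occurred is computed exactly by
propagating, between the forward table at the left flank and the backward
table at the right flank, the transition mass split into its recombination
component ($\rho(1-\theta_p)$ on a parent-index change, $\rho\,\theta_p$ on
a retained index — the coincident-event case) and its switch-error
component. The computation is a single left-to-right sweep, linear in $L$,
and is verified in the tests against exhaustive enumeration of all $4^L$
paths jointly with per-interval recombination indicators. Calls are
thresholded at 0.5 by default; higher thresholds (e.g. 0.7) trade
sensitivity for a very low false discovery rate, and the posteriors are
calibrated (among intervals with posterior near $p$, a fraction near $p$
contains a true event), so the threshold has a direct error-rate reading.

### Genotyping-error posteriors

The posterior probability of a genotyping error in at least one duo member
at locus $\ell$ is the summed posterior mass of states whose IBD pair
mismatches there. Masking genotypes that exceed a posterior threshold
(default 0.5) removes sites whose phase information is corrupted; on
simulated cohorts with confusion-matrix genotyping error this strictly
lowers the switch-error rate.

## Correcting haplotypes

T3/T4 transitions in a decoded path imply a child switch error; scanning
left to right, the child haplotypes are swapped from each such transition
onward. T2/T4 transitions imply either a parental switch error or a real
recombination; with two or more decoded children, a change present at the
same flanking-heterozygous-marker interval in a strict majority of siblings
is classified as a parental switch error and the parent is corrected
(minimum-recombinant correction; ties conservatively produce no correction).
Corrections cascade top-down through each pedigree: an individual's
haplotypes are finalized before any duo in which it is the parent is
decoded, and duo parameters are re-estimated after upstream corrections.

### Trio children: reconciling the two duos

Sequential per-duo correction is unstable for a child with both parents
genotyped: each duo sees only its own meiosis, and a parental crossover in a
low-$\rho$ interval can be cheaper to explain as a child flip (cost
$\theta_c$) than as a parent-index change (cost $\approx \theta_p +
\rho_\ell$), in which case one duo "corrects" the child against the other.
High IBD sharing between the parents makes this worse, because long
stretches satisfy both labelings. kinphase therefore corrects trio children
from both duos jointly. At every *anchor* locus — child heterozygous, parent
homozygous — the transmitted allele identifies which child haplotype is IBD
with that parent regardless of the parent's own gene flow (a homozygous
parent transmits the same allele from either haplotype). In a correctly
phased child the father-IBD haplotype index is constant and the mother-IBD
index is its complement, so the merged orientation sequence over both
parents' anchors is constant, and every value change marks a child switch
error. The scan is refined with the per-duo Viterbi decodes, which exploit
parent-heterozygous sites the anchors cannot: decoded change positions
inside an anchor gap localize the switch more finely; an isolated
single-anchor disagreement is kept as a switch pair when a decode brackets
it and otherwise attributed to genotyping error; switch pairs falling in
anchor-free stretches are accepted when both decodes report them (interior)
or when any decode reports them (beyond the terminal anchors, where no
anchor evidence can exist). Children with a single genotyped parent use the
plain per-duo Viterbi correction. Corrections never alter genotypes — only
the assignment of alleles to haplotypes.

Phase at a site that no duo can resolve — for example a stretch where both
parents are heterozygous at every informative site — is genuinely
undetermined by pedigree information, and the corrected haplotypes inherit
the input phase there. The recovery tests therefore score misphased regions
only when flipping them back improves some duo's likelihood appreciably
(by more than 2 log units); under that definition the correction recovers
every injected child switch in the simulation study below.

## The simulation machinery

The generator reproduces the validation design the method is meant for,
with known truth at every level:

* **Genetic map** — `simulate_genetic_map()` draws per-interval genetic
  distances from a two-component mixture: 5% of intervals are hotspots with
  heavy-tailed (squared-exponential) weights, the rest carry a small
  constant background; the total is normalized to 100 cM over 2,000 markers
  at 50 kb spacing. This mirrors the concentration of recombination in a
  small fraction of the sequence seen in fine-scale human maps, at array
  resolution. On a uniform map a parental switch error and a crossover
  produce identical posteriors, and event detection degenerates; the skew is
  what gives the posterior its discriminating power.
* **Haploid pool** — `generate_haploid_pool()` builds haplotypes by a
  copying mosaic over a small set of templates, with template switching
  tied to genetic distance and a small mutation rate. Fewer templates and a
  lower switch intensity give longer shared segments (a more isolated
  population). Monomorphic sites are re-seeded so every marker segregates.
* **Founders and cohorts** — pairs of haploids become pseudo-autosomal
  diploid founders (phase known by construction); a rejection scheme
  excludes pairs of source haplotypes with realised relatedness above a
  threshold (default 0.05 when enabled, the conventional cryptic-relatedness
  cutoff). A pool of $n$ haploids yields $\lfloor n/4 \rfloor$ trios, or
  arbitrary pedigree structures via `build_pedigree_cohort()`, with
  ungenotyped founders optionally dropped from the observed data.
* **Meiosis** — crossover counts are Poisson with mean equal to the
  sex-specific map length in Morgans (male maps scaled by 0.605), positions
  uniform on the genetic scale, and the gamete alternates source haplotype
  at each crossover. Truth haplotypes, crossover intervals and the starting
  haplotype of every transmission are recorded, so every non-founder is
  exactly reconstructible.
* **Genotyping error** — each genotype is resampled from the row of a
  4x4 confusion matrix (over observed 0/1/2/missing given truth).
  `default_confusion_matrix()` carries a small realistic error mass
  (0.2% miscalls, 0.2% missingness by default) and is a synthetic stand-in;
  a study-specific matrix can be supplied.
* **Phasing emulation** — `inject_switch_errors()` stands in for a
  population phasing engine, which is outside the package's scope: candidate
  switch errors are drawn at heterozygous sites (1-2% in the studies here)
  and suppressed wherever one of the individual's haplotypes is identical to
  a haplotype of someone outside the family across a 25-marker flanking
  window. This reproduces the key empirical behaviour of real engines —
  cohorts with more IBD sharing are phased with fewer switch errors — with
  one deliberate simplification: within-family sharing is not counted as
  support, because it is precisely the signal the gene-flow model consumes,
  and the validation needs residual errors to correct. The emulator does not
  reproduce other features of real phasing output (e.g. error clustering in
  low-LD regions or allele-frequency-dependent error rates), so passing
  tests demonstrate correct behaviour under the modelled error process, not
  performance guarantees on any particular cohort.

## Study scales and what the tests show

The test suite fixes its own seeds and uses these problem sizes: exactness
of likelihood, posteriors, Viterbi score, recombination and error posteriors
is checked against exhaustive $4^L$ enumeration on 200 random duos with
$L \le 8$ at $10^{-10}$ relative tolerance; the crossover process is checked
on 20,000 meioses of a 1-Morgan map (mean within $1 \pm 0.02$, chi-square
goodness of fit at $\alpha = 0.01$); switch-error recovery and the masking
effect use ten replicate cohorts of 50 trios and 2,000 markers; the
detection-power contrast uses six replicates each of a high-IBD pool
(5 templates, switch intensity 0.05) and a low-IBD pool (15 templates,
0.12), pooling events before computing the TPR at 5% FDR exactly because
per-replicate FDR estimates at a few dozen events are too granular; and the
hotspot-usage association's type-I error uses 1,000 null simulations of 500
parents. Posterior calibration is additionally checked distributionally on
duos simulated from the generative model itself, where calibration is exact
by construction and deviations would indicate an implementation defect.

## Numerical choices and degenerate inputs

* Forward-backward uses per-locus scaling; posteriors are renormalized per
  locus and each row of the state posterior sums to one within $10^{-9}$.
* Viterbi breaks ties deterministically toward the earlier state in A-D
  order, making the whole pipeline reproducible byte-for-byte.
* Parameter estimates are clamped to $[10^{-7}, 0.5]$ to avoid degenerate
  zero-probability transitions.
* Duos need at least two markers; recombination posteriors need at least
  two parent-heterozygous markers (otherwise the call set is empty); switch
  error is undefined (flagged `NA`) below two usable heterozygous sites.
* Pedigree partitioning enumerates exactly up to 12 parent-child edges and
  falls back to a greedy trio-first heuristic above that, with ties among
  optimal partitions broken uniformly at random under a caller seed.
* The Mendelian QC masks violating loci per pedigree and excludes loci
  cohort-wide when more than 5% of pedigrees violate (configurable); the
  cohort-wide fraction is a conventional QC choice.
* Hotspot-usage events are assigned to hotspots by their interval midpoint
  on the genetic scale; the chance correction subtracts the simulated null
  expectation and rescales (`H = max(0, raw - chance)/(1 - chance)`), with
  the raw proportion available via `correction = "none"`; pseudo-counts
  round half to even. Parents with zero observed crossovers are excluded
  from the association with a warning.

## Known limitations

* The model treats each duo independently; a joint pedigree likelihood
  (Lander-Green) would extract more information from large families at
  exponential cost, and is deliberately out of scope.
* Parental switch errors in duos without sibships are indistinguishable
  from recombination except through the map; in uninformative duos the
  detector's power is bounded by phasing quality, as the high- versus
  low-IBD contrast quantifies.
* A single-site phase flip between two adjacent heterozygotes is
  indistinguishable from a genotyping error at that site; the pipeline
  prefers the error explanation and leaves it to masking.
* The emission model uses one $\epsilon$ per duo rather than separate
  parent and child error rates; with array data the two are confounded in
  any case.
* X-chromosome-specific inheritance rules and pedigree reconstruction from
  genotypes are not implemented.
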