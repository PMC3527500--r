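---
title: "Inferring sex-biased dispersal from a mitochondrial-microsatellite contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-biased dispersal from a mitochondrial-microsatellite contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersr)
```

## The inference and its logic

Mitochondrial DNA is transmitted by mothers only; microsatellites by both
parents. When females are philopatric and males disperse, maternal
lineages accumulate among-population differentiation while male-mediated
gene flow keeps nuclear allele frequencies homogeneous. The observable
signature of male-biased dispersal (MBD) is therefore *discordance between
marker classes*: significant structure in mitochondrial pairwise
Φ~ST~ with absent — or markedly lesser — structure in nuclear pairwise
θ. Two confounds must be handled on the way: apparent heterozygote
deficits (null alleles, inbreeding, Wahlund mixing) that can distort
nuclear structure estimates, and shared ancestral polymorphism, which can
mimic low nuclear differentiation without any ongoing migration.

`dispersr` implements each link of that chain: diversity description,
network visualisation, structure estimation with permutation inference,
the heterozygote-deficit diagnostics, the marker-class correlation, and
migration-model ranking. A forward-time two-sex simulator generates
datasets with known dispersal asymmetry so the whole pipeline can be
validated end to end.

## Estimators

**Haplotype diversity.** For haplotype counts with frequencies $p_i$ in a
sample of $n$ sequences,
$$\hat H = \frac{n}{n-1}\Bigl(1-\sum_i p_i^2\Bigr), \qquad
V(\hat H) = \frac{2}{n(n-1)}\Bigl[2(n-2)\bigl(\textstyle\sum p_i^3 -
(\sum p_i^2)^2\bigr) + \sum p_i^2 - (\sum p_i^2)^2\Bigr],$$
reported as estimate ± SD. Small samples force these values: two distinct
haplotypes in $n=2$ give exactly $1.000 \pm 0.500$, counts $(2,1)$ give
$0.667 \pm 0.314$, and $(2,1,1,1)$ gives $0.900 \pm 0.161$; the test suite
pins these.

**Nucleotide diversity.** $\pi$ is the mean proportion of differing sites
between two sampled sequences, computed from pairwise difference counts
over unmasked sites and reported in percent. Its variance uses Nei's
total variance, $V(\pi) = \frac{n+1}{3(n-1)L}\pi +
\frac{2(n^2+n+3)}{9n(n-1)}\pi^2$, which combines the stochastic
(evolutionary) and sampling components; this choice reproduces the ±
values of the reference analysis exactly on the small forced samples.

**Site masking and windows.** Columns containing a gap or `N` anywhere in
the analysed set are removed before haplotype identity, $\pi$, and AMOVA
distances (complete deletion). A site window supports reconciling
datasets sequenced at different lengths; trimming 410 bp alignments to
361 bp can merge otherwise distinct haplotypes, which is why `h` is
monotone non-increasing under windowing (a tested property).

**F-statistics.** Nuclear structure uses the Weir–Cockerham
variance-component estimators: per locus and allele the among-population
($a$), among-individual ($b$) and within-individual ($c$) components are
summed, with $\hat\theta = \sum a / \sum(a+b+c)$ and $F_{IS} = 1 - \sum c
/ \sum(b+c)$. Components are *not* truncated at zero, so small negative
pairwise estimates are representable. The permutation null for θ moves
whole multilocus individuals between populations (preserving
within-individual disequilibrium); the null for $F_{IS}$ re-pairs alleles
within each population. Mitochondrial structure uses the AMOVA partition
of squared pairwise distances (difference counts), $\Phi_{ST} =
\sigma_a^2/(\sigma_a^2+\sigma_w^2)$, permuting individuals among
populations with sizes fixed. All permutation p-values use the add-one
rule $(1+k)/(1+B)$ and never reach zero. Both estimators are checked in
the tests against independent oracles: an indicator-variable nested ANOVA
for the Weir–Cockerham components, and a brute-force SSD partition for
AMOVA.

**Exact Hardy–Weinberg test.** The Markov chain operates on perfect
re-pairings of the observed allele pool. A symmetric swap proposal makes
the uniform distribution over pairings stationary, and uniform pairings
induce Levene's conditional distribution on genotype tables, so the
frequency of visited tables no more probable than the observed one
estimates the exact p-value. Defaults (chain 100000, dememorization 100)
follow common practice for microsatellite data; a batch-means Monte Carlo
standard error is reported, and the chain is verified against complete
enumeration for biallelic samples.

**Null-allele diagnostics.** The allele-randomization test pools the
$2n$ alleles of one (population, locus) cell and re-pairs them uniformly;
the one-sided p asks whether the observed heterozygote count is low. Null
alleles, inbreeding and Wahlund substructure all push this p down — the
test screens for homozygote excess, it does not attribute cause. The
locus bootstrap guards the structure estimates: loci are resampled with
replacement and θ recomputed; a locus is flagged as *driving* when the
mean of replicates that exclude it falls below the 2.5th percentile of
the replicates that include it. (Flagging against the full bootstrap
distribution is ineffective here: with $L$ loci, a fraction
$(1-1/L)^L \approx 1/3$ of replicates omit any given locus, so the full
distribution's lower tail already sits on the excluded values.)

**Median-joining networks.** The network iterates between an ε-relaxed
minimum spanning network over the current node set (an edge survives iff
its weight is within ε of the minimax path weight between its endpoints;
ε = 0 keeps exactly the union of all MSTs) and the addition of
quasi-median vectors — per-site majority states of three mutually linked
nodes — whenever they shorten the triple's connection. Multistate ties
break lexicographically (A < C < G < T), a policy chosen here because the
reference implementation's is undocumented. Median vectors of degree ≤ 2
are pruned. Canonical node ordering makes the ε = 0 result invariant to
input order, a tested property, and maximum-parsimony post-processing is
deliberately not implemented.

**Marker contrast.** The Mantel test correlates the off-diagonal entries
of the two pairwise matrices with Spearman's ρ (midranks for ties),
permuting rows and columns of the second matrix simultaneously; p is
two-sided since discordance can take either sign, and all $n!$ label
permutations are enumerated when that is cheaper than sampling. Migration
models summarised by harmonic-mean log-likelihoods are ranked by
$LBF_i = 2(\ln L_{best} - \ln L_i)$.

**The classification rule.** `contrast_report()` flags a population pair
as *discordant* when its mitochondrial Φ~ST~ is significant while nuclear
structure is either non-significant or no more than `ratio_max` (default
0.5) times the mitochondrial estimate. The magnitude clause matters:
male gene flow dilutes but need not erase nuclear differentiation, and
the motivating empirical case shows exactly that — significant nuclear
structure at roughly half the mitochondrial level, still read as MBD.
The dataset is classified "consistent with male-biased dispersal" when at
least half of all pairs are mitochondrially significant *and* at least
half of those are discordant; requiring mitochondrial evidence first
prevents a structureless dataset from being vacuously classified as MBD.
Pair-level significance is Bonferroni-corrected across pairs by default,
matching the multiple-comparison practice the rest of the pipeline uses.
All three thresholds are explicit arguments: the underlying biology
supports a qualitative argument, not a canonical cutoff.

## The simulator: what it emulates and what it does not

`simulate_metapopulation()` advances `P` demes of exactly `n_f` females
and `n_m` males through non-overlapping generations: sex-specific
migration (each adult relocates to a uniformly chosen other deme with
probability `m_f` or `m_m`), then reproduction (each deme produces its
fixed complement of offspring, drawing each offspring's mother and father
uniformly from the deme's post-migration adults — so deme sizes are
conserved exactly, and migration is conservative in expectation only),
then inheritance: mtDNA copied from the mother with per-site mutation to
a random different base (a Jukes–Cantor-like model without rate
heterogeneity), and one microsatellite allele per parent per locus under
a stepwise model (±1 repeat with probability `mu_ms`, reflecting at
repeat 1). Null alleles are modelled as founder allelic lineages that
never amplify: a carrier of one such copy is scored homozygous for the
visible allele, a carrier of two as missing. `inject_null_alleles()`
applies the same scoring independently per allele copy to an existing
table.

Defaults describe the study condition the package targets: 4 demes,
50 + 50 adults per deme, 200 generations, a 410 bp maternal sequence
(`mu_mt` = 2e-5 per site per generation, chosen so within-deme haplotype
diversity is appreciable at this deme size), 15 microsatellite loci
founded from 6–12 allele pools (which keeps realized per-locus richness
in the 4–13 range typical of the motivating data), `mu_ms` = 5e-4, and 12
sampled individuals per deme, in the middle of the 2–20 emulation range.
The MBD regime sets `m_f = 0, m_m = 0.2`; its equal-dispersal control
changes *only* the parameter under test, raising `m_f` to the male rate.
Founder mtDNA forms deme-specific lineage clusters (8 mutational steps
from a common ancestor plus Poisson(1) private mutations) while founder
microsatellite pools are shared across demes, so nuclear structure starts
at zero and mitochondrial structure starts high — the configuration from
which sex-specific migration either preserves or erases each signal. A
`founder_pool = "private"` option instead founds each deme from disjoint
allele pools, used for degenerate fixed-founder checks.

What the simulator does **not** emulate: overlapping generations,
non-1:1 sex ratios, river-network geometry or distance-dependent
migration, mutation-rate heterogeneity, and genotyping error other than
null alleles. Passing the simulation-based tests therefore shows the
statistical machinery responds correctly to sex-biased gene flow in an
idealised island model — not that any particular empirical dataset meets
the model's assumptions.

## Numerical and design choices

* Permutation p-values: add-one rule, one-sided for structure and
  heterozygote-deficit tests, two-sided for Mantel; exhaustive
  enumeration replaces sampling whenever $n! \le$ the requested
  permutation count.
* Missing genotypes: accepted as `?` or `-9` on input, written as `?`;
  pairwise deletion per locus in the Weir–Cockerham components; an
  individual missing everywhere is rejected on input validation but
  tolerated in the output of `inject_null_alleles()` (rate 1 blanks
  everything by design).
* Monomorphic cells: HWE and allele-randomization p-values are 1 by
  convention with a note; a zero total molecular variance defines
  Φ~ST~ = 0 with a note.
* Degenerate networks: a single haplotype yields a one-node network with
  a warning, not an error.
* Problem sizes in the test suite were chosen for a laptop-class run:
  oracle equivalences use ≤ 8 individuals, the simulation study uses 20
  replicates per regime at the default configuration, and the uniformity
  screens use 150–500 simulated loci; each block states its seed and the
  whole suite is deterministic.

## Known limitations

The exact HWE chain reports a batch-means standard error that understates
uncertainty if the chain mixes very slowly (extremely many rare alleles);
the enumeration cross-checks cover the biallelic case only. The
median-joining implementation adds the lowest-cost quasi-medians each
round and caps the number of rounds, which matches the published networks
on small problems but is not guaranteed identical to every implementation
of the algorithm on large ε > 0 problems. The MBD classification is a
decision rule over p-values and effect sizes, not a likelihood-based test
of dispersal models; with very few populations (three or fewer pairs) its
fractions quantise coarsely and results should be read qualitatively.
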