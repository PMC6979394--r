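---
title: "Methods: founder mosaic reconstruction and QTL mapping in multiparent intercrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: founder mosaic reconstruction and QTL mapping in multiparent intercrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`magicmap` implements the analysis path for large multiparent (MAGIC-type)
inter-cross populations descended from a panel of fully homozygous founders:
simulation of such populations, reconstruction of each progeny line's
founder identity-by-descent (IBD) mosaic from SNP genotypes, collapse of
the population's mosaics into recombination bins, single-variant and
bin-haplotype mixed-model association scans, a genome-wide pairwise
epistasis scan, phenotype-driven refinement of major QTL, and drivers for
the two standard simulation studies (tracing power and mapping power).
This vignette records the models, the tunable parameters, and the design
choices made where the methodology left room.

# The population model and its simulator

The simulated breeding scheme follows a complete-diallel-seeded
inter-cross: an initial round of crosses between random distinct founder
pairs, further rounds of random inter-mating, then selfing by single seed
descent. Gametes recombine with crossover counts drawn Poisson with mean
equal to the chromosome's genetic length in Morgans and crossover positions
placed by local cM density — i.e. no crossover interference (Haldane).
Interference is deliberately omitted because the IBD reconstruction model
assumes exponentially distributed segment lengths, which is exactly the
no-interference limit. Selection steps present in real breeding programmes
(phenotypic selection of F1s, seed mixing ratios, diversity retention) are
not simulated by default; a `select_fn` hook exists for users who need a
truncation-selection variant. Residual heterozygosity surviving the
selfing generations (about 1–2% of the genome after six generations) is
retained and later absorbed by the IBD marker filters, mirroring how real
pipelines treat it.

Founder panels are simulated site by site: the number of founders carrying
the minor allele is solved from the requested expected pairwise divergence
(`simulate_founders(divergence = )`), so two random founders differ at the
requested fraction of sites. With 24 founders the attainable divergence
tops out near 0.52; the defaults use 0.35–0.45, in the range observed for
diverse inbred panels. Optionally, carrier sets persist along the
chromosome in haplotype blocks (`ld_block_bp`), so nearby markers show the
local founder-level LD that real inbred panels have; per-site allele
frequencies are unchanged. Sites are independent by default, which is the
right null for the HMM studies; the block option matters only where linked
variants are the object of study (the mapping power study uses 30 kb
blocks).

Phenotypes are additive: QTN effect magnitudes follow the geometric series
$a^n$ with $a = 0.95$, jointly rescaled so that the realized genetic
variance equals $h^2 V_p$ (defaults $h^2 = 0.8$, $V_p = 1$, hence residual
variance 0.2), with optional pairwise epistatic product terms carrying a
stated variance fraction. The noise-free limit returns a phenotype that is
an exact linear function of the causal dosages.

# IBD reconstruction HMM

Hidden states are the $F$ founders. Between adjacent markers at map
distance $d$ Morgans a switch event occurs with probability
$1 - e^{-Gd}$, with the new founder drawn uniformly — the marginal segment
length is then exponential with mean $\rho/G$ up to a factor $F/(F-1)$,
matching the generative assumption; a variant that re-draws only among the
other $F-1$ founders is available (`distinct_redraw`). $G$ defaults to 9
effective generations (eight inter-cross rounds plus roughly one
contributed by six selfings, which accumulate about half a generation's
recombination each). Emissions compare the progeny's homozygous calls to
the founder allele: match $1-\varepsilon$, mismatch $\varepsilon$; missing
and heterozygous progeny calls are uninformative (probability 1 for every
founder), because under a haploid state space a residual heterozygous call
carries no founder signal. $\varepsilon$ defaults to 0.02 — no error rate
is dictated by the model itself, but low-coverage sequencing plus
imputation make a small nonzero value the sensible default.

Posteriors come from a scaled (per-site normalised) forward–backward pass,
vectorised over blocks of lines; the scaled and log formulations are
numerically equivalent and the scaled one exposes posteriors directly. The
per-SNP call is the maximum-posterior founder provided the maximum exceeds
`call_factor / F` (twice the uniform chance level by default); ties break
to the lowest founder index, and the threshold is capped just below 1 so
that the degenerate two-founder case (where $2/F = 1$) remains callable.
Consecutive identical calls merge into segments with boundaries midway
between flanking markers; UNKNOWN runs are emitted as UNKNOWN segments.
Zero map distance between markers yields an identity transition, and in
the $G \to 0$ limit noiseless data produce one segment per chromosome.
The forward–backward implementation is checked against an exhaustive
path-enumeration oracle on all-small instances ($S \le 8$, $F \le 4$) to
$10^{-12}$.

Markers enter the HMM only after the standard filters: across-line
heterozygosity at most 10% and missingness at most 25%.

# Recombination bins and bin kinship

A bin is a maximal genomic span in which no line recombines: boundaries
are the union of all inferred segment boundaries. Each line's state in a
bin is inherited from its covering segment; UNKNOWN propagates. The
bin-haplotype kinship reformats bins as founder-state dummy variables:
$K_{ij}$ is the fraction of bins at which lines $i$ and $j$ carry the same
founder state. UNKNOWN matches nothing (a conservative choice; the
alternative of dropping such bins pairwise would make $K$ depend on the
pair), so the diagonal equals each line's traceable fraction. Bins are
unweighted by default — bin counts, not bin lengths, are the unit of the
downstream scan — with a length-weighted variant behind a flag.

# Mixed-model scans

**Single-variant scan.** The model is
$y = X\beta + g b + u + e$ with $u \sim N(0, \sigma_g^2 K)$, $K$ the
centred dosage cross-product over markers, and optional top principal
components of the standardised dosage matrix as fixed covariates (10 by
default in large populations). Variance components are estimated once
under the no-marker null by REML on the eigenbasis of $K$ (profiling
$\delta = \sigma_e^2/\sigma_g^2$ by 1-D optimisation over a log grid with
local refinement), then held fixed for per-marker generalised least
squares — the P3D/EMMAX approximation; an exact per-marker refit is
available behind `exact = TRUE` and agrees within an order of magnitude in
P for null markers. With identity kinship the scan reduces exactly to OLS.
Markers below 2% MAF are skipped; significance uses an
effective-test-count threshold supplied by the user
(`significance_threshold(alpha, n_eff)`), since effective-test estimation
itself is out of scope.

Significant SNPs are grouped into loci by chaining consecutive significant
SNPs closer than 20 kb, dropping chains with fewer than 2 SNPs, merging
adjacent loci when any cross-locus pair of significant SNPs has
$r^2 \ge 0.2$ (all pairs are examined, not only the peaks), and extending
narrow (< 50 kb) loci with peak P below threshold/100 by 25 kb on each
side.

**Bin-haplotype scan.** Each bin adds a random founder-state effect
$Z_b a$, $a \sim N(0, \sigma_b^2 I)$, to the polygenic null (bin kinship).
The statistic is the REML likelihood ratio between the full and null
models with identical fixed effects. The polygenic and residual components
are fixed at the genome-wide null fit (the same P3D logic as the
single-variant scan), and $\sigma_b^2$ is profiled on the eigenbasis of
$K$ through Woodbury identities — per bin this costs one thin SVD plus a
vectorised evaluation over a log-spaced grid (25 points up to five
phenotypic variances, always including 0, with optional local refinement
above a small coarse-LRT floor). The LRT is therefore non-negative by
construction. Founder states observed in fewer than 3 lines are pooled
into one residual class to stabilise the component; UNKNOWN lines get a
zero row rather than being dropped. Because the null distribution of a
boundary-constrained variance component is awkward, significance is never
taken from an asymptotic reference: genome-wide thresholds come from
permutations of the phenotype across lines (500 by default), recording the
genome-wide maximum LRT per permutation and taking the empirical
$1-\alpha$ quantile. The null covariance is held fixed across
permutations; this is what makes a 500-permutation genome-wide scan
affordable, and the threshold is insensitive to it because permuted
phenotypes carry no kinship structure either way. Significant bins merge
into loci when separated by at most 1 Mb or at most 5 intervening bins.

A precomputed engine (`hgwas_engine`) caches the per-bin SVD structures so
that repeated scans over new phenotypes of the same population — the
permutation loop and the mapping power study — cost a fraction of the
first scan.

# Epistasis scan

Markers are MAF-filtered and LD-pruned (greedy, $r^2 < 0.5$ within 50-kb
windows advancing 5 SNPs). Every remaining pair is tested with the 1-df
interaction term of $y \sim g_A + g_B + g_A g_B$ on dosages — the
continuous-trait analogue of the fast case-control interaction screens
used in large GWAS cohorts. Pairs above the first-pass cut (default
$6 \times 10^{-16} \approx 0.01/N_e^2$) are discarded; among survivors
whose endpoints both fall within 100 kb of a stronger pair, only the most
significant representative is kept (implemented greedily from the most
significant pair down, which equals cluster-representative selection for
transitive clusters). Survivors are re-fit with principal components and
additive terms; the adjusted interaction P must fall below $10^{-12}$, and
the pair PVE is the interaction term's incremental $R^2$. The joint
epistatic variance first residualises the phenotype on structure and all
involved additive dosages, then regresses the residuals on all interaction
products jointly; it is reported as a fraction of the total phenotypic
variance (not of the residualised variance), so an engineered 10% share
reads back as 0.10. Pairs are categorised against an sQTL catalog within
50 kb: SS-1 (both sides linked to sQTL of one trait), SS-2 (both linked,
different traits), SN, NN.

# QTL refinement

A major QTL must be detected by both scan types for the same trait with at
least 10% PVE each; its region is the union of the two intervals. Lines
are grouped by founder state at the peak bin, and groups are collapsed
into "functional alleles": every pair of founder groups is compared with a
Welch t-test on line phenotypes, and clusters merge agglomeratively with
the between-cluster p-value defined as the largest group-pair p-value
(single linkage) until every between-cluster comparison is significant at
0.05. Equivalently the functional alleles are the connected components of
the indistinguishability graph over founder groups. This group-level
linkage matters: defining the between-cluster test on pooled member lines
over-splits badly, because clusters formed by similarity have
selection-deflated within-cluster variance — under a null phenotype such a
rule rarely collapses 24 groups below five clusters, whereas the
group-level rule almost always reaches one. Welch rather than Student
tests are used throughout because group sizes are unequal; no
multiple-testing correction is applied inside the collapse (the raw 0.05
rule is part of the procedure's definition).

For narrowing, the allele labels are projected onto every bin in the
region; lines sharing an allele vector form haplotypes and those carried
by more than 8 lines are the major haplotypes. Haplotype pairs are
classified by phenotype t-test as distinct (P < 0.01), equivalent
(P ≥ 0.05), or ambiguous (no constraint) — the gap guards against
borderline tests flipping class. Each bin is scored by the number of pair
constraints it satisfies (distinct pairs should differ in allele at the
bin, equivalent pairs should agree), and the refined interval is the
longest maximal run of maximum-score bins, preferring a run containing the
peak bin. A strict all-constraints rule was evaluated and rejected: with
~20 major haplotypes there are ~190 pairs, and a single false-positive
t-test among same-allele haplotypes then vetoes the causal bin itself
(observed in roughly 40% of simulation draws); the score rule recovers the
planted causal bin in well over 80% of draws while still returning the
full region when no recombinant information exists. The exact combination
rule lives in one function and is straightforward to swap.

# Simulation studies and their scales

**Tracing power.** 100 pseudoprogeny lines are built by cutting the genome
into 180 segments per line (allocated to chromosomes proportionally to map
length, breakpoints placed by local recombination density, founders
assigned uniformly with adjacent segments distinct), projecting genotypes,
and running the HMM with $G = 9$. The study genome is five chromosomes of
120 cM / 12 Mb with 3000 markers each (15,000 SNPs, roughly a sixteenth of
the real marker density this emulates) and founder divergence 0.45. At
this scale the genome-wide fraction of correctly traced SNPs is about
98-99%, comfortably above the 93% floor the method is expected to clear;
per-chromosome fractions are reported alongside, as is the truth-versus-
inferred segment count per line (inference slightly undercounts, since
short segments near breakpoints fall below posterior confidence).

**Mapping power.** The study population is 500 lines from a 24-founder
pedigree on a two-chromosome genome: a 20 Mb / 200 cM carrier chromosome
holding the causal loci and a 5 Mb / 50 cM null chromosome, 5000 markers
in total, founder haplotype blocks of 30 kb. The long genetic length keeps
the 30 causal loci several cM apart (one per 1/30 slot of the carrier
chromosome), which is what keeps neighbouring founder-state signals
separable — IBD segments span ~10 cM, so physical spacing alone is not
enough at desk scale. Per replicate, 30 causal bins receive 1, 2 or 3 QTNs
(biallelic, four-allelic, nine-allelic scenarios; ranks 1..30 rotate
across scenario triplets so mean effect ranks are equal), and each locus
contributes variance $q_k a^{2n}$ with $q_k = (1, 2, 3)$ — proportional to
the QTN count, since every functional variant carries an effect from the
same series. Within a locus the variance is realised in repulsion phase:
the QTN effect vector is the minor-eigenvector direction of the local LD
matrix (for two QTNs this is the classic $(1,-1)$ repulsion pair), chosen
for three-QTN loci within the two smallest eigendirections to maximise the
participation of distinct allele classes. This construction is the point
of the study: the allelic series carries real founder-level variance that
no single biallelic marker can tag (best local tag $r^2 \approx 0.15$
versus 1 for a biallelic locus), so single-variant power concentrates in
the biallelic scenario while bin-haplotype power rises with the allelic
series. Detections are scored within 50 kb of the causal bin (the 2.5%-of-
chromosome equivalent of a megabase-scale window on a full-size genome);
thresholds are 0.05 over the tested marker count for the single-variant
scan and a 300-permutation genome-wide LRT quantile for the bin scan. The
default replicate count is 200 — enough for the orderings to clear
one-sided 99% tests — with the full-scale 1000 available by argument.

What these studies do not show: the simulator has no crossover
interference, no selection during population development, no
coalescent-derived founder LD structure, no genotyping-error model beyond
the HMM's emission error, and phenotypes are Gaussian with purely additive
(plus optional product-term) architecture. Passing them demonstrates the
machinery and its statistical behaviour under the stated generative model,
not performance on any particular real dataset.

# Numerical choices and degenerate inputs

* Map interpolation is piecewise linear in both directions, clamped at
  chromosome ends; plateaus invert to their left edge.
* Coordinates are 1-based inclusive throughout.
* Kinships are checked for positive semidefiniteness (smallest eigenvalue
  above $-10^{-8}$ relative) before REML.
* The $\delta$ profile uses a 40-point log grid on $[10^{-5}, 10^{5}]$
  plus local refinement; the $\sigma_b^2$ profile a 25-point log grid up
  to five phenotypic variances.
* Bins with a single observed founder state get LRT 0; monomorphic markers
  are skipped by scans and pair tests; collinear predictors are dropped
  from PVE regressions with a warning.
* Empty significant sets return empty, typed catalogs rather than errors.

# Worked sizes

Unit tests run on a two-chromosome 100 cM / 10 Mb fixture with 400–5000
markers and populations of 150–1404 lines; the heavier study
configurations above are exercised by the acceptance suite and by
`scripts/acceptance.R`. All simulators take a `seed` argument and are
bit-reproducible under it.
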