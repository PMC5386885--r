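---
title: "Pedigree-based genotype imputation and genomic prediction in two-generation breeding populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based genotype imputation and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and motivation

Sib-testing aquaculture breeding programs record traits on thousands of fish
closely related to the selection candidates. Genotyping all of them on a
medium- or high-density SNP array is expensive, so a standard strategy is to
genotype the parents densely, genotype most offspring on a cheap low-density
(LD) panel, and impute the offspring up to full density before running
genomic prediction. `salimpute` implements that entire loop as testable
components:

1. **popsim** — a two-generation population simulator with known truth,
2. **panels** — QC and LD-panel masking designs,
3. **famimpute** — pedigree phasing plus an inheritance-origin HMM,
4. **relmat** — genomic (VanRaden) and pedigree (tabular) relationship matrices,
5. **predict** — the animal model, EM-REML and fivefold cross-validation,
6. **evalreport** — accuracy metrics, scenario grids, cost model.

# The simulator: what it emulates

The default configuration (`sim_config()`) mirrors a commercial Atlantic
salmon year group: 59 nuclear families from 30 sires and 59 dams (sires
reused round-robin, so each serves one or two families), about 624
offspring in total with family sizes drawn multinomially around 624/59.

* **Genome.** Five chromosomes of 100 Mb each carrying 1000 SNPs with
  uniformly drawn physical positions. Genetic positions use a constant
  1 cM/Mb, so a chromosome is 1 Morgan — a deliberate simplification; real
  salmon maps have strong sex- and region-specific rate variation that the
  physical-position arrays this design emulates do not expose anyway.
* **Founder haplotypes.** A Li–Stephens-style mosaic of 10 ancestral
  template haplotypes per chromosome, with template switch rate 0.05/cM.
  Template allele frequencies are drawn in [0.05, 0.5], matching panels
  already filtered at MAF ≥ 0.05. The mosaic produces LD that decays with
  distance (verified by a rank-correlation test), which is what gives the
  low-density panels their information content.
* **Meiosis.** Crossover counts are Poisson with mean equal to the map
  length in Morgans, positions uniform on the cM scale — the Haldane
  no-interference model. Interference is out of scope.
* **Traits.** Two polygenic traits on a standardized latent scale: 300 QTL
  are sampled from mapped SNPs, Normal effects are rescaled so the realized
  additive variance equals the target heritability (0.22 for lice
  resistance, 0.50 for body weight), residuals make up the remainder, and a
  sex effect of 0.2 latent SD is added to males. Body weight is reported in
  grams (mean 500 g, SD 100 g). Lice counts are observed through
  `exp(log(25) + 0.6 * latent) - 1`, clamped at zero: a lognormal-style
  observation model that produces the positive skew typical of parasite
  counts while keeping the latent heritability well defined.

What the simulator does **not** emulate: genotyping error on the arrays
(the imputation model allows it, the generator does not inject it),
selection or assortative mating among the parents, multi-generation
pedigrees, map errors, or genotype-by-environment effects. Passing tests
therefore demonstrate correctness of the algorithms under a clean
two-generation design, not performance on noisy real arrays.

The exact transformation applied to skewed lice counts in the source data
is cited rather than specified there; `transform_counts()` uses a
Box-Cox-family power transform on `counts + 1`, with the exponent chosen on
a grid from −2 to 2 (step 0.05) to minimize absolute sample skewness. It is
a documented, swappable stand-in with the same intent — symmetrizing the
observation scale — and it returns the chosen exponent so analyses can
report it.

# The imputation algorithm

The contract matches the study design: parents genotyped at the full base
panel, offspring at an LD subset (or the full panel), nuclear families
only, no grandparents.

1. **Mendelian fill** (`mendelian_fill`): a masked offspring genotype is
   filled only when the parents force it (0×0, 2×2, 0×2).
2. **Transmission inference** (`infer_transmissions`): for each trio and
   SNP where the offspring genotype and the other parent's genotype force
   the transmitted allele, the transmission is recorded. Mendelian-
   inconsistent sites are skipped and counted.
3. **Parent phasing** (`phase_parent`): homozygous sites are trivially
   phased. Heterozygous sites with at least one record ("informative") are
   chained in map order; each offspring with records at two consecutive
   informative sites votes *cis* or *trans*, the majority wins, and ties go
   to cis (fewest recombinations). A link with no votes starts a new phase
   segment. Sites inside a linked segment are flagged `phase_known`;
   orientation *between* segments is arbitrary, which the downstream HMM
   absorbs as an apparent state switch at the boundary. Heterozygous sites
   with no records keep `phase_known = FALSE`.
4. **Inheritance-origin HMM** (`origin_hmm`): per offspring and chromosome,
   four states (which sire haplotype × which dam haplotype the two gametes
   copy), uniform initial distribution, per-gamete switch probability
   between adjacent SNPs given by the Haldane map function
   `r = ½(1 − e^(−2d))` with `d` in Morgans, and emissions from a
   per-allele genotyping-error model (`error_rate`, default 0.001, the
   order of array error rates). Posteriors come from scaled
   forward–backward (compiled); masked SNPs contribute flat emissions, so
   their posteriors are interpolated through the chain.
5. **Dosages** (`impute_dosages`): the probability each gamete carries
   allele 1 is the posterior-weighted transmitted-allele probability of
   the parental haplotypes; the two gametes combine independently into a
   genotype posterior, expected dosage and most-likely genotype.
6. **Iteration** (`impute_population`, default 2 iterations): after the
   first pass, confident origin posteriors (margin > 0.95) combined with
   the other parent's known phase resolve transmissions that were
   ambiguous from genotypes alone (both parents heterozygous); parents are
   re-phased and the HMM re-run. This is the mechanism by which fully
   genotyped sibs (the "75% LD / 25% HD" strategies) sharpen the parental
   haplotypes and lift accuracy for their low-density sibs. Returns beyond
   two iterations were judged not worth the runtime in a two-generation
   design, where no new evidence types appear after one re-phase.

**Marginalizing unknown parental alleles.** When a parental haplotype
allele is needed but unknown, two cases are distinguished. If the parent's
*genotype* is missing, the allele is marginalized with the population
allele frequency. If the parent is heterozygous but its *phase* is
unresolved, the exact marginal of the transmitted allele is 0.5 regardless
of origin state — both alleles are present, only their assignment is
unknown — so 0.5 is used. Using the population frequency there would throw
away the observed genotype.

**Numerical safeguards.** Emissions of exactly zero across all states
(possible at a Mendelian-inconsistent site with `error_rate = 0`) fall
back to the transition-only prediction; posterior rows are renormalized;
gamete allele probabilities are clamped to [0,1] so dosages are exactly
bounded in [0,2]. A chromosome with no observed markers returns a uniform
posterior with a warning. Per-offspring failures are isolated, logged in
the result, and do not abort the population run.

# Relationship matrices and the animal model

`compute_grm` is VanRaden method 1, `G = ZZ′ / (2Σp(1−p))` with `Z`
centered by `2p`; allele frequencies default to the genotyped individuals
at hand, and real-valued dosages are accepted — the package feeds imputed
*dosages* into G by default because the expected allele count preserves
variance that hard calls discard (hard calls remain available via
`imputed_genotypes(..., mode = "most_likely")`). Monomorphic markers are
excluded with a warning. `compute_nrm` is the tabular method with
inbreeding on the diagonal. `regularized_inverse` adds an escalating ridge
(starting 1e-6) when the smallest eigenvalue demands it; a plain inverse
fails on, for example, duplicated individuals in G.

`solve_mme` solves Henderson's equations for `y = Xb + Za + e` with
`var(a) = Kσ²ₐ`; animals in `K` without records (the validation set)
receive predictions through the relationship structure. `em_reml` is
classical EM-REML for the one-random-effect animal model; the iteration is
carried out in the eigenbasis of `K`, computed once, so each EM step costs
O(n·p²) and the slow EM convergence (default tolerance 1e-6 relative
change, cap 5000 iterations) is affordable. The estimator is identical to
the naive MME-based EM — the tests pin this down against a dense
implementation — and non-convergence returns the last iterate flagged.

Cross-validation follows the study protocol: five nonoverlapping folds
(80/20), variance components re-estimated per fold on the training records
(a fixed-h² mode exists for fast tests and for matching an external
estimate), validation phenotypes withheld while the validation animals
stay in `K`, and fold accuracy `r(ŷ, y*)/h` where `y*` is the validation
phenotype pre-adjusted for the *training-estimated* fixed effects and `h`
is the square root of the training heritability. Adjusting the phenotype
removes sex-effect inflation of the correlation; taking `h` from the
training fold rather than a global value keeps folds independent.

# Accuracy metrics and reporting

Imputation accuracy is scored on masked cells only — unmasked cells are
trivially correct and would inflate the correlation. "Averaged across all
SNPs and all animals" is ambiguous between a per-animal mean, a per-SNP
mean and a pooled correlation; the primary summary is the **mean of
per-animal correlations** (the per-animal framing matches how accuracy
distributions over individuals are usually displayed), with the per-SNP
mean reported alongside and zero-variance cases excluded and counted. The
correlation uses the most-likely genotype by default, with a dosage mode
available; the headline design comparisons in this package's own checks
use the dosage mode.

The scenario runner evaluates the 2 × 2 × 2 grid (base panel HD/MD × 90/99%
masked × 100/75% offspring at LD) on one simulated population, and the
prediction comparison (PBLUP, GBLUP on LD SNPs only, GBLUP on imputed
dosages, GBLUP on true genotypes; both traits) on the medium-density base
panel. The cost model prices full-density samples at 40 and LD samples at
5 currency units per sample by default and reports the percentage saving
of the imputation design over genotyping everyone at full density; which
samples count toward the baseline is explicit configuration, not an
assumption.

# Test scale and determinism

All randomness flows from one integer seed through documented per-stage
sub-streams (`founders`, `meiosis`, `traits`, `folds`, ...), so identical
seeds give bitwise-identical populations. The unit and property tests run
on reduced designs chosen to keep the full suite in the minutes range:
oracle comparisons use up to 8 markers (exhaustive path enumeration), 50
pedigree members (gene dropping), 20 × 50 genotype matrices (loop-based
GRM); ordering and recovery checks use populations of 96–624 offspring on
maps of 400–1200 SNPs with 5–20 replicates. Heritability-recovery and
imputation-ceiling checks run at the full 59-family/624-offspring design.

# Known limitations

* Two generations only: no grandparents, no population-LD-only imputation
  of unrelated individuals; accuracy under sparse panels is limited by
  what transmissions can reveal about parental phase.
* Phase-segment orientation errors appear to the HMM as spurious
  recombinations; with very sparse panels and few informative offspring
  this lowers dosage confidence rather than producing wrong confident
  calls — conservative, but visibly below the accuracy of multi-generation
  phasing tools on the same designs.
* EM-REML is single-trait, one random effect; no dominance, no
  genotype-by-environment terms, no multi-trait models.
* The observed-scale lice model (exponential link, then a power transform
  back) slightly attenuates latent-scale heritability; the recovery tests
  quantify the attenuation implicitly by estimating on the transformed
  scale.
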