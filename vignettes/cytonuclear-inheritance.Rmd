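---
title: "A cytonuclear inheritance model for hybridizing Eisenia earthworms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cytonuclear inheritance model for hybridizing Eisenia earthworms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiseniahyb)
```

## The biological setting

*Eisenia andrei* (Ea) and *E. fetida* (Ef) are composting earthworms —
simultaneous hermaphrodites capable of self-fertilization, cross-fertilization
within a pair, and, as genotyping of controlled pairs has shown, asymmetrical
interspecific hybridization. Three marker systems delimit individuals:

* the **mitochondrial COI haplotype** (`a` or `f`), strictly maternally
  inherited and therefore a record of the ovum of origin;
* the **nuclear 28S rRNA diplotype** with species-diagnostic alleles `A` and
  `F`, biparentally inherited;
* the **M-fluorophore phenotype** of coelomic fluid: M-positive (`Mp`) worms
  show a distinctive fluorescence fingerprint (excitation peak 314–320 nm,
  emission peak 370–380 nm), M-negative (`Mn`) worms lack it.

The model treats M-positivity as controlled by a hypothetical nuclear gene
with a dominant allele `M` and recessive `m`, segregating independently of
the 28S locus. A genotype is written as a five-character code such as
`aAFMm`: mitochondrial haplotype, then the ordered (maternal, paternal) 28S
pair, then the ordered (maternal, paternal) M-locus pair. Parent-of-origin is
retained — `Mm` and `mM` are distinct genotypes with identical phenotypes —
because the maternal-first convention is what lets the mitochondrial and
nuclear records be cross-checked.

## The inheritance model

`make_gametes()` enumerates gametes exactly: each nuclear locus contributes
either allele with probability 1/2, independently across loci; ova carry the
parent's mitochondrion, sperm do not. `fertilize()` fuses an ovum and a sperm
maternal-first. On top of this Mendelian core sit four model ingredients:

1. **Mixed mating.** Within a pair, each ovum is self-fertilized with
   probability $\sigma$ (`selfing_rate`) and cross-fertilized with
   probability $1-\sigma$. Selfing is resolved per ovum, the simplest
   mechanism consistent with mixed broods from single pairs. A pair is the
   equal mixture of its two mother roles (`pair_distribution()`).
2. **Mito-nuclear incompatibility.** Ova combining the `a` mitochondrion
   with the foreign nuclear allele `F` are weighted by a viability $v$
   (`aF_ovum_viability`). The default $v = 0$ excludes them outright, which
   reproduces the crossed-out squares of the hybridization scheme; the
   parameter is exposed because the evidence says "less probable", not
   impossible.
3. **Asymmetrical hybridization.** Cross-fertilization of an `f`-mito ovum
   by `A`-bearing sperm carries an extra weight $h$ (`ef_cross_success`).
   At $h = 0$ no Ef-ova hybrid (fFA) can form; the default $h = 0.1$ makes
   them rare, matching their scarcity relative to Ea-ova hybrids.
4. **Hybrid sterility.** Hybrid × hybrid pairings produce no offspring
   (cocoons but no hatchlings), and fFA-type hybrids are sterile as mothers.
   Whether fFA worms can still sire offspring is unresolved; the package
   disables it by default (`fFA_paternal_fertile = FALSE`) because no
   successful fFA parent has been demonstrated, and exposes the switch.
   Self-fertilization of fertile aAF hybrids cannot be excluded during
   hybrid × parental matings but was never demonstrated either; it is off by
   default (`hybrid_selfing`).

After the weights are applied the distribution is **renormalized**: weights
shift brood composition, not brood size. Clutch-size effects are out of
scope. Normalization of every nonempty distribution is exact to 1e-12 and is
property-tested.

All distributions are computed from a shared *term table* — one row per
(ovum, sperm-source, sperm) combination with flags for which weight applies.
The forward simulator samples these same terms, and the likelihood grid
evaluates them at each $(\sigma, h)$, so the exact, simulated, and fitted
paths cannot drift apart. Sampling at the term level also records pedigrees
correctly: a selfed offspring lists its mother as both parents.

## Founder assumptions

Founders of the hybridization scheme are taken as `aAAMM` (M-positive Ea) and
`fFFmm` (M-negative Ef). Phenotype cannot distinguish `MM` from `Mm` in Mp
founders; fixing Ea founders at `MM` is therefore an assumption, kept as a
configuration default (`founder_genotypes()`, and
`assume_ea_founders_MM` in `infer_m_genotypes()`), not a fact.

## The alternative symbiont mechanism

The competing hypothesis holds that M-fluorescence derives from an
Ea-specific bacterial symbiont: vertically transmitted via the cocoon with
probability `symbiont_vertical_p`, and transferable to the partner's cocoons
during copulation with probability `symbiont_sexual_p` (resolved once per
pairing, matching the spermatheca/cocoon narrative). Under this mechanism a
worm is Mp iff infected. Neither probability is quantified empirically; the
defaults (vertical 1, sexual 0.5) are placeholders for sensitivity analysis.
The discriminating observation is a family of 7 offspring of a selfing
M-positive Ef mother containing 2 Mn worms: the Mendelian model gives the
finite binomial likelihood $\log\binom{7}{2}0.25^2\,0.75^5 \approx -1.17$,
while faithful vertical transmission from an infected mother gives
probability zero (`mechanism_loglik()` returns $-\infty$), so the
log-likelihood ratio favors Mendelian inheritance — unless vertical
transmission is imperfect, in which case the two binomials can coincide
(vertical $p = 0.75$ exactly mimics 1:3 segregation), which is why the
comparison is reported as likelihoods rather than a verdict. The suggestion
that intrinsic and microbial factors might cooperate is too unspecified to
model and is noted here only.

## Estimating $(\sigma, h)$

`estimate_params()` maximizes the multinomial log-likelihood of class ×
phenotype counts under the exact class probabilities of a mating design, on
a grid over $[0,1]^2$ (default 101 × 101, step 0.01). A grid, rather than a
numerical optimizer, because the surface is legitimately flat or
boundary-maximized in realistic cases — zero observed fFA hybrids drive
$\hat h$ to the boundary, and a design producing a single class is flat —
and the full surface is returned so such cases are visible rather than
silently "converged". The likelihood is multinomial over class counts, not
per-specimen pedigrees, because class counts are what the study design
reports for most specimens. Parameter recovery at the study-like size
$n = 5000$ over 20 seeded replicates has median absolute error within one
grid step for both parameters.

## Pedigree M-genotype inference

`infer_m_genotypes()` propagates constraints through a pedigree by arc
consistency to a fixpoint: a specimen's ordered diplotype survives iff each
of its alleles is transmissible by the corresponding parent's surviving set,
and a parent diplotype survives iff it can serve every child. Arc
consistency is deliberately conservative — it never eliminates the true
diplotype (property-tested on simulated pedigrees) at the cost of sometimes
retaining combinations a full global solver would reject. An emptied set is
reported as a named inconsistency rather than an error, since detecting
impossible transmissions is a use case, not a failure.

## Synthetic spectra

`generate_spectrum()` emulates the fluorimetric fingerprint on a 1-nm grid:
emission recorded 340–480 nm with the Mp peak at 380 nm, excitation
260–360 nm with the Mp peak at 320 nm, a Gaussian bump (SD 15 nm, an
invented generator width) of height 100 on a baseline of 10 (arbitrary
units), Mn scans baseline-only, additive Gaussian noise clipped at zero.
`classify_spectrum()` calls Mp iff both argmaxes fall in the reported
windows (370–380 and 314–320 nm) and both peaks exceed a prominence
threshold, default 2, where prominence is (peak − median)/median — scale
invariant, so classification is unaffected by uniform intensity scaling.
Argmax ties break toward the lower wavelength for determinism. The reported
windows are instrument observations; whether within-window variation is
biological or instrumental cannot be decided here, so the generator pins the
centers and the classifier accepts the windows. Because the emission center
sits on the window edge, even small noise pushes roughly half the Mp argmaxes
out of window: round-trip accuracy is 100% at zero noise and degrades
steeply and monotonically with noise, which the suite checks over a seeded
sweep (noise SD 0, 0.5, 5, 50, 150; 100 Mp + 100 Mn scan pairs per level).

## The packaged study table and synthetic cohorts

`load_study_fixture()` ships the 46-specimen class composition: 10 Ea and 19
Ea-derived hybrids, all Mp; 12 Mn and 1 Mp Ef; 3 Mp and 1 Mn Ef-derived
hybrids. Specimen codes named in the study text are kept; the remainder are
synthetic placeholders (prefix `syn`) because the published material does
not list every tip code, and pedigree links of the observed worms are left
empty. `load_poc_family()` ships the proof-of-concept family (selfing Mp Ef
mother, 7 offspring, 5 Mp : 2 Mn). Both files are hash-pinned in the tests.

`generate_cohort()` drives the simulator and the spectrum generator
together. The default design (`study_mating_design()`) mirrors the combined
mating scheme: an Ea × Ef founder pair (60 F1 offspring), then the first two
Ea-derived F1 hybrids test-crossed against a fresh Ea and a fresh Ef partner
(49 offspring each, totalling 158, the size of the genotyped families).
Body weights are truncated-normal with mean 0.77 g and SD 0.18 g, reading
the study's "0.77+0.18 g" as mean ± SD; truncation at zero is by rejection
and is numerically negligible at these values. What the synthetic cohorts do
*not* emulate: clutch-size variation (offspring counts are fixed per cross),
overlapping generations, genotyping error, fluorimetric drift, and any
linkage between the loci — so green tests certify the inheritance logic and
the analysis pipeline, not field realism.

## Problem sizes and numerics

The test suite runs the Monte-Carlo ↔ exact equivalence at $10^5$ offspring
per configuration (3-SE criterion per class), the selfing-segregation check
at $4 \times 10^4$, parameter recovery at 20 × $n = 5000$, and the weight
calibration at $n = 10^4$ — sizes chosen so every stochastic check has
comfortable power while the whole suite stays quick. All simulations require
an explicit seed and are byte-reproducible; unseeded calls are rejected.
Probabilities are exact rational arithmetic in double precision (sums of
1/16-weighted terms), so distribution comparisons use 1e-12 tolerances, not
statistical ones.
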