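---
title: "Models and methods behind killiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind killiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killiscreen)
```

`killiscreen` models a simultaneous zygotic/sterile forward-genetic
screen in a self-fertilizing hermaphroditic killifish. This vignette
explains the genetic model, the simulator's assumptions, the
classification rules and their error rates, the statistical conventions,
and the design decisions that were genuinely open.

## The genetic model

Each induced allele is recessive, autosomal, and belongs to one of four
functional classes:

* `ZYGOTIC_LETHAL` — homozygous embryos express an embryonic phenotype
  and die before scoring as viable;
* `STERILE_TYPE_I` — homozygous *mothers* lay fertilized eggs
  (perivitelline "halo" present) that arrest during early cleavage
  regardless of the embryo's own genotype (a maternal-effect mutation);
* `STERILE_TYPE_II` — homozygous mothers lay no eggs at all
  (ovotestis/gonadogenesis or anatomical defects such as embryo
  holding);
* `VISIBLE_VIABLE` — homozygotes show a visible phenotype (pigmentation,
  yolk colour) but survive and reproduce.

Transmission is exact Mendelian selfing: every heterozygous locus
segregates 1:2:1 and loci combine multiplicatively
(`self_cross_distribution()`). **Loci are assumed unlinked and
genotypes unordered** — the screen never outcrosses, selfing makes
parental origin irrelevant, and nothing in the screen's claims depends
on linkage; recombination and linkage maps are out of scope.
Conditioning on survival (`survivor_distribution()`) renormalizes the
surviving classes, giving the 2 carriers : 1 wild-type ratio among
survivors of a selfed lethal carrier that anchors the screen's
segregation tests. Equivalence with a brute-force enumeration of all
4^L ordered gamete pairs is asserted in the test suite for up to three
loci.

Two per-allele nuisance parameters modulate expression:

* **penetrance** (default 1): the probability a homozygote expresses its
  class phenotype. Observed per-family mutant-embryo fractions in real
  screens range widely (5–69% where 25% is expected), which incomplete
  penetrance plus sampling noise reproduces.
* **maternal dominance** (default 0): the probability a *heterozygous*
  Type I mother expresses the maternal effect. Some real sterile
  families show far more than 25% sterile offspring from carrier
  parents (up to ~71%, including single parents whose reared offspring
  were all sterile), a pattern consistent with partially dominant
  maternal effects; the parameter exists to reproduce that qualitative
  behaviour and the simulator's sterile fraction is monotone in it.

## What the simulator emulates

`simulate_screen()` gene-drops four generations:

1. **F1 founders** — one per family, heterozygous for `K` induced
   alleles. `K` is Poisson with mean 0.48 by default; combined with the
   default class mix (60% zygotic lethal, 15% Type I, 10% Type II, 15%
   visible) this puts the zygotic-lethal class mean at ≈ 0.29, i.e.
   roughly a quarter of mutagenized genomes carry at least one zygotic
   lethal — the hit rate a calibrated ENU dose is chosen to achieve.
   Setting `alleles_per_genome` fixes `K` exactly for controlled
   experiments.
2. **F2 cohorts** — selfed offspring of the founder; expressed
   homozygous lethals die as embryos, survivors are reared
   (`rearing_survival`, default 0.95) until a per-family target drawn
   uniformly from 2–13 scored fish is reached. Each reared fish is a
   primary male with probability 0.036, independent of genotype — the
   screen's observed male rate; no genetic model of male determination
   is assumed. Males lay no clutches and are excluded from genotype
   tallies. Small cohorts naturally lose alleles by drift (with a
   cohort of 2, both survivors of a lethal carrier are wild-type with
   probability 1/9).
3. **F3 clutches** — every F2 adult hermaphrodite is collected over 24
   discrete sessions (three per week for about two months). Clutch
   sizes are Poisson(4) truncated at 25 per session, which accumulates
   the ~20–100 embryos per fish that real collection schedules yield
   while letting zero-egg sessions occur naturally. Expressed Type II
   mothers lay nothing; expressed Type I mothers lay fully fertilized,
   fully nonviable clutches.
4. **F3 rearing and F4 clutches** — by default only in families where a
   sterile F2 appeared (`rear_f3 = "sterile_families"`), mirroring the
   confirmation design: up to 6 F3 per fertile F2 are reared and
   collected, enabling backward genotyping.

Two background nuisance rates apply to every fertile mother:
`background_unfertilized` (default 0.02) and `background_nonviable`
(default 0.20). The nonviable default is not a published constant; it
was chosen once from the observation that even nonsterile lines lose a
substantial fraction of embryos (pooled confirmation-screen viability
is barely above half even though expressed Type I mothers and 25%
zygotic-lethal classes account for only part of the loss). Unfertilized
eggs are never viable and, having no zygotic genome expression, never
display a zygotic phenotype — which is why phenotype fractions are
measured among fertilized embryos.

All randomness flows from the single `seed`; reruns are byte-identical.

**What the simulator does not emulate:** developmental staging,
dose–response of the mutagen, environmental plasticity of phenotypes,
outcrossing to primary males (androdiecy), linkage, paternal-effect
sterility, and mortality during the clutch-collection period (censoring
is applied at rearing only, for simplicity). Passing recovery tests on
simulated data therefore shows the decision rules are correct *given
this generative model*, not that real screens are free of scoring
error, stage-dependent death, or allele interactions.

## Classification rules and their error rates

`classify_screen()` applies the screen's published criteria verbatim:

* **Type I sterile**: at least 20 embryos scored and ≥ 90% nonviable or
  unfertilized. The two failure modes are pooled into one fraction —
  unfertilized eggs count inside the nonviable tally, so the criterion
  is `n_nonviable / n_scored ≥ 0.9`. No background correction is
  applied; at the default background (≤ 0.5) a wild-type fish
  essentially never reaches the 0.90 threshold with ≥ 20 embryos.
* **Type II sterile**: zero eggs over at least 24 post-maturity
  sessions (the "> 2 months" criterion discretized at 3 sessions/week).
  Shorter eggless stretches are `INDETERMINATE`. The two sterile calls
  are mutually exclusive by construction (≥ 20 embryos vs 0).
* **Zygotic carrier**: a fertile fish with ≥ 20 scored embryos of which
  ≥ 2 display a family mutant phenotype. The source screens state only
  that carriers "produce embryos displaying the family phenotype";
  they publish no numeric threshold, so the count threshold here is a
  documented package choice: with 20 embryos and a true
  mutant fraction of 1/4, the miss probability is
  P(X ≤ 1 | Binomial(20, 0.25)) ≈ 0.024 (sensitivity ≈ 0.976), while
  requiring 2 embryos suppresses single-embryo misscoring. A formal
  binomial test would add little at these counts.
* **Backward genotyping**: a parent with ≥ 1 sterile reared descendant
  is a carrier (a carrier's offspring are ~25% sterile, so evidence
  accumulates quickly); an all-fertile sibship of ≥ 8 supports a
  wild-type call, with residual miss probability 0.75^8 ≈ 0.10;
  anything less stays in the honest undetermined `*/+` class rather
  than forcing a call — exactly how real confirmation screens end up
  with large `*/+` cohorts.

Family categories are the union of confirmed types ("Zygotic",
"Sterile I/zygotic", "Sterile I and II/zygotic", ... , "Zygotic not
confirmed"), computed from member calls.

Whether a family showing both Type I and Type II sterility carries one
pleiotropic allele or two different alleles is unresolved in the
source screens; the simulator supports both parameterizations (one
allele of each class, or one allele whose homozygotes express either
way via penetrance).

## Statistical conventions

`chi_square_gof()` is the plain Pearson statistic with per-cell
contributions, df = cells − 1, no continuity correction, and the
conventional critical value (3.84 at α = 0.05, df = 1) — the analysis
style of printed screen tables. Two expected-count modes exist because
printed tables round expectations to integers before computing the
statistic (281 split 1:2 becomes 94 and 187, not 93.67 and 187.33):
`"PAPER_INTEGER"` reproduces those printed statistics exactly (rounding
each cell and repairing the largest so the total is conserved), while
`"EXACT"` is the default for new analyses. The result object reports
`consistent_with_ratio = (chi-square < critical value)` and leaves the
hypothesis-testing vocabulary to the user; screen reports sometimes
describe a tiny chi-square as "rejecting the null hypothesis" where
standard usage would say the data are *consistent* with the Mendelian
ratio, so the package reports numbers, not wording.

One printed family percentage (line R103 in the packaged
confirmation-count table) cannot be reconciled with its own printed
counts (21/(21+18) = 53.85% versus a printed 53.5%); the reproduction
suite recomputes from counts and documents the exclusion. The printed
percentages elsewhere in that table appear to be truncated rather than
rounded to one decimal; the package reports full precision.

For screen design, `min_individuals()` offers two conventions because
the conventional cohort sizes (8 selfing fish, 35 intercrosses, both
"90%") have exact detection probabilities of 0.8999 and 0.8959 — both
just below a strict 0.90. `"NEAREST_PERCENT"` rounds both sides to the
nearest percent and reproduces the conventional numbers; `"STRICT"`
enforces the exact inequality (9 and 36) and is the safer default for
new designs. The underlying rounding convention of the published
numbers is an inference, labelled as such.

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations so that
three-binomial-SD checks are sharp but cheap: ≥ 10,000 embryos for
clutch-level fractions, ≥ 5,000 adults for survivor-carrier fractions,
400 families for Monte-Carlo detection probability, and 1,000 fuzz
cases for chi-square oracle equivalence. Distribution probabilities are
validated to sum to 1 within 1e-12; survivor conditioning errors
explicitly on all-lethal inputs rather than returning an empty
distribution. Genotype dosages are exact integers throughout, so no
floating-point tie-breaking arises in transmission.

## Known limitations

* The classifier sees the same generative assumptions the simulator
  makes; real screens add scoring error, stage-dependent death and
  environmental effects that are not modelled.
* Carrier calling depends on family phenotype labels being consistent
  across generations; phenotype ontology beyond free-text labels is out
  of scope.
* The per-fish sterility expression model (one Bernoulli draw at
  adulthood) cannot represent fish that switch phenotype over their
  reproductive life.
* Multiple-testing correction across families is deliberately absent,
  matching the analysis style the package reproduces.
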