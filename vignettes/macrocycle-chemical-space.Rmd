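---
title: "Macrocycle chemical space: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrocycle chemical space: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrospace)
```

## The scientific problem

Macrocycles — organic molecules containing a ring of at least 12 heavy
atoms — are a productive source of drugs for difficult targets, yet most of
them live far beyond the Rule-of-5 limits that usually bound orally
available chemical space. The practical question this package addresses is:
*which simple physicochemical properties separate orally bioavailable
macrocycles from those that must be injected, and how should those
properties be counted for molecules that are substantially ionised at
physiological pH?*

The package implements the full analysis chain: descriptor computation
under pH-7.0 counting conventions, data-driven descriptor cutoffs,
conjunctive classification rules with chance-corrected quality statistics,
hydrogen-bond-donor chemotyping, 3D shape characterisation, and PCA mapping
of descriptor space — plus a synthetic-data generator so that every stage
is testable without proprietary descriptor software or curated drug tables.

## Charge-state model

Descriptors are computed on the *major microspecies at pH 7.0*, assigned by
deterministic structural rules rather than a pKa microspecies enumeration:

* **protonated (+1 per basic centre):** aliphatic amines, amidines,
  guanidines (pKa roughly 10–13);
* **deprotonated (−1):** carboxylic, sulfonic and (once per group)
  phosphonic/phosphoric acids, acylsulfonamides, tetrazoles (pKa roughly
  0–5);
* **unchanged:** phenols, alcohols, amides, anilines, pyridines and any
  group the rules do not recognise.

Rule-based assignment is deliberate: it is dependency-free, reproducible,
and idempotent by construction (every rule fires only on a formally neutral
centre). The cost is that zwitterion-capable borderline cases (e.g.
pKa ≈ 7 phosphate second ionisations) follow the fixed rule rather than a
titration model. Heavy-atom skeleton and bond orders are never altered —
only formal charges and hydrogen counts change.

## Counting conventions

Two counts deviate deliberately from the Rule-of-5 dialect, and both are
computed on the charge-state-resolved structure:

* **HBD** is the number of hydrogens on any N or O *without a negative
  formal charge*. A protonated secondary amine therefore donates two
  hydrogens where the neutral form donates one, and a deprotonated
  acylsulfonamide or carboxylate donates none.
* **HBA** is the number of N, O and F atoms, *excluding* nitrogens that are
  positively charged, in higher oxidation states (bonded to two or more
  oxygens: nitro, N-oxide) or pyrrole-type (aromatic N donating its lone
  pair into the ring, whether or not it carries an H).

Aromaticity, needed for the pyrrole exclusion, the aromatic-ring count and
phenol typing, is perceived with a Hückel-style electron count on the
Kekulé structure: a ring double bond contributes one π electron per atom, a
saturated N/O/S lone pair two, an exocyclic double bond zero; a five- or
six-membered ring is aromatic when the sum is six. This reproduces the
standard assignments (benzene, pyridine, pyrrole, furan, imidazole,
2-pyridone, fused bicyclics) but is not a universal model — exotic
kekulisations of large fused polycycles may be missed.

## The descriptor panel

`compute_panel()` fills, per molecule and charge state: MW (Da, average
masses, implicit hydrogens included), nC, cLogP, cLogS, cLogD, TPSA, HBD,
HBA, NRotB, NAR, the Kier flexibility index Φ, the largest SSSR ring size
and the tetrahedral stereocentre count. Notes on the individual choices:

* **Ring perception** is smallest-set-of-smallest-rings, built from
  shortest-cycle-per-edge candidates filtered by GF(2) linear independence;
  a macrocycle is a molecule whose largest SSSR ring has ≥ 12 heavy atoms.
  Fused systems report the largest member ring (naphthalene is a 6, not a
  10).
* **TPSA** uses the Ertl fragment scheme as implemented in OpenBabel, which
  includes the charged N/O fragment contributions — verified against the
  published fragment values (e.g. carboxylate 17.07 + 23.06 Å²).
* **cLogP** is an atom-contribution estimate (OpenBabel) on the *neutral*
  species; absolute values differ from commercial engines, so analyses on
  real compounds should treat lipophilicity comparatively.
* **cLogS** is the ESOL-style estimation equation
  `0.16 − 0.63·cLogP − 0.0062·MW + 0.066·NRotB − 0.74·AP` (AP = aromatic
  proportion of heavy atoms), in log mol/L.
* **cLogD** is approximated as cLogP minus 3 log-units per ionised centre
  of the rule-protonated species. It exists only to feed the AB-MPS score
  and is documented as an approximation wherever it appears.
* **NRotB** counts non-ring single bonds between two non-terminal heavy
  atoms, excluding amide C–N bonds (the strict dialect); the exclusion is
  switchable via `exclude_amide`.
* **Φ** is the Kier flexibility index, `¹κα·²κα / A`, with the
  covalent-radius α-correction and hybridisation-dependent radii. A linear
  alkane scores its heavy-atom count minus one (n-hexane: 5.0);
  cyclisation reduces it sharply (cyclohexane: 1.54).
* **Stereocentres** are tetrahedral candidates (defined + undefined): sp3
  carbons whose four substituents fall into distinct Morgan-refinement
  equivalence classes. This is not a full CIP implementation; rare
  meso/para-stereocentre cases may be miscounted.

Metal-containing structures are refused with an explicit error — their
descriptors are unreliable — and multi-fragment inputs (salts, mixtures)
are reduced to the largest organic fragment with ties broken by molecular
weight, then canonical SMILES, mirroring the major-component convention of
curated drug sets.

## Cutoffs and classification rules

`derive_cutoff()` operationalises "the intersection of the two class
density curves": Gaussian kernels, Silverman's bandwidth per class, a
512-point grid spanning the pooled range padded by three bandwidths, and
linear interpolation of the sign change of the density difference. The
*major* intersection is the crossing lying between the two class medians;
if several qualify, the one with the highest pooled density wins; if none
exists the midpoint of the medians is used with a warning. Discrete
descriptors (HBD, HBA, NRotB, NAR, ...) get a rounded cutoff with inclusive
(≤/≥) semantics; continuous ones keep the raw crossing with strict (</>)
semantics — matching the printed forms of the published guideline cutoffs
(HBD ≤ 7; MW < 982 Da, cLogP > 2.22, TPSA < 292 Å²).

Classifiers are conjunctions of one to three such conditions, with orals as
positives. `classifier_metrics()` computes sensitivity, specificity, GMean,
accuracy and Cohen's kappa; `enumerate_models()` ranks all
k-descriptor combinations by kappa (ties: accuracy, then GMean), because
kappa is the chance-corrected figure the analysis treats as its headline
reliability measure. Test-set evaluation reuses training-derived cutoffs.
The AB-MPS score, `|cLogD − 3| + NAR + NRotB` with oral cutoffs at 14/15,
is provided as the external benchmark.

## Shape analysis

`compute_npr()` diagonalises the mass-weighted inertia tensor about the
centre of mass and reports NPR1 = I1/I3, NPR2 = I2/I3. Hydrogens are
included and atoms mass-weighted by default (both switchable and recorded
in the result). Classification is by nearest vertex of the rod (0, 1),
disc (0.5, 0.5), sphere (1, 1) triangle; a point exactly equidistant
between two vertices is assigned to the later one in rod < disc < sphere
order, so ties resolve toward the more three-dimensional class. Conformer
generation and ligand extraction from complexes are out of scope: the
module takes already-extracted coordinates (SDF or PDB HETATM records).

## PCA mapping

`pca_map()` autoscales columns before eigendecomposition. The scaling
decision matters: with MW in Daltons against unit-scale counts, unscaled
PCA would be MW-dominated, contradicting the observed pattern in which
lipophilicity makes the largest contribution. Signs are fixed by making the
dominant loading of each component positive; class ellipses are covariance
ellipses scaled by the χ²(0.95, 2) quantile; an optional MW cap (off by
default, 1500 Da in the replication setting) excludes very large
parenterals; the default descriptor set drops the redundant nC, NAR and Φ.

## The synthetic generator

`generate_labelled_table()` emulates the statistical structure the
analyses assume: class sizes default to 24 orals / 38 parenterals (the
oral/parenteral split of the approved-macrocycle analysis set), log-normal
MW and TPSA, normal cLogP/cLogS/cLogD, Poisson counts, and a Gaussian
copula linking MW and TPSA with the normal-scores correlation set to
`2·sin(π·ρS/6)` so the *Spearman* correlation of the output matches the
configured value (0.8 by default). Default medians (oral MW 750 vs
parenteral 1100; cLogP 4 vs 0; TPSA 180 vs 320; HBD 4 vs 9; HBA 10 vs 16;
NRotB 8 vs 14) are synthetic stand-ins chosen once to reproduce the
documented qualitative ordering — orals smaller, more lipophilic, less
polar, less flexible — and are not published values. Generation is
deterministic per (configuration, seed) and restores the caller's RNG
state.

What passing tests on this generator demonstrate is recovery of *known*
statistical structure: marginal medians within 2% at n = 10 000, rank
correlation within ±0.05, correct selection of the informative descriptor
pair when only two descriptors carry signal. What they cannot demonstrate
is behaviour on real descriptor distributions, which are heavier-tailed,
multimodal (natural-product families) and correlated beyond the single
MW–TPSA link modelled here.

Fixture structures complement the statistical generator with analytic
ground truth: cyclo(Gly)~n~ (ring size exactly 3n, n amide N–H),
macrolactones (ring-size parameter, zero donors) and partially
N-methylated cyclic peptides (11 residues with 7 N-methyls reproduces the
four-amide donor pattern of cyclosporin).

## Worked example

```{r example, eval = FALSE}
# descriptor conventions on a protonatable amine
amine <- parse_structure("CCNCC", id = "diethylamine")
count_hbd(amine, "neutral")   # 1
count_hbd(amine, "ph7")       # 2  (protonated at pH 7)

# cyclosporin: 33-membered ring, four amide donors
csa <- parse_structure(cyclosporin_a_smiles, "cyclosporin_a")
detect_macrocycle(csa)        # ring 33, macrocycle
classify_hbds(csa, "ph7")     # amide_NH = 4, aliphatic_OH = 1

# synthetic two-class population -> cutoffs -> ranked bi-descriptor models
tab <- generate_labelled_table(generator_config(n_oral = 150,
                                                n_parenteral = 150,
                                                seed = 7))
res <- enumerate_models(tab, c("HBD", "MW", "cLogP", "TPSA"), order = 2)
head(res$ranking, 3)
```

## Numerical choices and degenerate inputs

* Implicit hydrogens follow a standard valence model (charge-adjusted
  default valences; hypervalent S/P/I pick the smallest allowed valence not
  below the bond-order sum).
* Φ is undefined below three heavy atoms and returned as `NA`.
* `derive_cutoff()` requires ≥ 5 finite values per class and refuses
  identical classes; `classifier_metrics()` refuses one-class inputs and
  signals the (theoretically unreachable under those preconditions)
  p~e~ = 1 kappa case explicitly.
* `compute_npr()` requires two non-coincident atoms; two-atom and collinear
  inputs are valid rod limits (I1 = 0).
* Constant descriptor columns are dropped from PCA with a warning;
  collinear score clouds flag a degenerate ellipse.
* Human-readable reports round half-even to two decimals; machine outputs
  keep full precision.

## Problem sizes used in the checks

The packaged checks run the statistical recoveries at n = 10 000 draws
(cutoff recovery, marginal/correlation recovery, isotropic PCA split),
1 000 random cases for the metric and triangle invariants, and 20
generator seeds for the model-selection recovery — sizes at which the
sampling bands quoted above are comfortably resolved while the whole suite
stays fast.

## Known limitations

* Lipophilicity/solubility estimates are open-scheme approximations;
  absolute agreement with commercial engines is out of scope by design.
* The aromaticity model and stereocentre count are conventional
  approximations (see above), adequate for drug-like input.
* The protonation rules ignore tautomerism and microspecies populations.
* Binding-site classification, conformer generation and literature
  curation are outside the package's scope.
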