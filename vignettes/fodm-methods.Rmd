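---
title: "Scoring hydrophobicity distributions with the fuzzy-oil-drop model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring hydrophobicity distributions with the fuzzy-oil-drop model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

A water-soluble globular protein behaves, to first approximation, like a
micelle: hydrophobic side chains concentrate in the centre and polar ones
coat the surface. The fuzzy-oil-drop picture makes this continuous. Each
residue is collapsed to one *effective atom* (the unweighted mean of its
heavy-atom coordinates), and an idealised hydrophobicity density — a 3D
Gaussian spread over the molecular body — is evaluated at those points,
giving the **theoretical profile** $T$:

$$T_i \propto
  \exp\!\Big(\!-\frac{x_i'^2}{2\sigma_x^2}\Big)
  \exp\!\Big(\!-\frac{y_i'^2}{2\sigma_y^2}\Big)
  \exp\!\Big(\!-\frac{z_i'^2}{2\sigma_z^2}\Big),
  \qquad \textstyle\sum_i T_i = 1,$$

with primed coordinates in the principal-axis frame of the effective-atom
cloud. What the structure actually does is summarised by the **observed
profile** $O$, accumulated from distance-damped pairwise hydrophobic
interactions,

$$O_i \propto \sum_{j \ne i} (H_i + H_j)\, f(r_{ij}),$$

where $H$ is an intrinsic hydrophobicity scale and $f$ a polynomial contact
function vanishing at a cutoff $c$. The **uniform reference** $R_i = 1/n$
represents no differentiation at all. Agreement is measured with
Kullback–Leibler divergence (bits), and the two distances are combined into
the relative-distance score

$$RD = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|R)} \in [0, 1],$$

where $RD < 0.5$ means $O$ is closer to the micelle-like ideal than to no
order at all.

Membrane-embedded structures invert the picture: hydrophobicity is exposed
on the surface, and channels carve a polar or empty centre. The modified
target field blends the Gaussian with its normalised complement,

$$M_i(K) = \big[T_i + K \, (T_{\max} - T_i)_n\big]_n,$$

($[\cdot]_n$ denoting normalisation to sum 1). The
**environment-participation parameter** is the $K \ge 0$ minimising
$D_{KL}(O\,|\,M(K))$: near 0 for idealised water-soluble folds, roughly
0.2–0.5 for most soluble proteins, and above 1 for membrane-embedded
structures. A useful landmark is the *R-equivalence* $K$ — the value at
which $M(K)$ comes closest to uniform, i.e. where the Gaussian and its
complement balance; systems optimised beyond it are dominated by the
inverted field.

## Analysis granularities

`analyze()` reproduces the bookkeeping used for multi-chain channel
proteins:

* **complex** — one Gaussian over all selected chains;
* **domain_set** — the corresponding domain fragments of every chain,
  treated as a body of their own (a fresh Gaussian is fitted to the set);
* **chain** / **individual_domain** — a single chain or fragment as an
  isolated structural unit, again with its own Gaussian;
* **fragment_in_complex** — no new Gaussian: the fragment's $T$ and $O$
  values are sliced out of the parent complex's profiles, renormalised, and
  $R$ rebuilt as $1/n_{\text{fragment}}$. This scores the *role a fragment
  plays inside the complex*, interactions with all partners included,
  rather than its viability as an isolated unit.

The distinction matters: a membrane domain scored inside its complex
reflects inter-chain burial, while the same residues refitted alone reveal
what an aqueous environment could or could not have folded.

## Parameters and conventions that matter

Absolute RD and K values depend on a handful of conventions, all recorded
in every output file:

* **Sigma rule.** The Gaussian's extent is tied to the molecule by
  $\sigma_j = \max_i |x'_{ij}| / 3$ per principal axis, which places every
  residue inside the $3\sigma$ ellipsoid and the surface at the field's
  near-zero tail. An optional fractional margin (`sigma_margin`, default 0)
  inflates the extent before division; flat fragments are floored at
  $\sigma = 1$ Å with a warning rather than collapsing the field.
* **Interaction kernel.** Levitt-form polynomial,
  $f(r) = 1 - \tfrac12\big(7u^2 - 9u^4 + 5u^6 - u^8\big)$ with $u = r/c$,
  cutoff $c = 9$ Å, zero beyond; `cutoff` and the pair term (`sum`,
  `product`, `partner`) are options because the literature varies here.
* **Hydrophobicity scale.** Any per-residue scale works; the shipped
  default is Kyte–Doolittle rescaled linearly to $[0,1]$
  (`hydrophobicity_scale()`), replaceable by a two-column text file
  (`read_scale()`).
* **K search.** Coarse grid from 0 to `k_max` (default 10) in steps of
  0.01, then golden-section refinement on the bracketing interval. Table
  output rounds K to one decimal; JSON keeps the raw optimum. The upper
  bound is configurable because strongly membrane-subordinated complexes
  optimise beyond 3, and an optimum *at* the bound is flagged (`at_bound`).
* **Zero handling.** $D_{KL}$ uses $0 \log 0 = 0$ and floors the reference
  distribution at $10^{-12}$ without renormalising; the Gaussian $T$ is
  strictly positive, so the floor only matters for pathological inputs. If
  no residue pair falls within the kernel cutoff, $O$ falls back to uniform
  with a warning instead of dividing by zero.

Structure input conventions: all heavy atoms enter the effective-atom mean
(side-chain-only averaging is a defensible alternative; the all-atom
reading is the default and the choice is deliberately localised in
`effective_atoms()`), hydrogens are ignored even when present, model 1 of
multi-model entries is used unless asked otherwise, alternate locations
resolve to the highest-occupancy conformer (ties by altloc letter), and
selenomethionine-style residues map to their parent amino acid. Residue
ranges are inclusive and follow author numbering, since published domain
tables are written that way.

## The synthetic generator

`generate_structure()` builds point clouds with controlled hydrophobicity
geometry: a uniformly filled ball whose hydrophobicity decays with radius
as a Gaussian (`two_layer_micelle` — the micelle archetype), the same
cloud with the complementary assignment (`inverted_micelle` — the membrane
archetype), an undifferentiated spherical shell, a filled ellipsoid and a
four-helix CA-trace stub. Defaults — 60 residues, outer radius 16 Å,
0.5 Å coordinate jitter — keep the 9 Å kernel local on the structure's
scale while a residue still interacts with a meaningful neighbourhood;
they were fixed once, from those geometric considerations. The
core-hydrophobic pattern is Gaussian-shaped ($H = 0.02 + 0.9
e^{-6 r_{\!rel}^2}$) rather than a linear ramp because "micelle-like" in
this model *means* hydrophobicity tracking the 3D Gaussian; with it the
micelle archetype scores RD ≈ 0.16–0.42 and K ≈ 0.2 across seeds (the
soluble-protein regime) while the inversion scores RD > 0.65 with K > 1.

`plant_k()` manufactures an observed profile as $M(T, K^\*)$ plus
multiplicative lognormal noise on the simplex (positivity preserved,
renormalised; default $\sigma = 0.05$). Noise-free recovery is exact to
the grid step; under noise the error in the recovered $K$ grows roughly
like $(1+K)^2$ because $\partial M/\partial K$ shrinks as the field
saturates towards the complement — recovery assertions therefore use the
mean over seeds.

What the generator does **not** emulate: peptide-bond connectivity, side
chains, secondary structure, realistic packing densities or crystal-quality
coordinates. Passing fixture tests demonstrates that the mathematics and
bookkeeping are right, not that any particular real protein will score in
a given band; real structures bring correlated geometry and scale effects
the fixtures deliberately avoid.

## Worked example

```{r example}
es <- generate_structure(synthetic_spec(60, "inverted_micelle", seed = 1))
sc <- fod_score(o_profile(es), t_profile(es), r_equiv = TRUE,
                selection_name = "inverted fixture")
sc
```

The same machinery drives file-based analyses:

```{r plan, eval = FALSE}
plan <- read_plan(system.file("extdata", "plans", "4hw9.yaml",
                              package = "fodm"))
es <- effective_atoms(read_structure("structures/4hw9.pdb"))
analyze(es, plan$selections, lenient = TRUE)
```

Packaged plans under `inst/extdata/plans/` encode the published analysis
grids for two MscS channels (heptamers: complex, DD1–DD4 domain sets,
fragments-in-complex, single chain, D1–D4 individual domains), two MsbA
transporter dimers and a water-soluble BRCT control. Structure files are
not redistributable and must be supplied by the user. Two footnotes on
those grids: the MscS source table gives the fourth domain as 261–272 at
the set level but 261–267 at the individual level — both are kept as
printed; and the MsbA table names domains without residue ranges, so the
plans reconstruct them from the standard architecture (transmembrane
domain ≈ 1–320, nucleotide-binding domain ≈ 321–582), which adds an
uncertainty of a few residues at the boundary.

## Numerical and design notes

* Divergences are computed in bits (log base 2); RD and arg-min K are
  base-invariant, profile-level divergences are not.
* The principal-axis rotation fixes eigenvector signs deterministically
  (first non-zero loading positive), so repeated runs are bit-identical;
  `cmd_score`/`cmd_profile` outputs of identical configurations are
  byte-identical.
* `r_equivalence_k()` minimises $D_{KL}(R\,|\,M(K))$. The direction (R
  against M rather than M against R) is a choice; both are exposed through
  `dkl()` directly if the other reading is wanted.
* Degenerate cases are explicit: constant $T$ makes $M(K)$ collapse to $T$
  (warning) and the R-equivalence K undefined (error); $O = T = R$ makes
  RD undefined (`NA` with warning).
* Test and example problem sizes (40–60 residues, 50–100 noise seeds)
  were chosen as the smallest sets at which the archetypes separate
  cleanly and the recovery statistics stabilise.

## Limitations

* The pair term and cutoff of the observed field, and the hydrophobicity
  scale, are conventions the wider literature does not fix uniquely;
  cross-study comparison of absolute RD/K values requires matching the
  convention block recorded in the outputs.
* Fragments-in-complex inherit the parent's Gaussian; for very small
  fragments (a handful of residues) the renormalised slice makes RD and K
  sensitive to a single residue.
* No statistical null model is attached to RD; the 0.5 landmark is a
  geometric statement about relative distances, not a significance level.
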