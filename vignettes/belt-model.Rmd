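---
title: "Modelling detergent belts as hollow cylinders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling detergent belts as hollow cylinders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detbelt)
```

## The problem

A detergent-solubilized membrane protein carries a belt of amphiphile
monomers over its hydrophobic transmembrane surface. The belt is mobile
and irregular in reality, but for reasoning about *how much* detergent a
sample carries — reconstitution planning, interpreting quantification
experiments, sanity-checking "micelle" language — a fast geometric
idealization is more useful than a faithful one. `detbelt` therefore
represents the belt as a hollow cylinder coaxial with the membrane
normal. The shape is deliberately non-physiological; it is an honest
volume bookkeeping device.

## The procedure and its assumptions

The input structure must already be membrane-oriented: z axis normal to
the membrane plane, origin at the membrane centre, as produced by the
OPM/PPM positioning ecosystem. `detbelt` performs no orientation of its
own; a mis-oriented structure gives a meaningless belt.

1. **Height.** `h = 2 d½`. The half-thickness `d½` is read from the
   structure's REMARK line ("1/2 of bilayer thickness:" or a generic
   "HALF-THICKNESS" keyword, case-insensitive, first match wins) or,
   failing that, from the largest |z| of the membrane dummy atoms
   (residue `DUM`), which sit on the two boundary planes. A matching
   REMARK with a non-numeric or non-positive value is an error rather
   than a silent fallback, because a malformed REMARK usually signals a
   mangled file, not a missing one.
2. **Inner radius.** Solvent accessibility is computed for *all* heavy
   atoms — not only transmembrane ones — so that burial by
   extramembranous domains is respected. Atoms with centre |z| ≤ d½ and
   SASA strictly greater than 3 Å² form the exposed transmembrane
   shell; the kernel density of their radial distances is scanned for
   its rightmost qualifying peak, and `r` is that position plus
   1.66 Å (the average heavy-atom van der Waals radius), placing the
   belt wall at the *outside* of the atom shell.
3. **Outer radius.** With total detergent volume `V = Σ Nᵢ vᵢ`,
   `R = sqrt(V/(π h) + r²)`. This closed form is the unique solution of
   the volume-conservation condition `π h (R² − r²) = V`; conservation
   is enforced to 1 part in 10⁶ by the test suite.
4. **Mixtures** become stacked slabs in input order with heights
   `hᵢ = h Vᵢ / V`, so each slab's hollow-cylinder volume equals its
   detergent's volume exactly. Stacking order is a display convention.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `asa_cutoff` | 3 | Å² | strict `>` separates genuinely exposed atoms from crevice atoms whose small areas are numerical noise |
| `vdw_offset` | 1.66 | Å | average heavy-atom van der Waals radius; moves the belt from atom centres to the atom surface |
| `probe_radius` | 1.4 | Å | standard water probe |
| `n_points` | 960 | — | Shrake–Rupley lattice size; areas at 960 and 4000 points differ by < 1 % on test clusters |
| `kde_bandwidth` | Silverman | Å | reproducible rule-of-thumb; an explicit bandwidth is accepted |
| `peak_min_fraction` | 0.10 | — | local maxima below 10 % of the global density maximum are ignored, so a stray outermost atom cannot define the belt |
| `inner_radius_override` | — | Å | manual belt wall for grooved oligomers and large complexes; V is preserved, R recomputed |

## Numerical choices

**SASA.** The Shrake–Rupley algorithm with a deterministic
Fibonacci-lattice point set makes every area a pure function of the
coordinates — no RNG, reproducible across runs, and directly testable
against closed forms (isolated sphere, two-sphere spherical caps) and an
independent Monte-Carlo surface-sampling oracle. Neighbour search uses a
uniform-grid cell list whose results are asserted identical to the
all-pairs scan. Van der Waals radii are the Bondi set; unlisted elements
fall back to 1.70 Å with a warning.

**Peak detection.** The density is evaluated on a fixed 512-point grid
over `[max(0, min − 3bw), max + 3bw]`. A local maximum qualifies if its
density is at least `peak_min_fraction` of the global maximum; the
largest-radius qualifying maximum wins. The guard fraction exists
because the "rightmost peak" is otherwise undefined against outliers: a
single detached atom at large radius produces a genuine local maximum of
negligible mass. When all radial distances coincide (as in the
jitter-free test fixture) the distribution is a point mass; the profile
is flagged degenerate and the peak is the common value itself, avoiding
a zero-bandwidth KDE.

**Transmembrane membership** is decided per atom centre (|z| ≤ d½,
inclusive). A residue-level rule would change little on real structures
and would complicate the synthetic fixtures.

**Degenerate inputs.** An empty structure, an all-dummy structure, a
structure that never enters the slab, a zero monomer count, and an
all-zero volume mixture each fail with a classed, stage-labelled error;
the CLI maps the classes to distinct exit codes.

## Monomer volumes

The nominal volume of one monomer converts counts into belt volume.
The shipped database computes volumes with an additive van der Waals
scheme: atomic increments (C 20.58, H 7.24, N 15.6, O 14.71, S 24.43,
P 24.87 Å³) minus 5.92 Å³ per bond, 14.7 Å³ per aromatic ring and
3.8 Å³ per non-aromatic ring. For a connected molecule the bond count is
`atoms − 1 + rings` independent of bond order. The scheme is
deterministic, transparent, and additive over fragments (asserted in the
tests); it underestimates the *packing* volume of a monomer in a real
belt, which includes free volume beyond the van der Waals envelope, so
absolute belt thicknesses are conservative. Every volume is labelled
with its provenance (`additive_estimate` or `curated`) and can be
overridden per run — a user with a measured partial specific volume
should prefer it. The amphipol A8-35 entry is curated from its average
molar mass and specific volume (0.81 mL/g), since a polymer has no
single molecular composition. Sodium cholate's volume is computed from
the cholic acid composition (the increment table carries no sodium).

## What the synthetic fixtures emulate

The fixture generator builds rings of carbon pseudo-atoms at a known
radius — an idealized transmembrane barrel — with optional Gaussian
radial jitter and an optional smaller decoy shell that mimics grooves
and inner surfaces. This gives every stage an analytically known answer:
the pipeline must recover `r = ρ + 1.66 Å` on a noiseless shell, stay
within 0.5 Å under 0.5 Å jitter, and pick the outer of two shells. What
the fixtures deliberately do *not* emulate: side-chain packing, mixed
element composition, tilted or conical transmembrane domains, and
surface roughness correlated along z. Passing tests therefore validate
the geometry and the selection logic, not the biological accuracy of the
hollow-cylinder idealization — which is a modelling choice, not a claim.

Problem sizes in the test suite (180–360-atom fixtures, 2 000-point
lattices, 10⁵-point Monte-Carlo oracles, 50–100 seeded replicates) were
chosen so the full suite characterizes the estimator's error bands while
completing in well under a minute.

## Known limitations

- The belt is a right circular hollow cylinder; tori, ellipses and
  locally deformed belts are out of scope.
- No per-monomer placement: the pseudo-atom output samples the annulus
  uniformly and is a visualization aid, not a configuration.
- Monomer volumes are van der Waals estimates, not measured partial
  volumes; comparisons across volume methods shift R by a few percent.
- Structures are trusted to be correctly membrane-oriented.
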