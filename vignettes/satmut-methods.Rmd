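---
title: "satmut: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{satmut: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmut)
```

This vignette documents the physical model implemented by `satmut`, the
protocols built on top of it, and every numerical choice that affects results.
All quantities are in kcal/mol, Å, and pK units unless stated otherwise.

## 1. Scope and assumptions

`satmut` estimates the *relative* effect of point substitutions at chosen
sites of a two-chain protein complex. It is a screening model, not a
quantitative free-energy method:

- The backbone is held fixed; only side chains are rebuilt and relaxed.
- The unfolded state is represented by a short excised peptide segment, not a
  simulated ensemble.
- Binding is rigid-body: monomers are taken bit-identically from the complex,
  with no post-separation relaxation.
- Solvation is implicit (generalized Born); there are no explicit waters,
  no entropy terms, and no bonded (bond/angle/torsion) energy terms — with a
  fixed backbone and ideal side-chain geometry these cancel to first order
  between wild type and mutant.

Differences between mutant and wild type under identical protocols are the
only quantities the model is intended to rank.

## 2. Energy model

The potential is a sum over nonbonded atom pairs of Lennard-Jones, Coulomb and
generalized-Born terms:

$$E = \sum_{i<j} w_{ij}\!\left[ 4\epsilon_{ij}\!\left(\frac{\sigma_{ij}^{12}}{r_{ij}^{12}} - \frac{\sigma_{ij}^{6}}{r_{ij}^{6}}\right) + k_e \frac{q_i q_j}{\varepsilon_{in} r_{ij}} \right] - \frac{k_e \tau}{2} \sum_{i,j} \frac{q_i q_j}{f^{GB}_{ij}}$$

with $k_e = 332.0636$ kcal·Å/(mol·e²) and
$\tau = 1/\varepsilon_{in} - 1/\varepsilon_{out}$.

**Combination rules.** Lorentz–Berthelot: $\sigma_{ij} = (\sigma_i +
\sigma_j)/2$, $\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}$.

**Exclusions.** Pair weights $w_{ij}$ come from the bond separation on the
*global* bond graph (covalent template bonds plus peptide links, including
across chains' internal rings): 1-2 and 1-3 pairs are excluded ($w = 0$), 1-4
pairs are scaled by $w = 0.5$, everything else is $w = 1$. The masks are built
with sparse boolean matrix products, so cost scales with the number of bonds,
not atoms².

**Generalized Born.** The Still pairwise energy
$f^{GB}_{ij} = \sqrt{r_{ij}^2 + B_i B_j \exp(-r_{ij}^2 / 4 B_i B_j)}$ uses
HCT pairwise-descreening effective Born radii with a descreening scale of 0.8
applied to the intrinsic radii. Two numerical guards apply: pair
contributions beyond 12 Å are dropped from the descreening sum (they are
negligible and this bounds the cost), and the inverse effective radius is
clamped below at 1/1000 Å⁻¹ so that heavily descreened atoms get a large but
finite Born radius instead of a negative one. The GB sum runs over *all*
pairs plus self-terms; exclusion weights apply only to the LJ and Coulomb
terms.

**Parameter sets.** Three bundled sets, `ff_a`, `ff_b` and `ff_c`
(`default_forcefields()`), share atom typing but differ in charges, LJ well
depths and GB radii; all use $\varepsilon_{in} = 1$, $\varepsilon_{out} =
78.5$. Averaging effects over the three sets (the default in `scan_site()`)
damps parameter-set idiosyncrasies. Parameters are stored as plain TSV in
`inst/extdata` and can be replaced via `read_forcefield()`; per-set residue
net charges are integral by construction (`net_charge()` checks this).

## 3. Mutagenesis

`saturation_scan()` produces, per site, the 19 substitutions other than the
wild type, in alphabetical order of one-letter code. `mutate_residue()`
rebuilds the target side chain with ideal bond lengths and angles over a small
backbone-independent rotamer library, keeping N, CA, C, O and CB-direction
fixed, and picks the rotamer with the lowest heavy-atom clash score
(soft-sphere overlap against all atoms outside the rebuilt side chain, with
bonded and geminal neighbours excluded). Glycine and alanine need no rotamer
choice; proline substitutions at positions whose backbone φ is far from the
proline range are flagged (`pro_strain`) but still scored.

After placement, `relax()` runs torsion-space coordinate descent on the χ
angles of all side chains with any atom within `relax_radius` (default 5 Å) of
the mutated side chain. Each sweep tries, per χ, the deltas
{−120, −60, −30, −10, +10, +30, +60, +120, +180}° and keeps the best;
sweeps stop when the energy improves by less than 0.01 kcal/mol or after
`relax_sweeps` (default 4) sweeps. Ties keep the current angle (first
improvement wins), which makes the protocol deterministic. The wild type is
passed through the *same* relaxation before computing differences, so protocol
bias cancels.

## 4. Folding and binding protocols

**Folding.** `folding_energy()` computes $\Delta G_{fold} = G(\text{chain}) -
G(\text{segment})$, where the segment is an excised window of odd length
`seg_len` (5, 7 or 9; default 7) centred at the site and truncated at chain
termini. The folding *effect* of a substitution is
$\Delta\Delta G = \Delta G_{fold}(\text{mut}) - \Delta G_{fold}(\text{wt})$:
negative values mean the substitution destabilizes the fold. Both monomers of
the homodimer are scanned and the per-chain values averaged.

**Binding.** `binding_energy()` computes $\Delta G_{bind} = G(CD) - G(C) -
G(D)$ with monomers split bit-identically from the dimer coordinates. The
binding effect is again mutant minus wild type, averaged over the two choices
of mutated chain.

`scan_site()` orchestrates both per substitution and per parameter set and
returns per-set columns plus the across-set average. `flip_sign = TRUE`
flips the reported sign convention when the opposite one is preferred for
reporting.

## 5. Titration model

`find_titratable()` selects ASP, GLU, HIS, LYS, ARG, CYS and TYR with model
pKas 4.0, 4.4, 6.3, 10.4, 12.0, 8.3 and 9.6. Cysteines and tyrosines are
treated as neutral by default in the *structure* charge assignment (their
model pKas are far from neutral pH); they still titrate in the titration
system itself.

For each site the intrinsic pKa is the model pKa shifted by the desolvation
and background-interaction free energies of ionizing that site alone,
converted at 1.364 kcal/mol per pK unit ($k_BT \ln 10$ at 298 K). Site-site
couplings $W_{ij} \ge 0$ are screened Coulomb interactions between the
ionizable-group charges. Protonation curves come from exact enumeration of
all $2^n$ microstates when $n \le 20$, otherwise from single-site Metropolis
Monte Carlo (a seed is then mandatory; the default is 10 000 sweeps with a
20% burn-in). pKa½ is the pH at which a site's protonated fraction first
crosses 0.5 on the pH grid (default 0 to 14 in 0.1 steps), linearly
interpolated; sites that never cross get sentinel values −1 (below the grid)
or 15 (above), and are flagged `out_of_range`. Non-monotonic curves are
flagged but still reported at their first crossing.

The per-substitution ionization effect is the cumulative shift
$\sum_k |\Delta\text{p}K_{a,k}|$ over all sites paired between wild type and
mutant — absolute values are taken *before* summing, so opposite shifts do
not cancel. `flag_ionization_discrepancy()` compares Henderson–Hasselbalch
ionized fractions at pH 7 (the default) between monomer and dimer and flags
sites whose fraction differs by more than 0.5.

## 6. Classification

`site_profile()` requires exactly 19 finite effects. The spread statistic is
the *population* standard deviation $\sigma$ (divide by $n$; `std_mode =
"sample"` is available), the threshold is the half standard deviation
$\text{HSTD} = \sigma/2$, and z-scores are $(x - \bar x)/\sigma$.

- **Tolerance:** a site is *non-tolerable* iff $|\bar x| > \text{HSTD}$
  (strict inequality; equality stays tolerable).
- **Specificity:** a site is *specific* iff strictly more than 20% of the 19
  substitutions fall beyond the HSTD *and* such outliers occur in both
  directions (some above $+\text{HSTD}$ and some below $-\text{HSTD}$).
- **Ionization:** a site is *sensitive* iff the mean cumulative shift exceeds
  2 pK units, and *specific* iff the range (max − min) exceeds 2.

`classify_site()` records both formal labels and a rationale string. A
`prose_override` field lets a human annotation coexist with the formal label
without replacing it — the formal, rule-derived label is never silently
edited. `site_report()` writes JSON and TSV reports with substitutions
ordered by ascending z-score.

## 7. Synthetic test system

`build_toy_dimer()` generates a deterministic, seeded homodimer: two
identical 22-residue chains built by ideal-geometry (NeRF) placement as a
β-hairpin, stacked by translation, with side chains cleaned up by a greedy
rotamer search and a small seeded coordinate jitter (0.02 Å). Three sites
realize distinct archetypes: a solvent-exposed loop glycine (residue 11), an
interface valine (residue 15, < 5 Å from the partner chain) and a buried
isoleucine (residue 7, highest neighbour count). The sequence seeds acidic,
basic and polar residues so that titration and electrostatics are non-trivial;
`build_negative_pocket()` can acidify the environment of a chosen site.

The generator's purpose is to exercise every code path reproducibly at small
size — 22 residues per chain is the package's own choice, small enough that a
full three-set, 19-substitution scan of one site completes in minutes on one
CPU, and large enough to have genuine buried, interface and loop environments.
It makes no claim of structural realism.

`effect_table_fixture()` and `make_titration_fixture()` supply seeded,
affine-standardized effect tables (exact regime mean/σ per archetype and
metric) and random titration systems for testing the statistics and the
classifiers independently of the energy engine.

## 8. Orchestration and artifacts

`run_config()` captures every knob (mandatory seed, input PDB or synthetic
spec, sites, parameter sets, segment length, pKa options, relax radius and
sweeps, std mode, output directory). `run_scan()` writes `run.log`,
`config.json`, `input.pdb`, `effects.tsv` (long format: site, metric, aa,
value), `effects_wide.tsv`, `report.json` and `report.tsv`; reruns with the
same config are byte-identical. `run_classify()` re-derives labels from an
effects TSV alone, validating that every (site, metric) group has exactly 19
numeric values and reporting offending line numbers otherwise. The
`inst/scripts/satmut` wrapper exposes `synth`, `scan` and `classify`
subcommands from the shell.

## 9. Reproducibility notes

All stochastic elements (toy-structure jitter, Monte-Carlo titration,
fixtures) consume an explicit integer seed; no global RNG state is left
modified. Real PDB input is read with altLoc resolution by highest occupancy
(first record on ties), insertion-code awareness, and a residue-numbering
offset so that reported site numbers can match a chosen reference numbering.
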