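---
title: "Methods: amino acid propensities for lipid head and tail contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino acid propensities for lipid head and tail contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipropen)
```

## The model

`lipropen` quantifies how the twenty amino acid types are used by
proteins to contact phospholipids, separately for the hydrophilic head
group and the hydrophobic tail group of the lipid. The analysis has four
layers, each exposed as its own function family:

1. **Geometry**: atomic contacts between a protein chain and lipid
   molecules, classed as hydrogen bonds, van der Waals contacts or salt
   bridges.
2. **Partition**: every lipid heavy atom is assigned to the head or tail
   group from the molecular bond graph.
3. **Statistics**: per-chain propensity scores, their averages with
   standard errors, and pooled signed chi-square enrichment tests.
4. **Comparison**: Pearson correlation between propensity vectors and
   experimental lipophilicity scales, with jackknife errors.

The propensity of residue type $i$ in one chain is

$$P_i = \frac{N_i^b / N_i}{N^b / N},$$

the binding fraction of type $i$ normalized by the chain's overall
binding fraction. It is undefined when the chain has no residue of type
$i$ (such chains are excluded from the average for that type), zero when
the type is present but never binds, and the weighted mean
$\sum_i (N_i/N) P_i$ equals 1 exactly for every chain — an algebraic
identity the test suite asserts on every synthetic chain. Counts always
cover the entire chain, including extra-membranous loops; no
membrane-segment masking is applied.

For a trajectory, the binding count of residue $k$ is the fraction of
snapshots in which it contacts any lipid,
$N_k^b = \sum_t I_k(t) / \sum_t 1 \in [0,1]$, and per-type counts are
sums of these occupancies. With all occupancies 0 or 1 this reduces
exactly to the single-structure computation, which is also tested.

Pooled enrichment uses the one-cell goodness-of-fit statistic
$\chi_i^2 = (O_i - E_i)^2 / E_i$ with $E_i = N_i N^b / N$ over the
pooled dataset, reported with the sign of $O_i - E_i$ and an upper-tail
1-d.f. p-value. Only chains with at least six binding residues for the
given contact class enter the pool, the threshold being applied per
class independently (a chain can qualify for tail but not head).

## Contact criteria and their parameters

All parameters live in `geometry_params()` (distances in Å, angles in
degrees):

| parameter | default | role |
|---|---|---|
| `da_max` | 3.9 | donor–acceptor distance, strict upper bound |
| `ha_max` | 2.5 | hydrogen–acceptor distance, inclusive upper bound |
| `min_angle` | 90 | lower bound on D–H–A, D–A–AA, H–A–AA |
| `aromatic_axis_max` | 20 | D–A–AX / H–A–AX bound for amino-aromatic bonds |
| `vdw_tolerance` | 0.5 | allowance above the atomic radii sum |
| `salt_bridge_max` | 4.0 | charged heavy-atom pair distance |

The hydrogen-bond thresholds follow the HBPLUS defaults. The
hydrogen–acceptor criterion is implemented as $\le 2.5$ Å: a point
equality would be physically meaningless, and 2.5 Å is the standard
maximum. The van der Waals radii are a bundled per-element table (C 1.7,
N 1.55, O 1.52, S 1.8, P 1.8 Å), overridable through the `radii`
argument; unknown elements fall back to 1.7 Å with a message. Salt
bridges have no universally fixed criterion; we use oppositely charged
heavy atoms within 4.0 Å, with ARG/LYS/HIS side-chain nitrogens and
lipid quaternary amines positive, ASP/GLU carboxylates and lipid
phosphate oxygens negative. All three classes are pooled into the binary
bound/unbound flags that the propensity statistics consume, so the exact
boundary between the classes does not move the headline numbers; when
one atom pair satisfies several criteria it is recorded once with
precedence hbond > salt > vdW.

Polar hydrogens are placed at idealized geometry (1.0 Å bonds; sp2
donors planar, rotatable sp3 donors — hydroxyls and the lysine
ammonium — sampled in 10° azimuth steps on the tetrahedral cone and
oriented toward the nearest acceptor within 5 Å). Lipid hydrogens are
never placed: acyl and choline hydrogen positions are unreliable, so
lipids act only as hydrogen-bond acceptors (their oxygens) and charge
centers. Chain-initial amides and prolines receive no backbone
hydrogen. Residues missing backbone atoms are skipped with a warning;
missing side-chain donor atoms are skipped silently, which lets the
engine run on reduced side-chain models.

Neighbor searching uses a cell-list grid with cells the size of the
cutoff, asserted equal to a brute-force all-pairs scan on random
instances for every contact type. Contact detection is invariant under
rigid-body motion to 10⁻⁶ Å, also asserted.

## The head/tail partition

The tail group is the set of acyl-chain atoms from the carbon *next to*
the ester carbonyl carbon through the terminal methyl; the carbonyl
carbon, both ester oxygens, glycerol, phosphate and the polar
substituent are head. We read this literally: it keeps the
hydrophobic/hydrophilic split clean, since the carbonyl/ester atoms are
polar. Mechanically, ester carbonyl carbons are recognized in the bond
graph (a carbon with exactly one terminal oxygen, one bridging oxygen
and a carbon neighbor — a pattern that deliberately does not match free
carboxylates such as a serine head group), and the tail is grown from
the adjacent acyl carbon along carbon–carbon bonds only. Phosphorus in
the tail is treated as an internal error.

Ether-linked and other mimetic lipids have no carbonyl, and "the
corresponding carbon" cannot be derived mechanically; the registry
therefore carries an explicit per-lipid `TAIL_START_ATOMS` override.
The bundled registry ships the 98 curated phosphoglyceride HET IDs with
no overrides; overrides must be curated per lipid when mimetic
compounds are analyzed. Bond graphs come from a chemical-component
dictionary file when available (`read_ccd_bonds()`), else from a
heavy-atom distance cutoff of 1.9 Å (`bonds_from_distance()`), because
deposited lipids often lack CONECT records.

## Dataset construction rules

`screen_structure()` implements the dataset filters: X-ray entries at
4.0 Å resolution or better (entries without a resolution record, e.g.
NMR, are rejected), chains of at least 30 residues, no non-standard
residues except selenomethionine, which is read as MET. Altloc
conformers keep the highest occupancy, ties resolved toward altloc "A".
Waters and non-registry heteroatoms are ignored. Sequence clustering
and TM/non-TM annotation are *inputs* (a sidecar TSV), not
computations: reproducing them would require external databases.
`select_representatives()` keeps, per cluster, the chain with the most
lipid-contacting residues, discards clusters whose members all have
fewer than five, and breaks ties lexicographically for determinism. The
"no lipid contacts" chain filter needs the contact engine, so it is
applied after screening, before representative selection.

## Trajectories

The per-snapshot contact criterion is not standardized; we default to a
heavy-atom distance cutoff (any residue heavy atom within 4.5 Å of any
lipid heavy atom of the given group), the MD-community norm, because
placing hydrogens in every frame is costly and their positions in
snapshots are force-field artifacts anyway. The full crystal-style
criteria remain available per frame via `criteria = "hbplus"` for users
who want strict comparability with the single-structure analysis. All
provided frames are used; subsampling is a property of the input. A
residue-range `mask` can exclude segments (e.g. a large
extra-membranous domain) from the counts.

When several trajectories are analyzed, their per-protein propensities
are averaged — the same procedure as for crystal chains — rather than
pooling raw counts; pooling remains possible by summing the count
tables before `chain_propensity()`.

## Correlations

Correlations always use raw values (no ranks, no rounded
intermediates); undefined propensities propagate as missing and shrink
the intersection, and $N$ in the jackknife is the intersection size.
The jackknife variance factor is $(N+1)/N$ by default, matching the
convention of the analyses this package follows; the textbook factor is
$(N-1)/N$ (`conventional = TRUE`), and results should state which was
used. For 20 points the two differ by under 5% in the standard error.
Reference vectors bundled for comparison (`reference_propensities()`,
`lipophilicity_scales()`, `reference_contact_counts()`) are printed to
2 decimals, so correlations computed from them are meaningful to about
that precision.

## The synthetic generator

`make_complex()` builds an ideal α-helix (φ = −57°, ψ = −47°, standard
bond lengths and angles, CB pseudo side chains) and places a minimal
lipid — reserved HET ID `ZZL`, 3 phosphate-like head atoms and an
8-carbon ether-linked tail, so it exercises the tail-start override —
radially outward of each designated residue, with the contact atom at
3.4 Å (tail) or 3.2 Å (head) from the residue anchor, inside the van
der Waals criteria. Every other residue–lipid-atom pair is required to
clear 4.3 Å, above every crystal criterion; the generator verifies this
by an independent brute-force distance scan and errors on infeasible
requests instead of emitting a wrong artifact. `make_trajectory()`
toggles each lipid between its contact position and a 30 Å-displaced
one so each residue is in contact in exactly
`round(occupancy * n_frames)` (leading) frames; occupancy is
order-invariant, which a shuffle test asserts. `make_count_tables()`
draws multinomial compositions and binomial binding counts with
prescribed probabilities. The seed fully determines all outputs, and
the caller's random stream is restored.

What the generator does *not* emulate: sterics between lipids and
protein, a bilayer geometry, realistic side chains beyond CB, B-factors
or disorder, and correlated frame-to-frame motion. Passing tests
therefore demonstrate that the pipeline's bookkeeping and geometry are
correct — designed patterns in, identical patterns out — not that any
particular biological propensity value is right; the latter depends on
the curated structure datasets, which are inputs.

## Numerical choices and degenerate inputs

- Sample standard deviations use the $n-1$ denominator; a type defined
  in a single chain reports SEM `NA` rather than 0.
- A chain with no binding residues for a class contributes nothing to
  that class (all propensities `NA`).
- Expected counts of zero are skipped in the chi-square with a message;
  $O = E$ yields statistic 0 and p = 1.
- Degenerate leave-one-out replicates (zero variance) are skipped and
  $N$ reduced.
- Test problem sizes were chosen for statistical resolution at desk
  scale: the null calibration of the chi-square uses 2000 simulated
  chains of 4000 residues at a 5% binding rate, where the expected
  rejection rate at the 3.841 critical value is slightly below 0.05
  because the expected counts are estimated from the same pooled data
  (variance factor $(1-p)(1-N_i/N)$); parameter recovery uses 200
  chains of 1000 residues, giving binomial standard errors well inside
  the asserted tolerances.

## Limitations

- Structure input is PDB-format only; mmCIF coordinate files are not
  parsed (the chemical-component reader does accept mmCIF dictionaries
  for bonds).
- Modified polymer residues recorded as HETATM (other than MSE) are not
  recognized as polymer, so a chain carrying one is kept without that
  residue rather than dropped; ATOM-recorded non-standard residues drop
  the chain as intended.
- Lipid-donated hydrogen bonds are not scored (no lipid hydrogens), a
  conservative choice that only affects the typed contact table, not
  the binary binding flags, whenever the same pair is also a vdW
  contact.
- Solvent accessibility, membrane depth and per-position (interface vs.
  core) breakdowns are out of scope.
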