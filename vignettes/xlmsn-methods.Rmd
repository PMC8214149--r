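---
title: "Methods: MSn identification of sulfoxide-cleavable cross-links"
author: "xlmsn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSn identification of sulfoxide-cleavable cross-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmsn)
```

This vignette documents the models, parameters and numerical choices behind
the package, in the spirit of a methods section: what is computed, under
which assumptions, and what the synthetic-data tests do and do not
demonstrate.

## Fragmentation model and mass arithmetic

The package models cross-linkers whose spacer contains a central sulfoxide
flanked by CID-labile C–S bonds. Cleavage separates an interlinked pair
α–β into single chains carrying complementary remnants: an alkene (A,
C₃H₂O) on the NHS/lysine side and a sulfenic acid (S) on the other, the
latter usually dehydrating to the thiol (T = S − H₂O, a loss of
18.010565 Da). Four linkers are registered by default; users can add more
via `register_linker()` without code changes.

| linker  | sulfenic | thiol | end-B targets | max Cα–Cα |
|---------|----------|-------|---------------|-----------|
| DSSO    | C₃H₄O₂S  | C₃H₂SO| K             | 30 Å      |
| SDASO-L | C₇H₁₃NO₂S| C₇H₁₁NOS| any residue | 35 Å      |
| SDASO-M | C₅H₁₀OS  | C₅H₈S | any residue   | 30 Å      |
| SDASO-S | C₄H₈OS   | C₄H₆S | any residue   | 30 Å      |

All masses are monoisotopic, computed from hard-coded IUPAC atomic masses
(≥ 6 decimals); the proton is 1.00728 Da and water 18.010565 Da. The
familiar integer remnant labels (+54, +175, …) are treated as nominal
names only — arithmetic always uses full precision. Two structural
identities are asserted for every registered linker: alkene + sulfenic
equals the intact bridge addition, and thiol equals sulfenic minus water
(both to 1e-6 Da). m/z values quoted to two decimals are compared after
ordinary rounding.

Variable modifications (cysteine carbamidomethylation, Met oxidation,
protein N-terminal acetylation, Gln→pyroGlu) are available with standard
masses; at most four are assumed per peptide in search configurations.
Only lysine is treated as an NHS target — the protein N-terminal amine is
a chemically plausible alternative but is deliberately excluded, keeping
the alkene strictly on uncleaved lysines.

## Digestion, decoys and candidates

Trypsin cleaves C-terminal to K/R and chymotrypsin C-terminal to F/W/Y/L,
neither before proline. Defaults are 3 missed cleavages for trypsin and 4
for chymotrypsin, peptide length 4–50 (the minimum can be lowered to 1
for pedagogical examples). A combined Lys-C/trypsin digestion is modeled
by the trypsin rule alone, since the cleavage residues coincide. Decoy
databases are built one decoy per target by seeded residue shuffling
(reversal is available), preserving length and composition and doubling
the entry count; decoy accessions carry the `DECOY_` prefix.

Candidate enumeration distinguishes the two linker ends. Side A
candidates carry the alkene on an uncleaved lysine: a remnant-modified K
must be internal, unless the peptide ends at the protein C-terminus
(remnant-blocked cleavage). Side B candidates enumerate the sulfenic and
thiol remnants on every residue position; positional isomers share a mass,
so the mass index stores one entry per peptide–moiety and positions are
expanded only after a window hit.

## Signature pairing and MS³ scoring

Pair detection tests all peak pairs and fragment-charge hypotheses
against the two reconstruction identities (A+S = M; A+T = M − H₂O) at
±20 ppm. Two numerical choices matter here. First, charge conservation:
the two fragments of one precursor molecule carry all of its protons, so
only charge assignments summing exactly to the precursor charge are
accepted. This prunes the hypothesis space and keeps the false-pair rate
on pure-noise spectra below 1% in the package's Monte-Carlo test (1000
random 10-peak spectra, 3+ precursors). Second, orientation: masses alone
cannot distinguish the alkene side from the thiol side, so pairs are
reported unoriented and the α (lysine) side is fixed at assembly time,
when the MS³ identifications are known. For DSSO, same-chain alkene/thiol
doublets (Δ = 31.9721 Da, one sulfur) corroborate pairs that share a
doublet peak. Pair intensities are not used; mass error is the tiebreaker.

MS³ spectra are matched against singly-protonated b/y ions of candidates
whose mass model fits the fragment precursor at ±20 ppm: side A, side B,
and the intralink fragment model (alkene + thiol on one peptide). Ions are
matched within 0.6 Da; sulfenic-containing fragments also emit −H₂O
neutral-loss companions, reflecting dehydration alongside backbone
fragmentation. The score is the −log₁₀ binomial tail probability of the
matched count, with per-ion match probability equal to the spectrum's
covered m/z fraction. The original workflow's proprietary scoring is not
reproduced; this score is simple, monotone in matched ions, and
rank-separates true from shuffled sequences in ≥ 99% of simulated cases,
which is all the downstream statistics require. A spectrum is identified
when its best score reaches 2 (P < 0.01); positional isomers within 0.01
score units of the best define the site-ambiguity set.

## Assembly, FDR and redundancy

An MS² spectrum with a signature pair whose two member fragments were both
identified in MS³ becomes an interlink, subject to the precursor
consistency check |m(α) + m(β) + bridge − M| ≤ 20 ppm; its combined score
is the smaller constituent score (conservative). Single-fragment spectra
are classified by mass model: peptide + bridge + water is a dead-end
(named for the hydrolyzed end: an alkene-carrying fragment means the
diazirine end hydrolyzed, a thiol/sulfenic fragment means the NHS end
did), and peptide + bridge with an alkene+thiol fragment is an intralink.
FDR is the simple concatenated-decoy estimator #decoy/#target at the
applied score cut, reported as a percentage. Collapse produces unique
peptide-pair sequences (localization ignored) and unique K–X residue
linkages, with ambiguity sets mapped to protein-coordinate intervals in
the `P1:K155--P2:X(128-131)` notation. Peptide-to-protein mapping uses the
digest provenance of each candidate. Replicate overlap is reported three
ways — fraction of the union in ≥ 2 replicates, fraction in all, and mean
pairwise Jaccard — because "overlap among replicates" is ambiguous; all
three are computed and none is privileged.

## Structural validation

Linkages map onto CA-level structure models (multi-MODEL PDB files are
read as conformational states s1…sN). Distances are Euclidean Cα–Cα;
ambiguity intervals use the minimum distance over the interval (the most
permissive reading), and residues unresolved in a model are excluded from
that model's denominator rather than counted as violations. A linkage is
satisfied when its distance is ≤ the linker threshold — the boundary value
itself satisfies. State-specific classification excludes linkages
satisfied by all models or none and assigns the rest to their exact
satisfied subset (14 proper subsets for four states; generalized to
2ⁿ − 2 with a warning otherwise). The random null enumerates all
K-to-any-residue Cα distances up to a cap (100 Å is appropriate for a
single protein, 300 Å for a large assembly), binned at 5 Å; observed
distances are compared to it with a two-sample KS test — the choice of
test is this package's, made because it is distribution-free and
sensitive to the left-shift that genuine cross-links show.

## Residue preference under localization ambiguity

For a diazirine-side peptide with n ambiguous sites, each site x receives
Wx = a_x,r / n, where the prior a_x,r defaults to 1 for every residue
(equal-preference assumption); per-residue totals Wx′ are normalized to
Px. Only diazirine-side constituents enter the statistic. Px sums to 1 by
construction (asserted to 1e-9) and is invariant under dataset
duplication. When several linkers are analyzed, the default is to pool
their linkages before computing Px; computing per linker and averaging is
possible by calling the function per subset — pooling is the default
because the statistic is a frequency over sites, not over experiments.

## The synthetic-data generator

The generator is the package's stand-in for real raw data and defines the
study conditions of all end-to-end tests. It emulates: the four species
types; precursor charges drawn from {3, 4, 5} (MSn acquisition selects 3+
and up); MS² signature fragments with the dominant thiol and a 1:4
sulfenic:thiol intensity ratio (the dehydrated form dominates; the exact
ratio is a package choice); top-four data-dependent MS³ selection by MS²
intensity; Gaussian ppm mass noise on every m/z; uniform random noise
peaks; and a configurable diazirine residue preference. The default
preference puts weight 0.30 on glutamate, 0.064–0.073 on Ala/Asp/Leu/Tyr,
and ~0.028 on each remaining residue, emulating the observed dominance of
glutamate among carbene insertion sites. Sites are drawn type-first
(residue type from the preference, then uniformly among occurrences), so
the planted marginal type distribution equals the preference exactly,
independent of database composition — this is what makes the ±0.03
recovery check at n = 2000 meaningful.

What the generator does not emulate: isotope envelopes, chromatography
and retention time, realistic intensity models, co-isolation, and
fragment-ion sampling losses (MS³ spectra contain the full b/y series
plus noise). Passing the end-to-end tests therefore shows that the
pipeline's logic and mass arithmetic are correct under instrument-scale
mass error, not that its recovery rates transfer to real data, where
incomplete fragmentation and chimeric spectra dominate the error budget.

Toy structure ensembles are written as multi-MODEL CA-only PDB text. The
chain is a 3.8 Å-spaced trace and each planted linkage relocates its
second residue along an axis-aligned direction, which keeps coordinates
exact at the PDB format's three decimals so planted distances are realized
exactly; plans where one residue would need two positions are rejected as
infeasible.

## Problem sizes and runtime choices

The shipped tests run the full pipeline at 60 noiseless and 500 noisy
interlinks (5 ppm σ, 20 noise peaks/spectrum) against a six-protein
synthetic database with decoys, verify digestion against a substring-
enumeration oracle on 200 random proteins, pair detection against an
all-pairs oracle on 100 random spectra, and the preference statistic at
n = 2000 planted linkages. These sizes give stable stochastic checks
(binomial SD of the glutamate fraction at n = 2000 is about 0.010 against
a ±0.03 band) while keeping the whole suite in the low minutes on one
CPU.

## Known limitations

- Scoring is intentionally simple; it is rank-adequate for validation but
  not calibrated across peptide lengths the way a production search
  engine's E-values are.
- Fragment ions are b/y only, singly charged, without a/c/x/z series or
  isotope peaks.
- Peptides mapping to multiple proteins are resolved by digest
  provenance; a real search against redundant databases would need
  explicit multi-mapping handling.
- Structure mapping requires an explicit accession-to-chain map; no
  sequence alignment to structures is attempted.
- Solvent-accessible-surface distances are out of scope; the null and the
  validation use Euclidean distances only.
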