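---
title: "Conformational-state and interface analysis of two-domain oligopeptidases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational-state and interface analysis of two-domain oligopeptidases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s9conf)
```

## The biological problem

Oligopeptidase B (OpB) and its relatives in the S9 (prolyl oligopeptidase)
family are built from two domains: a C-terminal α/β-hydrolase fold carrying
the Ser/His/Asp catalytic triad (together with the N-terminal loop it forms
the *catalytic domain*) and a seven-bladed β-propeller that gates access to
the active site.  The enzyme cycles between an **open** state (domains
apart, triad disassembled), a **closed**, catalytically competent state
(domains together, triad assembled) and an **intermediate** state (domains
together, triad still disassembled).  In closed structures the loop
carrying the catalytic Asp (the D-loop) is pinned against an opposing loop
of the propeller in one of two ways: a single interdomain salt bridge
between a propeller Glu/Asp and a D-loop Arg (the *SB1* mode, typical of
protozoan enzymes such as the *T. brucei* OpB), or a pair of neighbouring
propeller arginines packing against Ser/Gln residues that follow the
catalytic Asp (the *RR–SQ* complementary-surface mode, typical of the
*S. proteamaculans* enzyme and the majority of bacterial OpBs).  The same
two sequence patterns at the two anchor positions — R-Q versus E/D-R —
divide OpB sequences into an SpOpB-like and a TbOpB-like group.

`s9conf` implements the quantitative side of this analysis: triad geometry,
interdomain separation and interface burial, the polar-contact census, the
state and stabilization-mode classifiers, the sequence-group classifier
with taxonomy tallies, and Kitz–Wilson kinetics for irreversible
active-site inhibitors.

## Measurements

**Triad geometry** (`measure_triad`) reports four distances: the Cα
separations Ser–His and His–Asp, the Ser OG–His NE2 distance (the
proton-transfer contact) and the His ND1–Asp OD distance (reported for OD2
and as the minimum over OD1/OD2, since carboxylate atom naming in deposited
models is convention-dependent).  A triad is *assembled* when
OG–NE2 ≤ 4.5 Å and ND1–OD ≤ 4.0 Å.  These cutoffs sit far from both sides
of the observed distributions — closed structures show 2.8–3.5 Å /
3.0–3.1 Å while intermediate and open ones show ≥ 8.8 Å on the His–Asp
contact and ≥ 18 Å on OG–NE2 — so the call is insensitive to their exact
values; both are overridable through `opb_thresholds()`.  Ser-to-Ala
mutants carry no OG: the distance is reported as unavailable rather than an
error, and state classification falls back to the Cα separation (closed at
≤ 10 Å, between the observed closed 7.9–8.3 Å and non-closed 17.4–18.5 Å),
flagged `mutant_inference`.

**Center-of-mass separation** (`center_of_mass_distance`) uses
mass-weighted heavy atoms of the catalytic domain (N-terminal loop +
hydrolase fold) and of the propeller, with the two hinge peptides excluded
from both bodies.  Whether published values used all atoms or Cα only is
not stated anywhere we know of; the all-heavy-atom choice is the package's
own, and reproduction of literature values is therefore only expected
within ±1 Å, which also absorbs the uncertainty of the propeller boundary.

**Solvent-accessible surface area** (`compute_sasa`) is an own
Shrake–Rupley implementation: each atom's sphere (van der Waals radius +
probe) is sampled on a deterministic Fibonacci lattice and points are
discarded when inside a neighbouring sphere.  Defaults: C 1.70, N 1.55,
O 1.52, S 1.80 Å, probe 1.4 Å, 960 points.  With 960 points the quadrature
error against the analytic one- and two-sphere solutions is well under 1%,
and the fixed lattice makes every result exactly reproducible.  Buried
surface area of a domain is its isolated area minus its area in the whole
protein, as a percentage of the isolated area; a residue burying more than
0.1 Å² counts as an interface residue.  That 0.1 Å² floor is an operational
choice (published interface-residue counts come from services that do not
print their criterion) and is overridable.

**Polar contacts** (`find_polar_contacts`) are heavy-atom-distance
criteria only: any N/O–N/O pair across the two groups at ≤ 3.5 Å is a
hydrogen bond; Arg NH1/NH2/NE, Lys NZ or His ND1/NE2 against Asp OD1/OD2
or Glu OE1/OE2 at ≤ 4.0 Å is a salt bridge.  No angular term is used —
crystal structures at ~2 Å resolution carry no hydrogens, and published
contact tables list atom pairs with distances only.  Each residue pair is
reported once per kind with its minimal-distance atom pair.  Absolute
hydrogen-bond *counts* depend strongly on the (unpublished) criteria of the
service used for the original tables, so the package promises ordering
(closed > open) rather than exact counts; salt-bridge identities, by
contrast, reproduce exactly at the 4 Å cutoff.

## Classification rules

`classify_state` is a two-step quantization of the qualitative criteria:
closed ⇔ triad assembled; otherwise intermediate when the catalytic domain
still buries ≥ 10% of its surface, else open.  The 10% split lies between
the observed intermediate (11.7%) and open (8.8%) values; it is an explicit
reconstruction — no single numeric rule separating intermediate from open
has been published — and reports embed the full threshold block so the rule
is always visible.  The classifier is deterministic and threshold-monotone:
raising the burial threshold can only demote intermediate calls to open.

`classify_stabilization_mode` reads the residues at the SpOpB-numbering
anchor positions 150/151 (propeller) and 617–621 (D-loop region), resolved
on any homolog through a reference-anchored pairwise alignment
(`map_numbering`: global alignment, BLOSUM62, gap open 10, extend 0.5).
A Glu/Asp at the 151-equivalent with an Arg at the 619-equivalent forming a
side-chain salt bridge ≤ 4 Å gives `salt_bridge_SB1`; an Arg/Gln pair with
at least two of the four RR–SQ network contacts (R151~Q619, S618~Q619,
S618~R150 backbone, R150~Q621) within 4 Å gives `complementary_surface`;
anything else is `undetermined`, with the gathered evidence attached.  The
pairwise-anchored approach replaces the original multiple-alignment
bookkeeping; for anchor extraction the two are equivalent, and the pairwise
route is testable without an MSA engine.

## Sequence groups and taxonomy

`classify_sequence` applies the published rules verbatim: length < 500 →
`short` (such sequences cannot cover the anchor positions); anchors R-Q →
`SpOpB_like`; E/D-R → `TbOpB_like`; anything else — including ambiguity
codes at an anchor and anchors that align to a gap — → `other`.  Sequences
whose anchors are unresolved by alignment are additionally flagged, so the
two flavours of `other` remain distinguishable in output.  `tally_groups`
aggregates calls at a chosen taxonomy rank from a plain lineage table; no
live database queries are made, trading completeness for reproducibility.

## Synthetic reference sequences

The packaged SpOpB/TbOpB reference sequences are **synthetic stand-ins**
(`inst/extdata/references_synthetic.fasta`, built by
`data-raw/references_synthetic.R`).  Every residue identity documented for
the real proteins — the catalytic triad, all anchor and contact residues,
the hinge-1 peptide IPQQEH, the His-tag — is planted at its published
author position; the remaining positions are a seeded random fill with
typical globular-protein composition.  The TbOpB stand-in adds two
insertions (21 residues after position 100, 10 after 300) reproducing the
documented +21/+31 numbering offsets, ~35% background substitutions, and
the group-defining anchors E172/R650.  Consequences: anchor bookkeeping,
numbering maps (151↔172, 619↔650) and group classification behave exactly
as with the real sequences, but alignment *identities* against real OpBs
are meaningless, and the packaged references must not be used for any
analysis that depends on the true residue composition.

## What the toy structures emulate

`make_toy_structure` builds two rigid blocks of single-carbon
pseudo-residues on a 4.6 Å lattice (48 residues each), separated along x by
a van der Waals contact gap of 3.6 Å plus the requested `separation`.  The
triad sits on the outer face of the catalytic block as explicitly placed
side-chain pseudo-atoms, so the planted OG–NE2 and ND1–OD2 distances are
exact at separation 0.  The His functional atoms are displaced by 3 × the
separation — emulating the H-loop excursion to the domain periphery, which
in real open/closed pairs is several-fold larger than the domain
displacement itself.  The optional SB1 or RR–SQ network spans the gap at
the published closed-state distances (3.4 Å; 3.7/2.6/3.3/3.1 Å), again
growing with separation.

Under this geometry the canonical planted states are separation 0
(closed: triad assembled, catalytic-domain burial ≈ 15%), 0.7 Å
(intermediate: triad broken at OG–NE2 = 4.9 Å, burial ≈ 11%) and 8 Å
(open: no burial).  The intermediate value sits inside the narrow window
(≈ 0.6–0.9 Å) where the triad is already broken but burial still exceeds
10% — deliberately narrow, because in the real enzymes the intermediate
and closed states differ much less in domain separation than either does
from the open state.  Sweeping the separation from 0 to 10 Å moves the
call monotonically closed → intermediate → open.

The toys are *not* physical protein models: residues are pseudo-atoms, the
interface is a flat lattice face, and burial percentages have closed-state
magnitudes only because the block proportions were chosen that way.
Passing the planted-recovery tests therefore demonstrates that the
measurement and classification machinery is correct, not that real
structures will classify correctly — that check needs the deposited
coordinate files, which the test suite uses when they are available.

## Kinetics

Irreversible active-site alkylation follows E + I ⇌(K_i) EI →(k₂) EI′
under pseudo-first-order conditions ([I] ≫ [E]).  Per concentration,
`fit_pseudo_first_order` estimates k′ as minus the slope of ln(activity)
versus time; `fit_kitz_wilson` then fits 1/k′ = (K_i/k₂)(1/[I]) + 1/k₂ by
unweighted OLS, the classical graphical estimator.  k₂ is the inverse
intercept and K_i the slope times k₂; concentrations are entered in µM and
K_i reported in mM.  A direct nonlinear fit of k′ = k₂[I]/(K_i+[I]) is run
alongside as a cross-check only.  Degenerate inputs are handled explicitly:
a non-positive reciprocal intercept (saturation not identifiable) is an
error; a non-positive slope (no concentration dependence) clamps K_i to 0
with a `degenerate_slope` flag.  The simulator assumes residual activity is
normalized to the t = 0 value — the common convention when a per-timepoint
control is not described — and applies multiplicative lognormal noise when
requested, capped at 1 since activities are fractions of initial.

```{r kinetics-example}
sim <- simulate_inactivation(Ki_mM = 0.28, k2_per_min = 0.27,
                             concentrations_uM = c(50, 100, 150, 200, 260),
                             times_min = seq(0, 20, 2))
fit_inactivation(sim)
```

## Numerical choices and problem sizes

Reported SASA values use 960 sphere points (≈ 0.3% quadrature error);
toy-based tests and the classifier examples run in seconds.  The
property-style sequence checks use 1000 sequences at 5–10% mutation rates
(about 40 s of pairwise alignments per thousand), sizes at which planted
anchors are recovered without exception while keeping the default test run
comfortably short.  Alternate conformers in PDB input are collapsed to the
highest-occupancy copy (ties by altloc letter), hydrogens are ignored
everywhere, waters are dropped, and non-water hetero groups are kept for
ligand-environment analysis only.  The multi-chain chain choice defaults to
the first protein chain and is overridable per call.

## Known limitations

* Deposited-structure reproduction (triad distances, center-of-mass
  separation, salt-bridge identities) requires the coordinate files; the
  package ships none and fetches them once when network access exists.
* Hydrogen-bond counts use a distance-only criterion and will not match
  services that apply angular terms or solvation filters; only orderings
  across states are meaningful.
* The intermediate/open burial split (10%) is a reconstruction from two
  published values; borderline structures should be judged on the full
  metric report, not the label alone.
* The stabilization-mode classifier examines the canonical anchor network
  only; modes built on non-homologous contacts would return
  `undetermined` with the evidence listed.
* Electrostatic-surface rendering and phylogenetic tree building are out
  of scope; group frequencies and column frequencies are exported as data
  for external tools.
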