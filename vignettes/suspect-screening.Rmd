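---
title: "Suspect screening of silicon-containing synthetic cannabinoid metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suspect screening of silicon-containing synthetic cannabinoid metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Synthetic cannabinoid receptor agonists (SCRAs) are metabolized so
extensively that the parent drug is usually undetectable in urine;
abstinence-control and forensic casework therefore target metabolites.
ADMB-3TMS-PrINACA and Cumyl-3TMS-PrINACA are the first SCRAs carrying a
3-(trimethylsilyl)propyl (3TMS) *N*-alkyl tail, i.e. a silicon atom, which
breaks the assumptions of common metabolite-prediction tools and of mass
arithmetic code that treats only CHNOPS elements. `silascreen` implements
the complete suspect-screening workflow for these compounds: hypothesize
metabolites with a biotransformation rule engine, compute their exact
masses and adduct m/z with silicon as a first-class element, match
LC-HRMS features and product-ion spectra against the hypothesis list under
fixed identification criteria, localize the biotransformation site from
diagnostic fragment shifts, and rank urinary biomarkers by mean area
ratio (MAR).

## The mass engine

All masses derive from one immutable table of CODATA/IUPAC monoisotopic
atomic masses (`mass_constants()`, shipped as a JSON resource, >= 6
decimals). For a neutral molecule $M$ and an adduct gaining composition
$\delta$ with charge $z$,

$$ m/z = \frac{m(M) + m(\delta) - z\, m_e}{z}, $$

with the electron mass $m_e$ subtracted: the accurate masses printed in the
reference tables are only reproducible with electron bookkeeping. Fragment
cations given as atom inventories use $m - m_e$ directly. Reported m/z are
rounded half-even to 4 decimals; tests compare at an absolute tolerance of
2e-4, i.e. the precision of the printed tables. The m/z difference between
`[M+Na]+` and `[M+H]+` of the same molecule is the constant 21.9819.

The SMILES parser is deliberately a minimal, loudly-failing subset
(aliphatic/aromatic C, N, O, bracket atoms such as `[Si]`, single/double
bonds, branches, single-digit ring closures). Implicit hydrogens are filled
from standard valences (C 4, N 3, O 2, Si 4); aromatic carbon carries one
hydrogen unless substituted, aromatic nitrogen none unless written `[nH]`.
This covers the four published parent/analog SMILES exactly; anything
outside the grammar raises an "unsupported SMILES grammar" error rather
than risking a silent misparse. A full-grammar parser would add nothing
here but new failure modes.

## The biotransformation rule engine

Rules are composition deltas with structural applicability, stored in a
versioned JSON registry: hydroxylation (+O, up to 3 applications to cover
triols), di-/trihydroxylation, demethylation and Si-demethylation (-CH2),
3TMS cleavage with terminal hydroxylation (-C3H8Si +O), *N*-dealkylation
(-C6H14Si), amide hydrolysis (-NH +O, flagged tentative), and phase II
O-glucuronidation (+C6H8O6). Each rule may require a structural tag
(`requires_Si`, `requires_3TMS`, `requires_primary_amide`,
`requires_hydroxyl`) and grants/revokes tags along a chain: hydroxylation
grants the hydroxyl that glucuronidation needs; 3TMS cleavage revokes the
silicon tags so silicon-specific rules cannot fire downstream.

One design choice deserves emphasis: carbonyl and carboxylic-acid
formation are modeled as oxidations *of an existing hydroxyl* —
ketone/aldehyde formation is -H2 and acid formation +O -H2, both requiring
`requires_hydroxyl`. This matches the observed pathway (3TMS cleavage
gives a terminal alcohol, oxidized via the aldehyde to the *N*-propionic
acid). The alternative parameterization as direct-from-alkane deltas
(+O -H2, +O2 -H2 with no prerequisite) is composition-equivalent to
hydroxylation followed by these rules, and enumeration deduplicates by
(composition, chain multiset), so the reachable composition space is
identical; the hydroxyl-prerequisite form keeps chains mechanistically
ordered and prevents chemically empty chains like acid formation on a
substrate with no oxidizable group.

Enumeration is breadth-first to `max_steps = 3` (the conventional
iteration depth for systematic metabolite prediction), deduplicated, and
deterministically ordered by mass, chain length, and key. The default
registry regenerates every tabulated metabolite composition of both
parents, and inclusion lists (one row per candidate x adduct, sorted by
m/z) feed the screening stage.

## Diagnostic fragments and site localization

Each parent has a curated product-ion inventory (trimethylsilyl cation
73.0468; indazole acylium 145.0396; 3TMS-PrINACA indazolyl acylium
259.1261; for the cumyl parent additionally tropylium 91.0542 and the
cumyl cation 119.0855; for the ADMB parent the alpha-cleavage ion 344.2153
and an annotated "N-O exchange" ion at 277.1367 carried as a literal m/z
with no modeled mechanism). Every fragment is tagged with the structural
moieties it contains. A transformation shifts a fragment's composition iff
its site lies within the fragment's moieties — a side-chain hydroxylation
moves 259.1261 to 275.1210 while 145.0396 and 119.0855 stay put; a
head-group hydroxylation moves the cumyl ion to 135.0804 (+15.9949, one
oxygen). Silicon-excising rules act on every silicon-containing fragment
regardless of assumed site, producing the de-silylated series (203.0815
for the terminal alcohol, 217.0608 for the acid, 201.0658 for the
aldehyde, 161.0346 for a hydroxylated core after dealkylation); residues
that fall below the m/z 50 scan limit or lose all carbon are dropped.

Two modeling caveats are data, not code. First, the trimethylsilyl cation
is tagged with a `side_chain_tms` sub-moiety: the reference data cannot
distinguish hydroxylation on the propyl chain from the TMS methyls (both
are reported as site S), so a generic side-chain oxidation leaves m/z
73.0468 unshifted rather than asserting an unobservable shift. Second,
several tabulated metabolite ions (water losses, ammonia adducts of the
amide series, e.g. 293.1316, 220.1081, 302.1499) have compositions
back-calculated from the printed m/z within 5 ppm; they are flagged
`"inferred"` and are used to enrich synthetic spectra, never as ground
truth.

Site inference inverts the shift model: for each per-step site hypothesis
(silicon-excising steps fixed to S), the expected fragment set is compared
with the spectrum. A fragment observed unshifted where the hypothesis
expects a shift — or shifted where none is expected, or shifted
differently than predicted — refutes the hypothesis; an absent fragment is
neutral, because real product-ion spectra are incomplete. The site is
called only when positive evidence exists (at least one fragment observed)
and exactly one hypothesis per step survives; otherwise the call is
`undetermined`, rendered as `"(S?)"` when the chain's rules only permit
the side chain anyway. This mirrors how the reference tables mark sites
that fragmentation cannot pin down.

## Screening criteria and MAR

Identification requires precursor mass error strictly below 5 ppm,
signal-to-noise strictly above 3, and diagnostic fragments within +-10 ppm
(inclusive) — the boundary semantics are fixed and tested (5.5 ppm and
S/N 2.9 are rejected with the correct reason; a 10.1 ppm fragment does not
match). The minimum fragment count per identification defaults to 1 and is
configuration-exposed, since the source criteria state a tolerance but not
a count. Matches sharing a target m/z are split into separate
identifications when retention times differ by more than 0.2 min (the
reference data demonstrate isobar discrimination qualitatively; 0.2 min is
well below every tabulated isomer gap and above chromatographic jitter),
and co-eluting duplicates collapse to the best |ppm|, then the shortest
chain, then the lowest mass.

Metabolite IDs follow the field convention: a stage number per
transformation class (a curated per-parent registry; classes observed in
the tables carry their published stage numbers, remaining classes were
assigned once, in pathway order) with rt-ascending suffixes for isomers
and roman numerals for phase II conjugates. MAR normalizes each
metabolite's peak area to the most abundant metabolite *within each
sample* (= 100%), excluding the parent, then averages per-sample ratios
across the samples of a matrix — "mean area ratio" is otherwise undefined
in the source; normalizing before averaging keeps every sample's scale
comparable and makes MAR invariant under uniform area scaling. Hydrolyzed
mode (the default, matching routine enzymatic conjugate cleavage) screens
phase I candidates only; phase II species are represented by their
aglycones.

## The synthetic data generator

Raw instrument data for this chemistry are not publicly deposited, so the
generator emulates what the screening stage consumes: centroided features
(rt, m/z, area, S/N) and product-ion spectra. Planted metabolites use the
tabulated retention times and areas equal to the printed MAR percentages
(urine and pHLM samples; entries printed "not detected" in a matrix are
not planted there; the parent appears in vitro only). Mass error is
Gaussian in ppm (default sd 1 ppm, instrument-style relative error);
noise peaks are uniform over the m/z 50-650 scan range; each planted
feature gains an `[M+Na]+` twin at exactly +21.9819 with probability 0.5;
S/N is log-normal with median 30 and sdlog 0.3 by default — planted
features then pass the S/N filter essentially surely, which is what a
"detected metabolite" means; the `noise_stress` preset widens sdlog to 1
and lowers the median so the S/N criterion is exercised in both
directions, and adds 7.5 ppm off-target decoys carrying a fragment set
(nominal-mass isobar style, e.g. 217.1285 vs 217.0608, ~320 ppm apart)
that matches no candidate. A single seed drives all randomness in a
documented draw order, so a given configuration is byte-reproducible.

What passing these tests shows — and does not show. The generator
reproduces the *statistical structure* the screening stage assumes
(relative mass error, adduct spacing, fragment co-occurrence, decoy
interference at distinct rt). It does not simulate chromatographic peak
shapes, isotope envelopes, matrix effects, or in-source fragmentation, so
recovery rates here certify the decision logic, not instrument
performance. Likewise the in vivo metabolite counts (27 and 33) are
properties of the non-deposited raw data and are not reproducible at desk
scale; the panels plant the tabulated most-abundant metabolites instead.

## Numerical choices and problem sizes

Tolerances: m/z comparisons at 2e-4 (printed-table precision), mass
additivity at 1e-9, boundary ppm arithmetic exact per its closed form.
Ties in candidate assignment break deterministically (ppm, chain length,
mass, key). Degenerate inputs: empty feature tables yield an empty report
with a warning (exit 0 in scripts); empty spectra are
`insufficient_fragments`, never errors; the parent (empty chain) has no
site call. The test suite runs the two panel presets at zero mass error
for exact recovery and MAR checks, and 100 seeds per panel at 1 ppm
(plus 100 noise-stress seeds for decoy rejection); candidate enumeration
and expected-fragment sets are cached across seeds to keep the full suite
within a few minutes on one CPU.

## Known limitations

* Regiochemistry is out of reach by design: site calls are moiety-level
  (S/H/C), matching what fragment shifts can support; atom-level
  assignment needs isolation and NMR.
* The amide-hydrolysis delta (replace -NH2 by -OH) is flagged tentative;
  alternative hydrolysis chemistry would change candidate compositions in
  stage 2 only.
* Inferred fragment compositions (back-calculated from printed m/z) may be
  wrong in ways invisible at 4-decimal precision; they are flagged and
  never load-bearing for acceptance decisions.
* `min_matches = 1` is permissive; raising it tightens specificity at the
  cost of sensitivity on sparse spectra, and is the first knob to turn for
  real casework data.
* mzML reading requires the optional `mzR` package and is not exercised by
  the default test suite; MGF is the tested spectra dialect.
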