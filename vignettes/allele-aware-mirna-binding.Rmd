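---
title: "Allele-aware prediction of miRNA binding to polymorphic 3'UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-aware prediction of miRNA binding to polymorphic 3'UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelemir)
```

## The problem

Highly polymorphic genes such as *MICA* (the NKG2D-ligand gene of the MHC
class I region) carry single-nucleotide polymorphisms and small indels in
and around their 3' untranslated regions. Because canonical microRNA
recognition hinges on exact Watson-Crick pairing between the miRNA seed
(positions 2-8) and a 7-8 nt target window, a single SNP can create or
destroy a binding site, and a frameshifting indel upstream can move the stop
codon and hand an entirely different stretch of sequence to the 3'UTR. This
package implements the full desk-scale analysis of that situation: it
reconstructs each allele's 3'UTR from a reference transcript plus a
haplotype of variants, classifies the haplotypes into UTR types under a
global-frequency filter, scans for canonical seed sites, scores each site's
hybridization energy with a nearest-neighbor model, quantifies per-SNP
allele impact, folds the UTRs to ask whether sites are structurally
accessible, and groups the UTR types with a neighbor-joining tree.

## Allele reconstruction and coordinate conventions

`apply_haplotype()` edits the reference sequence (substitutions in place; an
insertion at position *p* occupies position *p* and shifts everything
downstream right; a deletion removes the base and shifts left) and returns a
total coordinate map from surviving reference positions to allele positions.
`find_stop()` scans codons from the CDS start in steps of three for the
first TAA/TAG/TGA (standard genetic code only, no readthrough).

All reported intervals are 1-based and end-exclusive, and the 3'UTR is
`[stop_first_nt + 3, end_exclusive)`, so a printed length always equals
`end - start`. This convention is forced by the coordinate arithmetic of the
MICA system: a stop whose first nucleotide sits at 997 yields a UTR starting
at 1,000 and running to the boundary 1,327, i.e. 327 nt; the reference-frame
stop at 1,154 yields 170 nt from 1,157. The source literature alternates
between quoting stop positions and UTR starts; the fixed `+3` offset is the
single reading that reconciles every printed number, and it is applied
uniformly. For alleles carrying upstream indels, stop and UTR coordinates
are reported *reference-projected* through the coordinate map, so a
frameshifted allele still reports positions comparable across alleles.

## UTR-type classification

`classify_utr_types()` groups haplotypes that agree at a designated
*grouping* set of variants into major types, after `filter_by_frequency()`
has dropped variants whose minor-allele global frequency (the smallest
listed frequency; the frequencies of a printed source table are accepted
verbatim and are not required to sum to one) falls below the cutoff
(default 0.005). The grouping set defaults to the variants marked `legacy`:
the major types of the established classification predate the newly added
SNPs, so new SNPs refine subtypes rather than founding new major types.
Subtypes then split by assignments at the newly introduced variants, by
length class (`long`/`medium`/`short`, i.e. which frameshifting indel the
haplotype carries), and finally by explicit overrides for splits that no
column of the table can express (the published UTR1b/UTR1c and UTR2a/UTR2b
splits state the grouping but not its criterion; the packaged configuration
simply records it). Subtype letters come from the overrides, with remaining
subtypes receiving unused letters in class order.

The ancestral allele of each variant defaults to the first allele of its
"(X/Y)" notation, which also serves as the reference base of the synthetic
fixture; the catalogue never states per-SNP ancestry explicitly, and this
orientation is the one under which the gain/loss bookkeeping below is
defined.

## Seed sites

`classify_site()` and `scan_sites()` implement the three canonical site
types with strict Watson-Crick seed pairing (no G:U): an 8mer pairs miRNA
positions 2-8 with a target A across from position 1; a 7mer-m8 pairs 2-8
without the A; a 7mer-A1 pairs 2-7 with the A. The A1 rule demands a literal
target A regardless of the miRNA's first base, and at one anchor the
strongest applicable type is reported (8mer over 7mer-m8 over 7mer-A1).
6mers and non-canonical or 3'-compensatory sites are out of scope. Sites are
annotated with the variants they overlap via each allele's coordinate map;
a variant deleted from an allele can, by definition, overlap none of its
sites.

## Energies

Both energy models share one embedded parameter set, `turner_params()`: the
published Turner 2004 free energies at 37 °C (Watson-Crick and wobble
stacks, hairpin/bulge/internal-loop initiation by size with the
Jacobson-Stockmayer `1.07856 * log(n/30)` extension, linear multiloop model
`9.3 - 0.9 * branches + 0.0 * unpaired` kcal/mol, terminal-AU penalty 0.50,
bimolecular initiation 4.10, RT = 0.61633 kcal/mol). Tetraloop bonuses,
terminal mismatches, dangling ends, the 1x1/2x1/2x2 special internal-loop
tables and the loop-asymmetry term are deliberately omitted. The package's
correctness claims are therefore claims about *its own stated model*: the
dynamic programs are verified to match exhaustive enumeration under
identical parameters, not to reproduce any web server's printed energies,
which depend on unstated parameterizations and are treated as
non-reproducible references throughout. One published consequence of the
embedded set worth knowing: the bulge table is non-monotone at sizes 1 to 2
(3.8 vs 2.8 kcal/mol), as printed in its source.

`duplex_mfe()` is a hybridization-only intermolecular dynamic program:
helices with bulges and internal loops capped at 10 nt per side, stacking +
loop + terminal-AU + initiation terms, no intramolecular pairs, and wobble
pairs allowed except across from miRNA positions 2-8 (configurable). Ties
in the traceback resolve toward the 5'-most, most-stacked pairing, so
output is deterministic. A pairing whose total energy is positive is not a
stable interaction and is collapsed into the no-interaction sentinel, which
never passes the energy threshold. The selection threshold follows the
convention that a site is retained when its energy is *lower than or equal
to* -8.00 kcal/mol ("lower" on a free-energy scale meaning more negative).
Per (miRNA, UTR), the reported energy is the minimum over windows anchored
at canonical seed sites; each window extends the site interval 16 nt toward
the UTR 5' end, the side the miRNA 3' region pairs with (windows are capped
at 60 nt).

`fold_mfe()` and `partition_bpp()` are the corresponding single-strand
Zuker and McCaskill dynamic programs over the same model (hairpins >= 3 nt,
interior loops capped at 30 nt total). The partition function is scaled per
nucleotide so outputs stay finite up to the 500 nt desk-scale guard, and
for each nucleotide the pair probabilities plus the unpaired probability
sum to one within 1e-6. Both are verified against full Boltzmann
enumeration on short sequences, including forced-multiloop cases.

`accessibility()` makes the binary call from the MFE structure — is the
site's start nucleotide unpaired? — and reports the ensemble view (mean
unpaired probability over the site) alongside, because the literature's
accessibility language mixes both readings. The start nucleotide is defined
as the UTR position pairing miRNA seed position 2 (`t1 - 1`); the offset is
configurable since published structure figures mark the start with arrows
but never define it.

## Allele impact

`delta_mfe()` is the printed formula taken literally:
`MFE(ancestral duplex) - MFE(derived duplex)`, positive when the derived
allele binds more strongly. The published tables around this statistic are
internally inconsistent about sign (a worked pair of energies implies the
negative of a printed delta), so no sign is ever silently flipped here.
"Presence" of a site on an allele couples the canonical seed call with the
energy threshold, mirroring a workflow in which both filters precede
reporting; `call_gain_loss()` then labels derived-only presence a gain,
ancestral-only a loss, two-sided presence with unequal energies modulated.
Gain/loss calls require the two alleles to differ at exactly the focal
variant; UTR types that differ at several SNPs are compared in pairwise
mode (`compare_utr_types()`), where each side's best threshold-passing
seed-anchored energy is compared directly.

## The phylogeny stage

`align_pair()` is Needleman-Wunsch global alignment (match +1, mismatch -1,
gap -2 by default; the published workflow names no parameters, so these are
documented defaults), `p_distance()` the uncorrected mismatch fraction over
gap-free columns, and `neighbor_joining()` the Saitou-Nei algorithm, exact
on additive matrices, with negative branch-length estimates clamped to zero.
Near-identical UTR haplotypes do not need a progressive MSA; pairwise global
alignments feed the distance matrix.

The tree stage aligns **full per-type transcript (coding) sequences**, not
the 3'UTRs alone. This is a deliberate design decision: across the
catalogued SNPs, UTR7 differs from the UTR1 group at a single retained
variant, so p-distances computed on UTR sequences alone would place UTR7
inside the UTR1 clade, while the established LI/LII lineage split (UTR2a,
UTR2b, UTR2c, UTR4 and UTR7 on one side; UTR1a, UTR1b, UTR1c on the other)
reflects coding-level divergence — and the workflow this stage re-implements
aligned coding DNA sequences in the first place. The synthetic fixture
accordingly plants twelve lineage-informative coding substitutions (LII
alleles carry C at marker positions), emulating the coding-level divergence
that real allele lineages show.

## The synthetic data generator

Nothing in this package downloads anything; all inputs are generated.
`make_mica_like_fixture()` builds, from a fixed internal seed, a 1,380 nt
transcript with CDS start 86 and UTR boundary 1,327 satisfying, by
constraint solving, the full stop-codon arithmetic: frame 0 stops first at
1,154 (TAG); a G inserted at 952 shifts the frame so the first stop becomes
TAA at reference-projected 997; a G deleted at 892 shifts it the other way
to TGA at 1,035; and no earlier stop exists in any of the three frames for
*any* combination of the eleven catalogued SNP alleles. The solver mutates
free bases (to C, which occurs in no stop codon) until all constraints
hold and aborts loudly if it cannot; the planted stops, start codon, SNP
positions, indel anchor and lineage markers are locked. The generated
transcript is committed under `inst/extdata/` (named `synthetic_...` to
make its provenance unmistakable) and a test asserts the packaged files
equal the generator output byte for byte. Two catalogued SNPs sit at
positions 1,349 and 1,361, downstream of the printed UTR end 1,327 — an
inconsistency of the printed source transcribed as-is — so the fixture
transcript extends past the boundary and those SNPs fall outside every
reconstructed UTR.

`make_mirnas_with_planted_sites()` plants canonical sites by making the
miRNA seed the reverse complement of the designated window (position 8
forced to mismatch for 7mer-A1), with complementarity extended through
miRNA position 13 so planted duplexes pass the -8 kcal/mol threshold the
way a strong canonical site would; decoy miRNAs are random and verified
site-free. `simulate_gain_loss_cases()` builds allele pairs differing at
exactly one SNP inside a planted site and verifies, at generation time,
presence (with a passing energy) on one allele and absence on the other, so
downstream precision/recall measures the caller's bookkeeping rather than
generation luck.

What the generator does *not* emulate: real miRNA sequence composition
biases, linkage disequilibrium arising from population history (haplotypes
are asserted via configuration, not simulated from a coalescent),
alternative polyadenylation, and the parameter-level behaviour of external
prediction servers. Green tests on synthetic data therefore demonstrate the
correctness of the pipeline's arithmetic, scanning, thermodynamic
programming and bookkeeping — not the biological accuracy of any particular
site call on real sequence.

## Problem sizes and runtime choices

The verification suite runs entirely on small instances chosen so the whole
suite completes in about a minute on one core: enumeration oracles cover
duplexes up to 10 nt per strand (200 random pairs), folds up to 12 nt (100
random sequences, agreement within 1e-6), seed scanning up to 40 nt UTRs
(1,000 random pairs), 50 planted gain/loss cases, and 100 random additive
trees of 5-8 taxa. The pipeline itself folds the three UTR lengths of the
fixture (170/289/327 nt) directly; the partition function's 500 nt guard
marks the intended desk scale.

## Known limitations

* Energies are model energies: comparable within this package, not with
  outputs of external servers or of the full Turner model with terminal
  mismatches and dangles.
* Substitutions must preserve length; multi-nucleotide-variant support is
  limited to what insertion + deletion pairs at distinct positions express.
* Stops falling entirely inside inserted sequence have no reference
  projection; such alleles report `NA` reference coordinates (the packaged
  system never produces this).
* The accessibility call is structural only; no RISC footprint or
  context-score modelling.
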