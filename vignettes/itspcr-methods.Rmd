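---
title: "In silico PCR for fungal ITS primer evaluation: models, rules and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR for fungal ITS primer evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itspcr)
```

## Scope and model

`itspcr` emulates PCR amplification against a reference database as a pure
sequence-matching problem: a primer pair amplifies a reference sequence
when both primers find acceptable binding sites in convergent orientation
within an amplicon-length window. Everything that a thermocycler
contributes — salt and primer concentrations, cycling programs, polymerase
kinetics, primer dimers — is out of scope; those parameters cannot be
simulated from sequence alone, and the package makes no claim about them.
What can be computed from sequence is (a) where a degenerate primer can
bind and how badly, (b) which binding sites a given stringency policy would
tolerate, and (c) how binding-site quality translates into duplex
stability. These three layers are the package.

### Matching layer

Primer/template agreement is evaluated per position by IUPAC set
intersection: symbols are compatible iff the nucleotide sets they denote
overlap. Consequently the degenerate S in the ITS4ngs binding region
matches C and G templates at no cost, and an N in the template never
counts as a mismatch. The alternative view — that a template N reflects a
base-calling failure and should not be trusted — is available as
`ambiguity_mode = "strict"` in `pcr_params()`, which counts any template
ambiguity code as a mismatch. The default is the permissive intersection
rule, consistent with IUPAC semantics.

Mismatch offsets are always indexed from the primer 5′ end of its binding
region, on either strand; "the 3′-terminal window" is the last
`protected_3prime_bases` offsets. This convention keeps profiles
strand-invariant and directly comparable between forward and reverse
primers.

### Acceptance layer

A candidate site is accepted iff all three of the following hold, with the
defaults chosen to emulate permissive-but-not-promiscuous environmental PCR
conditions:

| rule | parameter | default | why it matters |
|---|---|---|---|
| mismatch budget | `max_mismatches` | 3 | tolerates natural template variation without accepting spurious sites |
| no long runs | `forbid_consecutive_run` | 3 | a block of consecutive mismatches disrupts the duplex more than the same number scattered |
| protected 3′ terminus | `protected_3prime_bases` | 2 | polymerase extension requires a paired 3′ end; terminal mismatches are fatal regardless of count |

The three rules are independent: the test suite verifies each one against
planted violations, exhaustively over all 1351 mismatch position sets of
size ≤ 3 on a 20-mer.

### Amplicon definition

The reported amplicon is the inter-primer region by default
(`include_primers = FALSE`), with the length bounds applied to whichever
definition is active. Reference pipelines differ on whether reported
amplicon lengths include the primer annealing sites, and nothing in the
output of such tools forces one convention; both are therefore supported
and the choice is recorded in the run log. Coordinates are 0-based,
half-open, reported on the plus strand of the record as stored, and hits
are sorted by (strand, forward-site start). Default length bounds of
50–900 nt bracket fungal ITS1/ITS2 sub-regions generously; they are
parameters, not constants.

When one representative hit per record is needed (e.g. for length
summaries), ties are broken deterministically: fewest total mismatches,
then shorter amplicon, then leftmost forward site, then plus strand.
Coverage counting never needs the tie-break because a record counts at
most once however many hits it yields.

### Thermodynamic layer

Per-site melting temperatures come from a nearest-neighbor duplex model
with the unified parameter set, at fixed conditions: 50 mM monovalent
salt, 0.25 µM total oligo, and the entropic salt correction
0.368·(N−1)·ln[Na⁺]. Perfectly matched stacks use the tabulated ΔH/ΔS
values (verified against an independent NN implementation to < 0.001 °C on
perfect duplexes); stacks flanking a mismatched position contribute no
stabilisation, and each mismatch adds a fixed +3 kcal/mol enthalpic
penalty. The penalty term is deliberately simple: tabulated single-mismatch
NN parameters exist but depend on both flanking bases and would buy
precision the package does not need. The only load-bearing contract — that
Tm decreases strictly with every added mismatch on a fixed window — is
guaranteed by the penalty construction and property-tested on random
18–21-mers. Reported Tm values should be read as a stringency ranking, not
as bench-accurate predictions. `recommended_annealing()` encodes the
conventional guidance of annealing about 5 °C below Tm.

## Primer model

The shipped primers are fusion oligos: sequencing adapter (33 nt forward /
34 nt reverse), an optional sample tag, then the template-binding core.
Adapter and tag bases do not anneal to the template, so matching them
against reference sequences would count them as mismatches everywhere;
they are therefore assigned to a non-binding `tail` and excluded. For
ITS3tagmix1-5 the post-adapter remainder contains a 9-nt tag before the
18-nt ITS3-ngs core, and only the core is matched by default. The five
tagmix variants differ only in the non-binding tag, so a single binding
region models all of them; users studying tag effects can override any
binding region via `primer()` or a YAML primer config, where the
`tail + binding_region == printed_sequence` invariant is revalidated.

## Reference databases

`read_reference_fasta()` expects one seven-rank QIIME-style lineage per
header and validates the IUPAC alphabet (U is normalised to T, case
folded). A label is *unidentified* when it is empty, matches a configurable
token list (default `"unidentified"`), or — at species rank — lacks a
binomial epithet (`_sp`/`_sp.` suffixes). `Incertae_sedis` is a formal
placement and deliberately not in the default token list; reference
databases do not document an exhaustive token vocabulary, so the list is a
parameter rather than a constant. Unidentified labels are never indexed as
taxa: coverage queries against them return empty member sets, while
per-rank unidentified *counts* are reported separately. Counting is
independent per rank (a record unidentified at family counts again at
genus and species), matching how per-level bar summaries are usually read.
Whether unidentified counts and phylum representation are taken over
amplified records or the whole database is ambiguous in common usage; both
universes are implemented (`universe = "amplified"` is the default, since
the question the package answers is what a sequencing run would recover).

Databases for this engine must retain the conserved flanks (SSU/5.8S/LSU
fragments) around the spacers — trimmed releases remove exactly the primer
binding sites this analysis needs. The reader enforces nothing about the
flanks beyond the alphabet.

## The synthetic generator and what it does (not) show

`generate_reference_db()` builds databases where the right answer is known
by construction. Each record is

```
flank | ITS2-analogue: F2 site · insert · rc(R2 site) | spacer |
        ITS1-analogue: F1 site · insert · rc(R1 site) | flank
```

- **Exact truth labels.** Per taxon and pair, an exact number of records
  (fraction × n, warning on rounding) is designed to amplify. Amplifiable
  records carry 0–3 benign forward-primer mismatches — sampled only from
  positions that keep the site acceptable, cycling 0,1,2,3 deterministically
  so coverage grows stepwise as the allowed budget rises and the designed
  fraction is reached exactly at budget 3. Non-amplifiable records get one
  of four failure plans planted on the forward site: `exceed-count` (4
  scattered mismatches), `consecutive-run` (3 in a row), `3prime-hit` (1
  mismatch in the protected window), or `missing-site` (site replaced by
  screened random sequence). Planted mismatch bases are chosen
  IUPAC-incompatible with the primer base, so labels are exact rather than
  probabilistic.
- **Screened randomness.** Flanks, inserts and spacers are uniform random
  ACGT rejection-sampled to contain no window within 3 mismatches of any
  primer in either orientation, preventing accidental amplicons from
  corrupting truth labels.
- **Region order.** The ITS2-analogue region precedes the ITS1-analogue
  one. This mirrors a real overlap: the ITS2-pair forward core is a
  substring of the reverse complement of the ITS1-pair reverse primer
  (both sit in 5.8S), so every planted ITS1 reverse site embeds an exact
  ITS2 forward site. Placing the ITS1 region last leaves that embedded
  site with no downstream reverse partner, so it can never create an
  unplanned amplicon.
- **Length structure.** Insert lengths are drawn from truncated normals
  per barcode; `its_bias_spec()` sets the ITS2-analogue mean 100 nt above
  the ITS1-analogue (350 ± 60 vs 250 ± 40 nt), emulating the observed
  tendency of ITS2 fragments to run longer, at a gap large enough for a
  two-group t-test at n = 50 to be decisive.
- **Lineage structure.** `its_bias_spec()` spreads ~900 records over 12
  named phyla plus unidentified-lineage fillers, with 20% of each taxon's
  species labels rewritten to `unidentified`, and focal taxa encoding
  strong opposed contrasts (48%/0%, 89%/56%, 68%/92%, and eight more
  one-sided taxa at n = 50). The focal genera are given distinct synthetic
  families so that family-level and genus-level designs stay independent;
  the spec is a caricature with clean signal, not a taxonomy.

Passing the synthetic suite therefore demonstrates that the engine applies
its stated rules exactly, that coverage arithmetic is correct, and that
the pipeline is deterministic and self-consistent. It does **not**
demonstrate that real fungal lineages are covered at any particular rate:
real reference sequences have correlated evolution around binding sites,
length variation far from normal, and annotation errors, none of which the
generator emulates. Conclusions about real primers still require running
the pipeline on a real reference release.

## Numerical and design choices

- **Welch t-test.** Amplicon-length comparisons use the unequal-variance
  t-test: barcode length distributions have no reason to share a variance,
  and Welch is the safer default when they happen to. Identical
  zero-variance samples return t = 0, p = 1 rather than an error; no
  multiple-testing correction is applied because a run produces a single
  planned comparison.
- **Percentages.** Stored at full precision; `round_half_up()` is provided
  for comparison against printed integer percentages (so 89.5 → 90, which
  IEEE banker's rounding would break).
- **Budget-restriction identity.** The accepted-hit set at budget k equals
  the budget-3 hit set restricted to both per-primer counts ≤ k (the run
  and 3′ rules are budget-independent). The test suite verifies this
  identity against the engine and then exploits it to evaluate coverage
  monotonicity across budgets without re-scanning.
- **Candidate search.** Binding-site candidates come from
  `Biostrings::matchPattern` (IUPAC-aware, mismatch-bounded); profiles and
  acceptance are then recomputed by the package's own rules. Tests compare
  the full engine against an independent pure-R all-window oracle on
  random and planted templates across randomised parameter settings.
- **Problem sizes.** The validation suite uses ~900-record databases,
  200-record oracle comparisons and 100-primer Tm sweeps — sizes chosen so
  the designed fractions are exact integers and the full suite runs in a
  few minutes on a laptop core, while still exercising every rule path.
- **Determinism.** All generator randomness flows through a single seed
  (`withr::with_seed`, leaving the caller's RNG untouched); re-running any
  stage with identical inputs reproduces outputs byte for byte, and each
  amplification run writes a provenance file (config, package version,
  database checksum).

## Known limitations

- Tm values rank stringency; they are not calibrated against melt-curve
  data, and mismatch penalties ignore flanking-sequence context.
- The engine reports all convergent site pairs within bounds; it does not
  model competition between overlapping products in a real reaction.
- The ITS3 tagmix is modelled as one binding region (see above).
- `ecoPCR`-style tools differ in undocumented internals (exact mismatch
  weighting, Tm formulas); equivalence is claimed only for the explicit
  acceptance rules implemented here.
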