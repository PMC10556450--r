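---
title: "Fork PCR genome walking: the model behind forkpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fork PCR genome walking: the model behind forkpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genome walking is the task of reading unknown DNA sequence that flanks a
known region, without building a genomic library. A single gene-specific
primer can only copy *away* from the known region; to amplify the flank
exponentially you need a second priming site inside the unknown sequence,
and you do not know one. Walking methods solve this by letting an
arbitrary "walking" primer anneal semi-randomly in the unknown flank
during one permissive cycle, then spending the rest of the experiment
enriching the one product that carries both the walking primer and the
known locus, while starving every off-target product.

`forkpcr` implements the fork-primer variant of this strategy as a fully
deterministic in-silico model: primer design, annealing, three rounds of
nested amplification, product classification, suppression, a virtual gel,
and a sequence-level verification step.

## The fork primer system

Three walking primers form the fork:

* **PFP** (primary fork primer), 41 nt = a 20-nt 5′ *branch* `b_P`
  followed by a 21-nt 3′ *stem* `s`;
* **SFP** (secondary fork primer), 41 nt = a different 20-nt branch
  `b_S` followed by the *same* stem `s`;
* **BP** (branch primer), 20 nt, with `BP = b_S`.

So `PFP = b_P ‖ s`, `SFP = BP ‖ s`, and the two primers drawn 5′-to-3′
diverge at the branch like a fork. The stems are homologous, the branches
heterologous: `forkpcr` caps the longest common substring of `b_P` and
`BP` at 10 nt (`design_constraints()$heterology_cap`). One BP is
*universal*: parallel fork sets designed in one call share it, so a single
primer drives every secondary and tertiary reaction.

`decompose_fork()` checks these invariants on any primer triple. Note the
3′ overlap check is `suffix(PFP, SFP) ≥ 21`, not `= 21`: the reference
set 2 shares 22 nt because the last branch base coincides by chance.

Per-sequence design rules (applied once each by `validate_oligo()`):

* alphabet strictly `{A, C, G, T}`;
* no homopolymer run of 4 or more (`max_run = 3`);
* per-base counts within `[floor(0.10 L), ceiling(0.50 L)]`. The window is
  applied to *counts*, rounded outward, so that 20-mers are judged on
  whole bases; the upper bound admits the reference BP, in which C alone
  accounts for half the bases;
* role-specific length window (41 for PFP/SFP, 20 for BP, 20–32 for
  NSPs).

Three **nested site-specific primers** (oNSP, mNSP, iNSP) are exact
substrings of the known sequence on the strand pointing toward the
unknown flank, ordered outermost to innermost and non-overlapping, so
each round's gene-specific primer lies strictly inside the previous
round's product.

## Annealing model

The thermal programs use two annealing temperatures, and the simulator
mirrors them with two stringency regimes over the primer's 3′-terminal
21-nt window:

* **low** (the single 25 °C cycle of round 1): exact 3′-terminal match
  (`run`) ≥ 7 nt *and* identity ≥ 0.6 over the window;
* **high** (all 65 °C cycles): `run` ≥ 18 nt, identity 1. Only designed
  matches — a full NSP site, the 21-nt stem, the 20-nt BP — reach this.

`find_binding_sites()` scans both strands exhaustively (seeded by the
3′ `min_run`-mer with an overlap-safe lookahead, then verified
position-by-position; the test suite checks equivalence against a naive
full scan). Coordinates are 0-based on the plus strand; `end3` is the
plus-strand position aligned (or paired) with the primer's 3′ base.
`extend_product()` emits the **full** primer, including any unhybridized
5′ tail — tail incorporation is the mechanism that plants the fork-primer
site copied by later rounds — followed by template-complementary
extension, truncated at `max_len` (default 5000 nt, the practical product
ceiling under a 2-minute extension step).

## The three rounds and product categories

**Round 1** (PFP + oNSP, one low-stringency cycle then 30 high): every
facing pair of low-stringency sites within `max_len` yields a
double-stranded product. Products are classified by their end primers:

| ends                        | category | fate |
|-----------------------------|----------|------|
| genuine oNSP site × PFP     | target   | walked into rounds 2–3 |
| oNSP × oNSP                 | I        | no mNSP site: diluted |
| off-target oNSP × PFP       | II       | no mNSP site: diluted |
| PFP × PFP                   | III      | suppressed (below) |

Unpaired single strands persist as linear "carryover" — at most one copy
per cycle, never a band.

**Round 2** (SFP at 0.02 µM, BP + mNSP at 0.2 µM, all high stringency):
SFP is modeled as a *bridge*: at one tenth of BP's concentration it
performs a single copying event per stem site, which integrates the BP
sequence into the product's end; BP and mNSP then amplify exponentially.
If `sfp_uM ≥ bp_uM` the simulator lets SFP amplify in its own right,
which is how the concentration flag reproduces the qualitative effect of
an SFP titration.

**Round 3** (BP + iNSP) repeats the mechanism without bridging — the BP
end already exists — so the target shrinks by the mNSP-to-iNSP distance.

## Suppression of category III

A PFP-only product begins with the 41-nt PFP and ends with its reverse
complement: a terminal inverted repeat (TIR) of at least 41 nt. On
denaturation/reannealing each single strand folds into a panhandle
hairpin whose 41-bp stem outcompetes any primer matching only part of
the repeat (SFP's stem covers 21 of the 41 nt). `forkpcr` models this as
a hard rule: a product is suppressed iff

```
terminal_inverted_repeat(seq) ≥ 41  AND
max 3′ run of any present primer at a terminal-repeat site < TIR
```

The second clause keeps the rule honest: a primer that matched the
*entire* repeat would outcompete the intramolecular fold. Category I/II
products have short or absent TIRs and are instead lost by dilution —
they simply have no high-stringency primer pair in rounds 2–3.

## Melting temperatures

`melt_temp()` implements the unified nearest-neighbor model
(duplex initiation terms per terminal base class), with

* entropy salt correction `0.368 (N−1) ln[Mon⁺]`,
* divalent correction via the monovalent equivalent
  `Mon_eq = Mon + 120 √(Mg²⁺ − dNTP)` (all mM; dNTPs chelate Mg²⁺),
* strand term `R ln(C_T/4)` for a non-self-complementary primer.

Defaults follow the reaction recipe: 50 mM monovalent, 2.5 mM Mg²⁺,
1.6 mM total dNTP, 0.2 µM primer. The method is pinned so that every Tm
assertion is reproducible; the test suite checks it against 50 frozen
values from an independent implementation with a 1.5 °C tolerance, and
the design windows carry a ±3 °C method tolerance (design window
[60, 65] °C, acceptance window [57, 68] °C). Under this method the
reference stems, branches and BP fall between 61.97 and 63.48 °C, and
the full-length fork primers between 77.07 and 77.43 °C — which is why a
65 °C annealing step admits a full fork-primer site but not a partial
one.

Structure screening is combinatorial, not thermodynamic: the designer
rejects a candidate with a hairpin stem ≥ 5 bp (loop ≥ 3), any
3′-anchored self/cross-dimer ≥ 4 bp, or a non-anchored dimer ≥ 8 bp.
These thresholds are conventional primer-design practice; a free-energy
folder is out of scope because the suppression logic only needs the
length rule.

## The synthetic fixture generator

`make_fixture()` builds the study system: a uniform-random genome
carrying

1. a known locus with exact oNSP/mNSP/iNSP sites pointing right toward
   the unknown flank (gaps of 30 nt between primers, junction 60 nt past
   iNSP);
2. a *partial* PFP site on the minus strand, `walk_distance` nt beyond
   the junction — its 3′-terminal 12 nt are exact and its window identity
   is 15/21 ≈ 0.71, so it anneals in the low regime only, exactly like a
   genuine chance site;
3. optionally, planted site pairs that force exactly one product of each
   unwanted category (I, II, III), each in its own zone separated by more
   than `max_len` so no cross-zone product can form.

After planting, the background is *scrubbed*: any unplanned
low-stringency PFP/oNSP site is destroyed by a single-base substitution
outside all protected intervals. The result is that the truth metadata —
coordinates, junction, and closed-form expected band lengths

```
len_primary   = |oNSP| + |PFP| + (q − p_a − 1)
len_secondary = len_primary − (start_mNSP − start_oNSP)
len_tertiary  = len_primary − (start_iNSP − start_oNSP)
```

(`p_a` the oNSP 3′ end, `q` the PFP 3′ pairing position) — fully
determines the simulator output, and regeneration from a seed is
byte-identical.

**Realism and limits.** Uniform random DNA has no repeats, GC skew or
gene structure; chance low-stringency sites are planted or scrubbed
rather than emergent, so the fixture measures the machinery, not
genome-scale off-target statistics. Abundance is a three-level class
(exponential / linear / suppressed), not a copy-number model, so band
intensities and titration curves are out of scope. Typical problem sizes
used in the tests: genomes of 4–20 kb, walks of 0.4–4.5 kb, all within
seconds.

## Open design decisions

* **Balance window.** The per-base composition rule is enforced as count
  bounds with an upper fraction of 0.50; a narrower window would reject
  the reference BP itself.
* **NSP overlap policy.** NSPs are required non-overlapping (gap ≥ 0,
  abutting allowed). Overlapping nested primers would still amplify but
  blur the per-round size arithmetic.
* **Nesting orientation.** "Nested" is interpreted as successively closer
  to the unknown junction, so each inner primer lies inside the previous
  product — required for the round-over-round size decrease.
* **Bridge convention.** SFP below BP concentration contributes exactly
  one copying event per site rather than a partial amplification rate;
  the cutoff `sfp_uM ≥ bp_uM` for full amplification is a step function
  standing in for a continuous competition.
* **Low-regime thresholds.** `run ≥ 7`, identity ≥ 0.6 over 21 nt is a
  modeling choice for 25 °C annealing; the qualitative behavior (partial
  sites seed walking, designed sites survive 65 °C) is insensitive to
  moderate changes, which the tests exercise by planting sites on both
  sides of the thresholds.

## Worked pipeline

```{r}
library(forkpcr)

fork <- reference_fork_sets()$fork1
fx <- make_fixture(walk_distance = 1500, categories = c("target", "I", "III"),
                   seed = 42)
res <- walk_simulate(fx$genome, fork, fx$nsps)
res$gel
#> lane P (round1): 1736, 840, 600
#> lane S (round2): 1681
#> lane T (round3): 1626

tg <- target_amplicons(res)[[1]]
verify_walk(tg, fx$known_seq)
#> TRUE
```

The same pipeline is scriptable end to end through the command-line
interface (`run_cli()`: `design`, `scan`, `simulate`, `protocol`,
`fixture`, `verify`), with all artifacts as FASTA/TSV/BED/JSON.
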