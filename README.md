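# forkpcr

In-silico design and simulation of **fork PCR genome walking**: obtaining
unknown DNA sequence flanking a known region, without a genomic library.

## The problem

PCR needs two converging primers. When you know a locus but not its
flank, you can place nested gene-specific primers (oNSP, mNSP, iNSP) in
the known sequence, but there is no primer site in the unknown flank.
Fork PCR creates one: a *primary fork primer* (PFP) anneals semi-randomly
in the flank during a single permissive 25 °C cycle, and the next two
rounds enrich only the product that carries both the fork-primer end and
the known locus, while every off-target product is diluted or actively
suppressed.

## The fork primer system

Three walking primers, where `‖` is concatenation:

```
PFP = b_P ‖ s        41 nt  (20-nt branch b_P, 21-nt stem s)
SFP = BP  ‖ s        41 nt  (BP is SFP's branch)
BP                   20 nt  (universal across parallel fork sets)
```

The stems are homologous, the branches heterologous
(`longest common substring(b_P, BP) ≤ 10`). Round 1 uses PFP + oNSP with
one low-stringency cycle (3′ run ≥ 7 nt, window identity ≥ 0.6) and 30
high-stringency cycles (3′ run ≥ 18 nt, exact). Round 2 uses SFP at one
tenth of BP's concentration: SFP *bridges* the fork end once via the
shared stem, integrating the BP site; BP + mNSP then amplify
exponentially. Round 3 is BP + iNSP.

Off-target product fates:

* **category I** (oNSP × oNSP) and **II** (off-target oNSP × PFP): no
  mNSP site, diluted to linear carryover;
* **category III** (PFP × PFP): both ends are the 41-nt PFP, giving a
  terminal inverted repeat ≥ 41 nt; each strand folds into a panhandle
  hairpin that outcompetes SFP (whose stem matches only 21 of the 41 nt),
  so the product is *suppressed*:
  `suppressed ⇔ TIR ≥ 41 ∧ max primer 3′ run at the repeat < TIR`.

A genuine walk therefore shows one band per round, shrinking by the
oNSP→mNSP and mNSP→iNSP nesting distances.

Melting temperatures use the unified nearest-neighbor model with an
entropy salt correction `0.368 (N−1) ln[Mon⁺]`, a divalent correction
`Mon_eq = Mon + 120 √(Mg²⁺ − dNTP)` and strand term `R ln(C_T/4)`, at the
reaction conditions (50 mM monovalent, 2.5 mM Mg²⁺, 1.6 mM dNTP, 0.2 µM
primer).

## Worked example

Simulate a 1.5-kb walk on a seeded synthetic genome that also carries
planted category I and III products:

```r
library(forkpcr)

fork <- reference_fork_sets()$fork1
fork
#> <fork_primer_set> fork1
#>   PFP  5'-ACGCGTAATAGCTCGGGATG ATGCTGCTCGTGGATGACTCT-3'
#>   SFP  5'-CCTGACCGCCTTCTACACCT ATGCTGCTCGTGGATGACTCT-3'
#>   BP   5'-CCTGACCGCCTTCTACACCT-3'

round(melt_temp(fork$stem), 2)     # stem Tm under reaction conditions
#> [1] 63.48
round(melt_temp(fork$bp$seq), 2)
#> [1] 63.26

fx <- make_fixture(walk_distance = 1500,
                   categories = c("target", "I", "III"), seed = 42)
fx
#> <fixture> 13510-nt genome, seed 42
#>   known locus [11594, 11789), junction at 11789
#>   walk 1500 nt; expected target bands P/S/T = 1736/1681/1626 nt
#>   planted categories: I (600 nt), III (840 nt)

res <- walk_simulate(fx$genome, fork, fx$nsps)
res
#> <walk_result> fork set fork1
#> <product_pool> round 1: 7 product(s)
#>      840 nt  [III]     exponential PFP1--PFP1
#>      600 nt  [I]       exponential gadA_oNSP--gadA_oNSP
#>     1736 nt  [target]  exponential gadA_oNSP--PFP1
#>     5000 nt  [carryover] linear      PFP1--(template end)
#>     5000 nt  [carryover] linear      gadA_oNSP--(template end)
#>      796 nt  [carryover] linear      gadA_oNSP--(template end)
#>     1916 nt  [carryover] linear      gadA_oNSP--(template end)
#> <product_pool> round 2: 3 product(s)
#>      840 nt  [III]     suppressed  PFP1--PFP1  SUPPRESSED
#>      600 nt  [carryover] linear      gadA_oNSP--gadA_oNSP
#>     1681 nt  [target]  exponential gadA_mNSP--BP
#> <product_pool> round 3: 1 product(s)
#>     1626 nt  [target]  exponential gadA_iNSP--BP
#> <gel_report> band sizes (nt), largest first
#>   lane P (round1): 1736, 840, 600
#>   lane S (round2): 1681
#>   lane T (round3): 1626
```

The category III product is suppressed in round 2, category I dilutes to
carryover, and the target walks down 1736 → 1681 → 1626 nt, exactly the
closed-form truth of the fixture. Verify the tertiary product against the
known sequence and extract the newly walked bases:

```r
tg <- target_amplicons(res)[[1]]
verify_walk(tg, fx$known_seq)
#> [1] TRUE

overlap <- fx$truth$junction - fx$truth$insp[["start"]]  # 85 nt known
walked <- substr(tg$seq, overlap + 1, nchar(tg$seq))
nchar(walked)   # 1500 walked + 41 fork-primer tail
#> [1] 1541
substr(walked, 1, 60)
#> [1] "TCATGGGCCTTTTAACAAGTCTCCACTTAGCTGATCCGGGTTGGTAAGTTATGCACTATG"
```

Primer design de novo, bench protocol, and the whole pipeline are also
available from the command line:

```sh
Rscript inst/cli/forkpcr.R design   --seed 12 --out out/design --n-sets 2
Rscript inst/cli/forkpcr.R fixture  --seed 7  --out out/fx --walk-distance 1200
Rscript inst/cli/forkpcr.R simulate --genome out/fx/genome.fasta \
        --primers out/fx/primers.tsv --out out/sim
Rscript inst/cli/forkpcr.R verify   --amplicons out/sim/amplicons.fasta \
        --known out/fx/known.fasta --out out/verify
Rscript inst/cli/forkpcr.R protocol --out out/protocol
```

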