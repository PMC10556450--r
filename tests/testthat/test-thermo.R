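test_that("melt_temp agrees with frozen nearest-neighbor oracle values", {
  for (i in seq_len(nrow(tm_oracle))) {
    expect_lt(abs(melt_temp(tm_oracle$seq[i]) - tm_oracle$tm[i]), 1.5,
              label = paste("Tm of", tm_oracle$seq[i]))
  }
})

test_that("reference stems, branches and BP melt inside the design window", {
  segs <- c(ref_forks$fork1$stem, ref_forks$fork2$stem,
            ref_forks$fork1$pfp_branch, ref_forks$fork2$pfp_branch,
            ref_forks$fork1$bp$seq)
  tms <- vapply(segs, melt_temp, numeric(1))
  expect_true(all(tms >= 57 & tms <= 68))
  # full-length fork primers melt far above their segments
  full <- vapply(c(ref_forks$fork1$pfp$seq, ref_forks$fork1$sfp$seq,
                   ref_forks$fork2$pfp$seq, ref_forks$fork2$sfp$seq),
                 melt_temp, numeric(1))
  expect_true(all(full >= 71 & full <= 79))
  expect_true(min(full) > max(tms))
})

test_that("melt_temp responds to conditions in the physical direction", {
  s <- ref_forks$fork1$stem
  # more salt stabilizes the duplex
  expect_gt(melt_temp(s, thermo_conditions(monovalent_mM = 150)),
            melt_temp(s, thermo_conditions(monovalent_mM = 50)))
  # more primer raises Tm via the strand term
  expect_gt(melt_temp(s, thermo_conditions(primer_uM = 2)),
            melt_temp(s, thermo_conditions(primer_uM = 0.2)))
  # dNTPs chelate Mg2+ and destabilize
  expect_lt(melt_temp(s, thermo_conditions(dntp_mM = 2.4)),
            melt_temp(s, thermo_conditions(dntp_mM = 0.4)))
  expect_error(melt_temp("ACGT"), "8-64")
  expect_error(melt_temp(s, thermo_conditions(monovalent_mM = -1)))
  expect_error(thermo_conditions(mg_mM = NA))
})

test_that("hairpin_scan reports maximal stems matching full enumeration", {
  # constructed hairpin: 6-bp stem, 4-nt loop
  hp <- paste0("GCATGC", "TTTT", revcomp("GCATGC"))
  h <- hairpin_scan(hp, min_loop = 3L)
  expect_gte(max(h$stem), 6L)
  expect_identical(max(h$stem), oracle_hairpin_max(hp))
  expect_error(hairpin_scan(hp, min_loop = 2L), "min_loop")
  set.seed(11)
  for (i in seq_len(60)) {
    s <- random_dna(sample(10:30, 1))
    h <- hairpin_scan(s)
    got <- if (nrow(h)) max(h$stem) else 0L
    expect_identical(got, oracle_hairpin_max(s), label = s)
  }
})

test_that("dimer_scan finds duplex windows and 3'-anchor flags", {
  # a primer against its own reverse complement: full-length 3'-anchored duplex
  a <- "GACTTCGGATCAAGTCCGTA"
  d <- dimer_scan(a, revcomp(a))
  expect_identical(max(d$stem), nchar(a))
  expect_true(any(d$anchored3p & d$stem == nchar(a)))
  # no complementarity at all
  expect_identical(nrow(dimer_scan("AAAAAAAA", "CCCCCCCC")), 0L)
  # the reference BP has no dangerous 3'-anchored duplex with the gadA iNSP
  d2 <- dimer_scan(ref_forks$fork1$bp, ref_nsps$gadA$insp)
  expect_lt(if (any(d2$anchored3p)) max(d2$stem[d2$anchored3p]) else 0L, 4L)
  set.seed(12)
  for (i in seq_len(60)) {
    a <- random_dna(sample(8:25, 1))
    b <- random_dna(sample(8:25, 1))
    d <- dimer_scan(a, b)
    got <- c(if (nrow(d)) max(d$stem) else 0L,
             if (any(d$anchored3p)) max(d$stem[d$anchored3p]) else 0L)
    expect_identical(as.integer(got), as.integer(oracle_dimer_max(a, b)),
                     label = paste(a, b))
  }
})

test_that("fast structure screens agree with the full scanning functions", {
  set.seed(13)
  for (i in seq_len(80)) {
    s <- random_dna(sample(15:45, 1))
    h <- hairpin_scan(s)
    expect_identical(forkpcr:::max_hairpin_stem(s),
                     if (nrow(h)) max(h$stem) else 0L, label = s)
    b <- random_dna(sample(15:45, 1))
    d <- dimer_scan(s, b)
    expect_identical(
      as.integer(forkpcr:::max_dimer_stems(s, b)),
      as.integer(c(if (nrow(d)) max(d$stem) else 0L,
                   if (any(d$anchored3p)) max(d$stem[d$anchored3p]) else 0L)),
      label = paste(s, b))
  }
})

test_that("terminal_inverted_repeat measures panhandle-forming termini", {
  expect_identical(terminal_inverted_repeat("ACGT"), 4L)
  expect_identical(terminal_inverted_repeat("AATT"), 4L)
  expect_identical(terminal_inverted_repeat("AACC"), 0L)
  set.seed(14)
  x <- random_dna(41)
  prod3 <- paste0(x, random_dna(200), revcomp(x))
  expect_gte(terminal_inverted_repeat(prod3), 41L)
  # a product with unrelated ends has only a chance-level repeat
  y <- paste0("AC", random_dna(100), "AC")
  expect_lt(terminal_inverted_repeat(y), 41L)
  expect_error(terminal_inverted_repeat("A"), "at least 2")
})

test_that("structure thresholds classify designed primers as safe", {
  thr <- structure_thresholds()
  for (f in ref_forks) {
    expect_false(forkpcr:::severe_hairpin(f$bp$seq, thr))
    expect_false(forkpcr:::severe_dimer(f$bp$seq, f$stem, thr))
  }
  # a perfect self-complementary primer is a severe self-dimer
  pal <- paste0("GCATGCAT", revcomp("GCATGCAT"))
  expect_true(forkpcr:::severe_dimer(pal, pal, thr))
})
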