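test_that("dna normalizes case and rejects non-ACGT input", {
  expect_identical(dna("acgt"), "ACGT")
  expect_error(dna("ACGN"), "non-ACGT")
  expect_error(dna(""), "empty")
  expect_error(dna("ACGU"), "non-ACGT")
  expect_error(dna(c("A", "C")), "single character string")
})

test_that("revcomp matches hand-checkable examples", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAAC"), "GTTT")
  expect_identical(revcomp("CCTGACCGCCTTCTACACCT"), "AGGTGTAGAAGGCGGTCAGG")
  expect_error(revcomp("ACGX"), "non-ACGT")
})

test_that("revcomp is an involution and agrees with a table-lookup oracle", {
  set.seed(42)
  for (i in seq_len(10000)) {
    s <- random_dna(sample(1:50, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
  set.seed(43)
  for (i in seq_len(200)) {
    s <- random_dna(sample(1:60, 1))
    expect_identical(revcomp(s), oracle_revcomp(s))
  }
})

test_that("terminal-run lengths match the reference fork architecture", {
  f1 <- ref_forks$fork1; f2 <- ref_forks$fork2
  expect_identical(longest_common_suffix(f1$pfp$seq, f1$sfp$seq), 21L)
  # fork set 2 shares one extra base by coincidence of branch termini
  expect_identical(longest_common_suffix(f2$pfp$seq, f2$sfp$seq), 22L)
  expect_identical(longest_common_prefix(f1$bp$seq, f1$sfp$seq), 20L)
  expect_identical(longest_common_prefix(f2$bp$seq, f2$sfp$seq), 20L)
  expect_identical(longest_common_suffix("ACGT", "ACGT"), 4L)
  expect_identical(longest_common_prefix("AC", "GT"), 0L)
})

test_that("suffix/prefix/substring lengths agree with brute-force oracles", {
  set.seed(7)
  for (i in seq_len(150)) {
    a <- random_dna(sample(1:40, 1))
    b <- random_dna(sample(1:40, 1))
    expect_identical(longest_common_suffix(a, b), oracle_suffix(a, b))
    expect_identical(longest_common_prefix(a, b), oracle_prefix(a, b))
    expect_identical(forkpcr:::longest_common_substring(a, b),
                     as.integer(oracle_common_substring(a, b)))
  }
})

test_that("max_homopolymer_run reproduces known primer run lengths", {
  expect_identical(max_homopolymer_run(ref_forks$fork1$pfp$seq), 3L)
  expect_identical(max_homopolymer_run("ACACACAC"), 1L)
  expect_identical(max_homopolymer_run("AAAA"), 4L)
  # the reference gadR iNSP contains a 4-base run (AAAA)
  expect_identical(max_homopolymer_run(ref_nsps$gadR$insp$seq), 4L)
})

test_that("oligo construction enforces the length bound and role set", {
  o <- oligo("x", "acgtacgt", "BP")
  expect_s3_class(o, "oligo")
  expect_identical(o$seq, "ACGTACGT")
  expect_error(oligo("x", strrep("A", 65)), "maximum supported is 64")
  expect_error(oligo("x", "ACGT", "bogus"))
})

test_that("validate_oligo applies every design rule exactly once", {
  rep_bp <- validate_oligo(ref_forks$fork1$bp)
  expect_s3_class(rep_bp, "validation_report")
  expect_identical(sort(rep_bp$rule),
                   sort(c("alphabet", "run_length", "base_balance",
                          "length_window")))
  expect_true(report_ok(rep_bp))
  # all printed fork primers satisfy the rules
  for (f in ref_forks) {
    for (o in list(f$pfp, f$sfp, f$bp)) {
      expect_true(report_ok(validate_oligo(o)), label = o$name)
    }
  }
  # a 4-base run fails run_length only
  bad <- validate_oligo(oligo("bad", "GGTCAAAACGGTCAGTCCAT", "BP"))
  expect_false(report_ok(bad))
  expect_false(bad$pass[bad$rule == "run_length"])
  expect_true(all(bad$pass[bad$rule != "run_length"]))
  # the reference gadR iNSP violates run_length (and nothing else)
  gr <- validate_oligo(ref_nsps$gadR$insp)
  expect_false(report_ok(gr))
  expect_identical(gr$rule[!gr$pass], "run_length")
})

test_that("decompose_fork accepts both reference sets and derives segments", {
  f1 <- ref_forks$fork1
  expect_s3_class(f1, "fork_primer_set")
  expect_identical(nchar(f1$pfp$seq), 41L)
  expect_identical(nchar(f1$sfp$seq), 41L)
  expect_identical(nchar(f1$stem), 21L)
  expect_identical(nchar(f1$pfp_branch), 20L)
  expect_identical(paste0(f1$pfp_branch, f1$stem), f1$pfp$seq)
  expect_identical(paste0(f1$bp$seq, f1$stem), f1$sfp$seq)
  f2 <- ref_forks$fork2
  expect_identical(f2$bp$seq, f1$bp$seq)  # universal branch primer
  expect_identical(nchar(f2$stem), 21L)
})

test_that("decompose_fork rejects mismatched fork architectures", {
  f1 <- ref_forks$fork1; f2 <- ref_forks$fork2
  # PFP from set 1 with SFP from set 2: stems disagree
  expect_error(decompose_fork(f1$pfp, f2$sfp, f1$bp), "stem_overlap")
  expect_error(decompose_fork(oligo("p", strrep("AC", 10), "PFP"),
                              f1$sfp, f1$bp), "pfp_length")
  expect_error(decompose_fork(f1$pfp, f1$sfp,
                              oligo("b", "ACGTACGTAC", "BP")), "bp_length")
  # BP that is not SFP's branch
  wrong_bp <- oligo("b", revcomp(f1$bp$seq), "BP")
  expect_error(decompose_fork(f1$pfp, f1$sfp, wrong_bp), "bp_branch")
  # homologous branches are rejected: PFP branch equal to BP
  pfp_hom <- oligo("p", paste0(f1$bp$seq, f1$stem), "PFP")
  expect_error(decompose_fork(pfp_hom, f1$sfp, f1$bp), "branch_heterology")
})

test_that("nsp_set locates nested primers and rejects disorder", {
  g <- ref_nsps$gadA
  known <- paste0(strrep("GATC", 10), g$onsp$seq, "TTACG", g$mnsp$seq,
                  "CCATG", g$insp$seq, strrep("CTAG", 10))
  s <- nsp_set(g$onsp, g$mnsp, g$insp, known, "right")
  expect_s3_class(s, "nsp_set")
  expect_identical(unname(s$coords$onsp["start"]), 40L)
  expect_identical(unname(s$coords$onsp["end"]), 65L)
  expect_true(s$coords$onsp["end"] <= s$coords$mnsp["start"])
  expect_true(s$coords$mnsp["end"] <= s$coords$insp["start"])
  # walking left: primers live on the reverse complement strand
  s2 <- nsp_set(g$onsp, g$mnsp, g$insp, revcomp(known), "left")
  expect_identical(s2$coords$onsp, s$coords$onsp)
  # swapped order fails the nesting check
  expect_error(nsp_set(g$insp, g$mnsp, g$onsp, known, "right"),
               "not nested")
  expect_error(nsp_set(g$onsp, g$mnsp, "ACGTACGTACGTACGTACGTACGTA", known,
                       "right"), "not a substring")
  expect_error(nsp_set(g$onsp, g$mnsp, oligo("short", "ACGTACGTACGT"),
                       known, "right"), "length")
})
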