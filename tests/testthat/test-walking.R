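# a small fixture with all product categories planted, shared across tests
fx_all <- make_fixture(walk_distance = 900L,
                       categories = c("target", "I", "II", "III"),
                       seed = 301L)
res_all <- walk_simulate(fx_all$genome, fx_all$fork_set, fx_all$nsps)

expo <- function(pool) {
  Filter(function(a) a$abundance == "exponential" && !a$suppressed,
         pool$amplicons)
}

test_that("round 1 produces each planted category at its planted length", {
  p1 <- res_all$pools[[1]]
  e1 <- expo(p1)
  cats <- vapply(e1, `[[`, "", "category")
  lens <- vapply(e1, `[[`, integer(1), "length")
  truth <- fx_all$truth
  expect_identical(sort(unique(cats)), sort(c("target", "I", "II", "III")))
  expect_identical(lens[cats == "target"],
                   unname(truth$expected_target_len["primary"]))
  for (cat in c("I", "II", "III")) {
    expect_identical(lens[cats == cat],
                     unname(truth$expected_category_len[cat]),
                     label = paste("category", cat))
  }
  # unpaired single strands are retained as linear carryover
  expect_true(any(vapply(p1$amplicons, function(a)
    a$abundance == "linear", logical(1))))
})

test_that("category III products are suppressed in round 2", {
  p2 <- res_all$pools[[2]]
  sup <- Filter(function(a) a$suppressed, p2$amplicons)
  expect_true(length(sup) >= 1L)
  expect_true(all(vapply(sup, `[[`, "", "category") == "III"))
  # the panhandle rule: their terminal inverted repeat reaches the threshold
  for (a in sup) {
    expect_gte(terminal_inverted_repeat(a$seq), 41L)
  }
  # no suppressed product is carried as exponential
  e2 <- expo(p2)
  expect_false(any(vapply(e2, `[[`, "", "category") == "III"))
})

test_that("categories I and II dilute to carryover in round 2", {
  p2 <- res_all$pools[[2]]
  co <- Filter(function(a) a$abundance == "linear", p2$amplicons)
  expect_gte(length(co), 2L)
  # nothing with category I or II remains exponential
  e2 <- expo(p2)
  expect_true(all(vapply(e2, `[[`, "", "category") == "target"))
})

test_that("target bands shrink by the nesting offsets across rounds", {
  truth <- fx_all$truth
  for (r in 1:3) {
    e <- expo(res_all$pools[[r]])
    tg <- Filter(function(a) a$category == "target", e)
    expect_identical(length(tg), 1L, label = paste("round", r))
    expect_identical(tg[[1]]$length,
                     unname(truth$expected_target_len[r]),
                     label = paste("round", r))
  }
  d12 <- truth$expected_target_len["primary"] -
    truth$expected_target_len["secondary"]
  d23 <- truth$expected_target_len["secondary"] -
    truth$expected_target_len["tertiary"]
  expect_identical(unname(d12),
                   unname(truth$mnsp["start"] - truth$onsp["start"]))
  expect_identical(unname(d23),
                   unname(truth$insp["start"] - truth$mnsp["start"]))
})

test_that("the tertiary target starts with iNSP and ends with the BP site", {
  tg <- target_amplicons(res_all)
  expect_length(tg, 1L)
  a <- tg[[1]]
  expect_true(startsWith(a$seq, fx_all$nsps$insp$seq))
  expect_true(endsWith(a$seq, revcomp(fx_all$fork_set$bp$seq)))
  expect_true(verify_walk(a, fx_all$known_seq))
})

test_that("round sequencing is enforced", {
  fs <- fx_all$fork_set
  expect_error(simulate_secondary(res_all$pools[[2]], fs$sfp, fs$bp,
                                  fx_all$nsps$mnsp), "round-1 pool")
  expect_error(simulate_tertiary(res_all$pools[[1]], fs$bp,
                                 fx_all$nsps$insp), "round-2 pool")
})

test_that("a template without the oNSP site warns and yields no target", {
  # two-letter template: no primer 3' seed can occur on either strand
  tpl <- strrep("ACCA", 1000)
  expect_warning(
    p1 <- simulate_primary(tpl, ref_forks$fork1$pfp, ref_nsps$gadA$onsp),
    "binding site")
  expect_length(target_amplicons(p1, 1L), 0L)
})

test_that("SFP at amplifier concentration lifts the bridge-only behavior", {
  # at the default 1:10 ratio every exponential round-2 product ends in BP
  # or mNSP, never SFP
  p2 <- res_all$pools[[2]]
  ends <- unlist(lapply(expo(p2), function(a) c(a$left, a$right)))
  expect_false(any(grepl("SFP", ends)))
  params_hot <- sim_params(sfp_uM = 0.2, bp_uM = 0.2)
  p2_hot <- simulate_secondary(res_all$pools[[1]], fx_all$fork_set$sfp,
                               fx_all$fork_set$bp, fx_all$nsps$mnsp,
                               params_hot)
  lens_hot <- vapply(expo(p2_hot), `[[`, integer(1), "length")
  lens_def <- vapply(expo(p2), `[[`, integer(1), "length")
  expect_gte(length(lens_hot), length(lens_def))
})

test_that("virtual_gel shows only exponential, unsuppressed bands", {
  gel <- res_all$gel
  expect_s3_class(gel, "gel_report")
  expect_identical(names(gel), c("round1", "round2", "round3"))
  truth <- fx_all$truth
  expect_true(truth$expected_target_len["tertiary"] %in% gel$round3$length)
  # suppressed category III leaves no band after round 1
  expect_false(truth$expected_category_len["III"] %in% gel$round2$length)
  # lanes are sorted largest first
  for (lane in gel) {
    expect_false(is.unsorted(rev(lane$length)))
  }
  expect_error(virtual_gel(list()), "at least one")
})

test_that("virtual_gel merges equal-length bands with a count", {
  pool <- forkpcr:::new_pool(3L, list(
    forkpcr:::new_amplicon(strrep("A", 500), "x", "y", TRUE, TRUE,
                           "target", "exponential", 3L),
    forkpcr:::new_amplicon(strrep("C", 500), "x", "z", TRUE, TRUE,
                           "target", "exponential", 3L),
    forkpcr:::new_amplicon(strrep("G", 200), "x", "y", TRUE, TRUE,
                           "target", "linear", 3L)))
  gel <- virtual_gel(pool)
  expect_identical(gel$round3$length, 500L)
  expect_identical(gel$round3$count, 2L)
})

test_that("verify_walk accepts the true product and rejects corruptions", {
  tg <- target_amplicons(res_all)[[1]]
  expect_true(verify_walk(tg$seq, fx_all$known_seq, "right"))
  # single substitution inside the known overlap
  corrupt <- tg$seq
  substr(corrupt, 25, 25) <- if (substr(corrupt, 25, 25) == "A") "C" else "A"
  v <- verify_walk(corrupt, fx_all$known_seq, "right")
  expect_false(isTRUE(v))
  # too short to anchor
  v2 <- verify_walk("ACGTACGTACGTACG", fx_all$known_seq, "right")
  expect_false(isTRUE(v2))
  expect_match(attr(v2, "reason"), "not found")
  # amplicon from elsewhere entirely
  set.seed(72)
  v3 <- verify_walk(random_dna(400), fx_all$known_seq, "right")
  expect_false(isTRUE(v3))
})
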