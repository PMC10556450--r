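# make a low- but not high-stringency version of a primer's 3' window:
# the last `tail_keep` bases stay exact (seeds the low-stringency 3' run),
# the head is mutated except at every third position, holding window
# identity near 0.71 -- above the 0.6 low threshold, below a designed match
partial_site_window <- function(primer_seq, window = 21L, tail_keep = 12L) {
  w <- substr(primer_seq, nchar(primer_seq) - window + 1L, nchar(primer_seq))
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  head_len <- window - tail_keep
  for (i in seq_len(head_len)) {
    if (i %% 3L != 0L) chars[i] <- chartr("ACGT", "CAGT", chars[i])
  }
  # A->C, C->A, G->T leave T fixed; force T mutations too
  for (i in seq_len(head_len)) {
    if (i %% 3L != 0L && chars[i] == "T") chars[i] <- "G"
  }
  paste(chars, collapse = "")
}

.overlaps <- function(a_start, a_end, ivs) {
  any(vapply(ivs, function(iv) a_start < iv[2] && iv[1] < a_end, logical(1)))
}

#' Generate a seeded synthetic walking fixture
#'
#' Builds a random-base genome carrying (1) a known locus with exact
#' oNSP/mNSP/iNSP sites pointing right toward an unknown flank, (2) if
#' `"target"` is requested, a partial PFP site (low- but not
#' high-stringency) on the minus strand `walk_distance` nt beyond the
#' known junction, and (3) optional planted site pairs that force exactly
#' one primary product of each requested unwanted category (I: oNSP-oNSP,
#' II: oNSP-PFP off target, III: PFP-PFP). Plant zones are separated by
#' more than the maximum product length so no cross-zone product can form,
#' and the random background is scrubbed of unintended low-stringency
#' PFP/oNSP sites, so the truth metadata fully determines the simulator
#' output. Regeneration from the same seed is byte-identical.
#'
#' @param genome_len genome length (nt); `NULL` uses the minimum layout.
#' @param walk_distance distance (nt) from the known junction to the PFP
#'   site's 3' pairing position.
#' @param categories character subset of `c("target", "I", "II", "III")`.
#' @param fork_set a `fork_primer_set` (default: reference set 1).
#' @param nsps list with onsp/mnsp/insp oligos (default: gadA set).
#' @param seed integer seed.
#' @param params a [sim_params] (supplies the low-stringency model used
#'   for scrubbing and the max product length used for zone spacing).
#' @param category_gaps named insert gaps (nt between the facing 3' ends,
#'   exclusive) for planted category products.
#' @return a `fixture`: genome sequence, `truth` metadata (all coordinates
#'   0-based; expected per-round target lengths in closed form; expected
#'   category product lengths), known sequence, seed.
#' @export
make_fixture <- function(genome_len = NULL, walk_distance = 1500L,
                         categories = "target",
                         fork_set = reference_fork_sets()$fork1,
                         nsps = reference_nsps()$gadA,
                         seed = 1L, params = sim_params(),
                         category_gaps = c(I = 550L, II = 650L, III = 758L)) {
  stopifnot(inherits(fork_set, "fork_primer_set"))
  bad <- setdiff(categories, c("target", "I", "II", "III"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  onsp <- nsps$onsp; mnsp <- nsps$mnsp; insp <- nsps$insp
  pfp <- fork_set$pfp
  w <- params$stringency[[1]]$window  # planted-window width
  sep <- params$max_len + 1L          # no cross-zone product can form

  # --- layout (all 0-based plus-strand coordinates) ---
  pos <- 200L
  plants <- list()   # per category: fwd primer/end3, rev primer/end3
  for (cat in intersect(c("I", "II", "III"), categories)) {
    gap <- as.integer(category_gaps[[cat]])
    fwd_p <- if (cat == "III") pfp else onsp
    rev_p <- if (cat == "I") onsp else pfp
    f <- pos + w - 1L                 # fwd 3' end
    q <- f + gap + 1L                 # rev 3' end
    plants[[cat]] <- list(fwd_primer = fwd_p, fwd_end3 = f,
                          rev_primer = rev_p, rev_end3 = q,
                          expected_len = nchar(fwd_p$seq) +
                            nchar(rev_p$seq) + gap)
    pos <- q + w + sep
  }
  o_s <- pos
  m_s <- o_s + nchar(onsp$seq) + 30L
  i_s <- m_s + nchar(mnsp$seq) + 30L
  junction <- i_s + nchar(insp$seq) + 60L   # known region is [o_s, junction)
  q_target <- junction + as.integer(walk_distance)
  required <- q_target + w + 200L
  if (is.null(genome_len))
    genome_len <- max(required, walk_distance + 1000L)
  genome_len <- as.integer(genome_len)
  if (genome_len < walk_distance + 1000L)
    stop("genome_len must be at least walk_distance + 1000", call. = FALSE)
  if (genome_len < required)
    stop("fixture error: planted features collide or overflow the genome ",
         "(need ", required, " nt, have ", genome_len, ")", call. = FALSE)

  with_seed(seed, {
    g <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

    place <- function(g, start0, seq) {  # start0 0-based
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      g[(start0 + 1L):(start0 + length(chars))] <- chars
      g
    }
    protected <- list()
    protect <- function(start0, len) {
      protected[[length(protected) + 1L]] <<- c(start0, start0 + len)
    }
    expected_sites <- list()
    expect_site <- function(primer, strand, end3) {
      expected_sites[[length(expected_sites) + 1L]] <<-
        list(primer = primer$name, strand = strand, end3 = end3)
    }

    # known locus: exact NSP sites
    for (spec in list(list(onsp, o_s), list(mnsp, m_s), list(insp, i_s))) {
      g <- place(g, spec[[2]], spec[[1]]$seq)
      protect(spec[[2]], nchar(spec[[1]]$seq))
    }
    expect_site(onsp, "+", o_s + nchar(onsp$seq) - 1L)

    plant_fwd <- function(g, primer, end3) {
      win <- partial_site_window(primer$seq, w)
      g <- place(g, end3 - w + 1L, win)
      protect(end3 - w + 1L, w)
      expect_site(primer, "+", end3)
      g
    }
    plant_rev <- function(g, primer, end3) {
      win <- partial_site_window(primer$seq, w)
      g <- place(g, end3, revcomp(win))
      protect(end3, w)
      expect_site(primer, "-", end3)
      g
    }
    if ("target" %in% categories) g <- plant_rev(g, pfp, q_target)
    for (cat in names(plants)) {
      pl <- plants[[cat]]
      g <- plant_fwd(g, pl$fwd_primer, pl$fwd_end3)
      g <- plant_rev(g, pl$rev_primer, pl$rev_end3)
    }

    # --- scrub unintended low-stringency PFP/oNSP sites ---
    low <- params$stringency[[1]]
    gseq <- paste(g, collapse = "")
    for (iter in seq_len(40L)) {
      sites <- rbind(find_binding_sites(gseq, pfp, low, "fixture"),
                     find_binding_sites(gseq, onsp, low, "fixture"))
      keys <- vapply(expected_sites, function(s)
        paste(s$primer, s$strand, s$end3), "")
      spurious <- sites[!paste(sites$primer, sites$strand, sites$end3) %in%
                          keys, , drop = FALSE]
      if (!nrow(spurious)) break
      s <- spurious[1, ]
      seed_iv <- if (s$strand == "+") c(s$end3 - 6L, s$end3 + 1L) else
        c(s$end3, s$end3 + 7L)
      cand <- setdiff(seq(seed_iv[1], seed_iv[2] - 1L),
                      unlist(lapply(protected, function(iv)
                        seq(iv[1], iv[2] - 1L))))
      if (!length(cand))
        stop("fixture error: cannot scrub a spurious ", s$primer,
             " site at ", s$end3, " without touching a designed feature ",
             "(the primer's 3' seed recurs inside its own window)",
             call. = FALSE)
      p0 <- cand[1]
      g[p0 + 1L] <- chartr("ACGT", "CATG", g[p0 + 1L])
      gseq <- paste(g, collapse = "")
      if (iter == 40L)
        stop("fixture error: scrubbing did not converge", call. = FALSE)
    }

    # --- closed-form expected target lengths ---
    pa <- o_s + nchar(onsp$seq) - 1L
    len1 <- nchar(onsp$seq) + nchar(pfp$seq) + (q_target - pa - 1L)
    len2 <- len1 - (m_s - o_s)
    len3 <- len2 - (i_s - m_s)
    truth <- list(
      onsp = c(start = o_s, end = o_s + nchar(onsp$seq)),
      mnsp = c(start = m_s, end = m_s + nchar(mnsp$seq)),
      insp = c(start = i_s, end = i_s + nchar(insp$seq)),
      junction = junction,
      pfp_site_end3 = if ("target" %in% categories) q_target else NA_integer_,
      walk_distance = as.integer(walk_distance),
      expected_target_len = if ("target" %in% categories)
        c(primary = len1, secondary = len2, tertiary = len3) else NULL,
      expected_category_len = vapply(plants, `[[`, integer(1),
                                     "expected_len"),
      categories = categories)

    structure(list(
      genome = gseq,
      known_seq = substr(gseq, o_s + 1L, junction),
      truth = truth,
      fork_set = fork_set, nsps = nsps,
      seed = as.integer(seed), genome_len = genome_len),
      class = "fixture")
  })
}

#' @export
print.fixture <- function(x, ...) {
  t <- x$truth
  cat(sprintf("<fixture> %d-nt genome, seed %d\n", x$genome_len, x$seed))
  cat(sprintf("  known locus [%d, %d), junction at %d\n",
              t$onsp["start"], t$junction, t$junction))
  if (!is.null(t$expected_target_len)) {
    cat(sprintf("  walk %d nt; expected target bands P/S/T = %d/%d/%d nt\n",
                t$walk_distance, t$expected_target_len["primary"],
                t$expected_target_len["secondary"],
                t$expected_target_len["tertiary"]))
  }
  if (length(t$expected_category_len)) {
    cat("  planted categories:",
        paste(sprintf("%s (%d nt)", names(t$expected_category_len),
                      t$expected_category_len), collapse = ", "), "\n")
  }
  invisible(x)
}
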