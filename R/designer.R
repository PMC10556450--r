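#' Design constraints for fork primer sets and NSP selection
#'
#' @param stem_len stem length shared by PFP and SFP at the 3' end (nt).
#' @param branch_len branch length; also the BP length (nt).
#' @param stem_tm_window,branch_tm_window Tm windows (degrees C) for the
#'   stem and branch segments.
#' @param nsp_tm_window Tm window for nested site-specific primers.
#' @param nsp_len_window NSP length window (nt).
#' @param max_run maximum homopolymer run allowed (nt).
#' @param balance_window per-base frequency window; applied as count
#'   bounds \[floor(L*lo), ceiling(L*hi)\] so short primers are judged on
#'   whole bases.
#' @param heterology_cap maximum common substring (nt) tolerated between
#'   the PFP branch and BP ("heterologous branches"); also caps the 3'
#'   identity between a designed stem and BP (bridging guard).
#' @param thresholds a [structure_thresholds].
#' @param conditions a [thermo_conditions] used for all Tm evaluation.
#' @param retry_budget candidates tried per primer slot before the
#'   designer gives up with a diagnostic.
#' @return a `design_constraints` list.
#' @export
design_constraints <- function(stem_len = 21L, branch_len = 20L,
                               stem_tm_window = c(60, 65),
                               branch_tm_window = c(60, 65),
                               nsp_tm_window = c(60, 65),
                               nsp_len_window = c(20L, 32L),
                               max_run = 3L,
                               balance_window = c(0.10, 0.50),
                               heterology_cap = 10L,
                               thresholds = structure_thresholds(),
                               conditions = thermo_conditions(),
                               retry_budget = 1e5) {
  stopifnot(stem_len > 0L, branch_len > 0L,
            stem_tm_window[1] <= stem_tm_window[2],
            branch_tm_window[1] <= branch_tm_window[2],
            nsp_tm_window[1] <= nsp_tm_window[2],
            nsp_len_window[1] <= nsp_len_window[2],
            balance_window[1] <= balance_window[2])
  structure(list(stem_len = as.integer(stem_len),
                 branch_len = as.integer(branch_len),
                 stem_tm_window = stem_tm_window,
                 branch_tm_window = branch_tm_window,
                 nsp_tm_window = nsp_tm_window,
                 nsp_len_window = as.integer(nsp_len_window),
                 max_run = as.integer(max_run),
                 balance_window = balance_window,
                 heterology_cap = as.integer(heterology_cap),
                 thresholds = thresholds,
                 conditions = conditions,
                 retry_budget = retry_budget),
            class = "design_constraints")
}

# run body with a private, seeded RNG stream; outer RNG state untouched
with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(body)
}

random_mer <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# rejection-sample one segment; `extra` is an optional predicate
sample_segment <- function(len, tm_window, cons, role = "generic",
                           extra = NULL, slot = "segment") {
  rejects <- c(run = 0L, balance = 0L, tm = 0L, structure = 0L, extra = 0L)
  for (try in seq_len(cons$retry_budget)) {
    s <- random_mer(len)
    if (max_homopolymer_run(s) > cons$max_run) {
      rejects["run"] <- rejects["run"] + 1L; next
    }
    counts <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                           levels = c("A", "C", "G", "T")))
    lo <- floor(len * cons$balance_window[1])
    hi <- ceiling(len * cons$balance_window[2])
    if (any(counts < lo | counts > hi)) {
      rejects["balance"] <- rejects["balance"] + 1L; next
    }
    tm <- melt_temp(s, cons$conditions)
    if (tm < tm_window[1] || tm > tm_window[2]) {
      rejects["tm"] <- rejects["tm"] + 1L; next
    }
    if (severe_hairpin(s, cons$thresholds) ||
        severe_dimer(s, s, cons$thresholds)) {
      rejects["structure"] <- rejects["structure"] + 1L; next
    }
    if (!is.null(extra) && !extra(s)) {
      rejects["extra"] <- rejects["extra"] + 1L; next
    }
    return(s)
  }
  stop("design failure: no valid ", slot, " within ", cons$retry_budget,
       " candidates (rejections: ",
       paste(names(rejects), rejects, sep = "=", collapse = ", "), ")",
       call. = FALSE)
}

#' Design fork primer sets de novo
#'
#' Draws random primer segments and assembles `n_sets` fork primer sets
#' that all share one universal branch primer (BP), so a single BP drives
#' every parallel secondary and tertiary reaction. Every emitted set
#' passes [decompose_fork] and [validate_oligo] for all members; stems
#' differ pairwise across sets. Deterministic given `seed`.
#'
#' @param n_sets number of parallel sets (>= 1).
#' @param constraints a [design_constraints].
#' @param seed integer RNG seed.
#' @return list of `fork_primer_set` objects, `set_id`s "fork1", "fork2", ...
#' @export
design_fork_sets <- function(n_sets = 2L, constraints = design_constraints(),
                             seed = 1L) {
  if (n_sets < 1L) stop("n_sets must be >= 1", call. = FALSE)
  cons <- constraints
  with_seed(seed, {
    bp <- sample_segment(cons$branch_len, cons$branch_tm_window, cons,
                         slot = "branch primer")
    stems <- character(0)
    sets <- vector("list", n_sets)
    for (k in seq_len(n_sets)) {
      repeat {
        stem <- sample_segment(
          cons$stem_len, cons$stem_tm_window, cons, slot = "stem",
          extra = function(s) {
            longest_common_suffix(s, bp) <= cons$heterology_cap &&
              !(s %in% stems) &&
              !severe_dimer(s, bp, cons$thresholds)
          })
        branch <- sample_segment(
          cons$branch_len, cons$branch_tm_window, cons, slot = "PFP branch",
          extra = function(s) {
            longest_common_substring(s, bp) <= cons$heterology_cap &&
              !severe_dimer(s, bp, cons$thresholds)
          })
        pfp_seq <- paste0(branch, stem)
        sfp_seq <- paste0(bp, stem)
        pfp <- oligo(sprintf("PFP%d", k), pfp_seq, "PFP")
        sfp <- oligo(sprintf("SFP%d", k), sfp_seq, "SFP")
        # full-length rules can fail across the branch|stem junction
        ok <- report_ok(validate_oligo(pfp, cons)) &&
          report_ok(validate_oligo(sfp, cons)) &&
          !severe_hairpin(pfp_seq, cons$thresholds) &&
          !severe_hairpin(sfp_seq, cons$thresholds) &&
          !severe_dimer(pfp_seq, sfp_seq, cons$thresholds)
        if (ok) {
          stems <- c(stems, stem)
          sets[[k]] <- decompose_fork(pfp, sfp, oligo("BP", bp, "BP"),
                                      cons, set_id = sprintf("fork%d", k))
          break
        }
      }
    }
    names(sets) <- vapply(sets, `[[`, "", "set_id")
    sets
  })
}

#' Select a nested site-specific primer triple from a known sequence
#'
#' Enumerates primer windows on the strand of `known_seq` pointing toward
#' the unknown flank, keeps those passing [validate_oligo], the NSP Tm
#' window and the structure screens, then picks the innermost valid
#' window as iNSP (closest to the unknown junction, so the tertiary
#' product keeps as much walked sequence as possible), and works outward
#' for mNSP and oNSP with a non-overlap gap of at least `gap` nt. The
#' three are screened pairwise for cross-dimers.
#'
#' @param known_seq known flanking sequence (>= 150 nt).
#' @param walk_end `"right"` or `"left"`.
#' @param constraints a [design_constraints].
#' @param gap minimum gap between successive NSPs (nt, >= 0).
#' @param gene label used in primer names.
#' @return an `nsp_set`.
#' @export
select_nsp_set <- function(known_seq, walk_end = c("right", "left"),
                           constraints = design_constraints(), gap = 0L,
                           gene = "gene") {
  walk_end <- match.arg(walk_end)
  known_seq <- dna(known_seq, "known_seq")
  if (nchar(known_seq) < 150L)
    stop("known_seq must be at least 150 nt (got ", nchar(known_seq), ")",
         call. = FALSE)
  cons <- constraints
  strand <- if (walk_end == "right") known_seq else revcomp(known_seq)
  n <- nchar(strand)
  lens <- seq(cons$nsp_len_window[1], cons$nsp_len_window[2])
  # all candidate windows, scored; end = 0-based half-open end on strand
  cand <- list()
  diag <- c(windows = 0L, rules = 0L, tm = 0L, structure = 0L)
  for (L in lens) {
    for (st in seq_len(n - L + 1L)) {
      diag["windows"] <- diag["windows"] + 1L
      s <- substr(strand, st, st + L - 1L)
      if (max_homopolymer_run(s) > cons$max_run) {
        diag["rules"] <- diag["rules"] + 1L; next
      }
      tm <- melt_temp(s, cons$conditions)
      if (tm < cons$nsp_tm_window[1] || tm > cons$nsp_tm_window[2]) {
        diag["tm"] <- diag["tm"] + 1L; next
      }
      if (!report_ok(validate_oligo(oligo("cand", s, "oNSP"), cons))) {
        diag["rules"] <- diag["rules"] + 1L; next
      }
      if (severe_hairpin(s, cons$thresholds) ||
          severe_dimer(s, s, cons$thresholds)) {
        diag["structure"] <- diag["structure"] + 1L; next
      }
      cand[[length(cand) + 1L]] <- list(start = st - 1L, end = st - 1L + L,
                                        seq = s)
    }
  }
  if (length(cand) < 3L) {
    stop("design failure: only ", length(cand), " valid NSP window(s) in ",
         "known_seq (screened ", diag["windows"], "; rejected ",
         paste(names(diag)[-1], diag[-1], sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  ends <- vapply(cand, `[[`, integer(1), "end")
  starts <- vapply(cand, `[[`, integer(1), "start")
  ok_pair <- function(x, y) !severe_dimer(x$seq, y$seq, cons$thresholds)
  # innermost-first greedy with backtracking over iNSP choices
  for (ii in order(-ends)) {
    insp <- cand[[ii]]
    mm_pool <- which(ends <= insp$start - gap)
    for (mi in mm_pool[order(-ends[mm_pool])]) {
      mnsp <- cand[[mi]]
      if (!ok_pair(mnsp, insp)) next
      oo_pool <- which(ends <= mnsp$start - gap)
      for (oi in oo_pool[order(-ends[oo_pool])]) {
        onsp <- cand[[oi]]
        if (!ok_pair(onsp, mnsp) || !ok_pair(onsp, insp)) next
        return(nsp_set(
          oligo(paste0(gene, "_oNSP"), onsp$seq, "oNSP"),
          oligo(paste0(gene, "_mNSP"), mnsp$seq, "mNSP"),
          oligo(paste0(gene, "_iNSP"), insp$seq, "iNSP"),
          known_seq, walk_end, cons$nsp_len_window))
      }
    }
  }
  stop("design failure: no non-overlapping, dimer-compatible NSP triple ",
       "among ", length(cand), " valid windows", call. = FALSE)
}

#' Cross-compatibility check of a fork set and an NSP set
#'
#' Screens every primer pair that co-occurs in some reaction round
#' (primary: PFP + oNSP; secondary: SFP, BP, mNSP; tertiary: BP + iNSP)
#' for severe cross-dimers, and each primer against itself.
#'
#' @param fork_set a `fork_primer_set`.
#' @param nsps an `nsp_set`.
#' @param thresholds a [structure_thresholds].
#' @return a `validation_report` with one row per screened pair.
#' @export
check_compatibility <- function(fork_set, nsps,
                                thresholds = structure_thresholds()) {
  stopifnot(inherits(fork_set, "fork_primer_set"), inherits(nsps, "nsp_set"))
  rounds <- list(
    primary = list(fork_set$pfp, nsps$onsp),
    secondary = list(fork_set$sfp, fork_set$bp, nsps$mnsp),
    tertiary = list(fork_set$bp, nsps$insp))
  rows <- list()
  seen <- character(0)
  for (rn in names(rounds)) {
    prim <- rounds[[rn]]
    for (i in seq_along(prim)) for (j in i:length(prim)) {
      a <- prim[[i]]; b <- prim[[j]]
      key <- paste(sort(c(a$name, b$name)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      bad <- severe_dimer(a$seq, b$seq, thresholds)
      d <- dimer_scan(a$seq, b$seq)
      worst <- if (nrow(d)) max(d$stem) else 0L
      worst3 <- if (any(d$anchored3p)) max(d$stem[d$anchored3p]) else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        rule = paste0("dimer:", a$name, "+", b$name),
        pass = !bad,
        detail = sprintf("round %s; worst stem %d bp, worst 3'-anchored %d bp",
                         rn, worst, worst3),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("validation_report", "data.frame"),
            oligo = paste(fork_set$set_id, "vs NSP set"),
            ok = all(out$pass))
}
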