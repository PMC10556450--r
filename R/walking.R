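#' Simulation parameters for the three walking rounds
#'
#' @param stringency list of three [stringency_model]s, one per round.
#'   Defaults: round 1 low (the single 25 degree cycle seeds walking),
#'   rounds 2-3 high (all 65 degree cycles).
#' @param suppression_min minimum terminal inverted repeat (nt) that
#'   triggers hairpin suppression; default 41 ("more than 40 nt").
#' @param sfp_uM,bp_uM secondary fork primer and branch primer
#'   concentrations (uM). At the default 1:10 ratio SFP acts only as the
#'   bridging primer -- one copying event that integrates BP's site -- and
#'   BP is the amplifier. If `sfp_uM >= bp_uM`, SFP also amplifies.
#' @param max_len maximum product length (nt); default 5000 from the
#'   observed product ceiling under a 2-minute extension.
#' @return a `sim_params` list.
#' @export
sim_params <- function(stringency = list(stringency_model("low"),
                                         stringency_model("high"),
                                         stringency_model("high")),
                       suppression_min = 41L, sfp_uM = 0.02, bp_uM = 0.2,
                       max_len = 5000L) {
  if (suppression_min < 1L) stop("suppression_min must be >= 1", call. = FALSE)
  if (sfp_uM < 0 || bp_uM < 0) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(stringency = stringency,
                 suppression_min = as.integer(suppression_min),
                 sfp_uM = sfp_uM, bp_uM = bp_uM,
                 max_len = as.integer(max_len)),
            class = "sim_params")
}

new_amplicon <- function(seq, left, right, left_perfect, right_perfect,
                         category, abundance, round, suppressed = FALSE,
                         insert = c(NA_integer_, NA_integer_), note = "") {
  list(seq = seq, length = nchar(seq), left = left, right = right,
       left_perfect = left_perfect, right_perfect = right_perfect,
       category = category, abundance = abundance, suppressed = suppressed,
       round = round, insert = insert, note = note)
}

new_pool <- function(round, amplicons = list(), notes = character(0)) {
  structure(list(round = round, amplicons = amplicons, notes = notes),
            class = "product_pool")
}

#' @export
print.product_pool <- function(x, ...) {
  cat(sprintf("<product_pool> round %d: %d product(s)\n", x$round,
              length(x$amplicons)))
  for (a in x$amplicons) {
    cat(sprintf("  %6d nt  %-9s %-11s %s--%s%s\n", a$length,
                paste0("[", a$category, "]"), a$abundance, a$left, a$right,
                if (a$suppressed) "  SUPPRESSED" else ""))
  }
  invisible(x)
}

# drop duplicate (left, right, length) triples, keeping the first
dedup_amplicons <- function(amps) {
  if (!length(amps)) return(amps)
  key <- vapply(amps, function(a)
    paste(a$left, a$right, a$length, a$abundance, sep = "|"), "")
  amps[!duplicated(key)]
}

# all double-stranded products from facing site pairs of `primers` on a
# plus-strand template; returns a list of amplicons (category filled later)
pair_products <- function(template_seq, primers, model, max_len, round,
                          template_id = "template") {
  sites <- do.call(rbind, lapply(primers, function(p)
    find_binding_sites(template_seq, p, model, template_id)))
  prim_by_name <- stats::setNames(primers, vapply(primers, `[[`, "", "name"))
  fwd <- sites[sites$strand == "+", , drop = FALSE]
  rev_ <- sites[sites$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(fwd) && nrow(rev_)) {
    for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev_))) {
      gap <- rev_$end3[j] - fwd$end3[i] - 1L
      if (gap < 0L) next
      pa <- prim_by_name[[fwd$primer[i]]]
      pb <- prim_by_name[[rev_$primer[j]]]
      len <- nchar(pa$seq) + nchar(pb$seq) + gap
      if (len > max_len) next
      mid <- if (gap > 0L) substr(template_seq, fwd$end3[i] + 2L,
                                  rev_$end3[j]) else ""
      out[[length(out) + 1L]] <- new_amplicon(
        seq = paste0(pa$seq, mid, revcomp(pb$seq)),
        left = pa$name, right = pb$name,
        left_perfect = fwd$run[i] >= nchar(pa$seq),
        right_perfect = rev_$run[j] >= nchar(pb$seq),
        category = "unclassified", abundance = "exponential", round = round,
        insert = c(fwd$end3[i] + 1L, rev_$end3[j]),
        note = sprintf("%s@%d(+) x %s@%d(-)", pa$name, fwd$end3[i],
                       pb$name, rev_$end3[j]))
    }
  }
  attr(out, "sites") <- sites
  out
}

role_of <- function(name, primers) {
  for (p in primers) if (p$name == name) return(p$role)
  "generic"
}

#' Simulate primary fork PCR
#'
#' Round 1 is driven by PFP and oNSP. Under the low-stringency model both
#' primers may bind partially at many places; every facing site pair
#' within `max_len` yields a double-stranded product whose ends carry the
#' full primer sequences (5' tails are incorporated, which is what plants
#' the PFP site copied by round 2). Products are classified: oNSP at its
#' genuine (perfect full-length) site paired with PFP = target; oNSP-oNSP
#' = category I; off-target oNSP with PFP = category II; PFP-PFP =
#' category III. Unpaired first strands are retained as linear carryover.
#'
#' @param genome template sequence (string, or one record from
#'   [read_fasta]).
#' @param pfp,onsp [oligo]s (or strings) for the primary fork primer and
#'   outermost nested site-specific primer.
#' @param params a [sim_params].
#' @return a `product_pool` with `round = 1`.
#' @export
simulate_primary <- function(genome, pfp, onsp, params = sim_params()) {
  gseq <- dna(if (is.list(genome)) genome$seq else genome, "genome")
  pfp <- as_oligo(pfp, "PFP", "PFP")
  onsp <- as_oligo(onsp, "oNSP", "oNSP")
  model <- params$stringency[[1]]
  prims <- list(pfp, onsp)
  amps <- pair_products(gseq, prims, model, params$max_len, round = 1L)
  sites <- attr(amps, "sites")
  notes <- character(0)
  onsp_sites <- sites[sites$primer == onsp$name, , drop = FALSE]
  if (nrow(onsp_sites) == 0L) {
    notes <- c(notes, paste0("no ", onsp$name,
                             " site on the template: target absent"))
    warning("no ", onsp$name, " binding site on the template; ",
            "no target product is possible", call. = FALSE)
  }
  amps <- lapply(amps, function(a) {
    lr <- role_of(a$left, prims); rr <- role_of(a$right, prims)
    roles <- sort(c(lr, rr))
    a$category <-
      if (identical(roles, c("oNSP", "oNSP"))) "I"
      else if (identical(roles, c("PFP", "PFP"))) "III"
      else {
        perfect_nsp <- (lr == "oNSP" && a$left_perfect) ||
          (rr == "oNSP" && a$right_perfect)
        if (perfect_nsp) "target" else "II"
      }
    # normalize so the NSP end is the amplicon's 5' (left) end
    if (role_of(a$right, prims) == "oNSP" && role_of(a$left, prims) != "oNSP") {
      a$seq <- revcomp(a$seq)
      tmp <- a$left; a$left <- a$right; a$right <- tmp
      tmp <- a$left_perfect; a$left_perfect <- a$right_perfect
      a$right_perfect <- tmp
    }
    a
  })
  amps <- dedup_amplicons(amps)
  # unpaired single strands persist linearly (one copy per cycle at most)
  paired_keys <- unlist(lapply(amps, function(a) a$note))
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      p <- if (sites$primer[i] == pfp$name) pfp else onsp
      strand_prod <- extend_product(gseq, sites[i, ], p, params$max_len)
      amps[[length(amps) + 1L]] <- new_amplicon(
        seq = strand_prod, left = p$name, right = "(template end)",
        left_perfect = sites$run[i] >= nchar(p$seq), right_perfect = FALSE,
        category = "carryover", abundance = "linear", round = 1L,
        note = sprintf("single strand %s@%d(%s)", p$name, sites$end3[i],
                       sites$strand[i]))
    }
  }
  new_pool(1L, dedup_amplicons(amps), notes)
}

# longest exact 3'-terminal run any competing primer achieves at a site
# whose 3' window lies within the terminal repeat of the product
competing_primer_match <- function(amp_seq, primers, tir) {
  if (tir < 1L) return(0L)
  probe <- stringency_model("low", min_run = 5L, min_identity = 0.01,
                            window = 21L)
  best <- 0L
  n <- nchar(amp_seq)
  for (p in primers) {
    s <- tryCatch(find_binding_sites(amp_seq, p, probe),
                  error = function(e) NULL)
    if (is.null(s) || !nrow(s)) next
    terminal <- s$end3 < tir | s$end3 >= n - tir
    if (any(terminal)) best <- max(best, s$run[terminal])
  }
  as.integer(best)
}

# suppression rule: a long terminal inverted repeat folds into a panhandle
# hairpin that outcompetes any primer matching only part of the repeat
is_suppressed <- function(amp_seq, primers, params) {
  tir <- terminal_inverted_repeat(amp_seq)
  tir >= params$suppression_min &&
    competing_primer_match(amp_seq, primers, tir) < tir
}

# one nested round: suppression screen, optional SFP bridging, then
# exponential amplification by the round's primer pair
nested_round <- function(pool, amplifiers, bridge_primer, params, round) {
  model <- params$stringency[[round]]
  all_primers <- c(amplifiers, if (!is.null(bridge_primer)) list(bridge_primer))
  if (!is.null(bridge_primer) && params$sfp_uM >= params$bp_uM &&
      params$sfp_uM > 0) {
    # at amplifier-level concentration SFP amplifies in its own right
    amplifiers <- c(amplifiers, list(bridge_primer))
  }
  out <- list()
  notes <- character(0)
  for (a in pool$amplicons) {
    if (a$abundance != "exponential" || a$suppressed) next
    if (is_suppressed(a$seq, all_primers, params)) {
      sup <- a
      sup$suppressed <- TRUE
      sup$round <- round
      sup$abundance <- "suppressed"
      sup$note <- sprintf("terminal inverted repeat %d nt >= %d: panhandle",
                          terminal_inverted_repeat(a$seq),
                          params$suppression_min)
      out[[length(out) + 1L]] <- sup
      next
    }
    templates <- list(a$seq)
    if (!is.null(bridge_primer)) {
      # the bridge primer (SFP) performs one copying event per site,
      # integrating the amplifier's (BP's) 5' site into the product
      bsites <- find_binding_sites(a$seq, bridge_primer, model)
      if (nrow(bsites)) {
        for (i in seq_len(nrow(bsites))) {
          bridged <- extend_product(a$seq, bsites[i, ], bridge_primer,
                                    params$max_len)
          templates[[length(templates) + 1L]] <- revcomp(bridged)
        }
      }
    }
    prods <- list()
    for (tpl in templates) {
      prods <- c(prods, pair_products(tpl, amplifiers, model,
                                      params$max_len, round))
    }
    if (length(prods)) {
      for (p in prods) {
        p$category <- a$category
        p$insert <- a$insert
        # orient NSP end left, as in round 1
        rr <- role_of(p$right, amplifiers)
        lr <- role_of(p$left, amplifiers)
        if (rr %in% c("oNSP", "mNSP", "iNSP") &&
            !(lr %in% c("oNSP", "mNSP", "iNSP"))) {
          p$seq <- revcomp(p$seq)
          tmp <- p$left; p$left <- p$right; p$right <- tmp
          tmp <- p$left_perfect; p$left_perfect <- p$right_perfect
          p$right_perfect <- tmp
        }
        out[[length(out) + 1L]] <- p
      }
    } else {
      co <- a
      co$round <- round
      co$abundance <- "linear"
      co$category <- "carryover"
      co$note <- sprintf("round-%d carryover (%s): no primer pair; diluted",
                         round, a$category)
      out[[length(out) + 1L]] <- co
    }
  }
  new_pool(round, dedup_amplicons(out), notes)
}

#' Simulate secondary fork PCR
#'
#' Round 2 uses SFP, BP and mNSP on the round-1 pool, all cycles high
#' stringency. Category I/II products have no mNSP site and become diluted
#' carryover. Category III products carry a PFP terminal inverted repeat
#' of at least 41 nt and are suppressed: the panhandle hairpin outcompetes
#' SFP, whose stem matches only 21 nt of the repeat. The target's PFP end
#' is bridged once by SFP (integrating the BP site), after which BP and
#' mNSP amplify exponentially.
#'
#' @param pool the round-1 `product_pool`.
#' @param sfp,bp,mnsp round-2 primers.
#' @param params a [sim_params].
#' @return a `product_pool` with `round = 2`.
#' @export
simulate_secondary <- function(pool, sfp, bp, mnsp, params = sim_params()) {
  stopifnot(inherits(pool, "product_pool"))
  if (pool$round != 1L)
    stop("simulate_secondary expects a round-1 pool (got round ",
         pool$round, ")", call. = FALSE)
  sfp <- as_oligo(sfp, "SFP", "SFP")
  bp <- as_oligo(bp, "BP", "BP")
  mnsp <- as_oligo(mnsp, "mNSP", "mNSP")
  bridge <- if (params$sfp_uM > 0) sfp else NULL
  nested_round(pool, list(bp, mnsp), bridge, params, round = 2L)
}

#' Simulate tertiary fork PCR
#'
#' Round 3 uses BP and iNSP on the round-2 pool; its mechanism matches
#' round 2 except no bridging is needed (the BP end already exists), so
#' the target shrinks by the mNSP-to-iNSP nesting distance.
#'
#' @param pool the round-2 `product_pool`.
#' @param bp,insp round-3 primers.
#' @param params a [sim_params].
#' @return a `product_pool` with `round = 3`.
#' @export
simulate_tertiary <- function(pool, bp, insp, params = sim_params()) {
  stopifnot(inherits(pool, "product_pool"))
  if (pool$round != 2L)
    stop("simulate_tertiary expects a round-2 pool (got round ",
         pool$round, ")", call. = FALSE)
  bp <- as_oligo(bp, "BP", "BP")
  insp <- as_oligo(insp, "iNSP", "iNSP")
  nested_round(pool, list(bp, insp), NULL, params, round = 3L)
}

#' Virtual gel report
#'
#' The in-silico analog of agarose electrophoresis: per round, the lengths
#' of exponential, non-suppressed products, sorted descending; linear
#' carryover and suppressed products leave no visible band. Duplicate
#' lengths merge into one band with a multiplicity.
#'
#' @param pools list of `product_pool`s (any subset of rounds).
#' @return a `gel_report`: list of lanes, each a data frame
#'   (length, count).
#' @export
virtual_gel <- function(pools) {
  if (inherits(pools, "product_pool")) pools <- list(pools)
  if (!length(pools)) stop("need at least one product pool", call. = FALSE)
  lanes <- list()
  for (pool in pools) {
    lens <- vapply(Filter(function(a)
      a$abundance == "exponential" && !a$suppressed, pool$amplicons),
      function(a) a$length, integer(1))
    tab <- if (length(lens)) {
      t <- table(lens)
      data.frame(length = as.integer(names(t)), count = as.integer(t))
    } else data.frame(length = integer(0), count = integer(0))
    tab <- tab[order(-tab$length), , drop = FALSE]
    rownames(tab) <- NULL
    lanes[[paste0("round", pool$round)]] <- tab
  }
  structure(lanes, class = "gel_report")
}

#' @export
print.gel_report <- function(x, ...) {
  cat("<gel_report> band sizes (nt), largest first\n")
  lab <- c(round1 = "P", round2 = "S", round3 = "T")
  for (nm in names(x)) {
    bands <- if (nrow(x[[nm]])) {
      paste(sprintf("%d%s", x[[nm]]$length,
                    ifelse(x[[nm]]$count > 1,
                           paste0(" (x", x[[nm]]$count, ")"), "")),
            collapse = ", ")
    } else "(no bands)"
    cat(sprintf("  lane %s (%s): %s\n", lab[[nm]] %||% nm, nm, bands))
  }
  invisible(x)
}

#' Verify a walked amplicon against the known sequence
#'
#' The in-silico analog of the sequencing validation: the NSP-sided end of
#' a genuine product must match the known region exactly over the full
#' overlap between them (from the innermost primer's start to the unknown
#' junction).
#'
#' @param amplicon an amplicon (list with `$seq`) or plain sequence,
#'   oriented NSP end first.
#' @param known_seq the known flanking sequence.
#' @param walk_end which end of `known_seq` abuts the unknown flank.
#' @return logical; `FALSE` carries a `reason` attribute.
#' @export
verify_walk <- function(amplicon, known_seq, walk_end = c("right", "left")) {
  walk_end <- match.arg(walk_end)
  seq <- if (is.list(amplicon)) amplicon$seq else amplicon
  seq <- dna(seq, "amplicon")
  known <- dna(known_seq, "known_seq")
  strand <- if (walk_end == "right") known else revcomp(known)
  anchor <- substr(seq, 1L, 20L)
  at <- as.integer(regexpr(anchor, strand, fixed = TRUE))
  if (nchar(seq) < 20L || at < 0L) {
    return(structure(FALSE,
                     reason = "amplicon 5' end not found in the known region"))
  }
  overlap <- nchar(strand) - at + 1L
  if (nchar(seq) < overlap) {
    return(structure(FALSE, reason = sprintf(
      "amplicon (%d nt) shorter than the %d-nt overlap window",
      nchar(seq), overlap)))
  }
  ok <- substr(seq, 1L, overlap) == substr(strand, at, nchar(strand))
  if (!ok) return(structure(FALSE, reason = "mismatch inside the overlap"))
  TRUE
}

#' Run a full three-round fork PCR walk in silico
#'
#' Convenience pipeline: primary (PFP + oNSP), secondary (SFP + BP +
#' mNSP), tertiary (BP + iNSP), plus the virtual gel.
#'
#' @param genome template sequence.
#' @param fork_set a `fork_primer_set`.
#' @param nsps an `nsp_set` or a list with onsp/mnsp/insp oligos.
#' @param params a [sim_params].
#' @return a `walk_result`: list of the three pools and the `gel_report`.
#' @export
walk_simulate <- function(genome, fork_set, nsps, params = sim_params()) {
  stopifnot(inherits(fork_set, "fork_primer_set"))
  p1 <- simulate_primary(genome, fork_set$pfp, nsps$onsp, params)
  p2 <- simulate_secondary(p1, fork_set$sfp, fork_set$bp, nsps$mnsp, params)
  p3 <- simulate_tertiary(p2, fork_set$bp, nsps$insp, params)
  pools <- list(p1, p2, p3)
  structure(list(pools = pools, gel = virtual_gel(pools),
                 fork_set = fork_set$set_id),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("<walk_result> fork set %s\n", x$fork_set))
  for (p in x$pools) print(p)
  print(x$gel)
  invisible(x)
}

#' @export
summary.walk_result <- function(object, ...) {
  tert <- Filter(function(a) a$abundance == "exponential" && !a$suppressed,
                 object$pools[[3]]$amplicons)
  cat(sprintf("fork set %s: %d tertiary product(s)%s\n", object$fork_set,
              length(tert),
              if (length(tert)) paste0(" of ",
                paste(vapply(tert, function(a) a$length, integer(1)),
                      collapse = ", "), " nt") else ""))
  invisible(object)
}

#' Extract target amplicons from a pool or walk result
#' @param x a `product_pool` or `walk_result`.
#' @param round round to extract from a `walk_result` (default 3).
#' @return list of amplicons with category "target", exponential and not
#'   suppressed.
#' @export
target_amplicons <- function(x, round = 3L) {
  pool <- if (inherits(x, "walk_result")) x$pools[[round]] else x
  Filter(function(a) a$category == "target" &&
           a$abundance == "exponential" && !a$suppressed, pool$amplicons)
}
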