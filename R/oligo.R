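#' Normalize and check a DNA sequence
#'
#' Uppercases the input and verifies it is a plain A/C/G/T string. IUPAC
#' ambiguity codes, U (RNA) and gaps are rejected: fork primers are random
#' oligomers over the four standard bases and the simulator assumes an
#' unambiguous template.
#'
#' @param seq character scalar, DNA sequence (case-insensitive).
#' @param what label used in error messages.
#' @return The normalized uppercase sequence.
#' @export
dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- toupper(seq)
  if (nchar(s) == 0L) stop(what, " is empty", call. = FALSE)
  if (grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    stop(what, " contains non-ACGT character(s): ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param seq A/C/G/T string (case-insensitive).
#' @return The reverse complement, 5'->3'.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(seq) {
  s <- dna(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Longest common suffix / prefix length of two sequences
#'
#' Used to measure the designed 3' stem overlap between the primary and
#' secondary fork primers (21 nt) and the 5' identity between the branch
#' primer and the secondary fork primer (20 nt).
#'
#' @param a,b non-empty character scalars.
#' @return integer, length in nt of the maximal shared terminal run.
#' @export
longest_common_suffix <- function(a, b) {
  a <- dna(a, "a"); b <- dna(b, "b")
  ca <- rev(strsplit(a, "", fixed = TRUE)[[1]])
  cb <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  n <- min(length(ca), length(cb))
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq)) neq[1] - 1L else n
}

#' @rdname longest_common_suffix
#' @export
longest_common_prefix <- function(a, b) {
  a <- dna(a, "a"); b <- dna(b, "b")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq)) neq[1] - 1L else n
}

#' Longest homopolymer run
#'
#' Primer design forbids four or more consecutive identical bases.
#'
#' @param seq A/C/G/T string.
#' @return integer, length of the longest single-base run.
#' @export
max_homopolymer_run <- function(seq) {
  s <- dna(seq)
  max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
}

# longest common substring length between two strings (dynamic programme);
# the heterology screen between the PFP branch and the branch primer.
longest_common_substring <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- integer(length(cb))
  best <- 0L
  for (i in seq_along(ca)) {
    cur <- integer(length(cb))
    hit <- which(cb == ca[i])
    if (length(hit)) {
      cur[hit] <- 1L + c(0L, prev)[hit]
      best <- max(best, cur[hit])
    }
    prev <- cur
  }
  best
}

#' Primer roles recognised by the package
#' @export
OLIGO_ROLES <- c("PFP", "SFP", "BP", "oNSP", "mNSP", "iNSP", "generic")

#' Construct an oligo
#'
#' A named 5'->3' DNA primer with a role in the fork PCR scheme: primary
#' fork primer (PFP), secondary fork primer (SFP), branch primer (BP), or
#' one of the three nested site-specific primers (oNSP outermost, mNSP
#' middle, iNSP innermost).
#'
#' @param name short identifier.
#' @param seq A/C/G/T string, at most 64 nt.
#' @param role one of `OLIGO_ROLES`.
#' @return an object of class `oligo`.
#' @export
oligo <- function(name, seq, role = "generic") {
  role <- match.arg(role, OLIGO_ROLES)
  s <- dna(seq, paste0("oligo '", name, "'"))
  if (nchar(s) > 64L) {
    stop("oligo '", name, "' is ", nchar(s), " nt; maximum supported is 64",
         call. = FALSE)
  }
  structure(list(name = as.character(name), seq = s, role = role),
            class = "oligo")
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s [%s] %d nt  5'-%s-3'\n",
              x$name, x$role, nchar(x$seq), x$seq))
  invisible(x)
}

as_oligo <- function(x, role = "generic", name = role) {
  if (inherits(x, "oligo")) x else oligo(name, x, role)
}

#' Validate a primer against the fork PCR design rules
#'
#' Applies every sequence-level design rule once: plain ACGT alphabet, no
#' homopolymer run of four or more, roughly even base composition (each
#' base count within `balance` as a fraction of length, count-rounded
#' outward), and a role-specific length window.
#'
#' @param x an [oligo] or a plain sequence string.
#' @param constraints a [design_constraints] list; defaults used if `NULL`.
#' @return a `validation_report`: data frame of (rule, pass, detail) plus
#'   attributes `oligo` and `ok`.
#' @export
validate_oligo <- function(x, constraints = NULL) {
  x <- as_oligo(x)
  cons <- constraints %||% design_constraints()
  len_window <- switch(x$role,
    PFP = ,
    SFP = rep(cons$stem_len + cons$branch_len, 2L),
    BP = rep(cons$branch_len, 2L),
    oNSP = ,
    mNSP = ,
    iNSP = cons$nsp_len_window,
    generic = c(8L, 64L))
  n <- nchar(x$seq)
  counts <- table(factor(strsplit(x$seq, "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T")))
  lo <- floor(n * cons$balance_window[1])
  hi <- ceiling(n * cons$balance_window[2])
  run <- max_homopolymer_run(x$seq)
  rules <- data.frame(
    rule = c("alphabet", "run_length", "base_balance", "length_window"),
    pass = c(
      TRUE,  # dna() already enforced the alphabet on construction
      run <= cons$max_run,
      all(counts >= lo & counts <= hi),
      n >= len_window[1] && n <= len_window[2]
    ),
    detail = c(
      "ACGT only",
      sprintf("longest run %d (max %d)", run, cons$max_run),
      sprintf("counts A=%d C=%d G=%d T=%d (window [%d, %d] of %d nt)",
              counts["A"], counts["C"], counts["G"], counts["T"], lo, hi, n),
      sprintf("length %d (window [%d, %d])", n, len_window[1], len_window[2])
    ),
    stringsAsFactors = FALSE
  )
  structure(rules, class = c("validation_report", "data.frame"),
            oligo = x$name, ok = all(rules$pass))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %s\n", attr(x, "oligo"),
              if (attr(x, "ok")) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-14s %s\n", if (x$pass[i]) "ok" else "XX",
                x$rule[i], x$detail[i]))
  }
  invisible(x)
}

#' Does a validation report pass?
#' @param x a `validation_report`.
#' @return logical scalar.
#' @export
report_ok <- function(x) isTRUE(attr(x, "ok"))

#' Decompose three primers into a fork primer set
#'
#' Checks the fork architecture: PFP and SFP are both 41 nt, sharing a
#' 21-nt 3' stem; each carries a 20-nt 5' branch; the branch primer BP
#' equals SFP's branch (so BP can re-prime SFP-tailed products); and the
#' two branches are heterologous (longest common substring bounded), which
#' is what stops a PFP-only product from being bridged and amplified.
#'
#' The designed decomposition is authoritative: `stem` is taken as the
#' last `stem_len` bases of SFP. The literal 3' identity between PFP and
#' SFP may exceed the stem by coincidence (fork set 2 of the reference
#' design shares 22 nt because a branch-terminal base repeats), so the
#' overlap check is `>=` the stem length, not equality.
#'
#' @param pfp,sfp,bp oligos or sequence strings.
#' @param constraints optional [design_constraints].
#' @param set_id identifier for the set.
#' @return a `fork_primer_set` with fields pfp, sfp, bp, stem, pfp_branch.
#' @export
decompose_fork <- function(pfp, sfp, bp, constraints = NULL, set_id = "fork") {
  cons <- constraints %||% design_constraints()
  pfp <- as_oligo(pfp, "PFP"); sfp <- as_oligo(sfp, "SFP")
  bp <- as_oligo(bp, "BP")
  sl <- cons$stem_len; bl <- cons$branch_len
  fail <- function(which, msg) {
    stop("fork set invariant '", which, "' violated: ", msg, call. = FALSE)
  }
  if (nchar(pfp$seq) != sl + bl)
    fail("pfp_length", sprintf("PFP is %d nt, expected %d", nchar(pfp$seq), sl + bl))
  if (nchar(sfp$seq) != sl + bl)
    fail("sfp_length", sprintf("SFP is %d nt, expected %d", nchar(sfp$seq), sl + bl))
  if (nchar(bp$seq) != bl)
    fail("bp_length", sprintf("BP is %d nt, expected %d", nchar(bp$seq), bl))
  stem <- substr(sfp$seq, bl + 1L, bl + sl)
  pfp_branch <- substr(pfp$seq, 1L, bl)
  if (longest_common_suffix(pfp$seq, sfp$seq) < sl)
    fail("stem_overlap", sprintf(
      "PFP and SFP share only %d nt at the 3' end; the designed stem is %d",
      longest_common_suffix(pfp$seq, sfp$seq), sl))
  if (longest_common_prefix(bp$seq, sfp$seq) != bl)
    fail("bp_branch", sprintf(
      "BP matches SFP's 5' end over %d nt, expected %d",
      longest_common_prefix(bp$seq, sfp$seq), bl))
  lcsub <- longest_common_substring(pfp_branch, bp$seq)
  if (lcsub > cons$heterology_cap)
    fail("branch_heterology", sprintf(
      "PFP branch and BP share a %d-nt substring (cap %d)",
      lcsub, cons$heterology_cap))
  structure(list(pfp = pfp, sfp = sfp, bp = bp, stem = stem,
                 pfp_branch = pfp_branch, set_id = as.character(set_id)),
            class = "fork_primer_set")
}

#' @export
print.fork_primer_set <- function(x, ...) {
  cat(sprintf("<fork_primer_set> %s\n", x$set_id))
  cat(sprintf("  PFP  5'-%s %s-3'\n", x$pfp_branch, x$stem))
  cat(sprintf("  SFP  5'-%s %s-3'\n", x$bp$seq, x$stem))
  cat(sprintf("  BP   5'-%s-3'\n", x$bp$seq))
  invisible(x)
}

#' Build a nested site-specific primer set from a known sequence
#'
#' The three NSPs are exact substrings of the strand of `known_seq` that
#' points toward the unknown flank (`walk_end = "right"`: the plus strand;
#' `"left"`: the reverse complement). They must be nested -- oNSP, then
#' mNSP, then iNSP successively closer to the unknown junction -- and
#' non-overlapping, so each round's primer lies strictly inside the
#' previous round's product.
#'
#' @param onsp,mnsp,insp oligos or sequence strings.
#' @param known_seq the known flanking sequence.
#' @param walk_end `"right"` or `"left"`: which end of `known_seq` abuts
#'   the unknown flank.
#' @param nsp_len_window allowed primer lengths.
#' @return an `nsp_set` with 0-based half-open coordinates on `known_seq`'s
#'   walking strand.
#' @export
nsp_set <- function(onsp, mnsp, insp, known_seq,
                    walk_end = c("right", "left"),
                    nsp_len_window = c(20L, 32L)) {
  walk_end <- match.arg(walk_end)
  known_seq <- dna(known_seq, "known_seq")
  strand_seq <- if (walk_end == "right") known_seq else revcomp(known_seq)
  prim <- list(onsp = as_oligo(onsp, "oNSP"),
               mnsp = as_oligo(mnsp, "mNSP"),
               insp = as_oligo(insp, "iNSP"))
  coords <- lapply(prim, function(p) {
    n <- nchar(p$seq)
    if (n < nsp_len_window[1] || n > nsp_len_window[2])
      stop("NSP '", p$name, "' length ", n, " outside window [",
           nsp_len_window[1], ", ", nsp_len_window[2], "]", call. = FALSE)
    at <- as.integer(regexpr(p$seq, strand_seq, fixed = TRUE))
    if (at < 0L)
      stop("NSP '", p$name,
           "' is not a substring of the walking strand of known_seq",
           call. = FALSE)
    c(start = at - 1L, end = at - 1L + n)  # 0-based half-open
  })
  if (!(coords$onsp["end"] <= coords$mnsp["start"] &&
        coords$mnsp["end"] <= coords$insp["start"]))
    stop("NSPs are not nested: need oNSP, mNSP, iNSP in order toward the ",
         "unknown junction, non-overlapping", call. = FALSE)
  structure(list(onsp = prim$onsp, mnsp = prim$mnsp, insp = prim$insp,
                 coords = coords, walk_end = walk_end),
            class = "nsp_set")
}

#' @export
print.nsp_set <- function(x, ...) {
  cat(sprintf("<nsp_set> walking toward the %s end\n", x$walk_end))
  for (nm in c("onsp", "mnsp", "insp")) {
    p <- x[[nm]]
    cat(sprintf("  %-5s [%5d, %5d) %s\n", p$role,
                x$coords[[nm]]["start"], x$coords[[nm]]["end"], p$seq))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference fork primer sets and gene-specific NSP triples
#'
#' The two fork primer sets used to validate the method on the
#' Levilactobacillus brevis CD0817 and rice genomes, and the nested
#' site-specific primer triples for the gadA, gadR, pct and hyg loci.
#' Both fork sets share one universal branch primer.
#'
#' @return `reference_fork_sets()`: a named list of two `fork_primer_set`
#'   objects. `reference_nsps()`: a named list of per-gene lists of three
#'   [oligo]s (onsp, mnsp, insp).
#' @export
reference_fork_sets <- function() {
  bp <- "CCTGACCGCCTTCTACACCT"
  list(
    fork1 = decompose_fork(
      oligo("PFP1", "ACGCGTAATAGCTCGGGATGATGCTGCTCGTGGATGACTCT", "PFP"),
      oligo("SFP1", "CCTGACCGCCTTCTACACCTATGCTGCTCGTGGATGACTCT", "SFP"),
      oligo("BP", bp, "BP"), set_id = "fork1"),
    fork2 = decompose_fork(
      oligo("PFP2", "ATCCGCCCATAGCCTTCAGTGACTACGCTGCCTTGCTACTT", "PFP"),
      oligo("SFP2", "CCTGACCGCCTTCTACACCTGACTACGCTGCCTTGCTACTT", "SFP"),
      oligo("BP", bp, "BP"), set_id = "fork2")
  )
}

#' @rdname reference_fork_sets
#' @export
reference_nsps <- function() {
  mk <- function(gene, o, m, i) list(
    onsp = oligo(paste0(gene, "_oNSP"), o, "oNSP"),
    mnsp = oligo(paste0(gene, "_mNSP"), m, "mNSP"),
    insp = oligo(paste0(gene, "_iNSP"), i, "iNSP"))
  list(
    gadA = mk("gadA", "GTTTCTGGTCACAAGTACGGCATGG",
              "TGCTGATACGCTGCCAGAAGAAATG", "ACGGTTGACTCCATTGCCATTAACT"),
    gadR = mk("gadR", "TCCTTCGTTCTTGATTCCATACCCT",
              "CCATTTCCATAGGTTGCTCCAAGG",
              "GGATACTGGCTAAAATGAATTAACTCGGATAA"),
    pct = mk("pct", "TCTTGTTCTTCAACAGTGGTGGGTA",
             "TCGTCTTTCGTGTAAGTGTTGGTGT", "AGGAAATATGCACTCTTGGGAAGCG"),
    hyg = mk("hyg", "ACGGCAATTTCGATGATGCAGCTTG",
             "GGGACTGTCGGGCGTACACAA", "CTGGACCGATGGCTGTGTAGAAG")
  )
}
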