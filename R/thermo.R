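# Unified nearest-neighbor parameters (SantaLucia 1998), 1 M NaCl reference.
# dH kcal/mol, dS cal/(mol K), per 5'->3' dinucleotide on the top strand.
.NN_DH <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
            TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
            CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
            GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
            TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
            CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
            GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
.INIT_AT <- c(dh = 2.3, ds = 4.1)   # per A/T terminus
.INIT_GC <- c(dh = 0.1, ds = -2.8)  # per G/C terminus
.R_GAS <- 1.987  # cal/(mol K)

#' Reaction conditions for melting-temperature estimation
#'
#' Defaults reflect the walking reaction: 50 mM monovalent cation, 2.5 mM
#' Mg2+, 1.6 mM total dNTP (0.4 mM each) and 0.2 uM primer.
#'
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param mg_mM free Mg2+ (mM).
#' @param dntp_mM total dNTP (mM); dNTPs chelate Mg2+.
#' @param primer_uM primer concentration (uM).
#' @return a `thermo_conditions` list.
#' @export
thermo_conditions <- function(monovalent_mM = 50, mg_mM = 2.5,
                              dntp_mM = 1.6, primer_uM = 0.2) {
  v <- c(monovalent_mM, mg_mM, dntp_mM, primer_uM)
  if (any(!is.finite(v)) || any(v < 0))
    stop("thermo conditions must be finite and >= 0", call. = FALSE)
  structure(list(monovalent_mM = monovalent_mM, mg_mM = mg_mM,
                 dntp_mM = dntp_mM, primer_uM = primer_uM),
            class = "thermo_conditions")
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from the unified nearest-neighbor parameter set with the
#' entropy salt correction 0.368 (N-1) ln\[Mon+\] and the monovalent
#' equivalent for divalent cations Mon_eq = Mon + 120 sqrt(Mg - dNTP)
#' (all mM). Strand term is R ln(CT/4) for a non-self-complementary
#' primer in excess template, CT the primer concentration.
#'
#' @param seq primer sequence, 8 to 64 nt.
#' @param conditions a [thermo_conditions].
#' @return Tm in degrees Celsius (deterministic; double precision).
#' @export
melt_temp <- function(seq, conditions = thermo_conditions()) {
  s <- dna(seq)
  n <- nchar(s)
  if (n < 8L || n > 64L)
    stop("melt_temp supports 8-64 nt sequences; got ", n, call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  dints <- paste0(chars[-n], chars[-1])
  dh <- sum(.NN_DH[dints])
  ds <- sum(.NN_DS[dints])
  for (term in chars[c(1L, n)]) {
    ini <- if (term %in% c("A", "T")) .INIT_AT else .INIT_GC
    dh <- dh + ini[["dh"]]
    ds <- ds + ini[["ds"]]
  }
  mg_free <- max(conditions$mg_mM - conditions$dntp_mM, 0)
  mon_eq <- conditions$monovalent_mM + 120 * sqrt(mg_free)  # mM
  if (mon_eq <= 0) stop("no cations: Tm undefined", call. = FALSE)
  ds <- ds + 0.368 * (n - 1L) * log(mon_eq / 1000)
  ct <- conditions$primer_uM * 1e-6  # mol/L
  tm <- dh * 1000 / (ds + .R_GAS * log(ct / 4)) - 273.15
  unname(tm)
}

.structure_hit <- function(kind, stem, loop = NA_integer_, anchored = FALSE,
                           i = NA_integer_, j = NA_integer_) {
  data.frame(kind = kind, stem = as.integer(stem), loop = as.integer(loop),
             anchored3p = anchored, pos_a = as.integer(i),
             pos_b = as.integer(j), stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(kind = character(0), stem = integer(0), loop = integer(0),
             anchored3p = logical(0), pos_a = integer(0),
             pos_b = integer(0), stringsAsFactors = FALSE)
}

.complement_chars <- function(chars) chartr("ACGT", "TGCA", chars)

#' Hairpin scan
#'
#' Finds all maximal self-complementary stem pairings with a loop of at
#' least `min_loop` unpaired bases. The model is combinatorial -- longest
#' contiguous pairable stem, no free-energy weighting -- which is what the
#' suppression logic needs (the terminal-inverted-repeat length rule).
#'
#' @param seq sequence to fold.
#' @param min_loop minimum hairpin loop (nt), >= 3.
#' @return data frame of hits (kind, stem, loop, positions, 0-based), stem
#'   length descending. Positions are the outermost paired bases.
#' @export
hairpin_scan <- function(seq, min_loop = 3L) {
  s <- dna(seq)
  if (min_loop < 3L) stop("min_loop must be >= 3", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- .complement_chars(chars)
  n <- length(chars)
  hits <- list()
  for (i in seq_len(n)) {
    j <- n
    while (j - i - 1L >= min_loop) {
      if (chars[j] == comp[i]) {
        # extend stem inward from the (i, j) outer pair
        k <- 1L
        while (i + k <= n && j - k >= 1L &&
               (j - k) - (i + k) - 1L >= min_loop &&
               chars[j - k] == comp[i + k]) k <- k + 1L
        # maximal: outer pair (i-1, j+1) must not also pair
        outer_paired <- i > 1L && j < n && chars[j + 1L] == comp[i - 1L]
        if (!outer_paired) {
          hits[[length(hits) + 1L]] <- .structure_hit(
            "hairpin", k, loop = (j - k + 1L) - (i + k - 1L) - 1L,
            i = i - 1L, j = j - 1L)
        }
        j <- j - 1L
      } else {
        j <- j - 1L
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  out[order(-out$stem, out$pos_a), , drop = FALSE]
}

#' Primer-dimer scan
#'
#' Finds maximal complementary duplex windows between two primers (use the
#' same primer twice for a self-dimer). A hit is flagged 3'-anchored when
#' the duplex includes either primer's 3'-terminal base; 3'-anchored
#' dimers are the extensible, dangerous kind.
#'
#' @param a,b primer sequences (oligos or strings).
#' @return data frame of hits (stem length, 3'-anchor flag, 0-based start
#'   in `a` = pos_a and in `b` = pos_b of the duplex window), stem
#'   descending.
#' @export
dimer_scan <- function(a, b) {
  a <- if (inherits(a, "oligo")) a$seq else dna(a, "a")
  b <- if (inherits(b, "oligo")) b$seq else dna(b, "b")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  comp_b <- .complement_chars(cb)
  na <- length(ca); nb <- length(cb)
  hits <- list()
  # duplex: a[i + t] pairs b[j - t]; slide all antiparallel offsets
  for (d in (1L - nb):(na - 1L)) {
    # alignment: a index i pairs b index j = (i - d) reversed; concretely
    # a[i] pairs b[nb - (i - d) + ... ]; simpler: a[i] pairs b[j], i - j' = d
    # where j' = nb + 1 - j (b read 3'->5'). So a[i] pairs b[nb + 1 - (i - d)].
    i_lo <- max(1L, d + 1L)
    i_hi <- min(na, d + nb)
    if (i_lo > i_hi) next
    run <- 0L
    for (i in i_lo:(i_hi + 1L)) {
      match <- i <= i_hi && ca[i] == comp_b[nb + 1L - (i - d)]
      if (match) {
        run <- run + 1L
      } else if (run > 0L) {
        st_a <- i - run          # 1-based start in a
        j_hi <- nb + 1L - (st_a - d)   # b index paired with a[st_a]
        st_b <- j_hi - run + 1L        # 1-based start of window in b
        anchored <- (st_a + run - 1L == na) || (st_b + run - 1L == nb)
        hits[[length(hits) + 1L]] <- .structure_hit(
          if (identical(a, b)) "self-dimer" else "cross-dimer",
          run, anchored = anchored, i = st_a - 1L, j = st_b - 1L)
        run <- 0L
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  out[order(-out$stem, out$pos_a, out$pos_b), , drop = FALSE]
}

#' Terminal inverted repeat length
#'
#' Largest k such that the first k bases of `seq` equal the reverse
#' complement of its last k bases. A product confined by a terminal
#' inverted repeat longer than 40 nt folds into a panhandle hairpin in
#' preference to annealing a primer that matches only part of the repeat;
#' this is the suppression-PCR exclusion used against PFP-only products.
#'
#' @param seq product sequence, >= 2 nt.
#' @return integer k (0 if the termini do not pair at all).
#' @export
terminal_inverted_repeat <- function(seq) {
  s <- dna(seq)
  n <- nchar(s)
  if (n < 2L) stop("need at least 2 nt", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  comp_rev_tail <- .complement_chars(rev(chars))  # revcomp of whole string
  kmax <- n %/% 2L
  # allow k up to n (fully self-revcomp strings like "ACGT" return n)
  k <- 0L
  while (k < n && chars[k + 1L] == comp_rev_tail[k + 1L]) k <- k + 1L
  k
}

#' Structure screening thresholds
#'
#' Design-time rejection thresholds: a candidate fails if it has a hairpin
#' stem of `hairpin_stem` or more, any 3'-anchored self- or cross-dimer of
#' `dimer_3p_stem` or more, or a non-anchored dimer of `dimer_any_stem` or
#' more.
#'
#' @param hairpin_stem,dimer_3p_stem,dimer_any_stem integer thresholds (bp).
#' @param min_loop minimum hairpin loop used when scanning.
#' @return a `structure_thresholds` list.
#' @export
structure_thresholds <- function(hairpin_stem = 5L, dimer_3p_stem = 4L,
                                 dimer_any_stem = 8L, min_loop = 3L) {
  structure(list(hairpin_stem = as.integer(hairpin_stem),
                 dimer_3p_stem = as.integer(dimer_3p_stem),
                 dimer_any_stem = as.integer(dimer_any_stem),
                 min_loop = as.integer(min_loop)),
            class = "structure_thresholds")
}

# fast screening paths: same pairings as hairpin_scan / dimer_scan but only
# the maxima are tracked, no per-hit records (the designer screens thousands
# of candidate windows)
max_hairpin_stem <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- .complement_chars(chars)
  n <- length(chars)
  best <- 0L
  for (i in seq_len(n)) {
    j <- n
    while (j - i - 1L >= min_loop) {
      if (chars[j] == comp[i]) {
        k <- 1L
        while (i + k <= n && j - k >= 1L &&
               (j - k) - (i + k) - 1L >= min_loop &&
               chars[j - k] == comp[i + k]) k <- k + 1L
        if (k > best) best <- k
        j <- j - 1L
      } else j <- j - 1L
    }
  }
  best
}

# returns c(max stem overall, max 3'-anchored stem) across all duplex offsets
max_dimer_stems <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  comp_b <- .complement_chars(strsplit(b, "", fixed = TRUE)[[1]])
  na <- length(ca); nb <- length(comp_b)
  worst <- 0L; worst3 <- 0L
  for (d in (1L - nb):(na - 1L)) {
    i_lo <- max(1L, d + 1L)
    i_hi <- min(na, d + nb)
    if (i_lo > i_hi) next
    idx <- i_lo:i_hi
    m <- ca[idx] == comp_b[nb + 1L - (idx - d)]
    r <- rle(m)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      len <- r$lengths[k]
      i_end <- idx[ends[k]]            # last matched a index in this run
      i_start <- i_end - len + 1L
      # b window: a[i_start] pairs b[nb + 1 - (i_start - d)] (highest b idx)
      anchored <- (i_end == na) || (nb + 1L - (i_start - d) == nb)
      if (len > worst) worst <- len
      if (anchored && len > worst3) worst3 <- len
    }
  }
  c(worst, worst3)
}

# TRUE when the sequence (or pair) trips a "severe" structure threshold
severe_hairpin <- function(seq, thr) {
  max_hairpin_stem(seq, thr$min_loop) >= thr$hairpin_stem
}

severe_dimer <- function(a, b, thr) {
  st <- max_dimer_stems(a, b)
  st[2] >= thr$dimer_3p_stem || st[1] >= thr$dimer_any_stem
}
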