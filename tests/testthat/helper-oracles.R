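# Independent brute-force oracles used to cross-check the package's
# string / structure / annealing algorithms. Implementations here are
# deliberately naive (full enumeration) and share no code with R/.

# --- string oracles -------------------------------------------------------

oracle_suffix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  best <- 0L
  for (k in seq_len(n)) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) ==
        substr(b, nchar(b) - k + 1L, nchar(b))) best <- k
  }
  best
}

oracle_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  best <- 0L
  for (k in seq_len(n)) {
    if (substr(a, 1L, k) == substr(b, 1L, k)) best <- k
  }
  best
}

# longest common substring by full substring enumeration of `a`
oracle_common_substring <- function(a, b) {
  na <- nchar(a)
  for (k in seq(min(na, nchar(b)), 1L)) {
    for (i in seq_len(na - k + 1L)) {
      if (grepl(substr(a, i, i + k - 1L), b, fixed = TRUE)) return(k)
    }
  }
  0L
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- structure oracles (O(n^3) enumeration) -------------------------------

.comp <- function(chars) chartr("ACGT", "TGCA", chars)

# largest k with a fully paired hairpin stem of k bp and loop >= min_loop
oracle_hairpin_max <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- .comp(chars)
  n <- length(chars)
  best <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i + k - 1L > n || j - k + 1L < 1L) next
    if ((j - k + 1L) - (i + k - 1L) - 1L < min_loop) next
    ok <- TRUE
    for (t in 0:(k - 1L)) {
      if (chars[j - t] != comp[i + t]) { ok <- FALSE; break }
    }
    if (ok && k > best) best <- k
  }
  best
}

# c(max duplex stem, max 3'-anchored duplex stem) over all antiparallel
# alignments of a against b; a[i+t] pairs b[j-t]
oracle_dimer_max <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  comp_b <- .comp(cb)
  na <- length(ca); nb <- length(cb)
  worst <- 0L; worst3 <- 0L
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    k <- 0L
    while (i + k <= na && j - k >= 1L && ca[i + k] == comp_b[j - k]) {
      k <- k + 1L
      anchored <- (i + k - 1L == na) || (j == nb)
      if (k > worst) worst <- k
      if (anchored && k > worst3) worst3 <- k
    }
  }
  c(worst, worst3)
}

# --- annealing oracle: position-by-position scan --------------------------

# re-derives find_binding_sites() output by sliding the primer's 3' window
# over every position of both strands; no seed/regex shortcuts
oracle_sites <- function(template, primer_seq, min_run, min_identity,
                         window = 21L) {
  w <- min(window, nchar(primer_seq))
  np <- nchar(primer_seq)
  pc <- strsplit(primer_seq, "", fixed = TRUE)[[1]]
  pw <- pc[(np - w + 1L):np]
  scan <- function(strand_seq) {
    tc <- strsplit(strand_seq, "", fixed = TRUE)[[1]]
    n <- length(tc)
    hits <- list()
    if (n < w) return(hits)
    for (p in w:n) {
      m <- tc[(p - w + 1L):p] == pw
      run <- 0L
      while (run < np && p - run >= 1L && tc[p - run] == pc[np - run])
        run <- run + 1L
      id <- mean(m)
      if (run >= min_run && id >= min_identity)
        hits[[length(hits) + 1L]] <- data.frame(end3_1based = p, run = run,
                                                identity = id)
    }
    hits
  }
  n <- nchar(template)
  plus <- do.call(rbind, scan(template))
  minus <- do.call(rbind, scan(oracle_revcomp(template)))
  out <- rbind(
    if (!is.null(plus)) cbind(strand = "+", end3 = plus$end3_1based - 1L,
                              plus[, c("run", "identity")]),
    if (!is.null(minus)) cbind(strand = "-", end3 = n - minus$end3_1based,
                               minus[, c("run", "identity")]))
  if (is.null(out)) return(data.frame(strand = character(0),
                                      end3 = integer(0), run = integer(0),
                                      identity = numeric(0)))
  out <- out[order(out$end3, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- shared reference objects ---------------------------------------------

ref_forks <- reference_fork_sets()
ref_nsps <- reference_nsps()

# frozen duplex melting temperatures (degrees C) for random 18-41-mers,
# computed once with an independent published implementation of the
# unified nearest-neighbor model under the package's default conditions
# (50 mM monovalent, 2.5 mM Mg2+, 1.6 mM dNTP, 0.2 uM primer)
tm_oracle <- data.frame(
  seq = c("AGAAATACAAGGCGGGCGG",
          "GACACCGGGGTATATTAATGTCAGCACCGACGTCATA",
          "AGGATACTTTGCTATGAGACGCGTTCCTAG",
          "ATCGCCGAGTTTTGTATTAGACAGGTTCAGGCATACGGGA",
          "CACAAAATACCGGGCAATGCTAATTGCAGTATCTGA",
          "TCAGAGTATCGCAAGTCAGTTAGGAGGAGTATTT",
          "GATCTTCAAAGCCCGTTTACGATC",
          "GCTAGCAATGGTAGTTTACCT",
          "GGGGTTCAACCAAAGGAGA",
          "TTCGTACATGTCACCCCCTATTTAGCGAACTTACTTAATA",
          "TACAGTGGTTTAATACCACTCTCAGGGACAC",
          "TGTGTTTGAACCCCACGAGGGCACATCAC",
          "CTTTCTAGACTAGCCCAGCTTTCACTTCG",
          "TGAGAGTGATCGTTCATTTATTTAACAACGAGATAGCTT",
          "AATAAAACCGCTATAAAAAGGGACAGTGATCCAG",
          "AAGTAAGTGTCGCCCGGGGATCTGTTT",
          "CCTAAACACAGTATTGGGGAGTTGTTAACGGTACTACGAT",
          "GTTACACTCAATTGCACGTGACATTCACAGTCC",
          "CCGCTACATGCTAGCGACTT",
          "ACCGATTATGGTTTTCAGCAC",
          "TGCAACTAAGATTCCGCACAATCTACGGCGTTTCAC",
          "CACTGTCGTGTCGGTGAAACCCGTCGAACCCTCACGGCT",
          "GAATCTACCACGGCTGGGTTTAAGAGGTAGTCCGGAG",
          "GGCCCCGTAGGACGGTTTCTGCTATGGAAGGAAAGATATG",
          "TACTAGGGGTTAATCAGAGCACTTGCACCTGCTGATCAA",
          "CCAATAATCTCCACCGTTTTGTGCCCCGCAAGTC",
          "GCAAGTGTGCTCGTACGTTGCCAG",
          "TCATAATTTCTGATGCATC",
          "AACTTTGCACTGAAACGTCACTACGGGCAGAAAAGG",
          "ACACTCGAATTCGTTTGCTATCTACACAGTCGTATCGGGA",
          "TGAGGAGACTATGTAGGGCGAACTCCGTATCGCAGCGTACG",
          "GCAGTGAGAATCCCTCGTCTTGCCACTG",
          "CCCCCTCGTCCATCCCTTCCGAAAAGTAT",
          "TTTACTTTGGGTACCGGGCGCGATACATGGC",
          "CGAAGCGATATGTCAAGTTGA",
          "ATTATAGGCTCAGAGGTGGCTCTC",
          "CGGCTCATTTCACCGGCAAAGC",
          "GCCCGGAATATTGCAGAAGTT",
          "GTCTGGATACCGCGACTAGAAGATCCG",
          "ATGCGCGCGGCGTGGCCGGACCCACCCATATACTAG",
          "GGCATTCGCTAGCCAACCACCTATTAAT",
          "GAAAGTACCGCGCGTGCTTA",
          "GAATGGTTGTACTTGACGGCTAT",
          "CTGTATGACGCATGCCTTGCCGAATCATGGACATA",
          "TTCAGTCGTCCGTGATACCTAGAGAAATTACTGTA",
          "GCTTCACTTCATCTCTAGTGCGGGCA",
          "TGTCAGAGCATGCGGTCAATCGTGTCTGTTTGA",
          "AATTAGAGGGACATGTACAGCCGGGTAA",
          "GGGGCTGTCCGGAAAACCCAGGGTGGCCTAGGTACCGTGAA",
          "GGGCCTGGCGAGTAAGCTGCTCGTCCCCTATGTGGTCC"),
  tm = c(62.5188, 72.1556, 67.2010, 74.0766, 69.8479, 67.5123, 61.8814,
         57.2640, 58.9574, 68.8323, 66.8769, 72.0574, 66.4429, 67.1997,
         66.5709, 69.4319, 70.4525, 69.0924, 62.1872, 58.7385, 72.5063,
         79.5987, 73.3162, 74.4804, 72.8951, 73.3086, 68.4190, 49.9339,
         72.6123, 72.5556, 76.7449, 70.3352, 70.5160, 73.0538, 58.2925,
         62.9928, 67.0967, 60.8572, 67.4774, 80.8798, 66.8405, 63.2550,
         60.5288, 72.2577, 67.2734, 68.3201, 72.3094, 66.8023, 81.0096,
         79.8248),
  stringsAsFactors = FALSE)
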