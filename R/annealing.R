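#' Stringency model for primer annealing
#'
#' Two regimes mirror the thermal program. The low-stringency (25 degree)
#' cycle allows partial hybrids: a short exact 3' run plus a minimum
#' identity over the primer's 3'-terminal window. The high-stringency (65
#' degree) cycles demand a long exact 3' run, which only designed matches
#' (full NSPs, the 21-nt stem, the 20-nt BP) achieve.
#'
#' @param regime `"low"` or `"high"`.
#' @param min_run minimum exact 3'-terminal match (nt). Defaults: low 7,
#'   high 18.
#' @param min_identity minimum identity fraction over the 3' window
#'   (low regime only; high regime is run-only, identity 1 over the run).
#' @param window 3'-terminal window length (nt) over which identity is
#'   measured.
#' @return a `stringency_model`.
#' @export
stringency_model <- function(regime = c("low", "high"), min_run = NULL,
                             min_identity = NULL, window = 21L) {
  regime <- match.arg(regime)
  min_run <- as.integer(min_run %||% if (regime == "low") 7L else 18L)
  min_identity <- min_identity %||% if (regime == "low") 0.6 else 1.0
  if (min_run < 1L || min_identity <= 0 || min_identity > 1)
    stop("invalid stringency parameters", call. = FALSE)
  structure(list(regime = regime, min_run = min_run,
                 min_identity = min_identity, window = as.integer(window)),
            class = "stringency_model")
}

# positions (1-based, on `strand_seq`) where the primer's 3' window sits
# as strand_seq[p - w + 1 .. p] and the regime is satisfied; returns a
# data.frame with end3 (1-based), run, identity
.scan_one_strand <- function(strand_seq, primer_seq, model) {
  w <- min(model$window, nchar(primer_seq))
  n <- nchar(strand_seq)
  if (n < w) return(data.frame(end3 = integer(0), run = integer(0),
                               identity = numeric(0)))
  seed <- substr(primer_seq, nchar(primer_seq) - model$min_run + 1L,
                 nchar(primer_seq))
  # lookahead so that overlapping seed occurrences are all found
  hit0 <- gregexpr(paste0("(?=", seed, ")"), strand_seq, perl = TRUE)[[1]]
  if (hit0[1] == -1L) return(data.frame(end3 = integer(0), run = integer(0),
                                        identity = numeric(0)))
  ends <- as.integer(hit0) + model$min_run - 1L
  ends <- ends[ends >= w]  # full 3' window must lie on the template
  if (!length(ends)) return(data.frame(end3 = integer(0), run = integer(0),
                                       identity = numeric(0)))
  tc <- strsplit(strand_seq, "", fixed = TRUE)[[1]]
  pw <- strsplit(substr(primer_seq, nchar(primer_seq) - w + 1L,
                        nchar(primer_seq)), "", fixed = TRUE)[[1]]
  run <- integer(length(ends))
  ident <- numeric(length(ends))
  keep <- logical(length(ends))
  for (k in seq_along(ends)) {
    p <- ends[k]
    m <- tc[(p - w + 1L):p] == pw
    # exact 3' run (may exceed the window if the primer is longer)
    r <- 0L
    while (r < w && m[w - r]) r <- r + 1L
    if (r == w && nchar(primer_seq) > w) {
      pc <- strsplit(primer_seq, "", fixed = TRUE)[[1]]
      np <- nchar(primer_seq)
      while (r < np && p - r >= 1L && tc[p - r] == pc[np - r]) r <- r + 1L
    }
    id <- mean(m)
    run[k] <- r; ident[k] <- id
    keep[k] <- r >= model$min_run && id >= model$min_identity
  }
  data.frame(end3 = ends[keep], run = run[keep], identity = ident[keep])
}

#' Find primer binding sites on a template
#'
#' Exhaustively scans both strands of `template` for sites satisfying the
#' stringency model. Coordinates are 0-based on the plus strand of the
#' template. A `"+"` site means the primer reads along the plus strand
#' (it anneals to the minus strand and extension proceeds toward higher
#' coordinates); `end3` is the plus-strand position aligned with the
#' primer's 3' base. A `"-"` site means the primer anneals to the plus
#' strand; `end3` is the plus-strand position paired with the primer's 3'
#' base and extension proceeds toward lower coordinates.
#'
#' @param template template sequence (string or named list element of
#'   [read_fasta] output).
#' @param primer an [oligo] or sequence string.
#' @param model a [stringency_model].
#' @param template_id identifier recorded in the result.
#' @return data frame of class `binding_sites`: template, primer, strand,
#'   end3 (0-based), run (nt of exact 3' match), identity (over the 3'
#'   window), regime; sorted by coordinate.
#' @export
find_binding_sites <- function(template, primer,
                               model = stringency_model("high"),
                               template_id = "template") {
  tpl <- dna(if (is.list(template)) template$seq else template, "template")
  primer <- as_oligo(primer)
  w <- min(model$window, nchar(primer$seq))
  if (nchar(tpl) < w)
    stop("template shorter than the primer's 3' window", call. = FALSE)
  plus <- .scan_one_strand(tpl, primer$seq, model)
  minus <- .scan_one_strand(revcomp(tpl), primer$seq, model)
  n <- nchar(tpl)
  out <- rbind(
    if (nrow(plus)) data.frame(template = template_id, primer = primer$name,
                               strand = "+", end3 = plus$end3 - 1L,
                               run = plus$run, identity = plus$identity,
                               regime = model$regime,
                               stringsAsFactors = FALSE),
    if (nrow(minus)) data.frame(template = template_id, primer = primer$name,
                                strand = "-", end3 = n - minus$end3,
                                run = minus$run, identity = minus$identity,
                                regime = model$regime,
                                stringsAsFactors = FALSE))
  if (is.null(out)) out <- data.frame(template = character(0),
                                      primer = character(0),
                                      strand = character(0),
                                      end3 = integer(0), run = integer(0),
                                      identity = numeric(0),
                                      regime = character(0),
                                      stringsAsFactors = FALSE)
  out <- out[order(out$end3, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_sites", "data.frame")
  out
}

#' Extend a primer from a binding site along a template
#'
#' Models one polymerase extension. The product starts with the full
#' primer sequence -- including any unhybridized 5' tail, whose
#' incorporation is what creates the fork-primer site copied into round-2
#' templates -- followed by the template-complementary extension from the
#' site's 3' end, truncated at `max_len` total.
#'
#' @param template template sequence (plus strand).
#' @param site one row of a `binding_sites` data frame (or an equivalent
#'   list with `strand`, `end3`).
#' @param primer the [oligo] that bound (its full sequence is emitted).
#' @param max_len maximum total product length (nt).
#' @return single-strand product sequence, 5'->3'.
#' @export
extend_product <- function(template, site, primer, max_len = 5000L) {
  tpl <- dna(if (is.list(template) && !is.data.frame(template))
               template$seq else template, "template")
  primer <- as_oligo(primer)
  n <- nchar(tpl)
  end3 <- as.integer(site$end3)
  if (is.na(end3) || end3 < 0L || end3 >= n)
    stop("binding site 3' coordinate ", end3, " is off the template",
         call. = FALSE)
  room <- max(max_len - nchar(primer$seq), 0L)
  if (site$strand == "+") {
    from <- end3 + 2L  # 1-based position after the 3' end
    to <- min(n, end3 + 1L + room)
    ext <- if (from <= to) substr(tpl, from, to) else ""
  } else {
    to <- end3        # 1-based position before the 3' end is end3 (0-based end3 -> 1-based end3+1)
    from <- max(1L, end3 + 1L - room)
    ext <- if (from <= to) revcomp(substr(tpl, from, to)) else ""
  }
  paste0(primer$seq, ext)
}
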