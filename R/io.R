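#' Read a multi-record FASTA file
#'
#' Wraps Biostrings parsing with a validation pass that reports the line
#' number of the first malformed header or non-ACGT character. Lowercase
#' input is normalized to uppercase with a message.
#'
#' @param path FASTA file path.
#' @return list of records, each `list(name, seq)`; empty list (with a
#'   warning) for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*$", lines))
  if (!length(body)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(list())
  }
  if (!startsWith(lines[body[1]], ">"))
    stop("FASTA parse error at line ", body[1],
         ": expected a '>' header", call. = FALSE)
  lowercase <- FALSE
  for (i in body) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (nchar(trimws(sub("^>", "", ln))) == 0L)
        stop("FASTA parse error at line ", i, ": empty header",
             call. = FALSE)
    } else {
      if (grepl("[a-z]", ln)) lowercase <- TRUE
      if (grepl("[^ACGTacgt]", gsub("\\s", "", ln)))
        stop("FASTA parse error at line ", i,
             ": non-ACGT character", call. = FALSE)
    }
  }
  if (lowercase) message("note: lowercase bases normalized to uppercase")
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    list(name = names(set)[i], seq = toupper(as.character(set[[i]])))
  })
}

#' Write records as FASTA
#'
#' @param records list of `list(name, seq)` (or [oligo]s).
#' @param path output path; 70-column sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, function(r)
    if (inherits(r, "oligo")) r$seq else r$seq, "")
  names(seqs) <- vapply(records, function(r) r$name, "")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read and write primer sheets
#'
#' Tab-separated primer tables with columns `set`, `role`, `name`,
#' `sequence` -- one row per primer, mirroring the published layout of the
#' reference primer table.
#'
#' @param sets list of `fork_primer_set` and/or `nsp_set` objects, or a
#'   list of [oligo]s.
#' @param path file path.
#' @return `read_primer_tsv`: a data frame plus an `oligos` attribute
#'   (list of [oligo]); `write_primer_tsv`: `path`, invisibly.
#' @export
write_primer_tsv <- function(sets, path) {
  rows <- list()
  add <- function(set_id, o) {
    rows[[length(rows) + 1L]] <<- data.frame(
      set = set_id, role = o$role, name = o$name, sequence = o$seq,
      stringsAsFactors = FALSE)
  }
  for (s in sets) {
    if (inherits(s, "fork_primer_set")) {
      add(s$set_id, s$pfp); add(s$set_id, s$sfp); add(s$set_id, s$bp)
    } else if (inherits(s, "nsp_set")) {
      add("nsp", s$onsp); add("nsp", s$mnsp); add("nsp", s$insp)
    } else if (inherits(s, "oligo")) {
      add("misc", s)
    } else stop("unsupported object in primer sheet", call. = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_primer_tsv
#' @export
read_primer_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("set", "role", "name", "sequence")
  if (!all(need %in% names(df)))
    stop("primer sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  oligos <- lapply(seq_len(nrow(df)), function(i)
    oligo(df$name[i], df$sequence[i],
          if (df$role[i] %in% OLIGO_ROLES) df$role[i] else "generic"))
  attr(df, "oligos") <- oligos
  df
}

#' Write binding sites as a BED-like table
#'
#' Columns: template, start, end (0-based half-open span of the primer's
#' 3' window on the plus strand), name (primer), score (matched 3' run),
#' strand, identity, regime.
#'
#' @param sites a `binding_sites` data frame.
#' @param path file path.
#' @param window window width used for the span (defaults to 21).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, window = 21L) {
  bed <- data.frame(
    chrom = sites$template,
    start = ifelse(sites$strand == "+", sites$end3 - window + 1L,
                   sites$end3),
    end = ifelse(sites$strand == "+", sites$end3 + 1L,
                 sites$end3 + window),
    name = sites$primer,
    score = sites$run,
    strand = sites$strand,
    identity = sites$identity,
    regime = sites$regime,
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
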