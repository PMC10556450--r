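#' Thermal cycling program for a walking round
#'
#' Round 1: 95 C 2 min denaturation; one low-stringency cycle (95 C 10 s,
#' 25 C 30 s, 72 C 2 min); thirty high-stringency cycles (95 C 10 s, 65 C
#' 30 s, 72 C 2 min); 72 C 5 min final extension. Rounds 2 and 3 are
#' identical to each other: the same program without the 25 C cycle.
#'
#' @param round 1, 2 or 3.
#' @return a `thermal_program`: data frame of steps (block, temperature_C,
#'   duration_s, cycles) with a `round` attribute.
#' @export
thermal_program <- function(round) {
  if (!round %in% 1:3) stop("round must be 1, 2 or 3", call. = FALSE)
  step <- function(block, temp, dur, cycles) {
    data.frame(block = block, temperature_C = temp, duration_s = dur,
               cycles = cycles, stringsAsFactors = FALSE)
  }
  steps <- rbind(
    step("initial denaturation", 95, 120, 1L),
    if (round == 1L) rbind(
      step("low-stringency cycle", 95, 10, 1L),
      step("low-stringency cycle", 25, 30, 1L),
      step("low-stringency cycle", 72, 120, 1L)),
    step("high-stringency cycles", 95, 10, 30L),
    step("high-stringency cycles", 65, 30, 30L),
    step("high-stringency cycles", 72, 120, 30L),
    step("final extension", 72, 300, 1L))
  stopifnot(all(steps$cycles >= 1L),
            all(steps$temperature_C >= 4 & steps$temperature_C <= 99))
  rownames(steps) <- NULL
  structure(steps, class = c("thermal_program", "data.frame"), round = round)
}

#' @export
print.thermal_program <- function(x, ...) {
  cat(sprintf("<thermal_program> round %d\n", attr(x, "round")))
  for (b in unique(x$block)) {
    rows <- x[x$block == b, , drop = FALSE]
    cat(sprintf("  %s (x%d): %s\n", b, rows$cycles[1],
                paste(sprintf("%g C %g s", rows$temperature_C,
                              rows$duration_s), collapse = "; ")))
  }
  invisible(x)
}

#' Reaction recipe for a walking round
#'
#' The 50 uL reaction: per-round primers (round 1: PFP and oNSP at 0.2 uM;
#' round 2: SFP at 0.02 uM -- one tenth of BP and mNSP at 0.2 uM; round 3:
#' BP and iNSP at 0.2 uM), 0.4 mM each dNTP, 1x LA Taq buffer II with 2.5
#' mM Mg2+, 2.5 U LA Taq polymerase, and the round's template (genomic DNA
#' for round 1, the previous round's reaction for rounds 2-3, diluted
#' 10-1000 fold if necessary). Amounts are stored as exact strings to
#' avoid floating drift on round-trips.
#'
#' @param round 1, 2 or 3.
#' @param overrides named list of component amount overrides (names must
#'   already exist in the recipe); each override is recorded as a logged
#'   deviation.
#' @return a `reaction_recipe`: data frame (component, amount, unit) with
#'   attributes `round`, `total_volume_uL`, `template`, `deviations`.
#' @export
reaction_recipe <- function(round, overrides = NULL) {
  if (!round %in% 1:3) stop("round must be 1, 2 or 3", call. = FALSE)
  comp <- function(component, amount, unit) {
    data.frame(component = component, amount = amount, unit = unit,
               stringsAsFactors = FALSE)
  }
  primers <- switch(round,
    rbind(comp("PFP", "0.2", "uM"), comp("oNSP", "0.2", "uM")),
    rbind(comp("SFP", "0.02", "uM"), comp("BP", "0.2", "uM"),
          comp("mNSP", "0.2", "uM")),
    rbind(comp("BP", "0.2", "uM"), comp("iNSP", "0.2", "uM")))
  template <- switch(round,
    "10-100 ng microbial genome or 100-1000 ng plant genome",
    "1 uL primary PCR product (dilute 10-1000 folds if necessary)",
    "1 uL secondary PCR product (dilute 10-1000 folds if necessary)")
  recipe <- rbind(
    comp("template", switch(round, "10-100 / 100-1000", "1", "1"),
         switch(round, "ng", "uL", "uL")),
    primers,
    comp("each dNTP", "0.4", "mM"),
    comp("LA Taq buffer II (with Mg2+)", "1", "x"),
    comp("Mg2+", "2.5", "mM"),
    comp("LA Taq polymerase", "2.5", "U"))
  deviations <- character(0)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- which(recipe$component == nm)
      if (!length(i))
        stop("unknown recipe component: '", nm, "'", call. = FALSE)
      old <- recipe$amount[i]
      recipe$amount[i] <- as.character(overrides[[nm]])
      deviations <- c(deviations, sprintf("%s: %s -> %s %s", nm, old,
                                          recipe$amount[i], recipe$unit[i]))
    }
  }
  rownames(recipe) <- NULL
  structure(recipe, class = c("reaction_recipe", "data.frame"),
            round = round, total_volume_uL = 50, template = template,
            deviations = deviations)
}

#' @export
print.reaction_recipe <- function(x, ...) {
  cat(sprintf("<reaction_recipe> round %d, %g uL total\n", attr(x, "round"),
              attr(x, "total_volume_uL")))
  cat("  template:", attr(x, "template"), "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %s %s\n", x$component[i], x$amount[i], x$unit[i]))
  }
  for (d in attr(x, "deviations")) cat("  DEVIATION:", d, "\n")
  invisible(x)
}

#' Serialize the full three-round protocol
#'
#' @param overrides optional per-round override lists, e.g.
#'   `list(`2` = list(SFP = "0.2"))`.
#' @return `protocol_json()`: a list ready for [jsonlite::toJSON];
#'   `protocol_markdown()`: a character vector of markdown lines.
#' @export
protocol_json <- function(overrides = NULL) {
  lapply(1:3, function(r) {
    tp <- thermal_program(r)
    rc <- reaction_recipe(r, overrides[[as.character(r)]])
    list(round = r,
         thermal_program = as.data.frame(tp),
         recipe = list(total_volume_uL = attr(rc, "total_volume_uL"),
                       template = attr(rc, "template"),
                       components = as.data.frame(rc),
                       deviations = attr(rc, "deviations")))
  })
}

#' @rdname protocol_json
#' @export
protocol_markdown <- function(overrides = NULL) {
  lines <- c("# Fork PCR bench protocol", "")
  labs <- c("Primary", "Secondary", "Tertiary")
  for (r in 1:3) {
    tp <- thermal_program(r)
    rc <- reaction_recipe(r, overrides[[as.character(r)]])
    lines <- c(lines, sprintf("## %s fork PCR", labs[r]), "",
               sprintf("Reaction (%g uL total): %s.",
                       attr(rc, "total_volume_uL"), attr(rc, "template")),
               "")
    lines <- c(lines, "| component | amount | unit |", "|---|---|---|",
               sprintf("| %s | %s | %s |", rc$component, rc$amount, rc$unit),
               "")
    for (d in attr(rc, "deviations"))
      lines <- c(lines, sprintf("*Deviation from default:* %s", d), "")
    lines <- c(lines, "Thermal program:", "")
    for (b in unique(tp$block)) {
      rows <- tp[tp$block == b, , drop = FALSE]
      lines <- c(lines, sprintf("- %s (x%d): %s", b, rows$cycles[1],
                                paste(sprintf("%g C, %g s",
                                              rows$temperature_C,
                                              rows$duration_s),
                                      collapse = "; ")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Parse a protocol JSON back into programs and recipes
#'
#' Round-trip companion to [protocol_json]: given the list produced by it
#' (or read back via [jsonlite::fromJSON]), rebuilds the `thermal_program`
#' and `reaction_recipe` objects so structural equality can be asserted.
#'
#' @param x a list as produced by [protocol_json] (possibly after a JSON
#'   round trip with `simplifyVector = FALSE`).
#' @return list of rebuilt per-round `thermal_program` objects.
#' @export
protocol_parse <- function(x) {
  lapply(x, function(rd) {
    r <- if (is.list(rd$round)) rd$round[[1]] else rd$round
    tp <- rd$thermal_program
    if (!is.data.frame(tp)) tp <- do.call(rbind, lapply(tp, as.data.frame))
    tp$cycles <- as.integer(tp$cycles)
    structure(tp[, c("block", "temperature_C", "duration_s", "cycles")],
              class = c("thermal_program", "data.frame"), round = r)
  })
}
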