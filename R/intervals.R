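# Coordinate convention: all in-memory coordinates are 0-based half-open
# [start, end). External tables (ICGC-style, interaction tables, published
# locus notation) are 1-based inclusive and converted on read/write.

#' Flank breakpoints into genomic intervals
#'
#' Extends each breakpoint position by `flank` base pairs on both sides,
#' yielding the half-open interval `[pos - flank, pos + flank + 1)` clamped
#' at the chromosome origin. With the default 50 bp flank each breakpoint
#' becomes a 101 bp window.
#'
#' @param breakpoints Tibble with at least `chrom` and `pos` (0-based)
#'   columns; extra columns (e.g. `donor_id`) are carried through.
#' @param flank Non-negative flank in base pairs.
#' @return The input with `start` and `end` columns added (0-based
#'   half-open).
#' @export
#' @examples
#' bp <- tibble::tibble(donor_id = "D1", chrom = "chr1", pos = 1000L)
#' extend_breakpoint(bp, flank = 50)
extend_breakpoint <- function(breakpoints, flank = 50) {
  stopifnot(is.data.frame(breakpoints))
  if (length(flank) != 1 || is.na(flank) || flank < 0) {
    abort("`flank` must be a single non-negative number.")
  }
  req <- setdiff(c("chrom", "pos"), names(breakpoints))
  if (length(req)) abort(paste0("Missing column(s): ", toString(req)))
  if (nrow(breakpoints) && any(breakpoints$pos < 0)) {
    abort("Breakpoint positions must be >= 0.")
  }
  breakpoints |>
    mutate(
      start = pmax(0, .data$pos - .env$flank),
      end = .data$pos + .env$flank + 1
    )
}

#' Test overlap of interval pairs (half-open semantics)
#'
#' Vectorised elementwise overlap test: two intervals overlap iff they are
#' on the same chromosome and `a.start < b.end && b.start < a.end`.
#' Touching half-open intervals (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param chrom_a,start_a,end_a First interval set (parallel vectors).
#' @param chrom_b,start_b,end_b Second interval set.
#' @return Logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' Span of a cis promoter interaction
#'
#' For each interaction the span runs from the leftmost to the rightmost
#' coordinate of its bait (promoter) and PIR (promoter-interacting region)
#' fragments. Defined only for cis interactions: a trans interaction
#' (bait and PIR on different chromosomes) has no linear span and raises
#' an error; callers wanting trans support must use anchor mode.
#'
#' @param interactions Tibble with `bait_chrom`, `bait_start`, `bait_end`,
#'   `pir_chrom`, `pir_start`, `pir_end` columns.
#' @return The input with `span_chrom`, `span_start`, `span_end` added.
#' @export
interaction_span <- function(interactions) {
  stopifnot(is.data.frame(interactions))
  trans <- interactions$bait_chrom != interactions$pir_chrom
  if (any(trans)) {
    abort(sprintf(
      "Span undefined for %d trans interaction(s); use anchor mode.",
      sum(trans)
    ))
  }
  interactions |>
    mutate(
      span_chrom = .data$bait_chrom,
      span_start = pmin(.data$bait_start, .data$pir_start),
      span_end = pmax(.data$bait_end, .data$pir_end)
    )
}
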