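# Disruption mapper: flanked breakpoints x promoter interactions.

#' Map breakpoints onto promoter interactions
#'
#' Flanks every breakpoint by `flank_bp` and intersects it with the
#' promoter interactome. In `"span"` mode a hit is any overlap with the
#' full promoter-to-anchor span (cis interactions only; trans
#' interactions are skipped with a message), modelling that a break
#' anywhere between a promoter and its interacting region separates the
#' two on the rearranged allele. In `"anchor"` mode the flanked
#' breakpoint must overlap the distal PIR fragment itself. One event is
#' emitted per (breakpoint, interaction, annotated gene); the reported
#' anchor is always the PIR fragment of the hit interaction.
#'
#' @param breakpoints Tibble with `donor_id`, `chrom`, `pos` (0-based).
#' @param interactions Tibble as from [read_interactions()].
#' @param flank_bp Flank in base pairs (default 50).
#' @param mode `"span"` or `"anchor"`.
#' @return Tibble of disruption events sorted by donor, gene,
#'   interaction: `donor_id`, `gene_id`, `interaction_id`, `bp_chrom`,
#'   `bp_pos`, `anchor_chrom`, `anchor_start`, `anchor_end`, `hit_mode`.
#' @export
map_disruptions <- function(breakpoints, interactions, flank_bp = 50,
                            mode = c("span", "anchor")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(breakpoints), is.data.frame(interactions))

  empty <- tibble(
    donor_id = character(), gene_id = character(),
    interaction_id = character(), bp_chrom = character(),
    bp_pos = integer(), anchor_chrom = character(),
    anchor_start = integer(), anchor_end = integer(),
    hit_mode = character()
  )
  if (nrow(breakpoints) == 0 || nrow(interactions) == 0) return(empty)

  if (mode == "span") {
    trans <- interactions$bait_chrom != interactions$pir_chrom
    if (any(trans)) {
      inform(sprintf(
        "map_disruptions: skipped %d trans interaction(s) in span mode",
        sum(trans)))
      interactions <- interactions[!trans, , drop = FALSE]
      if (nrow(interactions) == 0) return(empty)
    }
    regions <- interaction_span(interactions) |>
      transmute(.data$interaction_id,
                region_chrom = .data$span_chrom,
                region_start = .data$span_start,
                region_end = .data$span_end,
                .data$pir_chrom, .data$pir_start, .data$pir_end,
                .data$gene_ids)
  } else {
    regions <- interactions |>
      transmute(.data$interaction_id,
                region_chrom = .data$pir_chrom,
                region_start = .data$pir_start,
                region_end = .data$pir_end,
                .data$pir_chrom, .data$pir_start, .data$pir_end,
                .data$gene_ids)
  }

  flanked <- extend_breakpoint(breakpoints, flank = flank_bp)

  hits <- flanked |>
    select("donor_id", bp_chrom = "chrom", bp_pos = "pos",
           "start", "end") |>
    inner_join(regions, by = c(bp_chrom = "region_chrom"),
               relationship = "many-to-many") |>
    filter(.data$start < .data$region_end,
           .data$region_start < .data$end)

  hits |>
    tidyr::unnest_longer("gene_ids", values_to = "gene_id") |>
    transmute(
      .data$donor_id, .data$gene_id, .data$interaction_id,
      .data$bp_chrom, .data$bp_pos,
      anchor_chrom = .data$pir_chrom,
      anchor_start = .data$pir_start,
      anchor_end = .data$pir_end,
      hit_mode = .env$mode
    ) |>
    distinct() |>
    arrange(.data$donor_id, .data$gene_id, .data$interaction_id,
            .data$bp_pos)
}

#' Aggregate disruption events per gene and donor
#'
#' Collapses events to the distinct (gene, donor, anchor) combinations
#' that feed the candidate stage: each gene maps to the donors whose
#' breakpoints disrupt one of its promoter interactions, together with
#' the PIR anchor involved.
#'
#' @param events Tibble from [map_disruptions()].
#' @return Tibble with `gene_id`, `donor_id`, `anchor_chrom`,
#'   `anchor_start`, `anchor_end` (distinct rows).
#' @export
disrupted_gene_donor_table <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    return(tibble(gene_id = character(), donor_id = character(),
                  anchor_chrom = character(), anchor_start = integer(),
                  anchor_end = integer()))
  }
  events |>
    distinct(.data$gene_id, .data$donor_id, .data$anchor_chrom,
             .data$anchor_start, .data$anchor_end) |>
    arrange(.data$gene_id, .data$donor_id, .data$anchor_start)
}
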