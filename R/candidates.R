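# Candidate stage: recurrence-filtered combination of disruption events
# and expression outlier calls.

#' Call recurrently deregulated candidate genes
#'
#' A gene becomes a candidate when (i) at least one donor both carries a
#' disrupting breakpoint for the gene and is a primary expression outlier
#' (beyond `k_primary` IQR with the expression floor), and (ii) at least
#' `min_recurrent_donors - 1` additional donors carry a similar
#' disruption and pass the recurrence filter (`k_recurrence` IQR).
#' "Similar" means, by default, a disruption of the same gene sharing the
#' same PIR anchor fragment (`similar_mode = "shared_anchor"`); the
#' relaxed `"any_interaction"` mode accepts any disrupted interaction of
#' the gene. The primary donor counts towards `min_recurrent_donors`.
#'
#' @param gene_donor_table Tibble from [disrupted_gene_donor_table()].
#' @param outlier_calls Tibble from [call_outliers()].
#' @param config A [pipeline_config()].
#' @param interactions Optional interaction tibble used to attach a
#'   promoter (bait) locus to each candidate gene.
#' @return Tibble sorted by `gene_id`: `gene_id`, `n_donors`,
#'   `primary_donors` and `recurrent_donors` (list-columns of donor ids),
#'   `anchors` (list-column of anchor tibbles), and when `interactions`
#'   is given `locus_chrom`/`locus_start`/`locus_end` (the gene's bait
#'   fragment standing in for the gene locus).
#' @export
call_candidates <- function(gene_donor_table, outlier_calls,
                            config = pipeline_config(),
                            interactions = NULL) {
  stopifnot(inherits(config, "hijack_config"),
            is.data.frame(gene_donor_table), is.data.frame(outlier_calls))

  empty <- tibble(
    gene_id = character(), n_donors = integer(),
    primary_donors = list(), recurrent_donors = list(), anchors = list()
  )
  if (nrow(gene_donor_table) == 0 || nrow(outlier_calls) == 0) return(empty)

  joined <- gene_donor_table |>
    inner_join(
      outlier_calls |>
        select("gene_id", "donor_id", "passes_primary",
               "passes_recurrence"),
      by = c("gene_id", "donor_id")
    )
  if (nrow(joined) == 0) return(empty)

  if (config$similar_mode == "shared_anchor") {
    grouped <- joined |>
      group_by(.data$gene_id, .data$anchor_chrom, .data$anchor_start,
               .data$anchor_end)
  } else {
    grouped <- joined |>
      distinct(.data$gene_id, .data$donor_id, .data$passes_primary,
               .data$passes_recurrence) |>
      mutate(anchor_chrom = NA_character_, anchor_start = NA_integer_,
             anchor_end = NA_integer_) |>
      group_by(.data$gene_id, .data$anchor_chrom, .data$anchor_start,
               .data$anchor_end)
  }

  per_group <- grouped |>
    summarise(
      any_primary = any(.data$passes_primary),
      n_recurrent = n_distinct(.data$donor_id[.data$passes_recurrence]),
      primary_donors = list(sort(unique(
        .data$donor_id[.data$passes_primary]))),
      recurrent_donors = list(sort(unique(
        .data$donor_id[.data$passes_recurrence]))),
      .groups = "drop"
    ) |>
    filter(.data$any_primary,
           .data$n_recurrent >= config$min_recurrent_donors)

  if (nrow(per_group) == 0) return(empty)

  out <- per_group |>
    group_by(.data$gene_id) |>
    summarise(
      primary_donors = list(sort(unique(unlist(.data$primary_donors)))),
      recurrent_donors = list(sort(unique(unlist(.data$recurrent_donors)))),
      anchors = list(distinct(
        pick("anchor_chrom", "anchor_start", "anchor_end")
      )),
      .groups = "drop"
    ) |>
    mutate(n_donors = lengths(.data$recurrent_donors)) |>
    select("gene_id", "n_donors", "primary_donors", "recurrent_donors",
           "anchors") |>
    arrange(.data$gene_id)

  if (!is.null(interactions)) {
    loci <- interactions |>
      tidyr::unnest_longer("gene_ids", values_to = "gene_id") |>
      group_by(.data$gene_id) |>
      summarise(locus_chrom = first(.data$bait_chrom),
                locus_start = min(.data$bait_start),
                locus_end = max(.data$bait_end), .groups = "drop")
    out <- out |> left_join(loci, by = "gene_id")
  }
  out
}

#' Pipeline funnel counts
#'
#' The four stage counts of the discovery funnel: disrupted interactions
#' (distinct donor x interaction pairs), genes with a disrupted
#' interaction, genes with at least one disrupted donor that is also a
#' primary expression outlier, and final recurrence-filtered candidates.
#'
#' @param events Tibble from [map_disruptions()].
#' @param outlier_calls Tibble from [call_outliers()].
#' @param candidates Tibble from [call_candidates()].
#' @return One-row tibble: `n_disrupted_interactions`,
#'   `n_disrupted_genes`, `n_primary_outlier_genes`, `n_candidates`.
#' @export
stage_counts <- function(events, outlier_calls, candidates) {
  primary_genes <- if (nrow(events) && nrow(outlier_calls)) {
    events |>
      distinct(.data$gene_id, .data$donor_id) |>
      inner_join(outlier_calls |> filter(.data$passes_primary),
                 by = c("gene_id", "donor_id")) |>
      summarise(n = n_distinct(.data$gene_id)) |>
      pull(.data$n)
  } else 0L
  tibble(
    n_disrupted_interactions = if (nrow(events)) {
      nrow(distinct(events, .data$donor_id, .data$interaction_id))
    } else 0L,
    n_disrupted_genes = n_distinct(events$gene_id),
    n_primary_outlier_genes = as.integer(primary_genes),
    n_candidates = nrow(candidates)
  )
}
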