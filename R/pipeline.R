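# End-to-end wrapper: breakpoints x interactome -> outliers ->
# recurrence-filtered candidates -> survival screen.

#' Run the full cis-disruption screen
#'
#' Chains every stage: flanked-breakpoint x interactome intersection,
#' median-of-ratios normalization, per-gene median/IQR statistics over
#' the structural-variant donor scope, IQR-unit outlier calls for
#' disrupted genes, the recurrence filter over shared anchors, and (when
#' survival data is supplied) the median-split log-rank screen with BH
#' correction.
#'
#' @param breakpoints Tibble from [read_breakpoints()] or
#'   [simulate_breakpoints()].
#' @param interactions Tibble from [read_interactions()] or
#'   [simulate_interactome()].
#' @param counts Integer matrix genes x donors.
#' @param survival_records Optional tibble from [read_survival()].
#' @param config A [pipeline_config()].
#' @return List of class `hijack_result`: `candidates`, `stage_counts`,
#'   `events`, `outliers`, `norm`, `stats`, `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 3, n_donors = 30, n_genes = 80,
#'                                   n_interactions = 40, n_breakpoints = 80,
#'                                   n_planted_genes = 2))
#' res <- run_pipeline(sim$breakpoints, sim$interactome, sim$counts,
#'                     sim$survival)
#' glance(res)
run_pipeline <- function(breakpoints, interactions, counts,
                         survival_records = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "hijack_config"))
  events <- map_disruptions(breakpoints, interactions,
                            flank_bp = config$flank_bp,
                            mode = config$disruption_mode)
  norm <- median_of_ratios(counts)
  scope <- if (config$stats_donor_scope == "sv_donors") {
    intersect(colnames(counts), unique(breakpoints$donor_id))
  } else {
    colnames(counts)
  }
  stats <- gene_stats(norm, donor_scope = scope)
  genes_hit <- intersect(unique(events$gene_id), rownames(counts))
  outliers <- if (length(genes_hit)) {
    call_outliers(norm, stats,
                  k_primary = config$k_primary,
                  k_recurrence = config$k_recurrence,
                  min_norm_expr = config$min_norm_expr,
                  directional = config$directional,
                  genes = genes_hit)
  } else {
    tibble(gene_id = character(), donor_id = character(),
           normalized_value = numeric(), deviation_iqr = numeric(),
           passes_primary = logical(), passes_recurrence = logical())
  }
  gdt <- disrupted_gene_donor_table(events)
  candidates <- call_candidates(gdt, outliers, config, interactions)
  counts_tbl <- stage_counts(events, outliers, candidates)
  if (!is.null(survival_records) && nrow(candidates)) {
    candidates <- survival_screen(candidates, norm, survival_records,
                                  config)
  }
  structure(
    list(candidates = candidates, stage_counts = counts_tbl,
         events = events, outliers = outliers, norm = norm,
         stats = stats, config = config),
    class = "hijack_result"
  )
}

#' @export
print.hijack_result <- function(x, ...) {
  sc <- x$stage_counts
  cat("<hijack_result>\n")
  cat(sprintf("  disrupted interactions: %d\n", sc$n_disrupted_interactions))
  cat(sprintf("  disrupted genes:        %d\n", sc$n_disrupted_genes))
  cat(sprintf("  primary-outlier genes:  %d\n", sc$n_primary_outlier_genes))
  cat(sprintf("  candidates:             %d\n", sc$n_candidates))
  if ("significant" %in% names(x$candidates)) {
    cat(sprintf("  survival-significant:   %d\n",
                sum(x$candidates$significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' Tidy the candidate table of a screen result
#'
#' @param x A `hijack_result`.
#' @param ... Unused.
#' @return One row per candidate gene with donor lists collapsed to
#'   comma-separated strings and anchors to `chrom:start-end` (1-based)
#'   notation.
#' @export
tidy.hijack_result <- function(x, ...) {
  cand <- x$candidates
  if (nrow(cand) == 0) return(as_tibble(cand))
  cand |>
    mutate(
      primary_donors = purrr::map_chr(.data$primary_donors, paste,
                                      collapse = ","),
      recurrent_donors = purrr::map_chr(.data$recurrent_donors, paste,
                                        collapse = ","),
      anchors = purrr::map_chr(.data$anchors, function(a) {
        if (is.null(a) || nrow(a) == 0 || all(is.na(a$anchor_chrom))) {
          return(NA_character_)
        }
        paste(sprintf("%s:%d-%d", a$anchor_chrom, a$anchor_start + 1,
                      a$anchor_end), collapse = ",")
      })
    )
}

#' One-row summary of a screen result
#'
#' @param x A `hijack_result`.
#' @param ... Unused.
#' @return The funnel counts plus the number of survival-significant
#'   candidates (NA when no survival data was screened).
#' @export
glance.hijack_result <- function(x, ...) {
  x$stage_counts |>
    mutate(n_significant = if ("significant" %in% names(x$candidates)) {
      sum(x$candidates$significant, na.rm = TRUE)
    } else {
      NA_integer_
    })
}

#' Funnel plot of a screen result
#'
#' Bar chart of the gene-level discovery funnel: disrupted genes,
#' disrupted genes with a primary expression outlier, recurrence-
#' filtered candidates, and (when screened) survival-significant
#' candidates.
#'
#' @param object A `hijack_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hijack_result <- function(object, ...) {
  sc <- glance(object)
  df <- tibble(
    stage = factor(
      c("disrupted", "primary outlier", "candidate", "survival"),
      levels = c("disrupted", "primary outlier", "candidate", "survival")
    ),
    n = c(sc$n_disrupted_genes, sc$n_primary_outlier_genes,
          sc$n_candidates, sc$n_significant)
  ) |>
    filter(!is.na(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Cis-disruption discovery funnel") +
    ggplot2::theme_minimal()
}

#' Step plot of a Kaplan-Meier estimate
#'
#' @param object A `km_tbl` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a median-split gene
#'
#' Convenience plot for one candidate gene: splits donors at the median
#' expression value (within cohorts, per the config) and draws the
#' high/low Kaplan-Meier curves.
#'
#' @param gene Gene identifier.
#' @param norm A `norm_matrix`.
#' @param survival_records Tibble from [read_survival()].
#' @return A ggplot object.
#' @export
plot_km_split <- function(gene, norm, survival_records) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (!gene %in% rownames(norm$values)) {
    abort(sprintf("Gene %s absent from the matrix.", gene))
  }
  dat <- tibble(donor_id = colnames(norm$values),
                value = norm$values[gene, ]) |>
    inner_join(survival_records, by = "donor_id") |>
    median_split()
  curves <- dat |>
    group_by(.data$group) |>
    group_modify(~ km_estimate(.x)) |>
    ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival",
                  title = gene, colour = "expression") +
    ggplot2::theme_minimal()
}
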