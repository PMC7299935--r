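#' Pipeline configuration
#'
#' Bundles every threshold of the screen in one validated object. The
#' defaults are the screen's published operating point: breakpoints are
#' flanked by +/- 50 bp before intersection, a primary expression outlier
#' deviates from the cohort median by more than 2 interquartile ranges
#' (IQR) with a normalized expression above 10, recurrence requires at
#' least one additional donor beyond 1 IQR at the same disrupted anchor
#' (2 donors in total), and survival candidates are kept below a
#' Benjamini-Hochberg adjusted p of 0.05.
#'
#' @param flank_bp Breakpoint flank in base pairs (each side).
#' @param k_primary Primary outlier threshold in IQR units (strict `>`).
#' @param k_recurrence Recurrence outlier threshold in IQR units.
#' @param min_norm_expr Normalized-expression floor applied to the donor's
#'   own value (strict `>`).
#' @param min_recurrent_donors Minimum donors supporting a candidate,
#'   including the primary donor.
#' @param padj_threshold BH-adjusted significance threshold for the
#'   survival screen.
#' @param decile_fraction Fraction of donors in each extreme group of the
#'   concordance stage; must lie in (0, 0.5].
#' @param disruption_mode `"span"` intersects flanked breakpoints with the
#'   full promoter-to-anchor span (cis only); `"anchor"` with the distal
#'   promoter-interacting region (PIR) fragment only.
#' @param stats_donor_scope `"sv_donors"` computes per-gene median/IQR over
#'   donors with structural-variant data only (the screen's convention);
#'   `"all_donors"` uses every donor in the expression matrix.
#' @param directional If `TRUE`, only upregulation (positive deviation)
#'   counts as an outlier; default is two-sided with the sign retained.
#' @param similar_mode `"shared_anchor"` requires recurrent donors to hit
#'   the same PIR anchor fragment; `"any_interaction"` accepts any
#'   disrupted interaction of the gene.
#' @param pooled_split If `TRUE` the survival median split pools cohorts;
#'   default splits within each cohort before pooling the log-rank test.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class `hijack_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(flank_bp = 50, k_primary = 2)
#' cfg$min_norm_expr
pipeline_config <- function(flank_bp = 50,
                            k_primary = 2,
                            k_recurrence = 1,
                            min_norm_expr = 10,
                            min_recurrent_donors = 2L,
                            padj_threshold = 0.05,
                            decile_fraction = 0.10,
                            disruption_mode = c("span", "anchor"),
                            stats_donor_scope = c("sv_donors", "all_donors"),
                            directional = FALSE,
                            similar_mode = c("shared_anchor", "any_interaction"),
                            pooled_split = FALSE,
                            seed = 1L) {
  disruption_mode <- match.arg(disruption_mode)
  stats_donor_scope <- match.arg(stats_donor_scope)
  similar_mode <- match.arg(similar_mode)
  if (flank_bp < 0) abort("`flank_bp` must be >= 0.")
  if (!(k_primary >= k_recurrence && k_recurrence >= 0)) {
    abort("Need k_primary >= k_recurrence >= 0.")
  }
  if (min_norm_expr <= 0) abort("`min_norm_expr` must be positive.")
  if (min_recurrent_donors < 1) abort("`min_recurrent_donors` must be >= 1.")
  if (padj_threshold <= 0 || padj_threshold > 1) {
    abort("`padj_threshold` must lie in (0, 1].")
  }
  if (decile_fraction <= 0 || decile_fraction > 0.5) {
    abort("`decile_fraction` must lie in (0, 0.5].")
  }
  structure(
    list(
      flank_bp = as.integer(flank_bp),
      k_primary = k_primary,
      k_recurrence = k_recurrence,
      min_norm_expr = min_norm_expr,
      min_recurrent_donors = as.integer(min_recurrent_donors),
      padj_threshold = padj_threshold,
      decile_fraction = decile_fraction,
      disruption_mode = disruption_mode,
      stats_donor_scope = stats_donor_scope,
      directional = directional,
      similar_mode = similar_mode,
      pooled_split = pooled_split,
      seed = as.integer(seed)
    ),
    class = "hijack_config"
  )
}

#' @export
print.hijack_config <- function(x, ...) {
  cat("<hijack_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
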