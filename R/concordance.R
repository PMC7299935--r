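# Concordance stage: extreme-decile donor grouping by a focal gene,
# per-gene fold changes, and a Mann-Whitney shift test of gene sets.

#' Extreme-decile donor groups for a focal gene
#'
#' Selects the `floor(fraction * n)` donors with the highest and lowest
#' expression values. Selection is deterministic: donors are ordered by
#' (value, donor id), the first block forms the low group and the last
#' block the high group, so ties are broken lexicographically and the
#' groups are always disjoint.
#'
#' @param expr_values Tibble with `donor_id` and `value` columns.
#' @param fraction Fraction per extreme group, in (0, 0.5].
#' @return Tibble of the selected donors with a `group` column
#'   (`"high"`/`"low"`); attribute `fraction` records the request.
#' @export
#' @examples
#' ev <- tibble::tibble(donor_id = sprintf("D%03d", 1:300), value = rnorm(300))
#' table(decile_groups(ev, 0.10)$group)
decile_groups <- function(expr_values, fraction = 0.10) {
  stopifnot(is.data.frame(expr_values))
  if (fraction <= 0 || fraction > 0.5) {
    abort("`fraction` must lie in (0, 0.5].")
  }
  n <- nrow(expr_values)
  k <- floor(fraction * n)
  if (k < 1) abort("Group size floor(fraction * n) must be >= 1.")
  ord <- order(expr_values$value, expr_values$donor_id)
  low <- expr_values[ord[seq_len(k)], , drop = FALSE]
  high <- expr_values[ord[seq.int(n - k + 1, n)], , drop = FALSE]
  out <- bind_rows(
    low |> mutate(group = "low"),
    high |> mutate(group = "high")
  )
  attr(out, "fraction") <- fraction
  out
}

#' Per-gene fold changes between extreme groups
#'
#' Log2 fold change of median normalized expression in the high versus
#' the low group, with a pseudocount to stabilise low counts:
#' `log2((median_high + eps) / (median_low + eps))`. Genes with zero
#' median in both groups therefore get fold change 0. Optionally a
#' per-gene two-sided Mann-Whitney p across the two donor groups.
#'
#' @param norm A `norm_matrix`.
#' @param groups Tibble from [decile_groups()].
#' @param pseudocount Pseudocount `eps` (default 1).
#' @param gene_p If `TRUE`, add a per-gene Mann-Whitney `p` column
#'   (slower).
#' @return Tibble with `gene_id`, `log2_fc` and optionally `p`.
#' @export
rank_fold_change <- function(norm, groups, pseudocount = 1,
                             gene_p = FALSE) {
  stopifnot(inherits(norm, "norm_matrix"), is.data.frame(groups))
  hi <- groups$donor_id[groups$group == "high"]
  lo <- groups$donor_id[groups$group == "low"]
  missing <- setdiff(c(hi, lo), colnames(norm$values))
  if (length(missing)) {
    abort(sprintf("Donors absent from matrix: %s",
                  toString(head(missing, 5))))
  }
  vh <- norm$values[, hi, drop = FALSE]
  vl <- norm$values[, lo, drop = FALSE]
  med_h <- unname(apply(vh, 1, median))
  med_l <- unname(apply(vl, 1, median))
  out <- tibble(
    gene_id = rownames(norm$values),
    log2_fc = log2((med_h + pseudocount) / (med_l + pseudocount))
  )
  if (gene_p) {
    out$p <- vapply(seq_len(nrow(vh)), function(i) {
      suppressWarnings(wilcox.test(vh[i, ], vl[i, ])$p.value)
    }, numeric(1))
  }
  out
}

#' Mann-Whitney shift test of a gene set's fold changes
#'
#' Tests whether the fold changes of a gene set are shifted relative to
#' the background of all other genes in the table (two-sided
#' Mann-Whitney U). Exact enumeration is used when both sides have at
#' most 20 genes and the data are tie-free; otherwise the normal
#' approximation with tie correction. The reported `direction` is the
#' sign of the median shift (set minus background).
#'
#' @param fc_table Tibble from [rank_fold_change()].
#' @param gene_set Character vector of gene ids.
#' @param set_name Label for the result row.
#' @return One-row tibble: `set_name`, `n_set`, `n_background`,
#'   `statistic` (U for the set side), `p`, `direction`.
#' @export
geneset_shift_test <- function(fc_table, gene_set, set_name = "set") {
  stopifnot(is.data.frame(fc_table))
  in_set <- fc_table$gene_id %in% gene_set
  if (!any(in_set)) {
    abort(sprintf(
      "Gene set has no overlap with the fold-change table (first missing: %s)",
      toString(head(setdiff(gene_set, fc_table$gene_id), 5))))
  }
  if (all(in_set)) abort("Background is empty: gene set covers every gene.")
  x <- fc_table$log2_fc[in_set]
  y <- fc_table$log2_fc[!in_set]
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 20 && length(y) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)
  )
  tibble(
    set_name = set_name,
    n_set = length(x),
    n_background = length(y),
    statistic = unname(wt$statistic),
    p = wt$p.value,
    direction = sign(median(x) - median(y))
  )
}
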