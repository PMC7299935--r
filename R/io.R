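# Readers/writers for the cohort's tabular formats. External coordinates
# are 1-based inclusive; everything in memory is 0-based half-open.

icgc_sv_cols <- c(
  donor_id = "icgc_donor_id",
  chr_from = "chr_from", pos_from = "chr_from_bkpt",
  chr_to = "chr_to", pos_to = "chr_to_bkpt",
  sv_type = "variant_type"
)

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()),
                  ...)
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, toString(miss)))
  }
}

parse_int_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | out != trunc(out))
  if (length(bad)) {
    abort(sprintf("%s: non-integer %s at data line %d (value '%s')",
                  path, col, bad[1], x[bad[1]]))
  }
  out
}

#' Read structural-variant breakpoints
#'
#' Two dialects are supported. `"icgc_sv"` consumes ICGC-style somatic SV
#' tables: only the donor id, from/to chromosome and position, and variant
#' type columns are used, and every row yields two breakpoints (the from-
#' and to-end of the rearrangement), treated independently under the same
#' donor. `"simple_tsv"` has columns `donor_id`, `chrom`, `pos` (1-based)
#' and optional `sv_type`. Positions are converted to 0-based on read and
#' exact duplicates (same donor, chromosome, position) are removed.
#'
#' @param path Tab-delimited input file.
#' @param format `"simple_tsv"` or `"icgc_sv"`.
#' @return Tibble with columns `donor_id`, `chrom`, `pos` (0-based),
#'   `sv_type`.
#' @export
read_breakpoints <- function(path, format = c("simple_tsv", "icgc_sv")) {
  format <- match.arg(format)
  df <- read_tsv_quiet(path)
  if (format == "simple_tsv") {
    require_cols(df, c("donor_id", "chrom", "pos"), path)
    out <- tibble(
      donor_id = df$donor_id,
      chrom = df$chrom,
      pos = parse_int_col(df$pos, "pos", path) - 1,
      sv_type = if ("sv_type" %in% names(df)) df$sv_type else NA_character_
    )
  } else {
    require_cols(df, unname(icgc_sv_cols), path)
    from <- tibble(
      donor_id = df[[icgc_sv_cols[["donor_id"]]]],
      chrom = df[[icgc_sv_cols[["chr_from"]]]],
      pos = parse_int_col(df[[icgc_sv_cols[["pos_from"]]]],
                          icgc_sv_cols[["pos_from"]], path) - 1,
      sv_type = df[[icgc_sv_cols[["sv_type"]]]]
    )
    to <- tibble(
      donor_id = df[[icgc_sv_cols[["donor_id"]]]],
      chrom = df[[icgc_sv_cols[["chr_to"]]]],
      pos = parse_int_col(df[[icgc_sv_cols[["pos_to"]]]],
                          icgc_sv_cols[["pos_to"]], path) - 1,
      sv_type = df[[icgc_sv_cols[["sv_type"]]]]
    )
    out <- bind_rows(from, to)
  }
  if (nrow(out) && any(out$pos < 0)) {
    abort(sprintf("%s: positions must be >= 1 (1-based input)", path))
  }
  out |> distinct(.data$donor_id, .data$chrom, .data$pos, .keep_all = TRUE)
}

#' Write breakpoints (simple dialect, 1-based)
#' @param breakpoints Tibble as returned by [read_breakpoints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(breakpoints, path) {
  breakpoints |>
    mutate(pos = .data$pos + 1) |>
    select(any_of(c("donor_id", "chrom", "pos", "sv_type"))) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read a promoter-interaction table
#'
#' Expects tab-delimited columns `interaction_id` (optional; synthesised
#' when absent), `bait_chr`, `bait_start`, `bait_end`, `pir_chr`,
#' `pir_start`, `pir_end`, `gene_ids` (semicolon-separated identifiers
#' annotated to the bait) and `score`. Coordinates are 1-based inclusive
#' and converted to 0-based half-open. Rows with no gene annotation are
#' dropped (the count is reported via a message).
#'
#' @param path Tab-delimited input file.
#' @return Tibble with one row per interaction; `gene_ids` is a
#'   list-column of character vectors.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_quiet(path)
  require_cols(df, c("bait_chr", "bait_start", "bait_end",
                     "pir_chr", "pir_start", "pir_end",
                     "gene_ids", "score"), path)
  n0 <- nrow(df)
  for (col in c("bait_start", "bait_end", "pir_start", "pir_end")) {
    df[[col]] <- parse_int_col(df[[col]], col, path)
  }
  bad <- which(df$bait_end <= df$bait_start | df$pir_end <= df$pir_start)
  if (length(bad)) {
    abort(sprintf("%s: fragment end <= start at data line %d", path, bad[1]))
  }
  gene_ids <- stringr::str_split(df$gene_ids, ";")
  gene_ids <- purrr::map(gene_ids, function(g) g[nzchar(g) & !is.na(g)])
  keep <- lengths(gene_ids) > 0
  if (any(!keep)) {
    inform(sprintf("read_interactions: dropped %d row(s) without gene annotation",
                   sum(!keep)))
  }
  df <- df[keep, , drop = FALSE]
  tibble(
    interaction_id = if ("interaction_id" %in% names(df)) {
      df$interaction_id
    } else {
      sprintf("int%05d", which(keep))
    },
    bait_chrom = df$bait_chr,
    bait_start = df$bait_start - 1,
    bait_end = df$bait_end,
    pir_chrom = df$pir_chr,
    pir_start = df$pir_start - 1,
    pir_end = df$pir_end,
    gene_ids = gene_ids[keep],
    score = suppressWarnings(as.numeric(df$score))
  )
}

#' Write a promoter-interaction table (1-based external coordinates)
#' @param interactions Tibble as returned by [read_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  interactions |>
    transmute(
      interaction_id = .data$interaction_id,
      bait_chr = .data$bait_chrom,
      bait_start = .data$bait_start + 1,
      bait_end = .data$bait_end,
      pir_chr = .data$pir_chrom,
      pir_start = .data$pir_start + 1,
      pir_end = .data$pir_end,
      gene_ids = purrr::map_chr(.data$gene_ids, paste, collapse = ";"),
      score = .data$score
    ) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read a raw count matrix (genes x donors)
#'
#' First column `gene_id`, remaining columns one per donor, values
#' non-negative integers. Duplicate gene or donor identifiers and
#' negative counts are format errors.
#'
#' @param path Tab-delimited input file.
#' @return Integer matrix with gene rownames and donor colnames.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(df, "gene_id", path)
  if (anyDuplicated(df$gene_id)) abort(sprintf("%s: duplicated gene ids", path))
  donors <- setdiff(names(df), "gene_id")
  if (anyDuplicated(donors)) abort(sprintf("%s: duplicated donor ids", path))
  m <- as.matrix(df[donors])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != trunc(m))) {
    abort(sprintf("%s: counts must be non-negative integers", path))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Write a count matrix
#' @param counts Integer matrix, genes x donors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  as_tibble(counts, rownames = "gene_id") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read overall-survival records
#'
#' Columns `donor_id`, `time` (non-negative, days), `event` (1 = death
#' observed, 0 = censored) and `cohort` (label; defaults to "cohort1"
#' when absent).
#'
#' @param path Tab-delimited input file.
#' @return Tibble with columns `donor_id`, `time`, `event`, `cohort`.
#' @export
read_survival <- function(path) {
  df <- read_tsv_quiet(path)
  require_cols(df, c("donor_id", "time", "event"), path)
  if (anyDuplicated(df$donor_id)) abort(sprintf("%s: duplicated donor ids", path))
  time <- suppressWarnings(as.numeric(df$time))
  if (any(is.na(time) | time < 0)) {
    abort(sprintf("%s: survival times must be non-negative numbers", path))
  }
  event <- suppressWarnings(as.numeric(df$event))
  if (any(is.na(event) | !event %in% c(0, 1))) {
    abort(sprintf("%s: event flag must be 0 or 1", path))
  }
  tibble(
    donor_id = df$donor_id,
    time = time,
    event = as.integer(event),
    cohort = if ("cohort" %in% names(df)) df$cohort else "cohort1"
  )
}

#' Write survival records
#' @param survival_records Tibble as returned by [read_survival()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(survival_records, path) {
  readr::write_tsv(survival_records, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets (plain list or GMT)
#'
#' Plain format: one gene identifier per line, one file per set (named
#' after the file). GMT: one set per line, tab-delimited
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Input file.
#' @param format `"plain"` or `"gmt"`.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path, format = c("plain", "gmt")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (format == "plain") {
    out <- list(unique(lines))
    names(out) <- tools::file_path_sans_ext(basename(path))
    out
  } else {
    parts <- stringr::str_split(lines, "\t")
    out <- purrr::map(parts, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
    names(out) <- purrr::map_chr(parts, 1)
    out
  }
}

#' Write the candidate table, disrupted anchors and run summary
#'
#' Writes (i) a tab-delimited candidate table mirroring the published
#' report layout (gene, overall-survival p-value and adjusted p-value,
#' promoter coordinates, disrupted PIR anchor, supporting-donor count);
#' (ii) a BED file (0-based half-open) of the disrupted anchors, next to
#' `path` with suffix `_anchors.bed`; and (iii) a JSON run summary
#' (config echo and stage counts) with suffix `_summary.json`.
#'
#' @param candidates Candidate tibble from [call_candidates()] or
#'   [survival_screen()].
#' @param path Output TSV path.
#' @param stage_counts Optional one-row tibble from [stage_counts()].
#' @param config Optional [pipeline_config()] echoed into the summary.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, stage_counts = NULL,
                             config = NULL) {
  fmt_iv <- function(chrom, start, end) {
    ifelse(is.na(chrom), NA_character_,
           sprintf("%s:%d-%d", chrom, start + 1, end))
  }
  tab <- tibble(
    gene = candidates$gene_id,
    p_value_os = if ("p" %in% names(candidates)) candidates$p else NA_real_,
    padj_os = if ("padj" %in% names(candidates)) candidates$padj else NA_real_,
    genomic_coordinates = if ("locus_chrom" %in% names(candidates)) {
      fmt_iv(candidates$locus_chrom, candidates$locus_start,
             candidates$locus_end)
    } else NA_character_,
    disrupted_pir_anchor = if ("anchors" %in% names(candidates)) {
      purrr::map_chr(candidates$anchors, function(a) {
        if (is.null(a) || nrow(a) == 0) return(NA_character_)
        paste(fmt_iv(a$anchor_chrom, a$anchor_start, a$anchor_end),
              collapse = ",")
      })
    } else NA_character_,
    n_donors = if ("n_donors" %in% names(candidates)) {
      candidates$n_donors
    } else NA_integer_
  )
  readr::write_tsv(tab, path, progress = FALSE)

  stem <- sub("\\.[^./]*$", "", path)
  bed_path <- paste0(stem, "_anchors.bed")
  if ("anchors" %in% names(candidates) && nrow(candidates)) {
    bed <- purrr::map2_dfr(candidates$anchors, candidates$gene_id,
                           function(a, g) {
                             if (is.null(a) || nrow(a) == 0) return(NULL)
                             tibble(chrom = a$anchor_chrom,
                                    start = a$anchor_start,
                                    end = a$anchor_end, name = g)
                           })
  } else {
    bed <- tibble(chrom = character(), start = integer(),
                  end = integer(), name = character())
  }
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)

  summary <- list(
    n_candidates = nrow(candidates),
    stage_counts = if (!is.null(stage_counts)) as.list(stage_counts),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(summary, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
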