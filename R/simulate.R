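# Synthetic-cohort generator with planted ground truth. Emulates the
# five pipeline inputs: a toy promoter interactome with non-overlapping
# fragments, donor breakpoints planted inside (or kept away from)
# interaction spans, negative-binomial counts with donor size factors
# and planted cis-upregulation, and exponential survival tied to the
# expression group of a designated gene with independent uniform
# censoring.

#' Simulation configuration
#'
#' Defaults emulate the structural-variant cohort scale the screen was
#' designed for: 92 donors contributing ~750 breakpoints, an interactome
#' of 850 promoter interactions annotating 1,700 genes (two genes per
#' shared anchor), negative-binomial counts with dispersion 0.1, an
#' 8-fold planted cis-effect in 2 donors per planted gene, and
#' exponential overall survival with a 3-fold hazard ratio between
#' expression groups and ~30% censoring.
#'
#' @param seed Integer seed; every generator draws from it
#'   deterministically.
#' @param n_donors Number of donors.
#' @param n_genes Number of genes in the count matrix.
#' @param n_interactions Number of promoter interactions.
#' @param chrom_length Toy chromosome length in bp.
#' @param genes_per_interaction Genes annotated to each bait/anchor.
#' @param n_breakpoints Total breakpoints, planted ones included.
#' @param n_planted_genes Genes given a planted cis-effect.
#' @param n_planted_donors_per_gene Donors per planted gene; all share
#'   that gene's anchor.
#' @param effect_multiplier Fold applied to the negative-binomial mean of
#'   a planted gene in its planted donors (>= 1).
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); must be > 0.
#' @param size_factor_range Log-uniform range of donor size factors.
#' @param baseline_mean_range Log-uniform range of per-gene baseline
#'   means.
#' @param hazard_rate_base Baseline exponential hazard (per day).
#' @param hazard_ratio Hazard ratio of the designated gene's high versus
#'   low expression group.
#' @param censoring_fraction_target Expected fraction of censored donors
#'   (independent uniform censoring; 0 disables censoring).
#' @return A list of class `hijack_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 92L,
                       n_genes = 1700L,
                       n_interactions = 850L,
                       chrom_length = 6e7,
                       genes_per_interaction = 2L,
                       n_breakpoints = 750L,
                       n_planted_genes = 2L,
                       n_planted_donors_per_gene = 2L,
                       effect_multiplier = 8,
                       nb_dispersion = 0.1,
                       size_factor_range = c(0.5, 2),
                       baseline_mean_range = c(20, 500),
                       hazard_rate_base = 1 / 1500,
                       hazard_ratio = 3,
                       censoring_fraction_target = 0.3) {
  stopifnot(n_donors >= 1, n_genes >= 1, n_interactions >= 0,
            genes_per_interaction >= 1, n_breakpoints >= 0,
            n_planted_genes >= 0, n_planted_donors_per_gene >= 1)
  if (effect_multiplier < 1) abort("`effect_multiplier` must be >= 1.")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  if (censoring_fraction_target < 0 || censoring_fraction_target >= 1) {
    abort("`censoring_fraction_target` must lie in [0, 1).")
  }
  structure(
    list(seed = as.integer(seed), n_donors = as.integer(n_donors),
         n_genes = as.integer(n_genes),
         n_interactions = as.integer(n_interactions),
         chrom_length = chrom_length,
         genes_per_interaction = as.integer(genes_per_interaction),
         n_breakpoints = as.integer(n_breakpoints),
         n_planted_genes = as.integer(n_planted_genes),
         n_planted_donors_per_gene = as.integer(n_planted_donors_per_gene),
         effect_multiplier = effect_multiplier,
         nb_dispersion = nb_dispersion,
         size_factor_range = size_factor_range,
         baseline_mean_range = baseline_mean_range,
         hazard_rate_base = hazard_rate_base,
         hazard_ratio = hazard_ratio,
         censoring_fraction_target = censoring_fraction_target),
    class = "hijack_sim_config"
  )
}

sim_donor_ids <- function(cfg) sprintf("D%03d", seq_len(cfg$n_donors))
sim_gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

# Fixed fragment layout (bp): promoter bait, bait-to-anchor gap, PIR
# anchor, spacer to the next interaction unit. Distances are in the
# 100 kb range typical of promoter-capture Hi-C anchors.
sim_layout <- list(bait_w = 5e3, gap_w = 1.5e5, pir_w = 3e4, spacer = 5e4)

#' Simulate a toy promoter interactome
#'
#' Lays interactions out as non-overlapping bait + anchor fragment pairs
#' on as many toy chromosomes as needed, each annotated with
#' `genes_per_interaction` gene identifiers assigned cyclically from the
#' gene pool (so with 2 genes per interaction every anchor is shared by
#' two genes). Deterministic for a given configuration.
#'
#' @param cfg A [sim_config()].
#' @return Interaction tibble in the [read_interactions()] layout.
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "hijack_sim_config"))
  empty <- tibble(interaction_id = character(), bait_chrom = character(),
                  bait_start = integer(), bait_end = integer(),
                  pir_chrom = character(), pir_start = integer(),
                  pir_end = integer(), gene_ids = list(),
                  score = numeric())
  if (cfg$n_interactions == 0) return(empty)
  unit <- with(sim_layout, bait_w + gap_w + pir_w + spacer)
  per_chrom <- floor(cfg$chrom_length / unit)
  if (per_chrom < 1) {
    abort("Interaction unit does not fit on the chromosome; increase `chrom_length`.")
  }
  i <- seq_len(cfg$n_interactions) - 1L
  chrom_idx <- i %/% per_chrom + 1L
  offset <- (i %% per_chrom) * unit
  genes <- sim_gene_ids(cfg)
  k <- cfg$genes_per_interaction
  gene_ids <- purrr::map(i, function(ii) {
    genes[(ii * k + seq_len(k) - 1L) %% cfg$n_genes + 1L]
  })
  tibble(
    interaction_id = sprintf("int%05d", i + 1L),
    bait_chrom = sprintf("chr%d", chrom_idx),
    bait_start = offset,
    bait_end = offset + sim_layout$bait_w,
    pir_chrom = sprintf("chr%d", chrom_idx),
    pir_start = offset + sim_layout$bait_w + sim_layout$gap_w,
    pir_end = offset + sim_layout$bait_w + sim_layout$gap_w +
      sim_layout$pir_w,
    gene_ids = gene_ids,
    score = 5
  )
}

#' Plant the ground truth of a synthetic cohort
#'
#' Chooses `n_planted_genes` genes, one distinct interaction each, and
#' `n_planted_donors_per_gene` donors per gene; all planted donors of a
#' gene share that gene's PIR anchor. The first planted gene is also the
#' designated survival-linked gene (falling back to the first gene of
#' the pool when nothing is planted).
#'
#' @param cfg A [sim_config()].
#' @param interactome Tibble from [simulate_interactome()].
#' @return List of class `hijack_truth`: `planted` (tibble of gene,
#'   donor, interaction and anchor), `survival_gene`.
#' @export
plant_truth <- function(cfg, interactome) {
  stopifnot(inherits(cfg, "hijack_sim_config"))
  donors <- sim_donor_ids(cfg)
  planted <- tibble(gene_id = character(), donor_id = character(),
                    interaction_id = character(),
                    anchor_chrom = character(), anchor_start = integer(),
                    anchor_end = integer())
  if (cfg$n_planted_genes > 0) {
    if (nrow(interactome) < cfg$n_planted_genes) {
      abort("Fewer interactions than planted genes.")
    }
    if (cfg$n_planted_donors_per_gene > cfg$n_donors) {
      abort("More planted donors per gene than donors.")
    }
    planted <- withr::with_seed(cfg$seed + 1L, {
      # walk interactions in random order, keeping the first with a lead
      # gene not planted yet (cyclic gene assignment can reuse genes)
      ord <- sample(nrow(interactome))
      lead <- purrr::map_chr(interactome$gene_ids, 1)
      picks <- ord[!duplicated(lead[ord])][seq_len(cfg$n_planted_genes)]
      if (anyNA(picks)) abort("Not enough distinct lead genes to plant.")
      purrr::map_dfr(picks, function(ix) {
        row <- interactome[ix, ]
        tibble(
          gene_id = row$gene_ids[[1]][1],
          donor_id = sample(donors, cfg$n_planted_donors_per_gene),
          interaction_id = row$interaction_id,
          anchor_chrom = row$pir_chrom,
          anchor_start = row$pir_start,
          anchor_end = row$pir_end
        )
      })
    })
  }
  structure(
    list(planted = planted,
         survival_gene = if (nrow(planted)) planted$gene_id[1] else
           sim_gene_ids(cfg)[1]),
    class = "hijack_truth"
  )
}

#' Simulate donor breakpoints
#'
#' Planted breakpoints fall uniformly inside the planted gene's anchor
#' fragment (one per planted gene-donor pair), so anchor-mode mapping
#' recovers them by construction. Background breakpoints are placed
#' uniformly in the gaps between interaction spans, keeping a 100 bp
#' margin so that the default +/-50 bp flank cannot reach a span.
#'
#' @param cfg A [sim_config()].
#' @param interactome Tibble from [simulate_interactome()].
#' @param truth A `hijack_truth` from [plant_truth()].
#' @return Breakpoint tibble (`donor_id`, `chrom`, `pos` 0-based,
#'   `sv_type`).
#' @export
simulate_breakpoints <- function(cfg, interactome, truth) {
  stopifnot(inherits(cfg, "hijack_sim_config"),
            inherits(truth, "hijack_truth"))
  donors <- sim_donor_ids(cfg)
  margin <- 100
  withr::with_seed(cfg$seed + 2L, {
    planted_bp <- if (nrow(truth$planted)) {
      truth$planted |>
        mutate(
          chrom = .data$anchor_chrom,
          pos = .data$anchor_start +
            floor(runif(n(), 0, .data$anchor_end - .data$anchor_start)),
          sv_type = "planted"
        ) |>
        select("donor_id", "chrom", "pos", "sv_type")
    } else {
      tibble(donor_id = character(), chrom = character(),
             pos = numeric(), sv_type = character())
    }
    n_bg <- cfg$n_breakpoints - nrow(planted_bp)
    if (n_bg < 0) abort("More planted breakpoints than `n_breakpoints`.")
    bg <- if (n_bg > 0) {
      gaps <- sim_background_gaps(cfg, interactome, margin)
      if (nrow(gaps) == 0) {
        abort("No space outside interaction spans for background breakpoints.")
      }
      pick <- sample(nrow(gaps), n_bg, replace = TRUE,
                     prob = gaps$end - gaps$start)
      tibble(
        donor_id = sample(donors, n_bg, replace = TRUE),
        chrom = gaps$chrom[pick],
        pos = gaps$start[pick] +
          floor(runif(n_bg, 0, gaps$end[pick] - gaps$start[pick])),
        sv_type = "background"
      )
    } else {
      tibble(donor_id = character(), chrom = character(),
             pos = numeric(), sv_type = character())
    }
    bind_rows(planted_bp, bg) |>
      mutate(pos = as.integer(.data$pos)) |>
      arrange(.data$donor_id, .data$chrom, .data$pos)
  })
}

# Complement of the interaction spans (with margin) on each toy
# chromosome used by the interactome.
sim_background_gaps <- function(cfg, interactome, margin) {
  if (nrow(interactome) == 0) {
    return(tibble(chrom = "chr1", start = 0, end = cfg$chrom_length))
  }
  spans <- interaction_span(interactome)
  purrr::map_dfr(split(spans, spans$span_chrom), function(s) {
    s <- s[order(s$span_start), ]
    edges_start <- c(0, s$span_end + margin)
    edges_end <- c(s$span_start - margin, cfg$chrom_length)
    tibble(chrom = s$span_chrom[1], start = edges_start, end = edges_end)
  }) |>
    filter(.data$end > .data$start)
}

#' Simulate a negative-binomial count matrix
#'
#' `count(g, d) ~ NB(mean = sf_d * q_g * m_gd, dispersion = alpha)` with
#' `m_gd = effect_multiplier` for planted gene-donor pairs and 1
#' otherwise; donor size factors and per-gene baseline means are drawn
#' log-uniformly from their configured ranges.
#'
#' @param cfg A [sim_config()].
#' @param truth A `hijack_truth`.
#' @return Integer matrix genes x donors; attributes `size_factors` and
#'   `baseline_means` carry the generating values.
#' @export
simulate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "hijack_sim_config"),
            inherits(truth, "hijack_truth"))
  genes <- sim_gene_ids(cfg)
  donors <- sim_donor_ids(cfg)
  withr::with_seed(cfg$seed + 3L, {
    log_unif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))
    sf <- setNames(log_unif(cfg$n_donors, cfg$size_factor_range), donors)
    q <- setNames(log_unif(cfg$n_genes, cfg$baseline_mean_range), genes)
    mult <- matrix(1, cfg$n_genes, cfg$n_donors,
                   dimnames = list(genes, donors))
    if (nrow(truth$planted)) {
      mult[cbind(truth$planted$gene_id, truth$planted$donor_id)] <-
        cfg$effect_multiplier
    }
    mu <- outer(q, sf) * mult
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = cfg$n_genes, dimnames = dimnames(mu)
    )
    storage.mode(counts) <- "integer"
    attr(counts, "size_factors") <- sf
    attr(counts, "baseline_means") <- q
    counts
  })
}

#' Simulate overall survival tied to a designated gene
#'
#' Donors are median-split on the designated gene's normalized
#' expression; survival times are exponential with rate
#' `hazard_rate_base * hazard_ratio^I(high group)`. Censoring is by an
#' independent uniform time on `(0, b)` with `b` calibrated per hazard
#' rate so that the expected censored fraction equals
#' `censoring_fraction_target`.
#'
#' @param cfg A [sim_config()].
#' @param truth A `hijack_truth`.
#' @param norm A `norm_matrix` containing the designated gene.
#' @return Survival tibble (`donor_id`, `time`, `event`, `cohort`) with
#'   attribute `groups` (the per-donor expression group labels).
#' @export
simulate_survival <- function(cfg, truth, norm) {
  stopifnot(inherits(cfg, "hijack_sim_config"),
            inherits(truth, "hijack_truth"),
            inherits(norm, "norm_matrix"))
  gene <- truth$survival_gene
  if (!gene %in% rownames(norm$values)) {
    abort(sprintf("Designated gene %s absent from the matrix.", gene))
  }
  split <- median_split(tibble(donor_id = colnames(norm$values),
                               value = norm$values[gene, ]))
  rate <- cfg$hazard_rate_base *
    cfg$hazard_ratio^(split$group == "high")
  withr::with_seed(cfg$seed + 4L, {
    t_event <- rexp(nrow(split), rate = rate)
    if (cfg$censoring_fraction_target > 0) {
      # P(C < T) = (1 - exp(-rate * b)) / (rate * b) for C ~ U(0, b);
      # solve rate * b once per distinct rate.
      target <- cfg$censoring_fraction_target
      solve_x <- function(target) {
        stats::uniroot(function(x) (1 - exp(-x)) / x - target,
                       interval = c(1e-8, 1e8), tol = 1e-10)$root
      }
      x <- solve_x(target)
      t_cens <- runif(nrow(split), 0, x / rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, nrow(split))
    }
    out <- tibble(donor_id = split$donor_id, time = time, event = event,
                  cohort = "sim")
    attr(out, "groups") <- split |> select("donor_id", "group")
    out
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generators under one seed and returns every pipeline input
#' plus the planted truth and the normalized matrix.
#'
#' @param cfg A [sim_config()].
#' @return List of class `hijack_sim`: `config`, `interactome`, `truth`,
#'   `breakpoints`, `counts`, `norm`, `survival`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7, n_donors = 24, n_genes = 60,
#'                                   n_interactions = 30, n_breakpoints = 60))
#' names(sim)
simulate_cohort <- function(cfg = sim_config()) {
  interactome <- simulate_interactome(cfg)
  truth <- plant_truth(cfg, interactome)
  breakpoints <- simulate_breakpoints(cfg, interactome, truth)
  counts <- simulate_counts(cfg, truth)
  norm <- median_of_ratios(counts)
  survival <- simulate_survival(cfg, truth, norm)
  truth$survival_groups <- attr(survival, "groups")
  structure(
    list(config = cfg, interactome = interactome, truth = truth,
         breakpoints = breakpoints, counts = counts, norm = norm,
         survival = survival),
    class = "hijack_sim"
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits the five pipeline inputs in the package's external dialects
#' (breakpoints, interactions, counts, survival, a planted-gene set) and
#' a truth JSON.
#'
#' @param sim A `hijack_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "hijack_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_breakpoints(sim$breakpoints, file.path(dir, "breakpoints.tsv"))
  write_interactions(sim$interactome, file.path(dir, "interactions.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_survival(sim$survival, file.path(dir, "survival.tsv"))
  readr::write_lines(unique(sim$truth$planted$gene_id),
                     file.path(dir, "planted_genes.txt"))
  jsonlite::write_json(
    list(planted = sim$truth$planted,
         survival_gene = sim$truth$survival_gene),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
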