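# Independent brute-force oracles used across the suite. These stay
# deliberately naive: base-by-base membership for interval overlap,
# sort-and-interpolate for quantiles, direct p*m/rank for BH.

# Base-by-base membership overlap on small coordinates.
overlap_bruteforce <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b) {
  if (chrom_a != chrom_b) return(FALSE)
  length(intersect(seq.int(start_a, end_a - 1L),
                   seq.int(start_b, end_b - 1L))) > 0
}

# Linear interpolation of order statistics at probability p.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Step-up BH by the direct formula with running minimum.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranked <- p[ord] * m / seq(m, 1)
  adj <- cummin(pmin(ranked, 1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hand log-rank: pooled O/E/V table over distinct event times.
logrank_oracle <- function(time, event, is_a) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & is_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & is_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# All-pairs disruption mapping by scalar loops (no joins).
map_disruptions_bruteforce <- function(breakpoints, interactions,
                                       flank_bp, mode) {
  rows <- list()
  for (i in seq_len(nrow(breakpoints))) {
    bp <- breakpoints[i, ]
    s <- max(0, bp$pos - flank_bp)
    e <- bp$pos + flank_bp + 1
    for (j in seq_len(nrow(interactions))) {
      pi <- interactions[j, ]
      if (mode == "span") {
        if (pi$bait_chrom != pi$pir_chrom) next
        rs <- min(pi$bait_start, pi$pir_start)
        re <- max(pi$bait_end, pi$pir_end)
        rc <- pi$bait_chrom
      } else {
        rs <- pi$pir_start
        re <- pi$pir_end
        rc <- pi$pir_chrom
      }
      if (bp$chrom == rc && s < re && rs < e) {
        for (g in pi$gene_ids[[1]]) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            donor_id = bp$donor_id, gene_id = g,
            interaction_id = pi$interaction_id,
            bp_chrom = bp$chrom, bp_pos = bp$pos,
            anchor_chrom = pi$pir_chrom, anchor_start = pi$pir_start,
            anchor_end = pi$pir_end, hit_mode = mode
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- dplyr::arrange(dplyr::distinct(out), donor_id, gene_id,
                          interaction_id, bp_pos)
  }
  out
}

# Random breakpoint/interaction tables on a small coordinate universe.
random_breakpoints <- function(n, max_coord = 10000, chroms = c("chr1", "chr2")) {
  tibble::tibble(
    donor_id = sprintf("D%02d", sample(1:10, n, replace = TRUE)),
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_coord, n, replace = TRUE) - 1L
  )
}

random_interactions <- function(n, max_coord = 10000,
                                chroms = c("chr1", "chr2"),
                                trans_frac = 0) {
  bait_start <- sample.int(max_coord - 200, n, replace = TRUE) - 1L
  pir_start <- sample.int(max_coord - 200, n, replace = TRUE) - 1L
  bait_chrom <- sample(chroms, n, replace = TRUE)
  pir_chrom <- bait_chrom
  if (trans_frac > 0) {
    flip <- runif(n) < trans_frac
    pir_chrom[flip] <- sample(chroms, sum(flip), replace = TRUE)
  }
  tibble::tibble(
    interaction_id = sprintf("int%04d", seq_len(n)),
    bait_chrom = bait_chrom,
    bait_start = bait_start,
    bait_end = bait_start + sample(10:200, n, replace = TRUE),
    pir_chrom = pir_chrom,
    pir_start = pir_start,
    pir_end = pir_start + sample(10:200, n, replace = TRUE),
    gene_ids = purrr::map(seq_len(n), ~ sprintf("G%03d", sample(1:60, sample(1:2, 1)))),
    score = runif(n, 0, 10)
  )
}
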