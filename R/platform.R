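#' Window/filler allocation of a reduced-representation platform
#'
#' A platform of `target_size` SNPs takes one SNP per eligible genomic
#' window and tops up with filler SNPs: `n_filler = target_size -
#' n_eligible_windows`.
#'
#' @param n_eligible_windows number of windows harboring at least one
#'   panel-eligible segregating site.
#' @param target_size total platform size.
#' @return List with `n_window` and `n_filler`.
#' @export
platform_allocation <- function(n_eligible_windows, target_size) {
  if (target_size < n_eligible_windows)
    stopf("target_size (%d) below the number of eligible windows (%d)",
          target_size, n_eligible_windows)
  list(n_window = as.integer(n_eligible_windows),
       n_filler = as.integer(target_size - n_eligible_windows))
}

#' Design an in silico reduced-representation SNP platform
#'
#' Emulates array design from a small, deeply sequenced discovery panel:
#' MAF is computed on the panel accessions only, SNPs with panel MAF
#' strictly greater than `panel_maf_min` are eligible, one eligible SNP is
#' drawn uniformly from each `window_bp` window that contains any, and
#' filler SNPs are drawn uniformly without replacement from the remaining
#' eligible SNPs until `target_size` is reached. If eligible SNPs run out
#' the platform is truncated with a warning.
#'
#' @param G a [genotype_matrix()] (full panel).
#' @param panel_ids accession ids of the discovery panel.
#' @param window_bp window length (default 1000 bp).
#' @param panel_maf_min panel MAF threshold, strict (default 0.10).
#' @param target_size total platform size; `NULL` scales the canonical
#'   250,000-for-224,339-windows design down to the simulated genome
#'   (fillers = ~11.4\% of eligible windows).
#' @param seed integer seed.
#' @return A list of class `platform_design`: `panel_accessions`,
#'   `window_bp`, `panel_maf_min`, `target_size`, `window_snp_ids`,
#'   `filler_snp_ids`, `snp_ids` (union), `n_eligible_windows`, `seed`.
#' @export
design_platform <- function(G, panel_ids, window_bp = 1000,
                            panel_maf_min = 0.10, target_size = NULL,
                            seed) {
  absent <- setdiff(panel_ids, G$accession_ids)
  if (length(absent))
    stopf("panel accession(s) not in genotypes: %s",
          paste(utils::head(absent, 3), collapse = ", "))
  P <- G$calls[panel_ids, , drop = FALSE]
  called <- colSums(!is.na(P))
  f_alt <- ifelse(called > 0, colSums(P, na.rm = TRUE) / called, NA_real_)
  panel_maf <- pmin(f_alt, 1 - f_alt)
  eligible <- which(!is.na(panel_maf) & panel_maf > panel_maf_min)

  win <- paste(G$variants$chrom, (G$variants$pos - 1L) %/% window_bp)
  ewin <- split(eligible, win[eligible])
  if (is.null(target_size))
    target_size <- length(ewin) + round(25661 / 224339 * length(ewin))
  alloc <- platform_allocation(length(ewin), target_size)

  with_seed(seed, {
    window_idx <- vapply(ewin, function(ix)
      if (length(ix) == 1) ix else sample(ix, 1), integer(1))
    window_idx <- sort(unname(window_idx))
    rest <- setdiff(eligible, window_idx)
    n_fill <- alloc$n_filler
    if (n_fill > length(rest)) {
      warning(sprintf(
        "only %d eligible SNPs remain for %d filler slots; platform truncated",
        length(rest), n_fill))
      n_fill <- length(rest)
    }
    filler_idx <- if (n_fill > 0) sort(sample(rest, n_fill)) else integer(0)
    out <- list(panel_accessions = panel_ids, window_bp = window_bp,
                panel_maf_min = panel_maf_min, target_size = target_size,
                window_snp_ids = G$variants$id[window_idx],
                filler_snp_ids = G$variants$id[filler_idx],
                snp_ids = G$variants$id[sort(c(window_idx, filler_idx))],
                n_eligible_windows = length(ewin), seed = seed)
    class(out) <- "platform_design"
    out
  })
}

#' Association scan restricted to the SNPs of an in silico platform
#'
#' Applies exactly the model and filters of the sequence-based analysis
#' (full-sample MAF and call-count thresholds, same variance components)
#' to the platform subset; p-values of SNPs shared with the full scan are
#' bit-identical, since the expedited scan tests each variant
#' independently.
#'
#' @param y phenotype (as in [gwas_scan()]).
#' @param G the full, unfiltered-or-filtered [genotype_matrix()].
#' @param vc `variance_components` from the full-data null fit.
#' @param design a [design_platform()] result.
#' @param min_maf,min_called the association filters (defaults 0.02, 100).
#' @return A `scan_result` restricted to platform SNPs passing the
#'   filters.
#' @export
scan_platform <- function(y, G, vc, design, min_maf = 0.02,
                          min_called = 100) {
  Gp <- subset_variants(G, design$snp_ids)
  keep <- !is.na(Gp$variants$maf) & Gp$variants$maf >= min_maf &
    Gp$variants$n_called >= min_called
  Gp$calls <- Gp$calls[, keep, drop = FALSE]
  Gp$variants <- Gp$variants[keep, , drop = FALSE]
  if (nrow(Gp$variants) == 0)
    stopf("no platform SNPs pass the association filters")
  gwas_scan(y, Gp, vc)
}

#' Overlap between platform candidates and sequence-based candidates
#'
#' For each platform replicate and each `top_n`, counts the top-`top_n`
#' platform candidates lying within each distance of the nearest top-200
#' sequence-based candidate on the same chromosome (boundaries
#' inclusive), then aggregates min/mean/max over replicates. Counts are
#' monotone in both `top_n` and distance.
#'
#' @param platform_scans list of `scan_result`s, one per platform.
#' @param sequence_candidates a `candidate_set` (k = 200) from the full
#'   sequence scan.
#' @param tops candidate-list sizes (default 20 and 50).
#' @param distances distance thresholds in bp (default 1,000 and 20,000).
#' @return A data frame of class `overlap_report`: `top_n`,
#'   `distance_bp`, `min`, `mean`, `max` over replicates.
#' @export
overlap_report <- function(platform_scans, sequence_candidates,
                           tops = c(20, 50), distances = c(1000, 20000)) {
  counts <- array(
    0L, c(length(platform_scans), length(tops), length(distances)))
  for (r in seq_along(platform_scans)) {
    S <- platform_scans[[r]]
    big <- select_candidates(S, max(tops))
    d_near <- nearest_candidate_distance(big, sequence_candidates)
    for (ti in seq_along(tops)) {
      dt <- d_near[seq_len(min(tops[ti], length(d_near)))]
      for (di in seq_along(distances))
        counts[r, ti, di] <- sum(dt <= distances[di])
    }
  }
  grid <- expand.grid(top_n = tops, distance_bp = distances)
  out <- cbind(grid, t(apply(grid, 1, function(g) {
    v <- counts[, match(g[["top_n"]], tops),
                match(g[["distance_bp"]], distances)]
    c(min = min(v), mean = mean(v), max = max(v))
  })))
  class(out) <- c("overlap_report", "data.frame")
  out
}

# For each row of `from` (ordered candidates), distance to the nearest
# row of `to` on the same chromosome (Inf when none).
nearest_candidate_distance <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i) {
    pos <- to$pos[to$chrom == from$chrom[i]]
    if (!length(pos)) Inf else min(abs(pos - from$pos[i]))
  }, numeric(1))
}

#' MAF ascertainment-bias report
#'
#' Histograms over the 2-5\%, 5-10\% and >10\% MAF bins for: all assayed
#' SNPs, the sequence-based candidates, the platform candidates, and the
#' sequence-based candidates "tagged" by the platform (within
#' `tag_distance` of at least one platform candidate). Ascertainment from
#' a small discovery panel with a frequency threshold depletes the tagged
#' set of rare variants relative to the full candidate set.
#'
#' @param all_maf MAF vector of all assayed SNPs (or a variant table /
#'   `scan_result` with a `maf` column).
#' @param seq_candidates sequence-based `candidate_set`.
#' @param platform_candidates platform `candidate_set` (e.g. top 50 of one
#'   platform, or several platforms' candidates pooled).
#' @param tag_distance tagging distance in bp (default 1000, inclusive).
#' @return A list of class `maf_bias_report`: `bins` (4 x 3 count
#'   matrix), `fractions` (rows renormalized), `tagged_ids`,
#'   `frac_below_10` (per population, fraction of SNPs with MAF < 0.10).
#' @export
maf_bias_report <- function(all_maf, seq_candidates, platform_candidates,
                            tag_distance = 1000) {
  if (is.data.frame(all_maf)) all_maf <- all_maf$maf
  d_near <- nearest_candidate_distance(seq_candidates, platform_candidates)
  tagged <- seq_candidates[d_near <= tag_distance, , drop = FALSE]
  pops <- list(all_snps = all_maf,
               seq_candidates = seq_candidates$maf,
               platform_candidates = platform_candidates$maf,
               tagged_seq_candidates = tagged$maf)
  bins <- t(vapply(pops, function(m)
    if (length(m)) maf_bins(m) else
      stats::setNames(integer(3), c("2-5%", "5-10%", ">10%")),
    integer(3)))
  fr <- bins / pmax(rowSums(bins), 1)
  out <- list(bins = bins, fractions = fr,
              tagged_ids = tagged$id,
              frac_below_10 = vapply(pops, function(m)
                if (length(m)) mean(m < 0.10) else NA_real_, numeric(1)))
  class(out) <- "maf_bias_report"
  out
}
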