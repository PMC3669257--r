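#' Block-adjusted least-squares means per accession
#'
#' Fits the additive fixed-effects model `value = accession + block` by
#' least squares (no interaction: a randomized complete block design has
#' one replicate per accession and block, making an interaction
#' inestimable) and returns the least-squares mean of each accession, i.e.
#' its prediction averaged over all blocks. Block effects carry a
#' sum-to-zero constraint, so with balanced data and no block differences
#' the adjusted mean equals the arithmetic mean. Unbalanced data are
#' handled by the normal equations of the full design.
#'
#' @param P a phenotype table: data frame with columns `accession`,
#'   `block`, `trait`, `value` (`NA` = not observed).
#' @param trait trait name to extract.
#' @return A data frame of class `accession_means` with columns
#'   `accession`, `adjusted_mean` (`NA` for accessions with no observed
#'   replicates) and `n_replicates`.
#' @export
block_adjusted_means <- function(P, trait) {
  d <- phenotype_subset(P, trait)
  obs <- d[!is.na(d$value), , drop = FALSE]
  if (length(unique(obs$block)) < 2)
    stopf("need observations in >= 2 blocks to adjust for block effects")
  obs$accession <- factor(obs$accession)
  obs$block <- factor(obs$block)
  fit <- stats::lm(value ~ 0 + accession + block, data = obs,
                   contrasts = list(block = "contr.sum"))
  co <- stats::coef(fit)
  acc_levels <- levels(obs$accession)
  means <- co[paste0("accession", acc_levels)]
  all_acc <- unique(d$accession)
  out <- data.frame(
    accession = all_acc,
    adjusted_mean = unname(means[match(all_acc, acc_levels)]),
    n_replicates = as.integer(table(factor(obs$accession,
                                           levels = all_acc))[all_acc]),
    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  class(out) <- c("accession_means", "data.frame")
  out
}

phenotype_subset <- function(P, trait) {
  need <- c("accession", "block", "trait", "value")
  if (!all(need %in% names(P)))
    stopf("phenotype table needs columns: %s", paste(need, collapse = ", "))
  d <- P[P$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stopf("trait '%s' not present in the phenotype table",
                          trait)
  if (anyDuplicated(d[, c("accession", "block")]))
    stopf("more than one record per (accession, block) for trait '%s'", trait)
  d
}

#' Encode flowering date as a 10-level continuous score
#'
#' Observed scoring dates (at most 9 distinct values) map to ranks 1..9 in
#' chronological order; plants that never flowered map to a 10th category.
#' The result is treated as a continuous variable downstream, with no
#' further transformation.
#'
#' @param dates per-replicate flowering dates: any orderable vector
#'   (numeric, `Date`, or comparable strings); `NA` means the plant never
#'   flowered.
#' @return Numeric vector of scores in 1..10. If every flowering plant
#'   shared a single date the output is degenerate (constant 1 for
#'   flowering plants) and carries the attribute `degenerate = TRUE`.
#' @export
encode_flowering <- function(dates) {
  lev <- sort(unique(dates[!is.na(dates)]))
  if (length(lev) > 9)
    stopf("%d distinct flowering dates observed; the scoring scheme allows at most 9",
          length(lev))
  score <- match(dates, lev)
  score[is.na(dates)] <- 10
  score <- as.numeric(score)
  if (length(lev) == 1 && any(!is.na(dates)))
    attr(score, "degenerate") <- TRUE
  score
}

#' Partition trait variance into among- and within-accession components
#'
#' Block effects are removed first (same sum-to-zero additive fit as
#' [block_adjusted_means()]); a one-way random-effects analysis on the
#' block-adjusted values then yields method-of-moments variance
#' components: `sigma2_within = MS_within` and
#' `sigma2_among = max(0, (MS_among - MS_within) / n0)` with `n0` the
#' standard unbalanced-design replicate coefficient
#' \eqn{n_0 = (N - \sum n_i^2 / N)/(a - 1)}. The among-accession
#' proportion is invariant to affine transforms of the trait and never
#' negative.
#'
#' @inheritParams block_adjusted_means
#' @return A list of class `variance_partition` with `sigma2_among`,
#'   `sigma2_within` and `proportion_among`.
#' @export
variance_partition <- function(P, trait) {
  d <- phenotype_subset(P, trait)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (length(unique(d$block)) < 2)
    stopf("need observations in >= 2 blocks")
  d$accession <- factor(d$accession)
  d$block <- factor(d$block)
  n_i <- table(d$accession)
  if (sum(n_i >= 2) < 2)
    stopf("need >= 2 accessions with >= 2 replicates to partition variance")

  fit <- stats::lm(value ~ 0 + accession + block, data = d,
                   contrasts = list(block = "contr.sum"))
  co <- stats::coef(fit)
  p <- nlevels(d$block)
  block_eff <- numeric(p)
  if (p > 1) {
    be <- co[paste0("block", seq_len(p - 1))]
    be[is.na(be)] <- 0
    block_eff <- c(be, -sum(be))
  }
  y_adj <- d$value - block_eff[as.integer(d$block)]

  N <- length(y_adj)
  a <- nlevels(d$accession)
  grand <- mean(y_adj)
  gm <- tapply(y_adj, d$accession, mean)
  ss_among <- sum(n_i * (gm - grand)^2)
  ss_within <- sum((y_adj - gm[as.integer(d$accession)])^2)
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  sigma2_among <- max(0, (ms_among - ms_within) / n0)
  out <- list(sigma2_among = sigma2_among,
              sigma2_within = ms_within,
              proportion_among = sigma2_among / (sigma2_among + ms_within))
  class(out) <- "variance_partition"
  out
}

#' Pairwise correlations between trait accession means
#'
#' A descriptive utility: Pearson correlations over pairwise-complete
#' accessions for a set of traits.
#'
#' @param means_list named list of [block_adjusted_means()] results (one
#'   per trait).
#' @return Correlation matrix (traits x traits).
#' @export
trait_correlations <- function(means_list) {
  acc <- sort(unique(unlist(lapply(means_list, `[[`, "accession"))))
  M <- sapply(means_list, function(m)
    m$adjusted_mean[match(acc, m$accession)])
  stats::cor(M, use = "pairwise.complete.obs")
}
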