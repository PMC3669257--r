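#' Build the candidate multiple-regression design
#'
#' Each candidate SNP enters the regression as a three-level categorical
#' predictor \{0, 1, missing\}: missing genotype calls are treated as an
#' additional state rather than imputed. The reference level is 0 when
#' present; a candidate with `s` observed states contributes `s - 1`
#' indicator columns. Zero-variance candidates are dropped and recorded.
#' Columns made redundant by perfect collinearity (e.g. two candidates in
#' complete LD) are detected by a pivoted QR of the full design and
#' dropped, with a record. When the full design would not be estimable
#' (columns + intercept approaching the number of observations),
#' candidates are pre-pruned from the bottom of the p-value ranking until
#' it is, and the pruning is recorded.
#'
#' @param y phenotype: `accession_means` or named numeric vector.
#' @param G a [genotype_matrix()].
#' @param C a `candidate_set` (ordered by ascending p), typically k = 50.
#' @return A list of class `candidate_design`: `y`, `X` (indicator
#'   matrix, no intercept), `groups` (candidate id -> column indices),
#'   `accessions`, `dropped_zero_variance`, `dropped_collinear`,
#'   `pruned_for_df`.
#' @export
candidate_design <- function(y, G, C) {
  if (inherits(y, "accession_means"))
    y <- stats::setNames(y$adjusted_mean, y$accession)
  acc <- intersect(G$accession_ids, names(y)[is.finite(y[names(y)])])
  if (length(acc) < 3) stopf("too few phenotyped accessions")
  y <- y[acc]
  absent <- setdiff(C$id, G$variants$id)
  if (length(absent))
    stopf("candidate(s) not in genotype matrix: %s",
          paste(utils::head(absent, 3), collapse = ", "))

  ids <- C$id
  n <- length(acc)
  # prune lowest-ranked candidates until the full model is estimable
  pruned <- character(0)
  max_cols <- n - 3          # intercept + residual df >= 2
  while (length(ids) * 2 > max_cols && length(ids) > 1) {
    pruned <- c(ids[length(ids)], pruned)
    ids <- ids[-length(ids)]
  }

  cols <- list(); groups <- list(); zero_var <- character(0)
  for (id in ids) {
    x <- G$calls[acc, match(id, G$variants$id)]
    state <- ifelse(is.na(x), "miss", as.character(x))
    lev <- intersect(c("0", "1", "miss"), unique(state))
    if (length(lev) < 2) { zero_var <- c(zero_var, id); next }
    ref <- lev[1]
    idx <- integer(0)
    for (l in setdiff(lev, ref)) {
      cols[[length(cols) + 1]] <- as.numeric(state == l)
      names(cols)[length(cols)] <- paste0(id, ":", l)
      idx <- c(idx, length(cols))
    }
    groups[[id]] <- idx
  }
  if (!length(groups)) stopf("no usable candidate predictors")
  X <- do.call(cbind, cols)
  rownames(X) <- acc

  # pivoted QR on [1, X]: drop aliased columns, whole candidates may go
  qrf <- qr(cbind(`(Intercept)` = 1, X))
  keep_cols <- sort(qrf$pivot[seq_len(qrf$rank)])
  aliased <- setdiff(seq_len(ncol(X) + 1), keep_cols) - 1L  # X indexing
  collinear <- character(0)
  if (length(aliased)) {
    collinear <- unique(sub(":(0|1|miss)$", "", colnames(X)[aliased]))
    keep <- setdiff(seq_len(ncol(X)), aliased)
    remap <- match(seq_len(ncol(X)), keep)
    X <- X[, keep, drop = FALSE]
    groups <- lapply(groups, function(ix) remap[ix][!is.na(remap[ix])])
    groups <- groups[lengths(groups) > 0]
  }
  out <- list(y = y, X = X, groups = groups, accessions = acc,
              dropped_zero_variance = zero_var,
              dropped_collinear = collinear,
              pruned_for_df = pruned)
  class(out) <- "candidate_design"
  out
}

# RSS of y on [1, X[, cols]]; cols may be empty (intercept-only model).
fit_rss <- function(y, X, cols) {
  M <- cbind(1, X[, cols, drop = FALSE])
  f <- stats::lm.fit(M, y)
  sum(f$residuals^2)
}

#' Backwards stepwise-AIC simplification of the candidate regression
#'
#' Starts from the full model containing every candidate (all of its
#' indicator columns together) and repeatedly removes the candidate whose
#' removal lowers AIC the most, stopping when no removal lowers AIC —
#' dropping SNPs whose contribution does not justify their parameters.
#' Removal granularity is the whole candidate, never an individual dummy
#' column. AIC uses the Gaussian profile log-likelihood
#' (\eqn{n\log(RSS/n) + 2\,\mathrm{edf}}, the `stepAIC` convention).
#'
#' @param design a [candidate_design()].
#' @return A list of class `regression_report`: `retained_variants`,
#'   `r2` (of the final model), `aic`, `n_candidates_in`, `n_retained`,
#'   plus the design's drop records.
#' @export
stepwise_regression <- function(design) {
  stopifnot(inherits(design, "candidate_design"))
  y <- design$y; X <- design$X; groups <- design$groups
  n <- length(y)
  aic_of <- function(cols) {
    rss <- fit_rss(y, X, cols)
    n * log(max(rss, 1e-300) / n) + 2 * (length(cols) + 1)
  }
  current <- names(groups)
  cur_cols <- sort(unlist(groups[current], use.names = FALSE))
  cur_aic <- aic_of(cur_cols)
  repeat {
    if (!length(current)) break
    trial <- vapply(current, function(g) {
      aic_of(sort(unlist(groups[setdiff(current, g)], use.names = FALSE)))
    }, numeric(1))
    best <- which.min(trial)
    if (trial[best] < cur_aic - 1e-8) {
      current <- setdiff(current, current[best])
      cur_cols <- sort(unlist(groups[current], use.names = FALSE))
      cur_aic <- unname(trial[best])
    } else break
  }
  rss <- fit_rss(y, X, cur_cols)
  tss <- sum((y - mean(y))^2)
  out <- list(retained_variants = current,
              r2 = 1 - rss / tss,
              aic = cur_aic,
              n_candidates_in = length(design$groups),
              n_retained = length(current),
              dropped_zero_variance = design$dropped_zero_variance,
              dropped_collinear = design$dropped_collinear,
              pruned_for_df = design$pruned_for_df)
  class(out) <- "regression_report"
  out
}

#' Phenotype-randomization null distribution for candidate regression
#'
#' Approximates the winner's-curse (Beavis effect) null: for each of `R`
#' replicates the accession labels of the phenotype are permuted (after
#' block adjustment; genotype data stay intact), the full mixed-model scan
#' is rerun, the top-`k` candidates are fed through
#' [stepwise_regression()], and the resulting r-squared, candidate
#' MAF-bin counts, and MAF-effect correlations (top 50 and top 200) are
#' recorded. These are approximate null expectations: the kinship term
#' makes the data non-exchangeable, so the permutation null is not exact.
#'
#' @param y phenotype (`accession_means` or named vector of block-adjusted
#'   means).
#' @param G a filtered [genotype_matrix()].
#' @param K kinship matrix.
#' @param R number of randomizations (default 20).
#' @param k candidate-list size for the regression (default 50).
#' @param seed integer seed; replicate `i` uses a seed derived from it.
#' @return A list of class `null_distribution`: `n_randomizations`,
#'   `r2_values`, `mean_r2`, `sd_r2`, `maf_bin_counts` (R x 3, top-k
#'   candidates), `cor_top50`, `cor_top200`.
#' @export
randomization_null <- function(y, G, K, R = 20, k = 50, seed = 1) {
  if (inherits(y, "accession_means"))
    y <- stats::setNames(y$adjusted_mean, y$accession)
  y0 <- align_phenotype(y, K)
  decomp <- reml_decompose(K, names(y0))
  r2 <- numeric(R)
  bins <- matrix(0L, R, 3, dimnames = list(NULL, c("2-5%", "5-10%", ">10%")))
  cor50 <- numeric(R); cor200 <- numeric(R)
  for (i in seq_len(R)) {
    yp <- with_seed(derive_seed(seed, paste0("randomization", i)),
                    stats::setNames(sample(y0), names(y0)))
    vc <- fit_null_reml(yp, K, decomp = decomp)
    S <- gwas_scan(yp, G, vc)
    Ck <- select_candidates(S, k)
    r2[i] <- stepwise_regression(candidate_design(yp, G, Ck))$r2
    bins[i, ] <- maf_bins(Ck)
    cor50[i] <- maf_effect_correlation(select_candidates(S, 50))$r
    cor200[i] <- maf_effect_correlation(select_candidates(S, 200))$r
  }
  out <- list(n_randomizations = R, r2_values = r2,
              mean_r2 = mean(r2), sd_r2 = stats::sd(r2),
              maf_bin_counts = bins, cor_top50 = cor50, cor_top200 = cor200)
  class(out) <- "null_distribution"
  out
}

#' Winner's-curse-adjusted proportion of variance explained
#'
#' Assuming the phenotypic variance that true causal SNPs could explain is
#' uniformly distributed between the randomized-data mean r-squared and
#' one, the adjusted proportion is
#' \deqn{(r^2_{emp} - \bar r^2_{null}) / (1 - \bar r^2_{null}).}
#' The value may be negative when the empirical r-squared falls below the
#' null mean.
#'
#' @param empirical_r2 r-squared of the candidate regression on observed
#'   phenotypes.
#' @param null_mean_r2 mean r-squared over the randomization replicates
#'   (must be < 1).
#' @return A list of class `adjusted_r2_report`: `empirical_r2`,
#'   `null_mean_r2`, `adjusted`.
#' @export
adjusted_r2 <- function(empirical_r2, null_mean_r2) {
  if (!is.finite(null_mean_r2) || null_mean_r2 >= 1)
    stopf("null_mean_r2 must be < 1")
  out <- list(empirical_r2 = empirical_r2, null_mean_r2 = null_mean_r2,
              adjusted = (empirical_r2 - null_mean_r2) / (1 - null_mean_r2))
  class(out) <- "adjusted_r2_report"
  out
}
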