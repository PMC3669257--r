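#' Estimate an allele-sharing (IBS) kinship matrix
#'
#' Relatedness between two accessions is the proportion of sampled SNPs at
#' which they carry the same allele, computed over pairwise-complete
#' (both-called) genotypes. Up to `snps_per_chrom` SNPs are sampled
#' without replacement from each chromosome (capped at the number
#' available). The estimator is bounded in \[0, 1\] with diagonal 1 and is
#' used as the covariance structure of the polygenic random effect in the
#' mixed model; it is deliberately simple and swappable. Because
#' pairwise-complete denominators can make the raw estimate slightly
#' indefinite, negative eigenvalues are clipped and the unit diagonal
#' restored ("bending") whenever needed, so the result is always positive
#' semidefinite; with no missing data the raw estimate is returned
#' unchanged.
#'
#' @param G a [genotype_matrix()].
#' @param snps_per_chrom SNPs sampled per chromosome (default 5000).
#' @param seed integer seed for the SNP sampling.
#' @return Symmetric numeric matrix with accession ids as dimnames and
#'   attributes `n_snps_used` and `seed`.
#' @export
estimate_kinship <- function(G, snps_per_chrom = 5000, seed = 1) {
  if (nrow(G$variants) == 0) stopf("genotype matrix has no variants")
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(G$variants)), G$variants$chrom),
                  function(ix) {
                    if (length(ix) <= snps_per_chrom) ix
                    else sort(sample(ix, snps_per_chrom))
                  }), use.names = FALSE)
  })
  X <- G$calls[, idx, drop = FALSE]
  A <- (!is.na(X) & X == 1) * 1
  B <- (!is.na(X) & X == 0) * 1
  called <- A + B
  matches <- tcrossprod(A) + tcrossprod(B)
  denom <- tcrossprod(called)
  if (any(denom == 0))
    stopf("some accession pairs share no called SNPs; cannot estimate kinship")
  K <- matches / denom
  # pairwise-complete denominators can leave the estimate slightly
  # indefinite; bend by clipping negative eigenvalues, then restore the
  # exact unit diagonal by congruence (preserves positive semidefiniteness)
  K <- 0.5 * (K + t(K))
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- 1 / sqrt(diag(K))
    K <- K * tcrossprod(d)
  }
  dimnames(K) <- list(G$accession_ids, G$accession_ids)
  attr(K, "n_snps_used") <- length(idx)
  attr(K, "seed") <- seed
  K
}

#' Variance explained by leading principal components of a kinship matrix
#'
#' Descriptive utility: the proportion of total kinship variance captured
#' by each of the first `n_pc` eigenvectors.
#'
#' @param K kinship matrix.
#' @param n_pc number of leading components.
#' @return Numeric vector of per-component variance proportions.
#' @export
kinship_pc_variance <- function(K, n_pc = 10) {
  ev <- eigen(0.5 * (K + t(K)), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  (ev / sum(ev))[seq_len(min(n_pc, length(ev)))]
}

# Align a phenotype vector with genotype/kinship accessions: returns the
# named numeric vector restricted to accessions present everywhere with a
# finite value, in kinship order.
align_phenotype <- function(y, K, accession_ids = rownames(K)) {
  if (inherits(y, "accession_means")) {
    y <- stats::setNames(y$adjusted_mean, y$accession)
  }
  if (is.null(names(y))) stopf("phenotype vector must be named by accession")
  keep <- intersect(accession_ids, names(y)[is.finite(y[names(y)])])
  if (length(keep) < 10)
    stopf("only %d accessions shared between phenotype and kinship; need >= 10",
          length(keep))
  y[keep]
}

# Eigen-decompositions reused across REML fits and scans for a fixed K and
# accession set: eigen(K) for the GLS rotation and eigen(SKS) for the
# restricted likelihood (S projects out the intercept).
reml_decompose <- function(K, accession_ids) {
  K <- K[accession_ids, accession_ids, drop = FALSE]
  K <- 0.5 * (K + t(K))
  n <- nrow(K)
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values), 1))
    stopf("kinship matrix is not positive semidefinite (min eigenvalue %g)",
          min(eK$values))
  J <- matrix(1 / n, n, n)
  M <- K - J %*% K - K %*% J + J %*% K %*% J
  eM <- eigen(0.5 * (M + t(M)), symmetric = TRUE)
  list(accession_ids = accession_ids, n = n,
       U = eK$vectors, lambda = pmax(eK$values, 0),
       Us = eM$vectors[, seq_len(n - 1), drop = FALSE],
       xi = pmax(eM$values[seq_len(n - 1)], 0))
}

#' Restricted maximum likelihood fit of the null polygenic model
#'
#' Fits \eqn{y = \mu + g + e} with \eqn{g \sim N(0, \sigma^2_g K)} and
#' \eqn{e \sim N(0, \sigma^2_e I)} by REML: the kinship matrix is
#' spectrally decomposed once and the restricted likelihood is maximized
#' over the single variance ratio \eqn{\delta = \sigma^2_e/\sigma^2_g} by
#' a bounded one-dimensional search on \eqn{\log\delta \in [-10, 10]}
#' (convergence tolerance 1e-8). The fitted components are then held fixed
#' for every variant in [gwas_scan()] (the P3D/EMMAX expedient).
#'
#' With `K = I` the model collapses to i.i.d. errors and
#' \eqn{\sigma^2_g, \sigma^2_e} are not separately identifiable; only
#' their total is meaningful (and the scan reduces to ordinary least
#' squares regardless of `delta`).
#'
#' @param y accession phenotype: an `accession_means` object or a named
#'   numeric vector of block-adjusted means.
#' @param K kinship matrix from [estimate_kinship()].
#' @param decomp optional precomputed [reml_decompose()] result (reused
#'   across permutation replicates).
#' @return A list of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `delta`, `log_restricted_likelihood`, plus the accession alignment
#'   and spectral decomposition reused by [gwas_scan()].
#' @export
fit_null_reml <- function(y, K, decomp = NULL) {
  y <- align_phenotype(y, K)
  if (is.null(decomp)) decomp <- reml_decompose(K, names(y))
  if (!identical(decomp$accession_ids, names(y)))
    stopf("decomposition accessions do not match the phenotype")
  n <- decomp$n
  eta2 <- as.numeric(crossprod(decomp$Us, y))^2
  xi <- decomp$xi
  nq <- n - 1
  rll <- function(log_delta) {
    delta <- exp(log_delta)
    denom <- xi + delta
    R <- sum(eta2 / denom)
    0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(R) - sum(log(denom)))
  }
  opt <- stats::optimize(rll, interval = c(-10, 10), maximum = TRUE,
                         tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma2_g <- sum(eta2 / (xi + delta)) / nq
  vc <- list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g,
             delta = delta, log_restricted_likelihood = opt$objective,
             accession_ids = decomp$accession_ids, decomp = decomp,
             y = y)
  class(vc) <- "variance_components"
  vc
}

#' Expedited mixed-model association scan (P3D/EMMAX)
#'
#' Tests every variant for association with the phenotype by generalized
#' least squares of \eqn{y} on \eqn{[1, x]} under
#' \eqn{V = \sigma^2_g K + \sigma^2_e I}, with the variance components
#' taken from the null fit and reused for every variant ("population
#' parameters previously determined"). The kinship eigen-rotation turns
#' each test into a two-parameter weighted regression, so the scan is a
#' single pass of vectorized algebra. Missing genotypes are mean-imputed
#' to the variant's allele frequency for the test only (`n_used` reports
#' the non-missing count); variants monomorphic after imputation get
#' `NA` statistics and are excluded from candidate selection. Two-sided
#' p-values come from the t statistic `beta/se` on `n - 2` degrees of
#' freedom.
#'
#' @param y phenotype (as in [fit_null_reml()]); must cover the same
#'   accessions the variance components were fitted on.
#' @param G a filtered [genotype_matrix()].
#' @param vc a `variance_components` object from [fit_null_reml()].
#' @return A data frame of class `scan_result` with one row per variant:
#'   `id`, `chrom`, `pos`, `maf`, `n_used`, `beta`, `se`, `p`, in input
#'   variant order.
#' @export
gwas_scan <- function(y, G, vc) {
  stopifnot(inherits(vc, "variance_components"))
  y <- align_phenotype(y, diag(1, 1), accession_ids = vc$accession_ids)
  if (!identical(names(y), vc$accession_ids))
    stopf("phenotype does not cover the accessions of the null fit")
  acc <- vc$accession_ids
  missing_acc <- setdiff(acc, G$accession_ids)
  if (length(missing_acc))
    stopf("accessions absent from genotypes: %s",
          paste(utils::head(missing_acc, 3), collapse = ", "))
  X <- G$calls[acc, , drop = FALSE]
  n <- length(acc)
  n_used <- colSums(!is.na(X))

  # mean imputation per variant (scan only)
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  na_idx <- which(is.na(X))
  if (length(na_idx))
    X[na_idx] <- cm[((na_idx - 1) %/% n) + 1]

  # Work with the precision matrix M = V^{-1} (up to scale) built from the
  # eigendecomposition. Every per-variant quantity is computed from the
  # fixed M, a and My vectors with one fixed-shape matrix-vector product
  # per variant, so scanning any subset of variants reproduces the full
  # scan bit for bit (the platform-subset consistency contract).
  U <- vc$decomp$U
  w <- 1 / (vc$decomp$lambda + vc$delta)
  M <- U %*% (w * t(U))
  a <- as.numeric(M %*% rep(1, n))
  My <- as.numeric(M %*% y)
  S_aa <- sum(a)
  S_ay <- sum(My)
  S_yy <- sum(y * My)
  m_var <- ncol(X)
  S_ab <- numeric(m_var); S_by <- numeric(m_var); S_bb <- numeric(m_var)
  for (j in seq_len(m_var)) {
    x <- X[, j]
    S_ab[j] <- sum(a * x)
    S_by[j] <- sum(My * x)
    S_bb[j] <- sum(x * as.numeric(M %*% x))
  }

  det <- S_aa * S_bb - S_ab^2
  degenerate <- !(det > 1e-10 * pmax(S_aa * S_bb, 1e-300))
  det[degenerate] <- NA_real_
  beta <- (S_aa * S_by - S_ab * S_ay) / det
  mu <- (S_bb * S_ay - S_ab * S_by) / det
  rss <- pmax(S_yy - mu * S_ay - beta * S_by, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * S_aa / det)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  out <- data.frame(id = G$variants$id, chrom = G$variants$chrom,
                    pos = G$variants$pos, maf = G$variants$maf,
                    n_used = as.integer(n_used),
                    beta = beta, se = se, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "n_accessions") <- n
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Quantile-quantile data and the genomic inflation factor
#'
#' Sorted observed \eqn{-\log_{10} p} against uniform expectation
#' \eqn{i/(m+1)}, plus the genomic control inflation factor
#' \eqn{\lambda_{GC}}: the median association chi-square divided by the
#' null median \eqn{\chi^2_1} quantile. \eqn{\lambda_{GC} \approx 1}
#' indicates that the kinship covariate has removed the bulk of
#' population-structure confounding.
#'
#' @param S a `scan_result`.
#' @return A list with `qq` (data frame: `expected`, `observed`, both in
#'   \eqn{-\log_{10}} units, ascending p order) and `lambda_gc`.
#' @export
qq_data <- function(S) {
  p <- S$p[!is.na(S$p)]
  m <- length(p)
  if (m < 100)
    stopf("q-q diagnostics need >= 100 tested variants (got %d)", m)
  ps <- sort(p)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(qq = data.frame(expected = -log10(seq_len(m) / (m + 1)),
                       observed = -log10(ps)),
       lambda_gc = stats::median(chisq) / stats::qchisq(0.5, df = 1))
}

#' Bonferroni adjustment of a p-value
#'
#' @param p raw p-value(s) in (0, 1\].
#' @param m number of tests (>= 1).
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  if (!is.numeric(m) || length(m) != 1 || m < 1)
    stopf("`m` must be a single number >= 1")
  pmin(1, p * m)
}

#' Manhattan-plot data for a scan
#'
#' @param S a `scan_result`.
#' @param C optional candidate set; member variants get `candidate = TRUE`.
#' @return Data frame: `chrom`, `pos`, `neglog10_p`, `candidate`,
#'   `maf_bin` (the 2-5\%, 5-10\%, >10\% bins).
#' @export
manhattan_data <- function(S, C = NULL) {
  bins <- cut(S$maf, c(0.02, 0.05, 0.10, 0.5),
              labels = c("2-5%", "5-10%", ">10%"),
              right = FALSE, include.lowest = TRUE)
  data.frame(chrom = S$chrom, pos = S$pos,
             neglog10_p = -log10(S$p),
             candidate = if (is.null(C)) FALSE else S$id %in% C$id,
             maf_bin = as.character(bins),
             stringsAsFactors = FALSE)
}
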