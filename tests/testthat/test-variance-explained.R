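test_that("candidate design encodes missing-as-state with a 0 reference", {
  set.seed(12)
  n <- 40
  calls <- cbind(
    rbinom(n, 1, 0.5),                      # no missing: 1 column
    ifelse(runif(n) < 0.3, NA, rbinom(n, 1, 0.5)),  # 3 states: 2 columns
    rep(1, n))                              # constant: dropped
  calls[1, 2] <- 0; calls[2, 2] <- 1        # ensure all three states
  v <- data.frame(id = c("s1", "s2", "s3"), chrom = "chr1",
                  pos = c(10L, 20L, 30L), ref = "A", alt = "T")
  G <- genotype_matrix(calls, v, sprintf("A%02d", 1:n))
  y <- setNames(rnorm(n), G$accession_ids)
  C <- fake_scan(p = c(0.01, 0.02, 0.03), pos = c(10, 20, 30))
  C$id <- c("s1", "s2", "s3")
  d <- candidate_design(y, G, C)
  expect_length(d$groups[["s1"]], 1)
  expect_length(d$groups[["s2"]], 2)
  expect_equal(d$dropped_zero_variance, "s3")
})

test_that("perfectly collinear candidates are pruned and recorded", {
  set.seed(13)
  n <- 50
  x <- rbinom(n, 1, 0.5)
  calls <- cbind(x, x, rbinom(n, 1, 0.5))
  v <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                  pos = c(1L, 2L, 3L), ref = "A", alt = "T")
  G <- genotype_matrix(calls, v, sprintf("A%02d", 1:n))
  y <- setNames(rnorm(n), G$accession_ids)
  C <- fake_scan(p = c(0.01, 0.02, 0.03), pos = 1:3); C$id <- c("a", "b", "c")
  d <- candidate_design(y, G, C)
  expect_equal(d$dropped_collinear, "b")
  expect_false("b" %in% names(d$groups))
})

test_that("stepwise selection matches stepAIC and the exhaustive optimum", {
  sm <- small_sim(seed = 21, n = 120, m = 600, n_causal = 3,
                  h2_causal = 0.4, h2_polygenic = 0.1,
                  missing_rate = 0.15, maf_spectrum_shape = 0.4)
  mns <- block_adjusted_means(sm$P, "trait1")
  G <- filter_variants(sm$G, 0.02, 80)
  K <- estimate_kinship(G, 500, seed = 5)
  vc <- fit_null_reml(mns, K)
  S <- gwas_scan(mns, G, vc)
  C10 <- select_candidates(S, 10)
  des <- candidate_design(mns, G, C10)
  rep <- stepwise_regression(des)

  # oracle 1: MASS::stepAIC on the equivalent factor design
  df <- data.frame(y = des$y)
  for (id in names(des$groups)) {
    x <- G$calls[des$accessions, match(id, G$variants$id)]
    st <- ifelse(is.na(x), "miss", as.character(x))
    df[[make.names(id)]] <- factor(st)
  }
  sa <- MASS::stepAIC(lm(y ~ ., data = df), direction = "backward",
                      trace = 0)
  kept <- setdiff(all.vars(formula(sa)), "y")
  expect_setequal(make.names(rep$retained_variants), kept)
  expect_equal(rep$aic, stats::extractAIC(sa)[2], tolerance = 1e-8)
  expect_equal(rep$r2, summary(sa)$r.squared, tolerance = 1e-8)

  # oracle 2: exhaustive enumeration of all candidate subsets (<= 2^10)
  ids <- names(des$groups)
  aic_of <- function(sub) {
    cols <- sort(unlist(des$groups[sub]))
    M <- cbind(1, des$X[, cols, drop = FALSE])
    rss <- sum(lm.fit(M, des$y)$residuals^2)
    length(des$y) * log(rss / length(des$y)) + 2 * (length(cols) + 1)
  }
  subs <- unlist(lapply(0:length(ids), function(k)
    utils::combn(ids, k, simplify = FALSE)), recursive = FALSE)
  best <- min(vapply(subs, aic_of, numeric(1)))
  expect_equal(rep$aic, best, tolerance = 1e-8)
})

test_that("pure-noise candidates are mostly discarded; a strong causal
           candidate survives", {
  kept_causal <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 200
    xs <- matrix(rbinom(n * 10, 1, 0.3), n, 10)
    y <- sqrt(0.5) * scale(xs[, 1])[, 1] + rnorm(n, 0, sqrt(0.5))
    v <- data.frame(id = paste0("s", 1:10), chrom = "chr1",
                    pos = 1:10 * 100L, ref = "A", alt = "T")
    G <- genotype_matrix(xs, v, sprintf("A%03d", 1:n))
    yv <- setNames(y, G$accession_ids)
    C <- fake_scan(p = seq(0.001, 0.01, length.out = 10), pos = 1:10 * 100)
    C$id <- paste0("s", 1:10)
    rep <- stepwise_regression(candidate_design(yv, G, C))
    "s1" %in% rep$retained_variants
  }, logical(1))
  expect_gte(sum(kept_causal), 19)

  set.seed(77)
  n <- 300
  xs <- matrix(rbinom(n * 10, 1, 0.3), n, 10)
  v <- data.frame(id = paste0("s", 1:10), chrom = "chr1",
                  pos = 1:10 * 100L, ref = "A", alt = "T")
  G <- genotype_matrix(xs, v, sprintf("A%03d", 1:n))
  yv <- setNames(rnorm(n), G$accession_ids)
  C <- fake_scan(p = seq(0.001, 0.01, length.out = 10), pos = 1:10 * 100)
  C$id <- paste0("s", 1:10)
  rep <- stepwise_regression(candidate_design(yv, G, C))
  expect_lt(rep$n_retained, 5)
  expect_lt(rep$r2, 0.1)
})

test_that("candidate pre-pruning keeps the model estimable", {
  sm <- small_sim(seed = 31, n = 40, m = 500, maf_spectrum_shape = 0.5)
  mns <- block_adjusted_means(sm$P, "trait1")
  G <- filter_variants(sm$G, 0.05, 20)
  K <- estimate_kinship(G, 300, seed = 1)
  vc <- fit_null_reml(mns, K)
  S <- gwas_scan(mns, G, vc)
  C50 <- select_candidates(S, 50)
  d <- candidate_design(mns, G, C50)
  expect_gt(length(d$pruned_for_df), 0)
  expect_lte(ncol(d$X) + 3, length(d$y))
  rep <- stepwise_regression(d)
  expect_true(is.finite(rep$aic))
})

test_that("randomization null is seed-reproducible", {
  sm <- small_sim(seed = 51, n = 60, m = 400)
  mns <- block_adjusted_means(sm$P, "trait1")
  K <- estimate_kinship(sm$Gf, 400, seed = 2)
  n1 <- randomization_null(mns, sm$Gf, K, R = 1, k = 10, seed = 99)
  n2 <- randomization_null(mns, sm$Gf, K, R = 1, k = 10, seed = 99)
  expect_identical(n1$r2_values, n2$r2_values)
  expect_identical(n1$maf_bin_counts, n2$maf_bin_counts)
})

test_that("the permutation null calibrates null data and is beaten by a
           strongly causal trait", {
  # with R inner randomizations an exchangeable empirical value falls
  # inside the null range with probability (R-1)/(R+1) = 0.905 at R = 20;
  # the assertion allows two binomial standard errors below that
  res <- vapply(1:20, function(s) {
    sm <- small_sim(seed = 800 + s, n = 100, m = 900, n_causal = 0,
                    h2_causal = 0, h2_polygenic = 0)
    mns <- block_adjusted_means(sm$P, "trait1")
    G <- filter_variants(sm$G, 0.02, 50)
    K <- estimate_kinship(G, 400, seed = s)
    vc <- fit_null_reml(mns, K)
    S <- gwas_scan(mns, G, vc)
    C <- select_candidates(S, 10)
    emp <- stepwise_regression(candidate_design(mns, G, C))$r2
    nul <- randomization_null(mns, G, K, R = 20, k = 10, seed = 80 + s)
    emp >= min(nul$r2_values) && emp <= max(nul$r2_values)
  }, logical(1))
  expect_gte(mean(res), 19 / 21 - 2 * sqrt(19 / 21 * 2 / 21 / 20))

  beats <- vapply(1:10, function(s) {
    sm <- small_sim(seed = 850 + s, n = 100, m = 900, n_causal = 3,
                    h2_causal = 0.7, h2_polygenic = 0,
                    causal_maf_range = c(0.1, 0.5))
    mns <- block_adjusted_means(sm$P, "trait1")
    G <- filter_variants(sm$G, 0.02, 50)
    K <- estimate_kinship(G, 400, seed = s)
    vc <- fit_null_reml(mns, K)
    S <- gwas_scan(mns, G, vc)
    C <- select_candidates(S, 10)
    emp <- stepwise_regression(candidate_design(mns, G, C))$r2
    nul <- randomization_null(mns, G, K, R = 20, k = 10, seed = 90 + s)
    emp > max(nul$r2_values)
  }, logical(1))
  expect_gte(sum(beats), 9)
})

test_that("adjusted r2 follows the uniform-rescaling formula", {
  a <- adjusted_r2(0.75, 0.65)
  expect_equal(a$adjusted, (0.75 - 0.65) / 0.35, tolerance = 1e-12)
  expect_equal(adjusted_r2(0.4, 0)$adjusted, 0.4)
  expect_equal(adjusted_r2(0.5, 0.5)$adjusted, 0)
  expect_lt(adjusted_r2(0.3, 0.5)$adjusted, 0)
  expect_error(adjusted_r2(0.5, 1), "< 1")
  # monotonicity
  expect_gt(adjusted_r2(0.8, 0.5)$adjusted, adjusted_r2(0.7, 0.5)$adjusted)
  expect_lt(adjusted_r2(0.7, 0.6)$adjusted, adjusted_r2(0.7, 0.5)$adjusted)
})

test_that("causal candidates are shifted toward common alleles relative to
           the randomization null profile", {
  # when causal MAFs span the full spectrum the selection step favors
  # detectable (commoner) alleles, so the empirical top-candidate bin
  # fraction above MAF 0.10 exceeds the null-replicate expectation
  ok <- vapply(1:5, function(s) {
    sm <- small_sim(seed = 900 + s, n = 150, m = 2000,
                    maf_spectrum_shape = 0.25, n_causal = 30,
                    h2_causal = 0.6, h2_polygenic = 0)
    mns <- block_adjusted_means(sm$P, "trait1")
    G <- filter_variants(sm$G, 0.02, 75)
    K <- estimate_kinship(G, 500, seed = s)
    vc <- fit_null_reml(mns, K)
    S <- gwas_scan(mns, G, vc)
    C <- select_candidates(S, 50)
    emp_common <- maf_bins(C)[">10%"] / nrow(C)
    nul <- randomization_null(mns, G, K, R = 5, k = 50, seed = 70 + s)
    null_common <- mean(nul$maf_bin_counts[, ">10%"] /
                          rowSums(nul$maf_bin_counts))
    emp_common > null_common
  }, logical(1))
  expect_gte(sum(ok), 4)
})
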