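test_that("candidate selection is deterministic with tie-breaking", {
  S <- fake_scan(p = c(0.5, 0.01, 0.2, 0.01, 0.9),
                 chrom = c("chr2", "chr2", "chr1", "chr1", "chr1"),
                 pos = c(10, 20, 30, 40, 50))
  C1 <- select_candidates(S, 1)
  expect_equal(C1$id, "chr1_40")   # tie at p=0.01 broken by (chrom, pos)
  C2 <- select_candidates(S, 2)
  expect_equal(C2$id, c("chr1_40", "chr2_20"))
  # order invariance
  idx <- c(4, 1, 5, 3, 2)
  S2 <- S[idx, ]
  expect_equal(select_candidates(S2, 3)$id, select_candidates(S, 3)$id)
  # short list flagged
  C9 <- select_candidates(S, 9)
  expect_true(attr(C9, "short"))
  expect_equal(nrow(C9), 5)
})

test_that("LD r2 hits exact limits and flags sparse pairs", {
  x <- c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0, 0, 1)
  calls <- cbind(x, x, 1 - x, rbinom(12, 1, 0.5))
  calls[1:11, 4] <- NA  # only 1 complete pair with others
  v <- data.frame(id = paste0("v", 1:4), chrom = "chr1", pos = 1:4 * 5,
                  ref = "A", alt = "T")
  G <- genotype_matrix(calls, v, sprintf("A%02d", 1:12))
  C <- fake_scan(p = rep(0.1, 4), pos = 1:4 * 5)
  C$id <- paste0("v", 1:4)
  L <- ld_matrix(G, C)
  expect_equal(L$r2["v1", "v2"], 1)
  expect_equal(L$r2["v1", "v3"], 1)   # complementary vectors: r = -1
  expect_true(is.na(L$r2["v1", "v4"]))
  expect_error(ld_matrix(G, transform(C, id = c("v1", "nope", "v3", "v4"))),
               "absent")
})

test_that("independent variants show near-zero LD", {
  set.seed(5)
  n <- 200
  calls <- matrix(rbinom(n * 15, 1, 0.4), n, 15)
  v <- data.frame(id = paste0("v", 1:15), chrom = "chr1", pos = 1:15 * 100,
                  ref = "A", alt = "T")
  G <- genotype_matrix(calls, v, sprintf("A%03d", 1:n))
  C <- fake_scan(p = rep(0.1, 15), pos = 1:15 * 100)
  C$id <- paste0("v", 1:15)
  L <- ld_matrix(G, C)
  off <- L$r2[upper.tri(L$r2)]
  expect_lt(mean(off), 0.03)  # 105 independent pairs
})

test_that("ld_summary counts candidates free of LD at each threshold", {
  mk <- function(r2) {
    diag(r2) <- 1
    structure(list(r2 = r2, ids = paste0("v", seq_len(nrow(r2)))),
              class = "ld_matrix")
  }
  all1 <- mk(matrix(1, 3, 3))
  expect_equal(unname(ld_summary(all1)), c(0, 0))
  all0 <- mk(matrix(0, 3, 3))
  expect_equal(unname(ld_summary(all0)), c(1, 1))
  # symmetric case: v1-v2 in high LD, v3-v4 free
  r2b <- matrix(0, 4, 4)
  r2b[1, 2] <- r2b[2, 1] <- 0.9
  r2b[3, 4] <- r2b[4, 3] <- 0.1
  expect_equal(unname(ld_summary(mk(r2b))), c(2 / 4, 2 / 4))
  # per-candidate maxima {0.9, 0.5, 0.1}: proportions 2/3 at 0.8, 1/3 at
  # 0.3 (row-maximum logic exercised with an asymmetric stand-in, since a
  # symmetric matrix cannot realize three distinct maxima)
  r2 <- matrix(0, 3, 3)
  r2[1, 2] <- 0.9; r2[2, 3] <- 0.5; r2[3, 1] <- 0.1
  expect_equal(unname(ld_summary(mk(r2), thresholds = c(0.8, 0.3))),
               c(2 / 3, 1 / 3))
})

test_that("MAF-effect correlation reports both signed and absolute effects", {
  C <- fake_scan(p = rep(0.01, 5), maf = c(0.1, 0.2, 0.3, 0.4, 0.5),
                 beta = c(5, -4, 3, -2, 1))
  r <- maf_effect_correlation(C)
  expect_equal(r$r, -1)
  expect_false(r$undefined)
  Cc <- fake_scan(p = rep(0.01, 5), maf = rep(0.2, 5), beta = 1:5)
  expect_true(maf_effect_correlation(Cc)$undefined)
  expect_error(maf_effect_correlation(C[1:2, ]), ">= 3")
})

test_that("causal MAF-effect coupling surfaces in scan candidates", {
  signs <- vapply(1:20, function(s) {
    sm <- small_sim(seed = 600 + s, n = 120, m = 2500, n_causal = 40,
                    h2_causal = 0.6, h2_polygenic = 0,
                    maf_effect_alpha = 0.6)
    mns <- block_adjusted_means(sm$P, "trait1")
    K <- estimate_kinship(sm$Gf, 500, seed = s)
    vc <- fit_null_reml(mns, K)
    S <- gwas_scan(mns, sm$Gf, vc)
    maf_effect_correlation(select_candidates(S, 200))$r < 0
  }, logical(1))
  expect_gte(sum(signs), 18)
})

test_that("MAF bins partition [0.02, 0.5] with left-closed boundaries", {
  expect_equal(unname(maf_bins(c(0.02, 0.049))), c(2L, 0L, 0L))
  expect_equal(unname(maf_bins(c(0.05, 0.099, 0.10))), c(0L, 2L, 1L))
  expect_equal(unname(maf_bins(0.5)), c(0L, 0L, 1L))
  expect_error(maf_bins(c(0.01, 0.2)), "filter violated")
  set.seed(2)
  u <- runif(10000, 0.02, 0.5)
  fr <- maf_bins(u) / 10000
  expect_equal(unname(fr), c(0.03, 0.05, 0.40) / 0.48, tolerance = 0.02)
  expect_equal(sum(maf_bins(u)), 10000)
})

test_that("gene tagging follows the inside-else-nearest rule", {
  A <- data.frame(gene_id = c("g1", "g2", "g3"),
                  chrom = c("chr1", "chr1", "chr1"),
                  start = c(100L, 500L, 1000L),
                  end = c(200L, 700L, 1200L),
                  name = NA_character_)
  C <- fake_scan(p = rep(0.01, 4), chrom = "chr1",
                 pos = c(150, 320, 851, 2000))
  tg <- tag_genes(C, A)
  expect_equal(tg$gene_id, c("g1", "g1", "g3", "g3"))
  expect_equal(tg$distance, c(0, 120, 150, 800))
  expect_false(any(tg$tie))

  # equidistant SNP: g1 = [100, 201), g2 = [500, 700); p0 = 350 is 150 bp
  # from both boundaries -> deterministic tie to the smaller start, flagged
  At <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(100L, 500L), end = c(201L, 700L),
                   name = NA_character_)
  t2 <- tag_genes(fake_scan(p = 0.01, chrom = "chr1", pos = 351), At)
  expect_true(t2$tie)
  expect_equal(t2$gene_id, "g1")  # smaller start wins

  # chromosome with no genes
  Cn <- fake_scan(p = 0.01, chrom = "chr9", pos = 5)
  expect_true(tag_genes(Cn, A)$unassigned)
})

test_that("named-gene windows are inclusive at 10 kb", {
  A <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                  start = c(50000L, 52000L), end = c(51000L, 53000L),
                  name = c("NFP", "MtFD"))
  near <- fake_scan(p = 0.01, chrom = "chr1", pos = 40002)
  # p0 = 40001: 9999 bp from gA (hit) but 11999 bp from gB (no hit)
  hitsA <- named_gene_hits(near, A)
  expect_equal(hitsA$gene_id, "gA")
  expect_equal(hitsA$distance, 9999)
  far <- fake_scan(p = 0.01, chrom = "chr1", pos = 39999)
  # p0 = 39998 -> distance 10002 to gA, > 10 kb
  expect_equal(nrow(named_gene_hits(far, A)), 0)
  mid <- fake_scan(p = 0.01, chrom = "chr1", pos = 51500)
  hits <- named_gene_hits(mid, A)
  expect_setequal(hits$gene_id, c("gA", "gB"))
})

test_that("specificity enrichment equals brute-force hypergeometric
           summation", {
  # small universe oracle: direct pmf summation
  tail_oracle <- function(q, N, K, n)
    sum(vapply(q:min(K, n), function(k)
      exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)),
      numeric(1)))
  for (cs in list(c(3, 200, 40, 10), c(0, 500, 100, 20), c(7, 2000, 60, 30))) {
    expect_equal(hypergeom_tail(cs[1], cs[2], cs[3], cs[4]),
                 tail_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }

  spec <- setNames(rep(c(TRUE, FALSE), c(8, 12)), paste0("g", 1:20))
  # observed 0 specific -> P = 1
  r0 <- specificity_enrichment(paste0("g", 9:20), spec,
                               universe_size = 100, universe_specific = 40)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_value, 1)
  # sample = universe -> P = 1 at observed = universe_specific
  rall <- specificity_enrichment(names(spec), spec,
                                 universe_size = 20, universe_specific = 8)
  expect_equal(rall$p_value, 1)
  expect_error(specificity_enrichment(names(spec), spec, 20, 5),
               "exceeds universe_specific")
})

test_that("nodule/root specificity requires absence from other tissues", {
  E <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 3),
    tissue = rep(c("nodule", "root", "leaf"), 3),
    expressed = c(1, 1, 0,   1, 0, 1,   0, 0, 1))
  sp <- nodule_root_specific(E)
  expect_equal(unname(sp[c("g1", "g2", "g3")]), c(TRUE, FALSE, FALSE))
  expect_error(nodule_root_specific(E[E$tissue != "leaf", ]), "other tissue")
})

test_that("candidate MAF tests behave under the null", {
  set.seed(9)
  genome <- runif(2000, 0.02, 0.5)
  rej <- vapply(1:100, function(i) {
    cand <- sample(genome, 50)
    candidate_maf_test(cand, genome, n_perm = 99, seed = i)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 100))

  aov <- candidate_maf_anova(list(a = runif(200, 0.02, 0.2),
                                  b = runif(200, 0.3, 0.5)))
  expect_lt(aov$p_value, 1e-6)
  expect_equal(aov$df1, 1)
})

test_that("manhattan data flags candidates and bins MAF", {
  S <- fake_scan(p = c(1e-8, 0.5, 0.2), maf = c(0.03, 0.07, 0.3))
  C <- select_candidates(S, 1)
  md <- manhattan_data(S, C)
  expect_equal(md$candidate, c(TRUE, FALSE, FALSE))
  expect_equal(md$maf_bin, c("2-5%", "5-10%", ">10%"))
})
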