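# Small fixtures shared across test files; everything is built in code.

# Hand-built genotype matrix: 5 accessions x 4 variants on 2 chromosomes.
tiny_genotypes <- function() {
  calls <- rbind(
    A1 = c(0, 1, 0, NA),
    A2 = c(0, 1, 1, 0),
    A3 = c(1, 0, 1, 0),
    A4 = c(1, 0, 0, 1),
    A5 = c(0, NA, 0, 1))
  variants <- data.frame(
    id = c("v1", "v2", "v3", "v4"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 250L, 50L, 400L),
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, rownames(calls))
}

# A moderately sized simulated dataset reused where a test only needs
# "some realistic data" rather than specific generator settings.
small_sim <- function(seed = 42, n = 80, m = 800, n_causal = 4,
                      h2_causal = 0.4, h2_polygenic = 0.2,
                      maf_spectrum_shape = 0.4, missing_rate = 0.1, ...) {
  cfg <- sim_config(seed = seed, n_accessions = n, n_variants = m,
                    chrom_length_bp = 1e5, n_chromosomes = 2,
                    maf_spectrum_shape = maf_spectrum_shape,
                    n_causal = n_causal,
                    h2_causal = h2_causal, h2_polygenic = h2_polygenic,
                    missing_rate = missing_rate, ...)
  sim <- simulate_genotypes(cfg)
  phe <- simulate_phenotypes(sim$genotypes, sim$truth, cfg)
  list(cfg = cfg, G = sim$genotypes, truth = phe$truth,
       P = phe$phenotypes,
       Gf = filter_variants(sim$genotypes, 0.02, round(0.5 * n)))
}

# Build a scan_result by hand from vectors (for candidate-selection tests).
fake_scan <- function(p, chrom = "chr1", pos = seq_along(p),
                      maf = rep(0.2, length(p)), beta = rep(1, length(p))) {
  out <- data.frame(id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
                    maf = maf, n_used = 100L, beta = beta, se = 1, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

identity_kinship <- function(ids) {
  K <- diag(1, length(ids))
  dimnames(K) <- list(ids, ids)
  K
}
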