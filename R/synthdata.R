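#' Configuration for the synthetic genotype-phenotype generator
#'
#' The generator emulates the design of a sequence-based association panel
#' of selfed plant accessions: a few hundred inbred lines with population
#' structure, block-structured linkage disequilibrium produced by founder
#' haplotype mosaics, a rare-skewed allele-frequency spectrum, genotype
#' missingness, sparse causal variants whose effect sizes can be coupled to
#' allele frequency, a polygenic background proportional to kinship, and
#' replicated phenotyping in randomized complete greenhouse blocks.
#'
#' Heritabilities are expressed at the accession-mean level: `h2_causal`
#' (`h2_polygenic`) is the fraction of the variance of block-adjusted
#' accession means attributable to the causal variants (the polygenic
#' background) when each accession is replicated once per greenhouse block.
#'
#' @param n_accessions number of inbred accessions (default 226, a typical
#'   resequenced association panel).
#' @param n_subpops number of subpopulations.
#' @param admixture_weights subpopulation proportions (sum to 1).
#' @param n_chromosomes,chrom_length_bp genome dimensions.
#' @param n_variants total number of segregating sites to place.
#' @param block_length_bp LD block length; within a block accessions
#'   carrying the same founder haplotype are identical (default 3000 bp,
#'   the scale over which LD typically extends in a selfing species).
#' @param n_founder_haplotypes_per_block founder haplotypes per block;
#'   controls the granularity of realized allele frequencies.
#' @param subpop_divergence in \[0, 1\]: how strongly each subpopulation
#'   prefers its own "home" founder haplotypes. 0 gives exchangeable
#'   founder usage (no structure); values near 1 give subpopulations
#'   nearly private founders (strong structure). The default 0.5 produces
#'   the pronounced population structure typical of a broad natural
#'   accession collection, where uncorrected association scans show
#'   clearly inflated test statistics.
#' @param maf_spectrum_shape shape of the Beta(shape, 10) density from
#'   which ancestral alternate-allele frequencies are drawn; smaller values
#'   skew the spectrum towards rare alleles. The default is calibrated so
#'   that the post-filter (MAF >= 0.02) spectrum has mean MAF near 0.09.
#' @param missing_rate per-call missingness probability (default 0.2,
#'   matching a panel whose median variant is scored in ~80\% of lines).
#' @param n_causal number of causal variants.
#' @param effect_scale baseline causal-effect magnitude before the global
#'   rescaling that enforces `h2_causal`.
#' @param maf_effect_alpha exponent coupling effect magnitude to
#'   \eqn{[p(1-p)]^{-\alpha}}; positive values make rare alleles have
#'   larger effects (mutation-selection-balance-like architecture).
#' @param h2_causal,h2_polygenic accession-mean-level variance fractions;
#'   their sum must be < 1.
#' @param n_blocks number of greenhouse blocks (one replicate per
#'   accession per block; default 8).
#' @param block_effect_sd standard deviation of additive block effects, in
#'   trait units.
#' @param causal_maf_range realized-MAF interval from which causal variants
#'   are sampled.
#' @param seed mandatory integer seed; all generator randomness derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 226,
                       n_subpops = 3,
                       admixture_weights = rep(1 / n_subpops, n_subpops),
                       n_chromosomes = 8,
                       chrom_length_bp = 5e5,
                       n_variants = 20000,
                       block_length_bp = 3000,
                       n_founder_haplotypes_per_block = 24,
                       subpop_divergence = 0.5,
                       maf_spectrum_shape = 0.12,
                       missing_rate = 0.2,
                       n_causal = 50,
                       effect_scale = 1,
                       maf_effect_alpha = 0,
                       h2_causal = 0.4,
                       h2_polygenic = 0.3,
                       n_blocks = 8,
                       block_effect_sd = 0.5,
                       causal_maf_range = c(0.02, 0.5),
                       seed) {
  if (missing(seed)) stopf("`seed` is mandatory in sim_config()")
  cfg <- list(n_accessions = check_count(n_accessions, "n_accessions"),
              n_subpops = check_count(n_subpops, "n_subpops"),
              admixture_weights = admixture_weights,
              n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
              chrom_length_bp = check_count(chrom_length_bp, "chrom_length_bp"),
              n_variants = check_count(n_variants, "n_variants"),
              block_length_bp = check_count(block_length_bp, "block_length_bp"),
              n_founder_haplotypes_per_block =
                check_count(n_founder_haplotypes_per_block,
                            "n_founder_haplotypes_per_block"),
              subpop_divergence = check_prob(subpop_divergence,
                                             "subpop_divergence"),
              maf_spectrum_shape = maf_spectrum_shape,
              missing_rate = check_prob(missing_rate, "missing_rate"),
              n_causal = check_count(n_causal, "n_causal", min = 0L),
              effect_scale = effect_scale,
              maf_effect_alpha = maf_effect_alpha,
              h2_causal = check_prob(h2_causal, "h2_causal"),
              h2_polygenic = check_prob(h2_polygenic, "h2_polygenic"),
              n_blocks = check_count(n_blocks, "n_blocks"),
              block_effect_sd = block_effect_sd,
              causal_maf_range = causal_maf_range,
              seed = as.integer(seed))
  if (!is.numeric(cfg$admixture_weights) ||
      length(cfg$admixture_weights) != cfg$n_subpops ||
      any(cfg$admixture_weights < 0) ||
      abs(sum(cfg$admixture_weights) - 1) > 1e-8)
    stopf("`admixture_weights` must be %d non-negative values summing to 1",
          cfg$n_subpops)
  if (cfg$h2_causal + cfg$h2_polygenic >= 1)
    stopf("`h2_causal` + `h2_polygenic` must be < 1 (got %g)",
          cfg$h2_causal + cfg$h2_polygenic)
  if (cfg$n_causal > cfg$n_variants)
    stopf("`n_causal` cannot exceed `n_variants`")
  if (!is.numeric(cfg$maf_spectrum_shape) || cfg$maf_spectrum_shape <= 0)
    stopf("`maf_spectrum_shape` must be a positive real")
  if (cfg$block_effect_sd < 0) stopf("`block_effect_sd` must be >= 0")
  if (length(cfg$causal_maf_range) != 2 ||
      cfg$causal_maf_range[1] > cfg$causal_maf_range[2])
    stopf("`causal_maf_range` must be an increasing length-2 interval")
  if (cfg$chrom_length_bp * cfg$n_chromosomes < cfg$n_variants)
    stopf("genome too short for `n_variants` distinct positions")
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields are passed straight to [sim_config()]; the seed is
#' mandatory.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Simulate genotypes for a structured panel of inbred accessions
#'
#' Genotypes are haploid-coded 0/1 mosaics of founder haplotypes: each
#' chromosome is cut into blocks of `block_length_bp`, each block carries
#' `n_founder_haplotypes_per_block` founder haplotypes whose alleles are
#' drawn from a rare-skewed frequency spectrum, and each accession picks
#' one founder per block with subpopulation-specific founder weights. This
#' yields complete LD within founder-sharing groups, a skewed MAF spectrum
#' and non-trivial kinship structure. Missing calls are then placed
#' independently at `missing_rate`. Sites that end up monomorphic are
#' retained (the variant filter removes them later, mirroring the order of
#' a real pipeline).
#'
#' @param config a [sim_config()].
#' @return A list with components `genotypes` (a [genotype_matrix()]) and
#'   `truth` (a `ground_truth` list carrying the causal variant ids, the
#'   subpopulation assignment, the kinship of the complete (pre-missingness)
#'   genotypes, and the complete causal genotype columns used later by
#'   [simulate_phenotypes()]).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genotypes"), {
    n <- config$n_accessions
    subpop <- sample.int(config$n_subpops, n, replace = TRUE,
                         prob = config$admixture_weights)
    acc_ids <- sprintf("ACC%04d", seq_len(n))

    n_per_chrom <- diff(floor(seq(0, config$n_variants,
                                  length.out = config$n_chromosomes + 1)))
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    pos_l <- lapply(n_per_chrom, function(k)
      sort(sample.int(config$chrom_length_bp, k)))
    variants <- data.frame(
      chrom = rep(chroms, n_per_chrom),
      pos = unlist(pos_l),
      ref = "A", alt = "T",
      stringsAsFactors = FALSE)
    variants$id <- paste0(variants$chrom, "_", variants$pos)

    F <- config$n_founder_haplotypes_per_block
    block <- (variants$pos - 1L) %/% config$block_length_bp
    key <- paste(variants$chrom, block)
    complete <- matrix(0L, n, nrow(variants))
    for (b in unique(key)) {
      idx <- which(key == b)
      m_b <- length(idx)
      # ancestral alternate-allele frequencies: Beta(shape, 3); the fixed
      # second parameter suppresses the common tail so the shape parameter
      # alone controls the rare-allele skew of the realized spectrum
      p <- stats::rbeta(m_b, config$maf_spectrum_shape, 10)
      H <- matrix(stats::rbinom(F * m_b, 1L, rep(p, each = F)), F, m_b)
      # founder usage: each founder has a "home" subpopulation whose
      # weight is boosted by subpop_divergence, giving partly private
      # founder pools and hence genome-wide population structure
      W <- matrix(stats::rgamma(config$n_subpops * F, 1), config$n_subpops, F)
      home <- rep_len(seq_len(config$n_subpops), F)
      boost <- 1 + 19 * config$subpop_divergence
      W <- W * (1 + (boost - 1) * outer(seq_len(config$n_subpops), home, "=="))
      W <- W / rowSums(W)
      founder <- integer(n)
      for (s in seq_len(config$n_subpops)) {
        in_s <- subpop == s
        if (any(in_s))
          founder[in_s] <- sample.int(F, sum(in_s), replace = TRUE,
                                      prob = W[s, ])
      }
      complete[, idx] <- H[founder, , drop = FALSE]
    }

    f_alt <- colMeans(complete)
    maf_complete <- pmin(f_alt, 1 - f_alt)
    eligible <- which(maf_complete >= config$causal_maf_range[1] &
                        maf_complete <= config$causal_maf_range[2])
    if (config$n_causal > 0 && length(eligible) < config$n_causal)
      stopf("only %d variants fall in causal_maf_range [%g, %g]; need %d",
            length(eligible), config$causal_maf_range[1],
            config$causal_maf_range[2], config$n_causal)
    causal_idx <- if (config$n_causal > 0)
      sort(sample(eligible, config$n_causal)) else integer(0)

    kin_true <- ibs_kinship(complete)
    dimnames(kin_true) <- list(acc_ids, acc_ids)

    calls <- complete
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(calls)) < config$missing_rate
      calls[miss] <- NA_integer_
    }

    G <- genotype_matrix(calls, variants, acc_ids)
    truth <- list(
      causal_variant_ids = variants$id[causal_idx],
      causal_effects = NULL,
      causal_maf = maf_complete[causal_idx],
      causal_genotypes = complete[, causal_idx, drop = FALSE],
      true_h2_causal = NA_real_,
      true_among_accession_fraction = NA_real_,
      subpop_assignment = stats::setNames(subpop, acc_ids),
      kinship_true = kin_true)
    class(truth) <- "ground_truth"
    list(genotypes = G, truth = truth)
  })
}

# IBS kinship for a complete (no-missing) 0/1 matrix: proportion of shared
# alleles over all variants.
ibs_kinship <- function(X) {
  m <- ncol(X)
  XA <- X
  S <- tcrossprod(XA) + tcrossprod(1 - XA)
  S / m
}

#' Simulate replicated phenotypes with known architecture
#'
#' Replicate-level trait values follow
#' \deqn{y_{ib} = \sum_j \beta_j x_{ij} + g_i + b_b + e_{ib}}
#' with causal genotypes \eqn{x}, a polygenic value \eqn{g} drawn with
#' covariance proportional to the true kinship of the panel, additive
#' greenhouse-block effects \eqn{b} and i.i.d. residuals \eqn{e}. Causal
#' effect magnitudes are proportional to
#' \eqn{\mathrm{effect\_scale}\,[p(1-p)]^{-\alpha}} with random signs and
#' are then globally rescaled so that the causal component contributes
#' exactly `h2_causal` of the accession-mean variance (similarly
#' `h2_polygenic`); the residual variance is chosen so block-adjusted
#' accession means have total variance 1.
#'
#' @param G a [genotype_matrix()] from [simulate_genotypes()] (used for
#'   dimension checks; the causal genotypes come from `truth`, i.e. the
#'   complete calls before missingness).
#' @param truth the `ground_truth` from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @param trait trait name recorded in the phenotype table.
#' @return A list with `phenotypes` (a `phenotype_table` data frame with
#'   columns accession, block, trait, value) and `truth` updated with the
#'   realized causal effects and variance fractions.
#' @export
simulate_phenotypes <- function(G, truth, config, trait = "trait1") {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (config$h2_causal + config$h2_polygenic >= 1)
    stopf("h2_causal + h2_polygenic must be < 1")
  if (length(truth$causal_variant_ids) &&
      !all(truth$causal_variant_ids %in% G$variants$id))
    stopf("causal variants are missing from the genotype matrix")
  with_seed(derive_seed(config$seed, paste0("phenotypes:", trait)), {
    n <- length(G$accession_ids)
    r <- config$n_blocks

    # causal component, rescaled to hit h2_causal exactly in-sample
    X <- truth$causal_genotypes
    beta <- numeric(ncol(X))
    cvar <- 0
    if (ncol(X) > 0 && config$h2_causal > 0) {
      p <- colMeans(X)
      mag <- config$effect_scale *
        pmax(p * (1 - p), 1e-12) ^ (-config$maf_effect_alpha)
      beta <- mag * sample(c(-1, 1), ncol(X), replace = TRUE)
      cv <- as.numeric(X %*% beta)
      v <- stats::var(cv)
      if (v < 1e-12)
        stopf("causal component has zero variance; check causal_maf_range")
      beta <- beta * sqrt(config$h2_causal / v)
      cv <- as.numeric(X %*% beta)
      cvar <- stats::var(cv)
    } else cv <- numeric(n)

    # polygenic component with covariance proportional to true kinship
    if (config$h2_polygenic > 0) {
      K <- truth$kinship_true
      L <- chol(K + diag(1e-6, n))
      g <- as.numeric(crossprod(L, stats::rnorm(n)))
      g <- g - mean(g)
      g <- g * sqrt(config$h2_polygenic / stats::var(g))
    } else g <- numeric(n)

    u <- cv + g
    # residual variance at replicate level: accession means (r replicates)
    # then carry (1 - h2_causal - h2_polygenic) of unit total variance
    ve <- r * (1 - config$h2_causal - config$h2_polygenic)
    block_eff <- stats::rnorm(r, 0, config$block_effect_sd)
    e <- matrix(stats::rnorm(n * r, 0, sqrt(ve)), n, r)

    P <- data.frame(
      accession = rep(G$accession_ids, r),
      block = rep(sprintf("B%d", seq_len(r)), each = n),
      trait = trait,
      value = as.numeric(sweep(e, 2, block_eff, `+`) + u),
      stringsAsFactors = FALSE)
    class(P) <- c("phenotype_table", "data.frame")

    var_u <- stats::var(u)
    var_e <- stats::var(as.numeric(e))
    truth$causal_effects <- stats::setNames(beta, truth$causal_variant_ids)
    truth$true_h2_causal <-
      if (var_u + ve / r > 0) cvar / (var_u + ve / r) else 0
    truth$true_among_accession_fraction <- var_u / (var_u + var_e)
    list(phenotypes = P, truth = truth)
  })
}

#' Draw a discovery (ascertainment) panel of accessions
#'
#' @param G a [genotype_matrix()].
#' @param d panel size (e.g. 26 deeply sequenced accessions).
#' @param seed integer seed.
#' @return Character vector of `d` distinct accession ids.
#' @export
subsample_discovery_panel <- function(G, d, seed) {
  d <- check_count(d, "d")
  if (d > length(G$accession_ids))
    stopf("panel size d = %d exceeds the %d available accessions", d,
          length(G$accession_ids))
  with_seed(seed, sample(G$accession_ids, d))
}

#' Simulate a gene annotation and a tissue expression-presence profile
#'
#' Genes tile each chromosome with intergenic gaps (non-overlapping,
#' 0-based half-open intervals). A fraction `frac_specific` of genes is
#' flagged as expressed exclusively in nodule and/or root tissue; the rest
#' are expressed in at least one other tissue.
#'
#' @param config a [sim_config()] (supplies the genome dimensions).
#' @param n_genes total number of genes.
#' @param frac_specific probability that a gene is nodule/root-specific.
#' @param seed integer seed.
#' @return A list with `annotation` (data frame: gene_id, chrom, start,
#'   end, name) and `expression` (long data frame: gene_id, tissue,
#'   expressed in \{0,1\}).
#' @export
simulate_annotation <- function(config, n_genes, frac_specific, seed) {
  n_genes <- check_count(n_genes, "n_genes")
  check_prob(frac_specific, "frac_specific")
  with_seed(seed, {
    per_chrom <- diff(floor(seq(0, n_genes,
                                length.out = config$n_chromosomes + 1)))
    rows <- vector("list", config$n_chromosomes)
    for (c_i in seq_len(config$n_chromosomes)) {
      k <- per_chrom[c_i]
      if (k == 0) next
      slot <- config$chrom_length_bp / k
      start <- floor((seq_len(k) - 1) * slot + 0.2 * slot)
      end <- floor((seq_len(k) - 1) * slot + 0.8 * slot)
      rows[[c_i]] <- data.frame(
        chrom = sprintf("chr%d", c_i), start = as.integer(start),
        end = as.integer(end), stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    ann$gene_id <- sprintf("gene%05d", seq_len(nrow(ann)))
    ann$name <- NA_character_
    ann <- ann[, c("gene_id", "chrom", "start", "end", "name")]

    tissues <- c("nodule", "root", "leaf", "flower")
    specific <- stats::runif(nrow(ann)) < frac_specific
    expr <- matrix(0L, nrow(ann), length(tissues),
                   dimnames = list(ann$gene_id, tissues))
    for (i in seq_len(nrow(ann))) {
      if (specific[i]) {
        pick <- sample(c("nodule", "root", "both"), 1)
        expr[i, c("nodule", "root")] <- switch(pick,
          nodule = c(1L, 0L), root = c(0L, 1L), both = c(1L, 1L))
      } else {
        expr[i, ] <- stats::rbinom(length(tissues), 1L, 0.6)
        other <- c("leaf", "flower")
        if (all(expr[i, other] == 0L))
          expr[i, sample(other, 1)] <- 1L
      }
    }
    expression <- data.frame(
      gene_id = rep(ann$gene_id, each = length(tissues)),
      tissue = rep(tissues, nrow(ann)),
      expressed = as.integer(t(expr)),
      stringsAsFactors = FALSE)
    list(annotation = ann, expression = expression)
  })
}

#' Write simulated tables to their plain-text interchange formats
#'
#' @param P,A,E phenotype table, annotation, expression profile.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_phenotypes <- function(P, path) {
  utils::write.table(P, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tables
#' @export
read_phenotypes <- function(path) {
  P <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("accession", "block", "trait", "value")
  if (!all(need %in% names(P)))
    stopf("phenotype TSV needs columns: %s", paste(need, collapse = ", "))
  class(P) <- c("phenotype_table", "data.frame")
  P
}

#' @rdname write_tables
#' @export
write_annotation <- function(A, path) {
  utils::write.table(A[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
read_annotation <- function(path) {
  A <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "gene_id"))
  A$name <- NA_character_
  A[, c("gene_id", "chrom", "start", "end", "name")]
}

#' @rdname write_tables
#' @export
write_expression <- function(E, path) {
  utils::write.table(E, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
read_expression <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
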