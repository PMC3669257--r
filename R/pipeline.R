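#' Run the analysis pipeline as an ordered set of stages
#'
#' Orchestrates the stages end to end: `simulate` (synthetic genotypes,
#' phenotypes, annotation), `filter` (variant inclusion filters),
#' `phenotypes` (block-adjusted accession means), `scan` (kinship +
#' mixed-model association scan), `candidates` (top-k lists and
#' architecture statistics), `variance` (randomization null and adjusted
#' r-squared) and `array` (in silico platform experiment). Each stage
#' writes plain-text artifacts (TSV/JSON) into `out_dir` and an entry in
#' `manifest.json` recording its inputs, parameters, derived seed and
#' artifact MD5 hashes; rerunning with the same config reproduces the
#' hashes. A stage whose inputs were produced neither earlier in the same
#' call nor by a previous run in `out_dir` raises an error naming the
#' stage and the missing artifact.
#'
#' All randomness flows from `config$seed` through per-stage derived
#' seeds, so stages are individually reproducible.
#'
#' @param config a [sim_config()] (supplies the generator settings and the
#'   master seed).
#' @param stages ordered character subset of
#'   `c("simulate", "filter", "phenotypes", "scan", "candidates",
#'   "variance", "array")`.
#' @param out_dir output directory (created if needed).
#' @param trait trait name (default `"trait1"`).
#' @param params named list overriding analysis defaults: `min_maf`
#'   (0.02), `min_called` (100), `snps_per_chrom` (5000), `k_regression`
#'   (50), `k_architecture` (200), `R` (20 randomizations),
#'   `n_platforms` (100), `panel_size` (26), `window_bp` (1000),
#'   `panel_maf_min` (0.10), `target_size` (derived from the genome if
#'   absent).
#' @return The manifest, invisibly (list of per-stage records).
#' @export
run_pipeline <- function(config, stages, out_dir, trait = "trait1",
                         params = list()) {
  all_stages <- c("simulate", "filter", "phenotypes", "scan", "candidates",
                  "variance", "array")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.unsorted(match(stages, all_stages)))
    stopf("stages must be given in pipeline order")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- utils::modifyList(list(
    min_maf = 0.02, min_called = 100, snps_per_chrom = 5000,
    k_regression = 50, k_architecture = 200, R = 20,
    n_platforms = 100, panel_size = 26, window_bp = 1000,
    panel_maf_min = 0.10, target_size = NULL), params)

  st <- new.env(parent = emptyenv())
  manifest <- list()
  path <- function(f) file.path(out_dir, f)
  log_stage <- function(stage, files, extra = list()) {
    message(sprintf("[%s] wrote %s", stage, paste(files, collapse = ", ")))
    manifest[[stage]] <<- c(list(
      stage = stage, seed = derive_seed(config$seed, stage),
      artifacts = as.list(tools::md5sum(vapply(files, path, "")))), extra)
  }
  need <- function(stage, obj, loader, file) {
    if (!is.null(st[[obj]])) return(st[[obj]])
    if (!file.exists(path(file)))
      stopf("stage '%s' needs artifact '%s'; run its producing stage first",
            stage, file)
    st[[obj]] <- loader(path(file))
    st[[obj]]
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        sim <- simulate_genotypes(config)
        phe <- simulate_phenotypes(sim$genotypes, sim$truth, config,
                                   trait = trait)
        st$G_raw <- sim$genotypes
        st$truth <- phe$truth
        st$P <- phe$phenotypes
        write_genotypes(st$G_raw, path("genotypes.tsv"), format = "tsv")
        write_phenotypes(st$P, path("phenotypes.tsv"))
        jsonlite::write_json(list(
          causal_variant_ids = phe$truth$causal_variant_ids,
          causal_effects = unname(phe$truth$causal_effects),
          true_h2_causal = phe$truth$true_h2_causal,
          true_among_accession_fraction =
            phe$truth$true_among_accession_fraction),
          path("truth.json"), auto_unbox = TRUE, digits = NA)
        log_stage(stage, c("genotypes.tsv", "phenotypes.tsv", "truth.json"))
      },
      filter = {
        G <- need(stage, "G_raw", function(f) read_genotypes(f, "tsv"),
                  "genotypes.tsv")
        st$G <- filter_variants(G, min_maf = p$min_maf,
                                min_called = p$min_called)
        write_genotypes(st$G, path("genotypes_filtered.tsv"), format = "tsv")
        log_stage(stage, "genotypes_filtered.tsv",
                  list(params = p[c("min_maf", "min_called")]))
      },
      phenotypes = {
        P <- need(stage, "P", read_phenotypes, "phenotypes.tsv")
        st$means <- block_adjusted_means(P, trait)
        utils::write.table(st$means, path(sprintf("means_%s.tsv", trait)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage(stage, sprintf("means_%s.tsv", trait))
      },
      scan = {
        G <- need(stage, "G", function(f) read_genotypes(f, "tsv"),
                  "genotypes_filtered.tsv")
        means <- if (!is.null(st$means)) st$means
          else if (file.exists(path(sprintf("means_%s.tsv", trait)))) {
            m <- utils::read.delim(path(sprintf("means_%s.tsv", trait)),
                                   stringsAsFactors = FALSE)
            class(m) <- c("accession_means", "data.frame"); m
          } else block_adjusted_means(
            need(stage, "P", read_phenotypes, "phenotypes.tsv"), trait)
        st$means <- means
        st$K <- estimate_kinship(G, snps_per_chrom = p$snps_per_chrom,
                                 seed = derive_seed(config$seed, "kinship"))
        st$vc <- fit_null_reml(means, st$K)
        st$scan <- gwas_scan(means, G, st$vc)
        utils::write.table(
          data.frame(accession = rownames(st$K), st$K, check.names = FALSE),
          path("kinship.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(st$scan, path(sprintf("scan_%s.tsv", trait)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage(stage, c("kinship.tsv", sprintf("scan_%s.tsv", trait)),
                  list(delta = st$vc$delta))
      },
      candidates = {
        S <- need(stage, "scan", function(f) {
          s <- utils::read.delim(f, stringsAsFactors = FALSE)
          class(s) <- c("scan_result", "data.frame"); s
        }, sprintf("scan_%s.tsv", trait))
        G <- need(stage, "G", function(f) read_genotypes(f, "tsv"),
                  "genotypes_filtered.tsv")
        C50 <- select_candidates(S, p$k_regression, trait)
        C200 <- select_candidates(S, p$k_architecture, trait)
        st$C50 <- C50; st$C200 <- C200
        utils::write.table(C50, path(sprintf("candidates_%s_top%d.tsv",
                                             trait, p$k_regression)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(C200, path(sprintf("candidates_%s_top%d.tsv",
                                              trait, p$k_architecture)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        arch <- list(
          ld_proportions = as.list(ld_summary(ld_matrix(G, C50))),
          maf_bins_top200 = as.list(maf_bins(C200)),
          maf_effect_correlation_top200 = maf_effect_correlation(C200)[
            c("r", "p_value")])
        jsonlite::write_json(arch, path(sprintf("architecture_%s.json",
                                                trait)),
                             auto_unbox = TRUE, digits = NA)
        log_stage(stage, c(
          sprintf("candidates_%s_top%d.tsv", trait, p$k_regression),
          sprintf("candidates_%s_top%d.tsv", trait, p$k_architecture),
          sprintf("architecture_%s.json", trait)))
      },
      variance = {
        if (is.null(st$scan) || is.null(st$G) || is.null(st$means) ||
            is.null(st$K))
          stopf("stage 'variance' needs the scan stage in the same run")
        C50 <- if (!is.null(st$C50)) st$C50
          else select_candidates(st$scan, p$k_regression, trait)
        emp <- stepwise_regression(candidate_design(st$means, st$G, C50))
        nul <- randomization_null(st$means, st$G, st$K, R = p$R,
                                  k = p$k_regression,
                                  seed = derive_seed(config$seed, "variance"))
        adj <- adjusted_r2(emp$r2, nul$mean_r2)
        jsonlite::write_json(list(
          empirical_r2 = emp$r2, n_retained = emp$n_retained,
          null_mean_r2 = nul$mean_r2, null_sd_r2 = nul$sd_r2,
          adjusted_r2 = adj$adjusted,
          retained_variants = emp$retained_variants),
          path(sprintf("variance_%s.json", trait)),
          auto_unbox = TRUE, digits = NA)
        log_stage(stage, sprintf("variance_%s.json", trait),
                  list(params = p["R"]))
      },
      array = {
        if (is.null(st$scan) || is.null(st$G) || is.null(st$means) ||
            is.null(st$vc))
          stopf("stage 'array' needs the scan stage in the same run")
        C200 <- if (!is.null(st$C200)) st$C200
          else select_candidates(st$scan, p$k_architecture, trait)
        panel <- subsample_discovery_panel(
          st$G, p$panel_size, derive_seed(config$seed, "panel"))
        scans <- vector("list", p$n_platforms)
        for (i in seq_len(p$n_platforms)) {
          des <- design_platform(
            st$G, panel, window_bp = p$window_bp,
            panel_maf_min = p$panel_maf_min,
            target_size = p$target_size,
            seed = derive_seed(config$seed, paste0("platform", i)))
          scans[[i]] <- scan_platform(st$means, st$G, st$vc, des,
                                      min_maf = p$min_maf,
                                      min_called = p$min_called)
        }
        ov <- overlap_report(scans, C200)
        bias <- maf_bias_report(st$G$variants$maf[st$G$variants$maf >= 0.02],
                                C200, select_candidates(scans[[1]], 50))
        jsonlite::write_json(list(
          overlap = ov, maf_bias_fractions = as.data.frame(bias$fractions),
          frac_below_10 = as.list(bias$frac_below_10)),
          path(sprintf("array_%s.json", trait)), digits = NA)
        log_stage(stage, sprintf("array_%s.json", trait),
                  list(params = p[c("n_platforms", "panel_size",
                                    "window_bp", "panel_maf_min")]))
      })
  }
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
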