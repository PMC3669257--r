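#' Select the top-k candidate SNPs from a scan
#'
#' Candidates are the `k` variants with smallest p-values (typically 50 or
#' 200). Ties are broken by ascending (chrom, pos) so candidate lists are
#' deterministic and invariant to input row order. Variants with undefined
#' p-values (monomorphic after imputation) are never selected.
#'
#' @param S a `scan_result`.
#' @param k number of candidates.
#' @param trait optional trait label carried in the result.
#' @return A data frame of class `candidate_set` (columns of `S`, ordered
#'   by the tie-broken key) with attributes `k`, `trait`, and
#'   `short = TRUE` when fewer than `k` valid tests were available.
#' @export
select_candidates <- function(S, k, trait = attr(S, "trait")) {
  valid <- S[!is.na(S$p), , drop = FALSE]
  ord <- order(valid$p, valid$chrom, valid$pos)
  kk <- min(k, nrow(valid))
  out <- valid[ord[seq_len(kk)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "trait") <- trait
  attr(out, "short") <- kk < k
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Pairwise linkage disequilibrium (r-squared) among candidates
#'
#' r-squared is the squared Pearson correlation of the two 0/1 call
#' vectors over pairwise-complete accessions; it is invariant to allele
#' recoding. Pairs with fewer than `min_pairs` complete observations are
#' flagged undefined (`NA`).
#'
#' @param G a [genotype_matrix()] containing all candidates.
#' @param C a `candidate_set`.
#' @param min_pairs minimum both-called accessions per pair (default 10).
#' @return A list of class `ld_matrix`: `r2` (symmetric, diagonal 1),
#'   `n_pairs_complete`, `ids`.
#' @export
ld_matrix <- function(G, C, min_pairs = 10) {
  absent <- setdiff(C$id, G$variants$id)
  if (length(absent))
    stopf("candidate(s) absent from genotypes: %s",
          paste(utils::head(absent, 3), collapse = ", "))
  X <- G$calls[, match(C$id, G$variants$id), drop = FALSE]
  npair <- crossprod((!is.na(X)) * 1)
  suppressWarnings(r <- stats::cor(X, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[npair < min_pairs] <- NA_real_
  diag(r2) <- 1
  dimnames(r2) <- list(C$id, C$id)
  out <- list(r2 = r2, n_pairs_complete = npair, ids = C$id)
  class(out) <- "ld_matrix"
  out
}

#' Proportion of candidates not in LD with any other candidate
#'
#' For each threshold `t`, the proportion of candidates whose maximum
#' off-diagonal r-squared with any other candidate is below `t`. Undefined
#' pairs are ignored.
#'
#' @param L an [ld_matrix()] result.
#' @param thresholds r-squared thresholds (default 0.8 and 0.3).
#' @return Named numeric vector of proportions, one per threshold.
#' @export
ld_summary <- function(L, thresholds = c(0.8, 0.3)) {
  r2 <- L$r2
  diag(r2) <- NA
  max_r2 <- apply(r2, 1, function(z)
    if (all(is.na(z))) 0 else max(z, na.rm = TRUE))
  stats::setNames(vapply(thresholds, function(t) mean(max_r2 < t),
                         numeric(1)),
                  sprintf("r2<%g", thresholds))
}

#' Correlation between candidate MAF and effect size
#'
#' Effect size is `|beta|`, the predicted phenotypic difference between
#' the two SNP variants of a 0/1 genotype. Reports the Pearson correlation
#' of MAF with `|beta|` and its two-sided p-value from the t transform;
#' the signed-beta correlation is included for transparency. A negative
#' correlation (rare alleles with larger effects) is the signature of
#' mutation-selection balance.
#'
#' @param C a `candidate_set`.
#' @return List with `r`, `p_value`, `r_signed`, `p_signed`, `n`;
#'   `r = NA` with `undefined = TRUE` when either vector has zero
#'   variance.
#' @export
maf_effect_correlation <- function(C) {
  if (nrow(C) < 3) stopf("need >= 3 candidates")
  eff <- abs(C$beta)
  if (stats::sd(C$maf) == 0 || stats::sd(eff) == 0)
    return(list(r = NA_real_, p_value = NA_real_, r_signed = NA_real_,
                p_signed = NA_real_, n = nrow(C), undefined = TRUE))
  ct <- stats::cor.test(C$maf, eff)
  cs <- stats::cor.test(C$maf, C$beta)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       r_signed = unname(cs$estimate), p_signed = cs$p.value,
       n = nrow(C), undefined = FALSE)
}

#' Count variants in the standard MAF bins
#'
#' Bins are \[0.02, 0.05), \[0.05, 0.10) and \[0.10, 0.5\] — the 2-5\%,
#' 5-10\% and >10\% classes. The bins exhaustively cover \[0.02, 0.5\];
#' a MAF below 0.02 indicates a violated variant filter and is an error.
#'
#' @param maf numeric vector of MAFs, or a data frame with a `maf` column
#'   (e.g. a `candidate_set`).
#' @return Named integer vector of counts summing to `length(maf)`.
#' @export
maf_bins <- function(maf) {
  if (is.data.frame(maf)) maf <- maf$maf
  if (any(is.na(maf))) stopf("MAF contains NA")
  if (any(maf < 0.02)) stopf("MAF below 0.02 present; variant filter violated")
  if (any(maf > 0.5)) stopf("MAF above 0.5 present")
  counts <- c(sum(maf < 0.05), sum(maf >= 0.05 & maf < 0.10),
              sum(maf >= 0.10))
  stats::setNames(as.integer(counts), c("2-5%", "5-10%", ">10%"))
}

#' One-way F test for differences in candidate MAF among traits
#'
#' Reproduces the fixed-effects one-way ANOVA comparing mean candidate MAF
#' across traits, using the per-trait candidate MAF lists as given.
#'
#' @param maf_by_trait named list of per-trait candidate MAF vectors.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
candidate_maf_anova <- function(maf_by_trait) {
  if (length(maf_by_trait) < 2) stopf("need >= 2 traits")
  d <- data.frame(maf = unlist(maf_by_trait, use.names = FALSE),
                  trait = rep(names(maf_by_trait),
                              lengths(maf_by_trait)))
  ow <- stats::oneway.test(maf ~ trait, data = d, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p_value = ow$p.value)
}

#' Two-sample permutation test comparing candidate MAF with the genome
#'
#' Tests whether the mean MAF of candidate SNPs differs from the
#' genome-wide mean by permuting group labels over the pooled MAFs.
#'
#' @param candidate_maf candidate MAF vector.
#' @param genome_maf genome-wide MAF vector.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `observed_diff` (candidate minus genome mean) and
#'   `p_value` (two-sided, with the +1 correction).
#' @export
candidate_maf_test <- function(candidate_maf, genome_maf, n_perm = 999,
                               seed = 1) {
  pool <- c(candidate_maf, genome_maf)
  n1 <- length(candidate_maf)
  obs <- mean(candidate_maf) - mean(genome_maf)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(length(pool), n1)
      abs(mean(pool[pick]) - mean(pool[-pick])) >= abs(obs) - 1e-15
    }, logical(1)))
  })
  list(observed_diff = obs, p_value = (1 + exceed) / (n_perm + 1))
}

#' Assign each candidate SNP to a gene
#'
#' A SNP inside a gene interval tags that gene; an intergenic SNP tags the
#' nearest gene on the same chromosome (distance to the closest interval
#' boundary, 0 inside). Equidistant ties resolve to the gene with the
#' smaller start coordinate and are flagged. Gene intervals are 0-based
#' half-open; SNP positions are 1-based.
#'
#' @param C a `candidate_set` (or any data frame with `id`, `chrom`,
#'   `pos`).
#' @param A gene annotation: data frame with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @return Data frame: `id`, `chrom`, `pos`, `gene_id` (`NA` when the
#'   chromosome has no genes), `distance`, `tie`, `unassigned`.
#' @export
tag_genes <- function(C, A) {
  res <- data.frame(id = C$id, chrom = C$chrom, pos = C$pos,
                    gene_id = NA_character_, distance = NA_real_,
                    tie = FALSE, unassigned = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(C))) {
    g <- A[A$chrom == C$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) { res$unassigned[i] <- TRUE; next }
    d <- snp_gene_distance(C$pos[i], g$start, g$end)
    dm <- min(d)
    hits <- which(d == dm)
    if (length(hits) > 1) {
      res$tie[i] <- TRUE
      hits <- hits[which.min(g$start[hits])]
    }
    res$gene_id[i] <- g$gene_id[hits]
    res$distance[i] <- dm
  }
  res
}

# Distance from a 1-based SNP position to 0-based half-open gene
# intervals: 0 inside, else the gap to the nearest boundary base.
snp_gene_distance <- function(pos, start, end) {
  p0 <- pos - 1
  ifelse(p0 >= start & p0 < end, 0,
         ifelse(p0 < start, start - p0, p0 - (end - 1)))
}

#' Candidate SNPs within a window of named genes
#'
#' Reports every (candidate, named gene) pair whose distance is at most
#' `window` bp (distance 0 inside the gene); a SNP inside two genes'
#' windows is reported for both.
#'
#' @param C a `candidate_set`.
#' @param named annotation data frame of named genes (`gene_id`, `chrom`,
#'   `start`, `end`, optional `name`).
#' @param window distance threshold in bp (default 10,000; inclusive).
#' @return Data frame: `id`, `gene_id`, `name` (if present), `distance`.
#' @export
named_gene_hits <- function(C, named, window = 10000) {
  out <- list()
  for (i in seq_len(nrow(C))) {
    g <- named[named$chrom == C$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- snp_gene_distance(C$pos[i], g$start, g$end)
    hit <- d <= window
    if (any(hit))
      out[[length(out) + 1]] <- data.frame(
        id = C$id[i], gene_id = g$gene_id[hit],
        name = if ("name" %in% names(g)) g$name[hit] else NA_character_,
        distance = d[hit], stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id = character(), gene_id = character(),
                  name = character(), distance = numeric())
}

#' Which genes are nodule- or root-specific?
#'
#' A gene is "specific" iff it is expressed in nodule and/or root and in
#' no other assayed tissue.
#'
#' @param E expression profile: long data frame `gene_id`, `tissue`,
#'   `expressed`.
#' @return Named logical vector over genes.
#' @export
nodule_root_specific <- function(E) {
  tis <- unique(E$tissue)
  if (!all(c("nodule", "root") %in% tis) || length(tis) < 3)
    stopf("expression profile must assay nodule, root and >= 1 other tissue")
  wide <- tapply(E$expressed, list(E$gene_id, E$tissue), max)
  in_nr <- rowSums(wide[, c("nodule", "root"), drop = FALSE],
                   na.rm = TRUE) > 0
  other <- setdiff(colnames(wide), c("nodule", "root"))
  in_other <- rowSums(wide[, other, drop = FALSE], na.rm = TRUE) > 0
  in_nr & !in_other
}

#' Hypergeometric enrichment of tissue-specific genes among candidates
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realized number of nodule/root-specific genes among the candidate-
#' tagged genes, drawing without replacement from a universe of
#' `universe_size` genes of which `universe_specific` are specific.
#'
#' @param tagged_genes character vector of candidate-tagged gene ids.
#' @param E expression profile (see [nodule_root_specific()]), or a named
#'   logical vector of specificity flags.
#' @param universe_size number of genes in the expression universe.
#' @param universe_specific number of specific genes in the universe.
#' @return List with `observed`, `sample_size`, `universe_size`,
#'   `universe_specific`, `p_value` (P(X >= observed)).
#' @export
specificity_enrichment <- function(tagged_genes, E, universe_size,
                                   universe_specific) {
  if (universe_specific > universe_size)
    stopf("universe_specific exceeds universe_size")
  tagged_genes <- unique(tagged_genes)
  if (length(tagged_genes) > universe_size)
    stopf("sample size exceeds universe_size")
  spec <- if (is.logical(E)) E else nodule_root_specific(E)
  known <- tagged_genes %in% names(spec)
  if (!all(known))
    stopf("gene(s) absent from the expression profile: %s",
          paste(utils::head(tagged_genes[!known], 3), collapse = ", "))
  observed <- sum(spec[tagged_genes])
  if (observed > universe_specific)
    stopf("observed specific count exceeds universe_specific")
  p <- hypergeom_tail(observed, universe_size, universe_specific,
                      length(tagged_genes))
  list(observed = observed, sample_size = length(tagged_genes),
       universe_size = universe_size, universe_specific = universe_specific,
       p_value = p)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= q) for X hypergeometric with population `N`, `K` successes and
#' sample size `n`.
#'
#' @param q observed success count.
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(q, N, K, n) {
  stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
}
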