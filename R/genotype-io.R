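#' Construct a genotype matrix for inbred accessions
#'
#' Genotypes of selfed (inbred) accessions are haploid-coded: each call is
#' 0 (reference allele), 1 (alternate allele) or `NA` (missing). No
#' heterozygote code exists anywhere in the package.
#'
#' @param calls integer/numeric matrix, accessions in rows, variants in
#'   columns; entries in \{0, 1, NA\}.
#' @param variants data frame with one row per variant and columns
#'   `id`, `chrom`, `pos` (1-based bp), `ref`, `alt`; rows must be sorted by
#'   (chrom, pos).
#' @param accession_ids character vector of unique accession labels.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants` (gains `maf` and `n_called` columns, see
#'   [compute_maf()]) and `accession_ids`.
#' @seealso [read_genotypes()], [compute_maf()], [filter_variants()]
#' @export
genotype_matrix <- function(calls, variants, accession_ids) {
  calls <- as.matrix(calls)
  if (nrow(calls) != length(accession_ids))
    stopf("calls has %d rows but %d accession ids", nrow(calls),
          length(accession_ids))
  if (ncol(calls) != nrow(variants))
    stopf("calls has %d columns but %d variants", ncol(calls),
          nrow(variants))
  if (anyDuplicated(accession_ids))
    stopf("accession ids are not unique")
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad))
    stopf("genotype calls must be 0, 1 or NA (found %s)",
          paste(unique(calls[bad]), collapse = ", "))
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stopf("variant table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(variants$pos < 1)) stopf("variant positions must be >= 1")
  if (anyDuplicated(variants$id)) stopf("variant ids are not unique")
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(calls) <- list(accession_ids, variants$id)
  g <- list(calls = calls, variants = variants,
            accession_ids = as.character(accession_ids))
  class(g) <- "genotype_matrix"
  compute_maf(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d variants (%d chromosome%s)\n",
              length(x$accession_ids), nrow(x$variants),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1) "" else "s"))
  if (nrow(x$variants)) {
    m <- x$variants$maf
    cat(sprintf("  MAF: mean %.3f, median %.3f; missing calls: %.1f%%\n",
                mean(m, na.rm = TRUE), stats::median(m, na.rm = TRUE),
                100 * mean(is.na(x$calls))))
  }
  invisible(x)
}

#' Read genotypes from VCF or rectangular TSV
#'
#' Accepts haploid (`0`, `1`, `.`) or homozygous-diploid (`0/0`, `1/1`,
#' `./.`, phased or unphased) genotype fields. A heterozygous call or a
#' multi-allelic record violates the inbred-lines contract and raises an
#' error that cites the offending record.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`. The TSV dialect is tab-separated with a
#'   header row: columns `chrom`, `pos`, `ref`, `alt` followed by one column
#'   per accession, values 0/1/NA.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stopf("multi-allelic record at %s:%s (only biallelic SNPs are supported)",
          fix[which(multi)[1], "CHROM"], fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  codes <- decode_gt(gt, fix)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(codes), variants, colnames(gt))
}

decode_gt <- function(gt, fix) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- c("0" = 0, "0/0" = 0, "0|0" = 0,
           "1" = 1, "1/1" = 1, "1|1" = 1)
  missing_codes <- c(".", "./.", ".|.")
  unknown <- setdiff(u, c(names(map), missing_codes))
  if (length(unknown)) {
    bad <- which(gt == unknown[1], arr.ind = TRUE)[1, ]
    stopf(paste0("genotype '%s' at %s:%s (accession %s) is not a homozygous",
                 " or missing call; inbred lines admit no heterozygotes"),
          unknown[1], fix[bad[1], "CHROM"], fix[bad[1], "POS"],
          colnames(gt)[bad[2]])
  }
  codes <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (k in names(map)) codes[gt == k] <- map[[k]]
  codes
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stopf("genotype TSV must start with columns chrom, pos, ref, alt")
  acc <- setdiff(names(tab), c("id", need))
  calls <- t(as.matrix(tab[, acc, drop = FALSE]))
  ids <- if ("id" %in% names(tab)) tab$id else paste0(tab$chrom, "_", tab$pos)
  variants <- data.frame(id = ids, chrom = tab$chrom, pos = as.integer(tab$pos),
                         ref = tab$ref, alt = tab$alt, stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, acc)
}

#' Write genotypes as VCF or rectangular TSV
#'
#' VCF output uses haploid GT fields (`0`, `1`, `.` for missing), the
#' natural representation for fully inbred material. `write_genotypes`
#' followed by [read_genotypes()] reproduces the calls exactly.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  v <- G$variants
  if (format == "vcf") {
    gt <- ifelse(is.na(G$calls), ".", as.character(G$calls))
    body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                  "GT", t(gt))
    lines <- c("##fileformat=VCFv4.2",
               "##source=seqgwas",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$accession_ids), collapse = "\t"),
               apply(body, 1, paste, collapse = "\t"))
    writeLines(lines, path)
  } else {
    tab <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref,
                      alt = v$alt, t(G$calls), check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("id", "chrom", "pos", "ref", "alt", G$accession_ids)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Compute minor allele frequency and call counts per variant
#'
#' MAF is the frequency of the rarer allele, computed over called
#' (non-missing) genotypes only, so it lies in \[0, 0.5\]. Variants with no
#' calls at all get `maf = NA` (an undefined flag removed by
#' [filter_variants()]).
#'
#' @param G a [genotype_matrix()].
#' @return `G` with `variants$maf` and `variants$n_called` refreshed.
#' @export
compute_maf <- function(G) {
  n_called <- colSums(!is.na(G$calls))
  alt <- colSums(G$calls, na.rm = TRUE)
  f_alt <- ifelse(n_called > 0, alt / n_called, NA_real_)
  G$variants$maf <- pmin(f_alt, 1 - f_alt)
  G$variants$n_called <- as.integer(n_called)
  G
}

#' Apply the variant inclusion filters
#'
#' Retains variants scored in at least `min_called` accessions with minor
#' allele frequency of at least `min_maf` (both bounds inclusive). The
#' defaults are the standard inclusion rules for a deeply resequenced
#' association panel: MAF >= 0.02 and calls in >= 100 accessions. Variant
#' order is preserved and filtering is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param min_maf minimum minor allele frequency (inclusive).
#' @param min_called minimum number of non-missing calls (inclusive).
#' @return The filtered [genotype_matrix()].
#' @export
filter_variants <- function(G, min_maf = 0.02, min_called = 100) {
  check_prob(min_maf, "min_maf", 0, 0.5)
  if (min_called > length(G$accession_ids))
    stopf("min_called (%d) exceeds the number of accessions (%d)",
          min_called, length(G$accession_ids))
  v <- G$variants
  keep <- !is.na(v$maf) & v$maf >= min_maf & v$n_called >= min_called
  G$calls <- G$calls[, keep, drop = FALSE]
  G$variants <- v[keep, , drop = FALSE]
  rownames(G$variants) <- NULL
  G
}

# Subset a genotype matrix to a set of variant ids (order preserved as in G).
subset_variants <- function(G, ids) {
  keep <- G$variants$id %in% ids
  G$calls <- G$calls[, keep, drop = FALSE]
  G$variants <- G$variants[keep, , drop = FALSE]
  rownames(G$variants) <- NULL
  G
}
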