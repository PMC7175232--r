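# Per-gene nucleotide diversity in the VariScan style: unbiased per-site
# heterozygosity summed over segregating sites, with impact-based filtering
# and cross-gene co-occurrence of deleterious variants.

#' Unbiased per-site heterozygosity
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with allele
#' frequencies \eqn{p_i} from haploid allele counts. This is the per-site
#' term whose sum over segregating sites equals the mean number of pairwise
#' differences among the sampled haplotypes.
#'
#' @param counts Named integer vector of allele counts at one site, or a
#'   single row of a `variant_sites` data frame.
#' @return Numeric heterozygosity in `[0, 1]`.
#' @export
site_heterozygosity <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$allele_counts[[1]]
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < 2) stop("site heterozygosity needs n >= 2 called samples (got ", n, ")")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

.dedupe_sites <- function(sites) {
  # multiallelic decomposition shares (chrom, pos); keep one row per site
  key <- paste(sites$chrom, sites$pos)
  sites[!duplicated(key), , drop = FALSE]
}

#' Per-gene nucleotide diversity
#'
#' Sums unbiased per-site heterozygosity over the segregating sites of a gene
#' and normalizes either by the interval length in bp (`per_site`, the
#' classical \eqn{\pi}) or by the number of segregating sites
#' (`per_segregating_site`). The normalization has no default and both values
#' differ by orders of magnitude, so the choice is always explicit. Sites
#' with fewer than 2 called samples are excluded and logged. Multiallelic
#' per-ALT rows at the same position count as one site.
#'
#' @param sites `variant_sites` data frame (possibly empty).
#' @param L Interval length in bp.
#' @param normalization `"per_site"` or `"per_segregating_site"` (mandatory).
#' @param gene_id Optional label carried into the result.
#' @return Object of class `diversity_result`: `gene_id`, `n_snps`, `pi`,
#'   `normalization`, `L`, `n_min`, `n_max`, `h_sum`.
#' @export
pi_gene <- function(sites, L, normalization, gene_id = NA_character_) {
  if (missing(normalization)) {
    stop("'normalization' is mandatory: choose \"per_site\" or \"per_segregating_site\"")
  }
  normalization <- match.arg(normalization,
                             c("per_site", "per_segregating_site"))
  if (is.null(gene_id)) gene_id <- NA_character_
  if (L <= 0) stop("interval length L must be positive")
  u <- .dedupe_sites(sites)
  low_n <- u$n < 2
  if (any(low_n)) {
    message("pi_gene: excluded ", sum(low_n), " site(s) with n < 2")
    u <- u[!low_n, , drop = FALSE]
  }
  h <- if (nrow(u) == 0) numeric(0) else
    vapply(u$allele_counts, function(ct) site_heterozygosity(ct), numeric(1))
  h_sum <- sum(h)
  n_snps <- nrow(u)
  pi <- if (normalization == "per_site") {
    h_sum / L
  } else if (n_snps == 0) {
    NA_real_
  } else {
    h_sum / n_snps
  }
  structure(list(gene_id = gene_id, n_snps = n_snps, pi = pi,
                 normalization = normalization, L = L,
                 n_min = if (n_snps) min(u$n) else NA_integer_,
                 n_max = if (n_snps) max(u$n) else NA_integer_,
                 h_sum = h_sum),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Nucleotide diversity%s: pi = %s (%s), %d SNPs over %d bp\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              ifelse(is.na(x$pi), "NA", format(x$pi, digits = 6)),
              x$normalization, x$n_snps, x$L))
  invisible(x)
}

#' Filter variant sites by SnpEff impact class
#'
#' Keeps sites whose impact is in `keep` (default the MODERATE + HIGH filter
#' used to isolate protein-affecting SNPs: missense, frameshift, premature
#' stop). Sites with `impact == "unknown"` are dropped and logged.
#'
#' @param sites `variant_sites` data frame.
#' @param keep Character vector of impact classes to retain.
#' @return Filtered data frame, input order preserved.
#' @export
filter_by_impact <- function(sites, keep = c("MODERATE", "HIGH")) {
  unknown <- sites$impact == "unknown" & !"unknown" %in% keep
  if (any(unknown)) {
    message("filter_by_impact: dropped ", sum(unknown),
            " site(s) with unknown impact")
  }
  sites[sites$impact %in% keep, , drop = FALSE]
}

#' Summarize variant effects for a gene
#'
#' @param sites Annotated `variant_sites`.
#' @param gene_id Optional label.
#' @return List of class `impact_summary`: per-class counts,
#'   `n_nonsynonymous` (missense effects), `n_nonsense_or_frameshift`
#'   (stop-gain/stop-loss/frameshift effects), `n_deleterious`.
#' @export
effect_summary <- function(sites, gene_id = NA_character_) {
  if (is.null(gene_id)) gene_id <- NA_character_
  u <- sites
  lv <- c("HIGH", "MODERATE", "LOW", "MODIFIER", "unknown")
  imp <- factor(ifelse(u$impact %in% lv, u$impact, "unknown"), levels = lv)
  eff <- ifelse(is.na(u$effect), "", u$effect)
  structure(list(
    gene_id = gene_id,
    n_total = nrow(u),
    impact_counts = c(table(imp)),
    n_nonsynonymous = sum(grepl("missense", eff)),
    n_nonsense_or_frameshift = sum(grepl("stop_gained|stop_lost|frameshift", eff)),
    n_deleterious = sum(u$deleterious, na.rm = TRUE)
  ), class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  cat(sprintf("Impact summary%s: %d variants\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$n_total))
  print(x$impact_counts)
  cat("  non-synonymous:", x$n_nonsynonymous,
      "| nonsense/frameshift:", x$n_nonsense_or_frameshift,
      "| deleterious:", x$n_deleterious, "\n")
  invisible(x)
}

#' Do any accessions carry deleterious variants in both genes?
#'
#' @param mat_a,mat_b Accession-by-variant 0/1 matrices (from
#'   [genotype_matrix()]) restricted to each gene's deleterious variants;
#'   rownames are accession ids and must agree between the two.
#' @return List: `any_shared` and the offending `accessions`.
#' @export
shared_deleterious <- function(mat_a, mat_b) {
  if (is.null(rownames(mat_a)) || is.null(rownames(mat_b)) ||
      !setequal(rownames(mat_a), rownames(mat_b))) {
    stop("accession sets of the two matrices differ")
  }
  carriers <- function(m) {
    rownames(m)[rowSums(m == 1, na.rm = TRUE) > 0]
  }
  shared <- intersect(carriers(mat_a), carriers(mat_b))
  list(any_shared = length(shared) > 0, accessions = shared)
}
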