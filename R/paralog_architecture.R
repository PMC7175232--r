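# Tandem-duplication architecture: physical distances between paralog pairs,
# the naive <2.5 kb tandem rule, and per-species copy-number tabulation.

#' Physical distances between two gene models
#'
#' For genes on the same chromosome the intergenic gap is
#' `max(0, max(start_a, start_b) - min(end_a, end_b) - 1)` (0 when the genes
#' overlap) and the start-to-start distance is `|start_a - start_b|`. Both are
#' reported because "physical distance" between genes has no single standard
#' definition. For genes on different chromosomes the distances are NA.
#'
#' @param a,b Gene models: lists or one-row data frames with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return List with `gap_bp`, `start_to_start_bp`, `same_chrom`.
#' @export
pair_distance <- function(a, b) {
  same <- as.character(a$chrom) == as.character(b$chrom)
  if (!same) {
    return(list(gap_bp = NA_integer_, start_to_start_bp = NA_integer_,
                same_chrom = FALSE))
  }
  gap <- max(0L, max(a$start, b$start) - min(a$end, b$end) - 1L)
  list(gap_bp = as.integer(gap),
       start_to_start_bp = as.integer(abs(a$start - b$start)),
       same_chrom = TRUE)
}

#' Classify a paralog pair as a tandem duplication
#'
#' The naive rule: tandem iff the two genes lie on the same chromosome at a
#' physical distance strictly below `threshold_bp` (default 2500 bp). The
#' distance metric is selectable; the intergenic gap is the default.
#'
#' @param pair Result of [pair_distance()].
#' @param threshold_bp Strict upper bound in bp.
#' @param metric `"gap"` (intergenic distance) or `"start_to_start"`.
#' @return Logical.
#' @export
classify_tandem <- function(pair, threshold_bp = 2500,
                            metric = c("gap", "start_to_start")) {
  metric <- match.arg(metric)
  if (!isTRUE(pair$same_chrom)) return(FALSE)
  d <- if (metric == "gap") pair$gap_bp else pair$start_to_start_bp
  !is.na(d) && d < threshold_bp
}

#' Distance and tandem classification for a table of paralog pairs
#'
#' @param genes Gene models from [read_gff3()].
#' @param relations Relation table with columns `gene_a`, `gene_b` (and
#'   optionally `species`, `relation`); only rows with `relation == "paralog"`
#'   are used when the column is present.
#' @param threshold_bp,metric Passed to [classify_tandem()].
#' @return `data.frame`: one row per pair with `gap_bp`, `start_to_start_bp`,
#'   `same_chrom`, `is_tandem`.
#' @export
tandem_scan <- function(genes, relations, threshold_bp = 2500,
                        metric = c("gap", "start_to_start")) {
  metric <- match.arg(metric)
  if ("relation" %in% names(relations)) {
    relations <- relations[relations$relation == "paralog", , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(relations)), function(i) {
    ga <- genes[genes$gene_id == relations$gene_a[i], , drop = FALSE]
    gb <- genes[genes$gene_id == relations$gene_b[i], , drop = FALSE]
    if (nrow(ga) != 1 || nrow(gb) != 1) {
      stop("pair (", relations$gene_a[i], ", ", relations$gene_b[i],
           "): gene id not resolvable against gene models")
    }
    pd <- pair_distance(ga, gb)
    data.frame(gene_a = relations$gene_a[i], gene_b = relations$gene_b[i],
               gap_bp = pd$gap_bp, start_to_start_bp = pd$start_to_start_bp,
               same_chrom = pd$same_chrom,
               is_tandem = classify_tandem(pd, threshold_bp, metric),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-species paralog copy numbers
#'
#' Counts the distinct genes each species contributes to the family's
#' relation table; a species listed with a single gene and no paralog partner
#' has one copy. Rows may carry `gene_b = NA` to declare singletons.
#'
#' @param relations `data.frame` with columns `species`, `gene_a`, `gene_b`.
#' @return `data.frame` (`species`, `n_copies`), one row per species, plus a
#'   `histogram` attribute tabulating species per copy number.
#' @export
copy_number_table <- function(relations) {
  stopifnot(all(c("species", "gene_a") %in% names(relations)))
  long <- rbind(
    data.frame(species = relations$species, gene = relations$gene_a,
               stringsAsFactors = FALSE),
    if ("gene_b" %in% names(relations)) {
      data.frame(species = relations$species, gene = relations$gene_b,
                 stringsAsFactors = FALSE)
    }
  )
  long <- long[!is.na(long$gene) & long$gene != "", , drop = FALSE]
  dup <- tapply(long$species, long$gene, function(s) length(unique(s)))
  if (any(dup > 1)) {
    stop("gene '", names(dup)[dup > 1][1],
         "' is assigned to more than one species: inconsistent group membership")
  }
  counts <- tapply(long$gene, long$species, function(g) length(unique(g)))
  out <- data.frame(species = names(counts), n_copies = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "histogram") <- table(out$n_copies)
  out
}

#' Summary statistics of tandem-pair distances
#'
#' @param pairs Output of [tandem_scan()] (or any data frame with the chosen
#'   metric column and `is_tandem`).
#' @param metric `"gap"` or `"start_to_start"`.
#' @return List with `mean_bp`, `min_bp`, `max_bp`, `n_pairs`.
#' @export
tandem_distance_stats <- function(pairs, metric = c("gap", "start_to_start")) {
  metric <- match.arg(metric)
  col <- if (metric == "gap") "gap_bp" else "start_to_start_bp"
  d <- pairs[[col]][pairs$is_tandem]
  if (length(d) == 0) stop("no tandem pairs to summarize")
  list(mean_bp = mean(d), min_bp = min(d), max_bp = max(d),
       n_pairs = length(d))
}
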