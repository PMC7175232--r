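# Readers and writers for the standard formats the pipeline touches. All
# coordinates on the public interface are 1-based inclusive (GFF3/VCF
# convention).

#' Read a FASTA file
#'
#' Thin wrapper over Biostrings that validates the alphabet against the
#' requested molecule type and, for coding sequences, checks that each
#' ungapped sequence length is divisible by 3.
#'
#' @param path FASTA file.
#' @param moltype `"nt"` for nucleotide, `"aa"` for protein.
#' @param is_cds For `moltype = "nt"`, require in-frame coding sequences.
#' @return A `DNAStringSet` or `AAStringSet`, record order preserved.
#' @export
read_fasta <- function(path, moltype = c("nt", "aa"), is_cds = FALSE) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw strings first: DNAStringSet would silently drop letters
  # outside its alphabet instead of raising a parse error
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (moltype == "nt" && length(raw) > 0) {
    bad <- grepl("[^ACGTN-]", toupper(as.character(raw)))
    if (any(bad)) {
      stop("record '", names(raw)[bad][1],
           "' contains characters outside {A,C,G,T,N,-}")
    }
  }
  seqs <- if (moltype == "nt") {
    Biostrings::DNAStringSet(raw)
  } else {
    Biostrings::AAStringSet(raw)
  }
  if (moltype == "nt" && length(seqs) > 0) {
    if (is_cds) {
      ungapped <- gsub("-", "", as.character(seqs), fixed = TRUE)
      off <- nchar(ungapped) %% 3 != 0
      if (any(off)) {
        stop("CDS record '", names(seqs)[off][1],
             "' has ungapped length not divisible by 3")
      }
    }
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector or `XStringSet`.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file with rtracklayer and returns one row per feature of the
#' requested type. Coordinates stay 1-based inclusive. Every returned feature
#' must carry an `ID` attribute.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (column 3), default `"gene"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  # pre-scan coordinate sanity so errors can name the offending line
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && s > e) {
        stop("GFF3 line ", i, ": start ", s, " > end ", e)
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    miss <- if (is.null(ids)) seq_along(gr) else which(is.na(ids))
    loc <- paste0(GenomicRanges::seqnames(gr)[miss[1]], ":",
                  GenomicRanges::start(gr)[miss[1]], "-",
                  GenomicRanges::end(gr)[miss[1]])
    stop("GFF3 feature without ID attribute at ", loc)
  }
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to GFF3
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path Output file.
#' @param source Value for GFF3 column 2.
#' @export
write_gff3 <- function(genes, path, source = "paralogdiv") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.split_gt_allele <- function(gt) {
  # haploid allele index per inbred accession; heterozygous and missing -> NA
  a <- sub("[/|].*$", "", gt)
  b <- sub("^[^/|]*[/|]?", "", gt)
  b[b == ""] <- a[b == ""]
  out <- suppressWarnings(as.integer(a))
  out[a != b] <- NA
  out[a == "." | b == "."] <- NA
  out
}

#' Read SNPs from a VCF interval
#'
#' Returns one record per SNP ALT allele inside `[start, end]` (1-based
#' inclusive) on `chrom`. Accessions are treated as haploid inbred lines: a
#' homozygous diploid genotype contributes one allele; heterozygous and
#' missing genotypes are excluded from the per-site sample size `n`. Indels
#' and other non-SNP records are skipped and counted. SnpEff `ANN`
#' annotations are parsed when present; the first annotation whose gene
#' name/ID matches `gene_id` (and, preferentially, whose allele matches the
#' record's ALT) supplies `effect` and `impact`, otherwise `impact =
#' "unknown"`. Multiallelic SNPs are decomposed into per-ALT rows that share
#' the same position and full allele-count vector, so a site is counted once.
#'
#' @param path VCF file (plain text or gzipped).
#' @param chrom,start,end Query interval, 1-based inclusive.
#' @param gene_id Gene whose ANN annotation should be selected, or NULL for
#'   the first annotation.
#' @param ann_field Parse `INFO/ANN` (default TRUE).
#' @return `data.frame` of class `variant_sites` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `n`, `effect`, `impact`, `deleterious` and a list column
#'   `allele_counts`; attributes `n_skipped_nonsnp` and `n_sites`.
#' @export
read_vcf_interval <- function(path, chrom, start, end, gene_id = NULL,
                              ann_field = TRUE) {
  if (end < start) stop("interval end (", end, ") < start (", start, ")")
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  keep <- fix[, "CHROM"] == chrom & pos >= start & pos <= end
  n_skipped <- 0L
  rows <- list()
  if (any(keep)) {
    gt <- vcfR::extract.gt(vcf)
    ann_all <- if (ann_field) vcfR::extract.info(vcf, element = "ANN") else NULL
    for (i in which(keep)) {
      ref <- fix[i, "REF"]
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      if (nchar(ref) != 1 || !ref %in% .BASES ||
          !all(nchar(alts) == 1 & alts %in% .BASES)) {
        n_skipped <- n_skipped + 1L
        next
      }
      idx <- .split_gt_allele(gt[i, ])
      called <- idx[!is.na(idx)]
      if (length(called) == 0) next   # no called haploid genotypes at site
      alleles <- c(ref, alts)
      counts <- as.integer(table(factor(called, levels = 0:length(alts))))
      names(counts) <- alleles
      nn <- sum(counts)
      anns <- if (!is.null(ann_all) && !is.na(ann_all[i])) {
        strsplit(strsplit(ann_all[i], ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
      } else list()
      for (alt in alts) {
        eff <- NA_character_; imp <- "unknown"
        pick <- NULL
        if (length(anns) > 0) {
          gene_ok <- vapply(anns, function(a) {
            is.null(gene_id) ||
              (length(a) >= 4 && a[4] == gene_id) ||
              (length(a) >= 5 && a[5] == gene_id)
          }, logical(1))
          allele_ok <- vapply(anns, function(a) length(a) >= 1 && a[1] == alt,
                              logical(1))
          if (any(gene_ok & allele_ok)) pick <- anns[[which(gene_ok & allele_ok)[1]]]
          else if (any(gene_ok)) pick <- anns[[which(gene_ok)[1]]]
        }
        if (!is.null(pick) && length(pick) >= 3) {
          eff <- pick[2]; imp <- pick[3]
        }
        rows[[length(rows) + 1L]] <- list(
          chrom = chrom, pos = pos[i], ref = ref, alt = alt, n = nn,
          effect = eff, impact = imp, counts = counts)
      }
    }
  }
  df <- if (length(rows) == 0) {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), n = integer(0), effect = character(0),
               impact = character(0), deleterious = logical(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      chrom = vapply(rows, `[[`, character(1), "chrom"),
      pos = vapply(rows, `[[`, integer(1), "pos"),
      ref = vapply(rows, `[[`, character(1), "ref"),
      alt = vapply(rows, `[[`, character(1), "alt"),
      n = vapply(rows, `[[`, integer(1), "n"),
      effect = vapply(rows, `[[`, character(1), "effect"),
      impact = vapply(rows, `[[`, character(1), "impact"),
      deleterious = NA,
      stringsAsFactors = FALSE
    )
  }
  df$allele_counts <- I(lapply(rows, `[[`, "counts"))
  if (n_skipped > 0) {
    message("read_vcf_interval: skipped ", n_skipped, " non-SNP record(s)")
  }
  attr(df, "n_skipped_nonsnp") <- n_skipped
  attr(df, "n_sites") <- length(unique(df$pos))
  class(df) <- c("variant_sites", class(df))
  df
}

#' Per-accession presence matrix for ALT alleles in a VCF interval
#'
#' Builds the 0/1 accession-by-variant matrix needed to ask whether any
#' accession carries variants in two genes simultaneously. An entry is 1 when
#' the accession's (haploid) call is any ALT allele, 0 for REF, NA for
#' missing or heterozygous calls.
#'
#' @inheritParams read_vcf_interval
#' @param positions Optional subset of positions to keep.
#' @return Integer matrix, accessions x variants (columns named by position).
#' @export
genotype_matrix <- function(path, chrom, start, end, positions = NULL) {
  if (end < start) stop("interval end < start")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  keep <- fix[, "CHROM"] == chrom & pos >= start & pos <= end
  if (!is.null(positions)) keep <- keep & pos %in% positions
  gt <- vcfR::extract.gt(vcf)
  m <- matrix(NA_integer_, nrow = ncol(gt), ncol = sum(keep),
              dimnames = list(colnames(gt), pos[keep]))
  for (j in seq_len(sum(keep))) {
    idx <- .split_gt_allele(gt[which(keep)[j], ])
    m[, j] <- ifelse(is.na(idx), NA_integer_, as.integer(idx > 0))
  }
  m
}

#' Write a homogeneous table as TSV
#' @param rows `data.frame`.
#' @param path Output file.
#' @export
write_report <- function(rows, path) {
  df <- as.data.frame(rows)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#' @param path TSV file.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a deleteriousness call table
#'
#' A TSV with columns `chrom`, `pos`, `alt`, `deleterious` (0/1), as produced
#' by an external protein-effect predictor, consumed as-is.
#'
#' @param path TSV file.
#' @export
read_deleterious_tsv <- function(path) {
  # allele columns like "T" must not be type-converted to logical
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         alt = "character"))
  need <- c("chrom", "pos", "alt", "deleterious")
  if (!all(need %in% names(df))) {
    stop("deleteriousness table must have columns: ", paste(need, collapse = ", "))
  }
  df$deleterious <- as.logical(as.integer(df$deleterious))
  df
}

#' Attach deleteriousness calls to variant sites
#' @param sites `variant_sites` data frame.
#' @param calls Table from [read_deleterious_tsv()].
#' @return `sites` with its `deleterious` column filled (NA where no call).
#' @export
apply_deleterious <- function(sites, calls) {
  key <- paste(sites$chrom, sites$pos, sites$alt)
  ck <- paste(calls$chrom, calls$pos, calls$alt)
  sites$deleterious <- calls$deleterious[match(key, ck)]
  sites
}
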