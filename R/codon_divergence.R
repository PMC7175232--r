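# Pairwise divergence of coding sequences: codon-threaded alignment, fourfold
# degenerate transversion distance (4DTv) and Nei-Gojobori (1986) Ka/Ks.

#' Construct and validate a pairwise codon alignment
#'
#' A codon alignment holds two aligned, in-frame coding sequences in which
#' gaps occur only as whole codons (`"---"`). It is the substrate for
#' [fourDTv()], [ng86_kaks()] and [pairwise_identity()].
#'
#' @param row_a,row_b Aligned nucleotide strings over `{A,C,G,T,N,-}`, equal
#'   length, divisible by 3.
#' @return An object of class `codon_alignment`: a list with elements `rows`
#'   (character vector of length 2) and `n_codons`.
#' @examples
#' codon_alignment("ATGGCT", "ATGGCA")
#' @export
codon_alignment <- function(row_a, row_b) {
  rows <- toupper(c(row_a, row_b))
  if (nchar(rows[1]) != nchar(rows[2])) {
    stop("alignment rows differ in length (", nchar(rows[1]), " vs ",
         nchar(rows[2]), ")")
  }
  if (nchar(rows[1]) %% 3 != 0) {
    stop("alignment length ", nchar(rows[1]), " is not divisible by 3")
  }
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad)) stop("alignment row ", which(bad)[1], " contains characters outside {A,C,G,T,N,-}")
  gc <- .genetic_code()
  for (r in 1:2) {
    cods <- .split_codons(rows[r])
    has_gap <- grepl("-", cods, fixed = TRUE)
    if (any(has_gap & cods != "---")) {
      stop("row ", r, ": gaps must occupy whole codons ('---'); offending codon '",
           cods[has_gap & cods != "---"][1], "'")
    }
    plain <- cods[!has_gap & !grepl("N", cods)]
    # terminal stops must be trimmed before alignment
    if (any(gc[plain] == "*", na.rm = TRUE)) {
      stop("row ", r, " contains a stop codon within the alignment")
    }
  }
  structure(list(rows = rows, n_codons = nchar(rows[1]) %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", x$n_codons, "codon columns\n")
  for (r in x$rows) {
    if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
    cat(" ", r, "\n")
  }
  invisible(x)
}

#' Thread a protein alignment back onto coding sequences
#'
#' Replaces each aligned amino-acid residue by its source codon and each
#' alignment gap by a whole-codon gap, producing a codon-aware nucleotide
#' alignment without re-aligning at the nucleotide level (the pal2nal idiom).
#' A terminal stop codon on either CDS is tolerated and trimmed.
#'
#' @param prot_a,prot_b Aligned amino-acid strings (gaps as `-`), equal length.
#' @param cds_a,cds_b In-frame coding sequences whose translations equal the
#'   ungapped protein rows.
#' @return A [codon_alignment()].
#' @export
thread_codon_alignment <- function(prot_a, prot_b, cds_a, cds_b) {
  prot <- toupper(c(prot_a, prot_b))
  if (nchar(prot[1]) != nchar(prot[2])) {
    stop("protein alignment rows differ in length")
  }
  cds <- toupper(c(as.character(cds_a), as.character(cds_b)))
  gc <- .genetic_code()
  out <- character(2)
  for (r in 1:2) {
    if (nchar(cds[r]) %% 3 != 0) {
      stop("CDS ", r, " length ", nchar(cds[r]), " is not divisible by 3")
    }
    cods <- .split_codons(cds[r])
    aa <- gc[cods]
    aa[is.na(aa)] <- "X"          # codons containing N or other ambiguity
    if (length(aa) > 0 && aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
    }
    res <- strsplit(prot[r], "")[[1]]
    idx <- which(res != "-")
    if (length(idx) != length(aa)) {
      stop("CDS ", r, " encodes ", length(aa), " residues but protein row has ",
           length(idx))
    }
    mismatch <- which(aa != res[idx] & aa != "X" & res[idx] != "X")
    if (length(mismatch) > 0) {
      k <- mismatch[1]
      stop("translation of CDS ", r, " disagrees with protein row at residue ",
           k, " (", aa[k], " vs ", res[idx][k], ")")
    }
    cells <- rep("---", length(res))
    cells[idx] <- cods
    out[r] <- paste(cells, collapse = "")
  }
  codon_alignment(out[1], out[2])
}

#' Locate fourfold-degenerate sites in a codon alignment
#'
#' A codon column contributes one fourfold-degenerate (4D) site when neither
#' codon is a gap or contains an ambiguity, the two codons agree at positions
#' 1-2, and that shared dinucleotide prefix heads a fourfold-degenerate codon
#' family in the standard genetic code (CT, GT, TC, CC, AC, GC, CG, GG).
#' Requiring prefix agreement guarantees that any third-position difference is
#' synonymous in both sequence backgrounds.
#'
#' @param aln A [codon_alignment()].
#' @return Integer vector of third-position alignment column indices (1-based).
#' @export
identify_4d_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ca <- .split_codons(aln$rows[1])
  cb <- .split_codons(aln$rows[2])
  usable <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  pa <- substr(ca, 1, 2)
  ok <- usable & pa == substr(cb, 1, 2) & pa %in% .FOURFOLD_PREFIXES
  which(ok) * 3L
}

#' Fourfold-degenerate transversion distance (4DTv)
#'
#' Counts transversion differences (purine vs pyrimidine) at the
#' fourfold-degenerate third positions of a codon alignment. The raw value is
#' the transversion proportion Q; the corrected value applies a Kimura-type
#' multiple-hit correction for a transversion-only distance,
#' \eqn{-\frac{1}{2}\log(1 - 2Q)}. When Q >= 0.5 the correction is undefined
#' and the estimate is flagged as saturated. The correction is pluggable: pass
#' a function of Q to use an alternative.
#'
#' @param aln A [codon_alignment()].
#' @param correction `"k2p"` (default), `"none"`, or a function of the raw
#'   transversion proportion returning the corrected distance.
#' @return A list of class `fourdtv`: `n_4d_sites`, `n_4d_transversions`,
#'   `Q`, `fourDTv_raw`, `fourDTv_corrected` (NA when saturated), `saturated`.
#' @export
fourDTv <- function(aln, correction = "k2p") {
  stopifnot(inherits(aln, "codon_alignment"))
  sites <- identify_4d_sites(aln)
  if (length(sites) == 0) stop("no fourfold degenerate sites")
  b1 <- substring(aln$rows[1], sites, sites)
  b2 <- substring(aln$rows[2], sites, sites)
  tv <- (b1 %in% .PURINES) != (b2 %in% .PURINES)
  q <- sum(tv) / length(sites)
  corr_fun <- if (is.function(correction)) {
    correction
  } else if (identical(correction, "k2p")) {
    function(q) -0.5 * log(1 - 2 * q)
  } else if (identical(correction, "none")) {
    identity
  } else {
    stop("unknown correction '", correction, "'")
  }
  saturated <- !is.function(correction) && identical(correction, "k2p") && q >= 0.5
  corrected <- if (saturated) NA_real_ else corr_fun(q)
  structure(list(n_4d_sites = length(sites),
                 n_4d_transversions = sum(tv),
                 Q = q,
                 fourDTv_raw = q,
                 fourDTv_corrected = corrected,
                 saturated = saturated),
            class = "fourdtv")
}

#' @export
print.fourdtv <- function(x, ...) {
  cat("4DTv:", x$n_4d_transversions, "transversions /", x$n_4d_sites,
      "fourfold-degenerate sites\n")
  cat(sprintf("  raw = %.4f, corrected = %s%s\n", x$fourDTv_raw,
              ifelse(is.na(x$fourDTv_corrected), "NA",
                     sprintf("%.4f", x$fourDTv_corrected)),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Nei-Gojobori (1986) Ka/Ks for a pairwise codon alignment
#'
#' Synonymous site counts per codon are the fractions of single-nucleotide
#' changes that preserve the amino acid (changes to a stop codon count as
#' nonsynonymous), averaged over the two sequences; observed differences in
#' codons with more than one change are partitioned by equal-weight averaging
#' over all minimal substitution pathways, excluding pathways through stop
#' codons. The proportions ps = Sd/S and pn = Nd/N are corrected for multiple
#' hits with the Jukes-Cantor formula \eqn{d = -\frac{3}{4}\log(1 - 4p/3)}.
#' Codon columns containing a gap or an ambiguous base are excluded.
#'
#' @param aln A [codon_alignment()].
#' @return A list of class `ng86`: `Ka`, `Ks`, `omega` (NA when Ks = 0),
#'   `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `n_codons_used`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
ng86_kaks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- .codon_tables()
  ca <- .split_codons(aln$rows[1])
  cb <- .split_codons(aln$rows[2])
  use <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ca <- ca[use]; cb <- cb[use]
  if (length(ca) == 0) stop("no comparable codon columns")
  s_a <- sum(tabs$syn[ca]); s_b <- sum(tabs$syn[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  if (S == 0) stop("no synonymous sites in alignment")
  Sd <- sum(tabs$SD[cbind(ca, cb)])
  Nd <- sum(tabs$ND[cbind(ca, cb)])
  ps <- Sd / S
  pn <- Nd / N
  if (ps >= 0.75 || pn >= 0.75) {
    stop("substitution saturation: ps or pn >= 3/4, Jukes-Cantor correction undefined")
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps)
  Ka <- jc(pn)
  omega <- if (Ks == 0) NA_real_ else Ka / Ks
  structure(list(Ka = Ka, Ks = Ks, omega = omega, S = S, N = N, Sd = Sd,
                 Nd = Nd, ps = ps, pn = pn, n_codons_used = length(ca)),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f, Ks = %.4f, Ka/Ks = %s  (S = %.2f, N = %.2f, %d codons)\n",
              x$Ka, x$Ks,
              ifelse(is.na(x$omega), "NA", sprintf("%.4f", x$omega)),
              x$S, x$N, x$n_codons_used))
  invisible(x)
}

#' Percent identity of two aligned rows
#'
#' Matches divided by the number of columns where neither row has a gap,
#' times 100. Works for nucleotide and amino-acid rows alike.
#'
#' @param row_a,row_b Aligned strings of equal length.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(row_a, row_b) {
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b)) stop("rows differ in length")
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) stop("no comparable (gap-free) columns")
  100 * sum(a[comparable] == b[comparable]) / sum(comparable)
}

#' Classify a cohort of paralog pairs by corrected 4DTv
#'
#' Duplication-age classification used for paralog cohorts: corrected 4DTv
#' below `recent_lt` marks a recent duplication, above `ancient_gt` an ancient
#' one; saturated estimates (raw >= 0.5) are reported separately.
#'
#' @param alns List of [codon_alignment()] objects (or precomputed `fourdtv`
#'   results).
#' @param recent_lt,ancient_gt Class boundaries on the corrected distance.
#' @return List with a per-pair data frame (`estimates`) and a named count
#'   vector `counts` over `{recent, intermediate, ancient, saturated}`.
#' @export
divergence_profile <- function(alns, recent_lt = 0.01, ancient_gt = 0.5) {
  if (length(alns) == 0) stop("at least one pair required")
  ests <- lapply(alns, function(x) {
    if (inherits(x, "fourdtv")) x else fourDTv(x)
  })
  cls <- vapply(ests, function(e) {
    if (e$saturated) "saturated"
    else if (e$fourDTv_corrected > ancient_gt) "ancient"
    else if (e$fourDTv_corrected < recent_lt) "recent"
    else "intermediate"
  }, character(1))
  df <- data.frame(
    pair = if (is.null(names(alns))) seq_along(alns) else names(alns),
    fourDTv_raw = vapply(ests, `[[`, numeric(1), "fourDTv_raw"),
    fourDTv_corrected = vapply(ests, `[[`, numeric(1), "fourDTv_corrected"),
    class = cls,
    stringsAsFactors = FALSE
  )
  counts <- table(factor(cls, levels = c("recent", "intermediate", "ancient",
                                         "saturated")))
  list(estimates = df, counts = c(counts))
}

#' One-stop divergence estimate for a pair of coding sequences
#'
#' Translates both CDS, aligns the proteins globally (Needleman-Wunsch via
#' Biostrings, BLOSUM62) unless an alignment is supplied, threads the codons,
#' and computes identity, 4DTv and NG86 Ka/Ks.
#'
#' @param cds_a,cds_b Coding sequences (character or `DNAString`).
#' @param prot_aln Optional aligned protein rows (character vector length 2);
#'   when missing the proteins are aligned internally.
#' @param correction Passed to [fourDTv()].
#' @return Object of class `divergence_estimate` collecting all statistics.
#' @export
estimate_divergence <- function(cds_a, cds_b, prot_aln = NULL,
                                correction = "k2p") {
  cds <- toupper(c(as.character(cds_a), as.character(cds_b)))
  gc <- .genetic_code()
  prots <- vapply(cds, function(x) {
    aa <- gc[.split_codons(x)]
    if (length(aa) > 0 && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
    }
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (is.null(prot_aln)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prots[1]), Biostrings::AAString(prots[2]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    prot_aln <- c(as.character(Biostrings::alignedPattern(pa)),
                  as.character(Biostrings::alignedSubject(pa)))
  }
  aln <- thread_codon_alignment(prot_aln[1], prot_aln[2], cds[1], cds[2])
  ftv <- tryCatch(fourDTv(aln, correction = correction), error = function(e) NULL)
  kaks <- tryCatch(ng86_kaks(aln), error = function(e) NULL)
  structure(list(
    alignment = aln,
    nt_identity_pct = pairwise_identity(aln$rows[1], aln$rows[2]),
    aa_identity_pct = pairwise_identity(prot_aln[1], prot_aln[2]),
    fourdtv = ftv,
    ng86 = kaks
  ), class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("Pairwise divergence estimate\n")
  cat(sprintf("  identity: %.1f%% nt, %.1f%% aa over %d codon columns\n",
              x$nt_identity_pct, x$aa_identity_pct, x$alignment$n_codons))
  if (!is.null(x$fourdtv)) print(x$fourdtv)
  if (!is.null(x$ng86)) print(x$ng86)
  invisible(x)
}
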