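# Standard-code codon bookkeeping shared by the divergence estimators and the
# codon-pair simulator. Tables are built once per session and cached.

.pd_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

# dinucleotide prefixes whose codon family is fourfold degenerate
.FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
}

.is_stop <- function(codon) unname(.genetic_code()[codon] == "*")

.translate_codons <- function(codons) {
  aa <- .genetic_code()[codons]
  unname(aa)
}

.is_transversion <- function(b1, b2) {
  (b1 %in% .PURINES) != (b2 %in% .PURINES)
}

# Per-codon count of synonymous sites: at each position, the fraction of the
# three single-nucleotide changes that preserve the amino acid. Changes into a
# stop codon count as nonsynonymous.
.syn_sites_one <- function(codon, gc) {
  s <- 0
  aa <- gc[codon]
  for (pos in 1:3) {
    for (b in setdiff(.BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (gc[alt] != "*" && gc[alt] == aa) s <- s + 1 / 3
    }
  }
  unname(s)
}

# all orderings of k differing positions (k <= 3)
.orderings <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(c(1L, 2L), c(2L, 1L)))
  out <- list()
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    out[[length(out) + 1L]] <- c(i, j, setdiff(1:3, c(i, j)))
  }
  out
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal substitution pathways, excluding pathways that pass through a
# stop codon (all pathways used if every one is blocked).
.pathway_diffs_one <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  paths <- .orderings(k)
  res <- matrix(NA_real_, length(paths), 2)
  ok <- logical(length(paths))
  for (p in seq_along(paths)) {
    ord <- pos[paths[[p]]]
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (step in ord) {
      nxt <- cur
      substr(nxt, step, step) <- substr(c2, step, step)
      if (gc[nxt] == "*" && nxt != c2) blocked <- TRUE
      if (gc[nxt] == gc[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[p, ] <- c(sd, nd)
    ok[p] <- !blocked
  }
  if (!any(ok)) ok[] <- TRUE
  c(sd = mean(res[ok, 1]), nd = mean(res[ok, 2]))
}

# Lookup tables over all 64 codons: synonymous-site counts and, for every
# ordered codon pair, pathway-averaged synonymous/nonsynonymous differences.
.codon_tables <- function() {
  if (!is.null(.pd_cache$tabs)) return(.pd_cache$tabs)
  gc <- .genetic_code()
  codons <- names(gc)
  syn <- vapply(codons, .syn_sites_one, numeric(1), gc = gc)
  n <- length(codons)
  SD <- matrix(0, n, n, dimnames = list(codons, codons))
  ND <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- .pathway_diffs_one(codons[i], codons[j], gc)
      SD[i, j] <- d["sd"]
      ND[i, j] <- d["nd"]
    }
  }
  .pd_cache$tabs <- list(codons = codons, gc = gc, syn = syn, SD = SD, ND = ND)
  .pd_cache$tabs
}

.split_codons <- function(x) {
  stopifnot(nchar(x) %% 3 == 0)
  n <- nchar(x) %/% 3
  substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
}
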