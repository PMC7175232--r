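# Independent oracles used to cross-check the package's estimators. These are
# written directly against the genetic code and by exhaustive/brute-force
# enumeration, sharing no code with the implementation under test.

.GC <- Biostrings::GENETIC_CODE
.SENSE_CODONS <- names(.GC)[.GC != "*"]

# fraction of single-nucleotide changes at each position that preserve the
# amino acid; a change into a stop codon is nonsynonymous
oracle_syn_sites <- function(codon) {
  aa <- .GC[[codon]]
  s <- 0
  for (p in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (nt == substring(codon, p, p)) next
      mut <- codon
      substring(mut, p, p) <- nt
      if (.GC[[mut]] != "*" && .GC[[mut]] == aa) s <- s + 1
    }
  }
  s / 3
}

# brute-force enumeration of every minimal substitution pathway between two
# codons; pathways through intermediate stop codons are dropped (all kept if
# every pathway is blocked); returns pathway-averaged c(sd, nd)
oracle_pathway_diffs <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0) {
      return(list(c(sd = sd, nd = nd, blocked = as.numeric(blocked))))
    }
    res <- list()
    for (p in remaining) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      hit_stop <- .GC[[nxt]] == "*" && length(remaining) > 1
      syn <- .GC[[nxt]] == .GC[[cur]]
      res <- c(res, walk(nxt, setdiff(remaining, p),
                         sd + as.numeric(syn), nd + as.numeric(!syn),
                         blocked || hit_stop))
    }
    res
  }
  paths <- do.call(rbind, walk(c1, diffs, 0, 0, FALSE))
  ok <- paths[, "blocked"] == 0
  if (!any(ok)) ok[] <- TRUE
  c(sd = mean(paths[ok, "sd"]), nd = mean(paths[ok, "nd"]))
}

# full NG86 on two equal-length in-frame sequences, built purely from the two
# helpers above
oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  ca <- substring(seq_a, 3 * (1:n) - 2, 3 * (1:n))
  cb <- substring(seq_b, 3 * (1:n) - 2, 3 * (1:n))
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * n - S
  d <- mapply(function(x, y) oracle_pathway_diffs(x, y), ca, cb)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# mean pairwise difference count between haplotype rows, by direct
# enumeration of all pairs
oracle_mean_pairwise_diff <- function(geno) {
  n <- nrow(geno)
  tot <- 0; pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(geno[i, ] != geno[j, ])
      pairs <- pairs + 1
    }
  }
  tot / pairs
}

# write a hand-built VCF body (list of tab-joined record lines) with a
# standard header for the given sample names
write_test_vcf <- function(path, samples, records, contig = "chr4") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contig, ">"),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}
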