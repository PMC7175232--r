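# Ground-truth simulators: codon-pair evolution with controllable Ts/Tv and
# selection, neutral-SFS SNP panels with exactly known pi, and planted
# paralog genomes for tandem detection. Truth is always recorded as realized
# on the emitted data, so estimator tests are not confounded by Monte-Carlo
# noise in the generator.

.base_int <- function() c(A = 1L, C = 2L, G = 3L, T = 4L)

.aa_array <- function() {
  if (!is.null(.pd_cache$aa_arr)) return(.pd_cache$aa_arr)
  gc <- .genetic_code()
  arr <- array("", dim = c(4, 4, 4))
  bi <- .base_int()
  for (cod in names(gc)) {
    i <- bi[substr(cod, 1, 1)]; j <- bi[substr(cod, 2, 2)]; k <- bi[substr(cod, 3, 3)]
    arr[i, j, k] <- gc[cod]
  }
  .pd_cache$aa_arr <- arr
  arr
}

.fourfold_prefix_matrix <- function() {
  if (!is.null(.pd_cache$ff_mat)) return(.pd_cache$ff_mat)
  bi <- .base_int()
  m <- matrix(FALSE, 4, 4)
  for (p in .FOURFOLD_PREFIXES) {
    m[bi[substr(p, 1, 1)], bi[substr(p, 2, 2)]] <- TRUE
  }
  .pd_cache$ff_mat <- m
  m
}

# transition partner of each base (A<->G, C<->T), transversion alternatives
.TS_PARTNER <- c(3L, 4L, 1L, 2L)
.TV_ALTS <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

.evolve_branch <- function(seq_int, t, kappa, omega, aa_arr, ff) {
  len <- length(seq_int)
  k <- stats::rpois(1, t * len)
  acc_syn <- 0L; acc_nonsyn <- 0L; tv_4d <- 0L
  p_ts <- kappa / (kappa + 2)
  for (ev in seq_len(k)) {
    site <- sample.int(len, 1)
    old <- seq_int[site]
    is_ts <- stats::runif(1) < p_ts
    new <- if (is_ts) .TS_PARTNER[old] else .TV_ALTS[old, sample.int(2, 1)]
    cod0 <- ((site - 1L) %/% 3L) * 3L
    c1 <- seq_int[cod0 + 1L]; c2 <- seq_int[cod0 + 2L]; c3 <- seq_int[cod0 + 3L]
    aa_old <- aa_arr[c1, c2, c3]
    pos_in_codon <- site - cod0
    if (pos_in_codon == 1L) c1 <- new else if (pos_in_codon == 2L) c2 <- new else c3 <- new
    aa_new <- aa_arr[c1, c2, c3]
    if (aa_new == "*") next                               # never emit stops
    if (aa_new != aa_old && stats::runif(1) >= omega) next # purifying rejection
    seq_int[site] <- new
    if (aa_new == aa_old) acc_syn <- acc_syn + 1L else acc_nonsyn <- acc_nonsyn + 1L
    if (pos_in_codon == 3L && !is_ts && ff[c1, c2]) tv_4d <- tv_4d + 1L
  }
  list(seq = seq_int, n_syn = acc_syn, n_nonsyn = acc_nonsyn, n_tv_4d = tv_4d)
}

#' Evolve a pair of coding sequences from a common ancestor
#'
#' Samples a random stop-free ancestor of `n_codons` codons and evolves two
#' descendants along independent branches of length `d/2` each. Substitution
#' events are proposed at Poisson(`d/2` x sites) per branch; each event picks
#' a uniform site and proposes the transition with probability
#' `kappa/(kappa+2)`, otherwise one of the two transversions. Proposals
#' creating a stop codon are always rejected; amino-acid-changing proposals
#' are accepted with probability `min(1, omega)`. `d` is therefore the
#' expected number of proposed substitutions per site along the whole path
#' between the two descendants; at fourfold-degenerate sites (where every
#' change is synonymous) it is also the realized substitution rate, with
#' transversion component `d * 2/(kappa+2)`.
#'
#' @param n_codons Number of codons (>= 1).
#' @param d Expected substitutions per site between the two sequences (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Acceptance probability of amino-acid-changing proposals
#'   (>= 0; values > 1 behave as 1).
#' @param seed Optional integer seed (sets the RNG for reproducibility).
#' @return List: `a`, `b` (uppercase CDS strings, stop-free, `3*n_codons`
#'   nt) and `truth` with the generating parameters, the analytic expected
#'   transversion distance at 4D sites (`expected_4dtv`, exact when
#'   `omega >= 1`), and realized accepted-event counts per branch.
#' @export
evolve_codon_pair <- function(n_codons, d, kappa, omega = 1, seed = NULL) {
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (d < 0) stop("branch length d must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tabs <- .codon_tables()
  aa_arr <- .aa_array(); ff <- .fourfold_prefix_matrix(); bi <- .base_int()
  sense <- tabs$codons[tabs$gc != "*"]
  anc_cod <- sample(sense, n_codons, replace = TRUE)
  anc <- unname(bi[unlist(strsplit(anc_cod, ""), use.names = FALSE)])
  br_a <- .evolve_branch(anc, d / 2, kappa, omega, aa_arr, ff)
  br_b <- .evolve_branch(anc, d / 2, kappa, omega, aa_arr, ff)
  to_str <- function(x) paste(names(bi)[x], collapse = "")
  list(
    a = to_str(br_a$seq),
    b = to_str(br_b$seq),
    truth = list(
      n_codons = n_codons, d = d, kappa = kappa, omega = omega,
      expected_4dtv = d * 2 / (kappa + 2),
      n_syn = br_a$n_syn + br_b$n_syn,
      n_nonsyn = br_a$n_nonsyn + br_b$n_nonsyn,
      n_tv_4d_events = br_a$n_tv_4d + br_b$n_tv_4d
    )
  )
}

#' Simulate a haploid SNP panel with a known site frequency spectrum
#'
#' Draws the number of segregating sites as Poisson(`theta * L * a_n`) with
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, places them at distinct positions in
#' `1..L`, and draws each site's derived-allele count `i` proportional to
#' `1/i` (the neutral frequency spectrum) or at a fixed frequency. Carriers
#' are assigned at random. `truth_pi` is the exact average pairwise
#' difference per site of the emitted panel, computed from the emitted
#' allele counts; its expectation over panels is `theta`.
#'
#' @param n_accessions Haploid sample size (>= 2).
#' @param L Locus length in bp.
#' @param theta Expected per-site diversity (>= 0).
#' @param sfs_model `"neutral_1_over_i"` or `"fixed_frequency"`.
#' @param f Derived-allele frequency for `"fixed_frequency"`.
#' @param seed Optional integer seed.
#' @param chrom Chromosome label for the emitted sites.
#' @param ann_classes Optional `data.frame(effect, impact, prob)`; when
#'   given, each site is assigned one (effect, impact) pair sampled with the
#'   stated probabilities, emulating SnpEff annotation.
#' @return List: `sites` (a `variant_sites` data frame), `truth_pi`,
#'   `genotypes` (accession x site 0/1 matrix), `n_accessions`, `L`, `theta`.
#' @export
simulate_snp_panel <- function(n_accessions, L, theta,
                               sfs_model = c("neutral_1_over_i", "fixed_frequency"),
                               f = NULL, seed = NULL, chrom = "sim1",
                               ann_classes = NULL) {
  sfs_model <- match.arg(sfs_model)
  if (n_accessions < 2) stop("n_accessions must be >= 2")
  if (theta < 0) stop("theta must be >= 0")
  if (L < 1) stop("L must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_accessions)
  a_n <- sum(1 / seq_len(n - 1))
  S <- stats::rpois(1, theta * L * a_n)
  if (S > L) {
    warning("segregating sites capped at locus length L")
    S <- L
  }
  acc <- sprintf("acc%04d", seq_len(n))
  if (S == 0) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0), n = integer(0),
                        effect = character(0), impact = character(0),
                        deleterious = logical(0), stringsAsFactors = FALSE)
    sites$allele_counts <- I(list())
    class(sites) <- c("variant_sites", class(sites))
    return(list(sites = sites, truth_pi = 0,
                genotypes = matrix(0L, n, 0, dimnames = list(acc, NULL)),
                n_accessions = n, L = L, theta = theta))
  }
  pos <- sort(sample.int(L, S))
  i_count <- if (sfs_model == "neutral_1_over_i") {
    sample(seq_len(n - 1), S, replace = TRUE, prob = 1 / seq_len(n - 1))
  } else {
    if (is.null(f) || f <= 0 || f >= 1) stop("fixed_frequency needs f in (0,1)")
    rep(max(1L, min(n - 1L, as.integer(round(f * n)))), S)
  }
  ref <- sample(.BASES, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), character(1),
                USE.NAMES = FALSE)
  geno <- matrix(0L, n, S, dimnames = list(acc, pos))
  for (j in seq_len(S)) geno[sample.int(n, i_count[j]), j] <- 1L
  eff <- rep(NA_character_, S); imp <- rep("unknown", S)
  if (!is.null(ann_classes)) {
    pick <- sample.int(nrow(ann_classes), S, replace = TRUE,
                       prob = ann_classes$prob)
    eff <- ann_classes$effect[pick]
    imp <- ann_classes$impact[pick]
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, n = n,
                      effect = eff, impact = imp, deleterious = NA,
                      stringsAsFactors = FALSE)
  sites$allele_counts <- I(lapply(seq_len(S), function(j) {
    ct <- c(n - i_count[j], i_count[j])
    names(ct) <- c(ref[j], alt[j])
    ct
  }))
  class(sites) <- c("variant_sites", class(sites))
  # realized diversity of the emitted panel: the unbiased per-site
  # heterozygosity sum, identical in value and floating-point path to what
  # pi_gene computes from the same counts
  truth_pi <- sum(vapply(sites$allele_counts, site_heterozygosity,
                         numeric(1))) / L
  list(sites = sites, truth_pi = truth_pi, genotypes = geno,
       n_accessions = n, L = L, theta = theta)
}

#' Write a simulated panel as a SnpEff-annotated VCF
#'
#' Emits minimal VCF 4.2 text with homozygous diploid genotypes (`0/0`,
#' `1/1`) per inbred accession, and an `INFO/ANN` entry in the SnpEff
#' pipe-delimited dialect for sites carrying an effect annotation.
#'
#' @param panel Result of [simulate_snp_panel()].
#' @param path Output VCF path.
#' @param gene_id Gene name/ID written into ANN.
#' @export
write_panel_vcf <- function(panel, path, gene_id = "gene1") {
  sites <- panel$sites
  acc <- rownames(panel$genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", if (nrow(sites)) sites$chrom[1] else "sim1", ">"),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", acc), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(sites))) {
    info <- if (!is.na(sites$effect[j])) {
      paste0("ANN=", paste(sites$alt[j], sites$effect[j], sites$impact[j],
                           gene_id, gene_id, "transcript",
                           paste0(gene_id, ".1"), sep = "|"))
    } else "."
    gtv <- ifelse(panel$genotypes[, j] == 1L, "1/1", "0/0")
    writeLines(paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j],
                       sites$alt[j], ".", "PASS", info, "GT", gtv),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Plant a genome of paralog pairs with known tandem status
#'
#' Lays out paralog pairs along chromosomes with the requested intergenic
#' gaps and records the answer key (`is_tandem` under the strict `< 2500 bp`
#' gap rule). Pairs may be split across chromosomes by giving `chrom_b`.
#'
#' @param pairs `data.frame` with columns `chrom`, `gap_bp` and optionally
#'   `chrom_b` (defaults to `chrom`).
#' @param gene_length Planted gene length in bp.
#' @param threshold_bp Tandem rule threshold recorded in the answer key.
#' @param dir Optional directory; when given, writes `genes.gff3`,
#'   `relations.tsv` and `answer_key.tsv` there.
#' @param species Species label for the relation table.
#' @return List: `genes` (gene models), `relations`, `key` (answer key with
#'   `gap_bp` and `is_tandem`), and `paths` when `dir` was given.
#' @export
plant_paralog_genome <- function(pairs, gene_length = 2000,
                                 threshold_bp = 2500, dir = NULL,
                                 species = "synthetica") {
  stopifnot(all(c("chrom", "gap_bp") %in% names(pairs)))
  same_chrom <- if ("chrom_b" %in% names(pairs)) {
    is.na(pairs$chrom_b) | pairs$chrom_b == pairs$chrom
  } else rep(TRUE, nrow(pairs))
  if (any(same_chrom & pairs$gap_bp < 0)) {
    stop("planted genes would overlap: gap_bp must be >= 0")
  }
  cursor <- new.env(parent = emptyenv())
  nxt <- function(chr, len) {
    at <- get0(chr, envir = cursor, ifnotfound = 10000L)
    assign(chr, at + len + 50000L, envir = cursor)
    at
  }
  genes <- list(); key <- list()
  for (p in seq_len(nrow(pairs))) {
    chr_a <- as.character(pairs$chrom[p])
    chr_b <- if (same_chrom[p]) chr_a else as.character(pairs$chrom_b[p])
    ida <- sprintf("pg%03d_a", p); idb <- sprintf("pg%03d_b", p)
    if (same_chrom[p]) {
      sa <- nxt(chr_a, 2L * gene_length + pairs$gap_bp[p])
      ea <- sa + gene_length - 1L
      sb <- ea + pairs$gap_bp[p] + 1L
      eb <- sb + gene_length - 1L
    } else {
      sa <- nxt(chr_a, gene_length); ea <- sa + gene_length - 1L
      sb <- nxt(chr_b, gene_length); eb <- sb + gene_length - 1L
    }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = c(ida, idb), chrom = c(chr_a, chr_b),
      start = c(sa, sb), end = c(ea, eb), strand = "+",
      stringsAsFactors = FALSE)
    key[[length(key) + 1L]] <- data.frame(
      gene_a = ida, gene_b = idb,
      gap_bp = if (same_chrom[p]) as.integer(pairs$gap_bp[p]) else NA_integer_,
      is_tandem = same_chrom[p] && pairs$gap_bp[p] < threshold_bp,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  key <- do.call(rbind, key)
  relations <- data.frame(species = species, gene_a = key$gene_a,
                          gene_b = key$gene_b, relation = "paralog",
                          stringsAsFactors = FALSE)
  out <- list(genes = genes, relations = relations, key = key)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(gff3 = file.path(dir, "genes.gff3"),
                  relations = file.path(dir, "relations.tsv"),
                  key = file.path(dir, "answer_key.tsv"))
    write_gff3(genes, paths$gff3)
    write_report(relations, paths$relations)
    write_report(key, paths$key)
    out$paths <- paths
  }
  out
}
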