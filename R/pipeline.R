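# Orchestration: configuration handling and the two report-producing stages
# (paralog architecture + divergence; per-gene diversity + co-occurrence).

#' Assemble a pipeline configuration
#'
#' Defaults < configuration file (YAML, flat keys or nested maps) < direct
#' arguments; the merged configuration is written into every run manifest.
#'
#' @param config_file Optional YAML file.
#' @param ... Overrides (e.g. `gff`, `cds`, `relations`, `vcf`, `intervals`,
#'   `deleterious`, `threshold_bp`, `tandem_metric`, `pi_normalization`,
#'   `correction`, `seed`, `out_dir`).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(threshold_bp = 2500, tandem_metric = "gap",
              pi_normalization = NULL, correction = "k2p", seed = 1L,
              out_dir = ".")
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  cfg[names(dots)] <- dots
  if (cfg$threshold_bp <= 0) stop("threshold_bp must be > 0")
  structure(cfg, class = "pipeline_config")
}

.write_manifest <- function(cfg, stage, inputs, out_dir) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    parameters = unclass(cfg)[setdiff(names(cfg), names(inputs))],
    seed = cfg$seed,
    package = as.character(utils::packageVersion("paralogdiv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the paralog architecture + divergence stage
#'
#' Reads gene models, a paralog relation table and CDS sequences, computes
#' pair distances and tandem calls, and per-pair identity, 4DTv and NG86
#' Ka/Ks. Writes `tandem_pairs.tsv`, `divergence.tsv` and a JSON run
#' manifest into `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()] with `gff`, `relations`, `cds` paths.
#' @return Invisibly, a list with the two report data frames.
#' @export
run_divergence_report <- function(cfg) {
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  genes <- .stage("read-gff3", {
    if (!file.exists(cfg$gff)) stop("GFF3 not found: ", cfg$gff)
    read_gff3(cfg$gff)
  })
  relations <- .stage("read-relations", read_report(cfg$relations))
  if (nrow(relations) == 0) {
    pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                        gap_bp = integer(0), start_to_start_bp = integer(0),
                        same_chrom = logical(0), is_tandem = logical(0))
  } else {
    pairs <- .stage("tandem-scan",
                    tandem_scan(genes, relations, threshold_bp = cfg$threshold_bp,
                                metric = cfg$tandem_metric))
  }
  write_report(pairs, file.path(out_dir, "tandem_pairs.tsv"))
  div <- NULL
  if (!is.null(cfg$cds) && nrow(pairs) > 0) {
    cds <- .stage("read-cds", {
      if (!file.exists(cfg$cds)) stop("CDS FASTA not found: ", cfg$cds)
      read_fasta(cfg$cds, moltype = "nt", is_cds = TRUE)
    })
    div <- .stage("divergence", {
      rows <- lapply(seq_len(nrow(pairs)), function(i) {
        a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
        if (!a %in% names(cds) || !b %in% names(cds)) {
          stop("pair (", a, ", ", b, "): CDS record missing")
        }
        est <- estimate_divergence(cds[[a]], cds[[b]],
                                   correction = cfg$correction)
        data.frame(
          gene_a = a, gene_b = b,
          nt_identity_pct = est$nt_identity_pct,
          aa_identity_pct = est$aa_identity_pct,
          n_4d_sites = if (is.null(est$fourdtv)) NA else est$fourdtv$n_4d_sites,
          fourDTv_raw = if (is.null(est$fourdtv)) NA else est$fourdtv$fourDTv_raw,
          fourDTv_corrected = if (is.null(est$fourdtv)) NA else est$fourdtv$fourDTv_corrected,
          saturated = if (is.null(est$fourdtv)) NA else est$fourdtv$saturated,
          Ka = if (is.null(est$ng86)) NA else est$ng86$Ka,
          Ks = if (is.null(est$ng86)) NA else est$ng86$Ks,
          omega = if (is.null(est$ng86)) NA else est$ng86$omega,
          stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    write_report(div, file.path(out_dir, "divergence.tsv"))
  }
  .write_manifest(cfg, "divergence",
                  list(gff = cfg$gff, relations = cfg$relations,
                       cds = cfg$cds), out_dir)
  invisible(list(tandem_pairs = pairs, divergence = div))
}

#' Run the per-gene diversity stage
#'
#' For each gene interval, reads SNPs from the VCF, reports SNP counts, pi
#' under both normalizations, the impact/effect summary, and (when a
#' deleteriousness table is supplied) whether any accession carries
#' deleterious variants in more than one gene. Writes `diversity.tsv`,
#' `co_occurrence.tsv` and a JSON manifest.
#'
#' @param cfg A [pipeline_config()] with `vcf`, `intervals` (data frame or
#'   TSV path with `gene_id`, `chrom`, `start`, `end`) and optionally
#'   `deleterious` (TSV path).
#' @return Invisibly, a list with the diversity table and the co-occurrence
#'   verdict.
#' @export
run_diversity_report <- function(cfg) {
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  intervals <- .stage("read-intervals", {
    if (is.character(cfg$intervals)) read_report(cfg$intervals) else
      as.data.frame(cfg$intervals)
  })
  del <- if (!is.null(cfg$deleterious)) {
    .stage("read-deleterious", read_deleterious_tsv(cfg$deleterious))
  }
  rows <- list(); carriers <- list()
  for (i in seq_len(nrow(intervals))) {
    g <- intervals$gene_id[i]
    sites <- .stage(paste0("read-vcf:", g),
                    read_vcf_interval(cfg$vcf, intervals$chrom[i],
                                      intervals$start[i], intervals$end[i],
                                      gene_id = g))
    if (!is.null(del)) sites <- apply_deleterious(sites, del)
    L <- intervals$end[i] - intervals$start[i] + 1
    ps <- pi_gene(sites, L, "per_site", gene_id = g)
    pss <- pi_gene(sites, L, "per_segregating_site", gene_id = g)
    es <- effect_summary(sites, gene_id = g)
    rows[[i]] <- data.frame(
      gene_id = g, n_snps = ps$n_snps, L = L,
      pi_per_site = ps$pi, pi_per_segregating_site = pss$pi,
      n_nonsynonymous = es$n_nonsynonymous,
      n_nonsense_or_frameshift = es$n_nonsense_or_frameshift,
      n_deleterious = es$n_deleterious,
      stringsAsFactors = FALSE)
    if (!is.null(del)) {
      dsites <- sites[!is.na(sites$deleterious) & sites$deleterious, , drop = FALSE]
      carriers[[g]] <- .stage(paste0("genotypes:", g),
                              genotype_matrix(cfg$vcf, intervals$chrom[i],
                                              intervals$start[i], intervals$end[i],
                                              positions = unique(dsites$pos)))
    }
  }
  diversity <- do.call(rbind, rows)
  write_report(diversity, file.path(out_dir, "diversity.tsv"))
  co <- NULL
  if (length(carriers) >= 2) {
    gs <- names(carriers)
    verdicts <- list()
    for (a in seq_along(gs)) for (b in seq_along(gs)) if (a < b) {
      sd <- shared_deleterious(carriers[[a]], carriers[[b]])
      verdicts[[length(verdicts) + 1L]] <- data.frame(
        gene_a = gs[a], gene_b = gs[b], any_shared = sd$any_shared,
        accessions = paste(sd$accessions, collapse = ","),
        stringsAsFactors = FALSE)
    }
    co <- do.call(rbind, verdicts)
    write_report(co, file.path(out_dir, "co_occurrence.tsv"))
  }
  .write_manifest(cfg, "diversity",
                  list(vcf = cfg$vcf,
                       intervals = if (is.character(cfg$intervals)) cfg$intervals else "inline",
                       deleterious = cfg$deleterious), out_dir)
  invisible(list(diversity = diversity, co_occurrence = co))
}
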