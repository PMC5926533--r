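#' Pipeline configuration
#'
#' Collects input paths and all stage parameters with their standard
#' defaults (minimum fragment separation 1 kb, promoter window 2 kb,
#' enhancer stitch gap 12.5 kb, TSS exclusion 2 kb, broad fraction 5%,
#' matrix resolution 40 kb, expressed-gene RPKM cutoff 0.5, q 0.05).
#'
#' @param fasta,pairs_bedpe,genes_tsv,expression_tsv input file paths.
#' @param h3k4me3,h3k4me1,h3k27ac histone peak BED paths (optional; HOCI
#'   classification is skipped without them).
#' @param ... parameter overrides (see defaults in the function body).
#' @return validated `PipelineConfig` list.
#' @export
pipeline_config <- function(fasta, pairs_bedpe, genes_tsv = NULL,
                            expression_tsv = NULL, h3k4me3 = NULL,
                            h3k4me1 = NULL, h3k27ac = NULL, ...) {
  cfg <- list(fasta = fasta, pairs_bedpe = pairs_bedpe,
              genes_tsv = genes_tsv, expression_tsv = expression_tsv,
              h3k4me3 = h3k4me3, h3k4me1 = h3k4me1, h3k27ac = h3k27ac,
              include_chroms = NULL,
              site = "GATC", mapq_min = 1, min_separation = 1000,
              bin_bp = 50, q_threshold = 0.05, min_width = 150,
              merge_gap = 200, peak_mode = "narrow",
              promoter_up = 2000, min_network_weight = 1,
              stitch_gap = 12500, tss_exclusion = 2000, broad_frac = 0.05,
              resolution = 40000, rpkm_cutoff = 0.5, seed = 1,
              run_matrix = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg configuration list.
#' @export
validate_pipeline_config <- function(cfg) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$q_threshold > 0 && cfg$q_threshold <= 1,
      "q_threshold must be in (0, 1]")
  chk(cfg$broad_frac > 0 && cfg$broad_frac <= 1,
      "broad_frac must be in (0, 1]")
  chk(cfg$min_separation >= 0, "min_separation must be >= 0")
  chk(cfg$promoter_up > 0, "promoter_up must be > 0")
  chk(cfg$resolution > 0, "resolution must be > 0")
  chk(cfg$rpkm_cutoff >= 0, "rpkm_cutoff must be >= 0")
  for (f in c("fasta", "pairs_bedpe")) {
    chk(!is.null(cfg[[f]]) && file.exists(cfg[[f]]),
        paste0("missing input: ", f))
  }
  for (f in c("genes_tsv", "expression_tsv", "h3k4me3", "h3k4me1",
              "h3k27ac")) {
    if (!is.null(cfg[[f]]))
      chk(file.exists(cfg[[f]]), paste0("input does not exist: ", f))
  }
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' Load a YAML pipeline config
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  message("[oceanc] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Stage order: digest, filter-pairs, call-hoci, annotate (when histone
#' peaks are given), network, gene-types (when genes and expression are
#' given), and optionally the contact-matrix/compartment stage. Artifacts
#' and a machine-readable run manifest are written to `out_dir`; any stage
#' failure halts with an error naming the stage.
#'
#' @param config `PipelineConfig`.
#' @param out_dir output directory.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  assembly <- .stage("read-genome",
                     read_genome_fasta(config$fasta, config$include_chroms))
  frag <- .stage("digest", digest_genome(assembly, config$site))
  write_fragments_bed(frag, file.path(out_dir, "fragments.bed"))

  pairs <- .stage("read-pairs", read_pairs_bedpe(config$pairs_bedpe))
  flt <- .stage("filter-pairs",
                filter_pairs(pairs, frag, mapq_min = config$mapq_min,
                             min_separation = config$min_separation))
  write_valid_pairs(flt$valid, file.path(out_dir, "valid.pairs.tsv"))
  write_pair_report(flt$counts, file.path(out_dir, "pair_report.tsv"))

  track <- .stage("coverage",
                  build_coverage(flt$valid, assembly, config$bin_bp))
  hocis <- .stage("call-hoci",
                  call_hoci(track, q_threshold = config$q_threshold,
                            min_width = config$min_width,
                            merge_gap = config$merge_gap,
                            mode = config$peak_mode))
  write_narrowpeak(hocis, file.path(out_dir, "hoci.narrowPeak"))

  genes <- if (!is.null(config$genes_tsv)) read_genes(config$genes_tsv)
  if (!is.null(config$h3k4me3) && !is.null(config$h3k4me1) &&
      !is.null(config$h3k27ac) && !is.null(genes)) {
    hocis <- .stage("annotate", classify_hoci(
      hocis, read_bed(config$h3k4me3), read_bed(config$h3k4me1),
      read_bed(config$h3k27ac), genes, assembly, config$promoter_up))
    write_bed(data.frame(hocis[, c("chrom", "start", "end", "name")],
                         score = round(hocis$score, 2), strand = ".",
                         class = hocis$class),
              file.path(out_dir, "hoci_annotated.bed"))
  }

  net <- .stage("network",
                build_network(flt$valid, hocis, config$min_network_weight))
  write_network_bedpe(net, file.path(out_dir, "network.bedpe"))

  typed <- NULL
  if (!is.null(genes) && !is.null(config$expression_tsv)) {
    expr <- read_expression(config$expression_tsv)
    typed <- .stage("gene-types",
                    type_genes(genes, hocis, flt$valid, assembly,
                               config$promoter_up))
    eb <- expression_by_type(typed, expr[genes$gene_id],
                             config$rpkm_cutoff)
    utils::write.table(data.frame(genes, type = typed,
                                  rpkm = unname(expr[genes$gene_id])),
                       file.path(out_dir, "gene_types.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(eb$summary, file.path(out_dir, "expression_by_type.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$expression <- eb
  }

  if (isTRUE(config$run_matrix)) {
    res$matrices <- .stage("matrix", lapply(assembly$chroms, function(ch) {
      cm <- ice_balance(bin_pairs(flt$valid, assembly, ch,
                                  config$resolution))
      write_contact_matrix(cm, file.path(out_dir, paste0("matrix_", ch)))
      cm
    }))
  }

  summary_df <- data.frame(
    metric = c("n_pairs_in", "n_valid", "n_hoci", "n_network_edges"),
    value = c(nrow(pairs), nrow(flt$valid), nrow(hocis), nrow(net$edges)))
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("oceanc")),
    parameters = config[!vapply(config, is.null, TRUE)],
    input_checksums = as.list(tools::md5sum(stats::na.omit(unlist(
      config[c("fasta", "pairs_bedpe", "genes_tsv", "expression_tsv",
               "h3k4me3", "h3k4me1", "h3k27ac")])))),
    counts = as.list(flt$counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  res <- c(list(assembly = assembly, fragments = frag, filtered = flt,
                hocis = hocis, network = net, gene_types = typed), res)
  invisible(res)
}
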