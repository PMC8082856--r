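#' Default pipeline configuration
#'
#' Builds the fully resolved configuration record consumed by
#' [run_pipeline()]; every run writes this record, as YAML, next to its
#' outputs so results are reproducible from the manifest alone.
#'
#' @param het_vcf,het_tsv,reduced_reads,alignments,fastq Input paths
#'   (mutually optional): heterozygous positions from a VCF or plain TSV;
#'   reads from a reduced-read TSV or a SAM/BAM; optional raw FASTQ for
#'   per-haplotig FASTQ output.
#' @param vcf_mode Het-position extraction mode, see [parse_het_positions()].
#' @param simulate A [sim_config()] to generate inputs instead of reading
#'   them (used when no read input is given).
#' @param truth Optional truth-set TSV path (or `truth_set` data frame) to
#'   compute evaluation metrics.
#' @param params A [phase_params()].
#' @param use_split_reads,edge_size Split-read stitching controls.
#' @param clean,gap_fill,filter_fraction Cleaning controls.
#' @param chromosome Optional chromosome filter (process one chromosome).
#' @param max_het_fraction When set, down-sample the heterozygous positions
#'   to a random subset of this fraction before phasing (useful for very
#'   dense variant sets).
#' @param plot Write a haplotig plot (PNG) of the final result.
#' @param seed Integer seed for every stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(het_vcf = NULL, het_tsv = NULL, reduced_reads = NULL,
                       alignments = NULL, fastq = NULL,
                       vcf_mode = "het_genotype", simulate = NULL,
                       truth = NULL, params = phase_params(),
                       use_split_reads = TRUE, edge_size = 10L,
                       clean = TRUE, gap_fill = TRUE,
                       filter_fraction = 0.01, chromosome = NULL,
                       max_het_fraction = NULL, plot = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full phasing pipeline
#'
#' Chains the stages: load or simulate inputs, restrict reads to the
#' heterozygous-position set, remove subset reads, build the
#' context-coverage table and weight the reads, phase (with the split-read
#' stitching pass when split segments are present), optionally clean, write
#' outputs, and — when a truth set is available — evaluate. Outputs are
#' written with deterministic ordering so identical configurations and
#' seeds give byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return List with `haplotigs`, `reads`, `metrics` (or `NULL`),
#'   `manifest` (data frame of files written) and `config`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- config$truth
  if (is.character(truth)) truth <- read_truth_tsv(truth)

  if (!is.null(config$simulate)) {
    sim <- simulate_polyploid(config$simulate)
    het <- sim$het_positions
    reads <- sim$reads
    if (is.null(truth)) truth <- sim$truth
  } else {
    het <- if (!is.null(config$het_vcf)) {
      parse_het_positions(config$het_vcf, config$vcf_mode)
    } else if (!is.null(config$het_tsv)) {
      read_het_tsv(config$het_tsv)
    } else {
      stop("no heterozygous-position input: set het_vcf, het_tsv or simulate")
    }
    reads <- if (!is.null(config$reduced_reads)) {
      read_reduced_reads(config$reduced_reads)
    } else if (!is.null(config$alignments)) {
      reduce_alignments(config$alignments, het)
    } else {
      stop("no read input: set reduced_reads, alignments or simulate")
    }
  }

  if (!is.null(config$chromosome)) {
    het <- het[het$chromosome %in% config$chromosome, , drop = FALSE]
    if (!is.null(truth)) {
      truth <- truth[truth$chromosome %in% config$chromosome, , drop = FALSE]
    }
  }
  if (!is.null(config$max_het_fraction) && config$max_het_fraction < 1) {
    set.seed(config$seed)
    keep <- sort(sample.int(nrow(het),
                            round(config$max_het_fraction * nrow(het))))
    het <- het[keep, , drop = FALSE]
  }
  reads <- restrict_reads(reads, het)
  if (length(reads) == 0L) stop("no read covers a heterozygous position")

  reads <- remove_subset_reads(reads)
  ctx <- build_context_table(reads)
  reads <- weight_reads(reads, ctx)

  params <- config$params
  params$rng_seed <- params$rng_seed %||% config$seed
  haplotigs <- phase_with_stitching(
    reads, ctx, params,
    edge_size = config$edge_size,
    use_split_reads = config$use_split_reads
  )
  raw_haplotigs <- haplotigs
  if (isTRUE(config$clean)) {
    haplotigs <- clean_haplotigs(haplotigs, reads,
                                 filter_fraction = config$filter_fraction,
                                 gap_fill = config$gap_fill,
                                 seed = config$seed + 1L)
  }

  fq_index <- if (!is.null(config$fastq)) read_fastq_index(config$fastq)
  manifest <- write_haplotig_outputs(haplotigs, out_dir, fq_index)

  # combined consensus TSV, membership table, merge log, resolved config
  combined <- do.call(rbind, lapply(haplotigs, function(h) {
    cbind(haplotig = h$id, as.data.frame(h))
  })) %||% data.frame(haplotig = character(), chromosome = character(),
                      position = integer(), base = character())
  comb_path <- file.path(out_dir, "haplotigs.tsv")
  utils::write.table(combined, comb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  memb <- do.call(rbind, lapply(haplotigs, function(h) {
    data.frame(haplotig = h$id, read_id = h$members)
  })) %||% data.frame(haplotig = character(), read_id = character())
  memb_path <- file.path(out_dir, "haplotig_reads.tsv")
  utils::write.table(memb, memb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_path <- file.path(out_dir, "merge_log.tsv")
  utils::write.table(attr(raw_haplotigs, "merge_log"), log_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.config_as_yaml(config), cfg_path)
  files <- c(comb_path, memb_path, log_path, cfg_path)

  metrics <- NULL
  if (!is.null(truth)) {
    assignment <- assign_haplotigs(haplotigs, truth)
    metrics <- compute_metrics(haplotigs, assignment, truth)
    met_path <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(
      list(rates = as.list(metrics$rates), counts = as.list(metrics$counts),
           haplotigs_per_haplotype = metrics$haplotigs_per_haplotype,
           haplotigs_per_haplotype_by_chrom =
             metrics$haplotigs_per_haplotype_by_chrom,
           l90 = metrics$l90, n_unknown = metrics$n_unknown),
      met_path, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, met_path)
  }
  if (isTRUE(config$plot)) {
    plot_path <- file.path(out_dir, "haplotigs.png")
    p <- plot_haplotigs(haplotigs,
                        assignment = if (!is.null(truth)) {
                          assign_haplotigs(haplotigs, truth)
                        })
    ggplot2::ggsave(plot_path, p, width = 10, height = 6, dpi = 120)
    files <- c(files, plot_path)
  }
  manifest <- rbind(manifest,
                    data.frame(haplotig = NA_character_, file = files,
                               type = c("haplotigs_tsv", "membership_tsv",
                                        "merge_log", "config",
                                        if (!is.null(metrics)) "metrics",
                                        if (isTRUE(config$plot)) "plot")))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(haplotigs = haplotigs, reads = reads, metrics = metrics,
       manifest = manifest, config = config)
}

# flatten nested S3 config objects into plain lists for YAML
.config_as_yaml <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, c("phase_params", "sim_config"))) {
      unclass(x)
    } else if (is.data.frame(x)) {
      NULL   # inline truth tables are not echoed
    } else {
      x
    }
  })
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the [run_config()] fields; `params`
#'   and `simulate` sub-maps are promoted to [phase_params()] and
#'   [sim_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) y$params <- do.call(phase_params, y$params)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

#' Plot haplotigs along the reference genome
#'
#' One horizontal segment per haplotig, one row per haplotig, faceted by
#' chromosome — the standard way to eyeball the contiguity of a phasing
#' result. When a truth assignment is supplied, haplotigs are coloured by
#' the haplotype they represent.
#'
#' @param haplotigs List of `haplotig` objects.
#' @param assignment Optional [assign_haplotigs()] result.
#' @return A ggplot object.
#' @export
plot_haplotigs <- function(haplotigs, assignment = NULL) {
  df <- do.call(rbind, lapply(haplotigs, function(h) {
    data.frame(haplotig = h$id, chromosome = h$chrom,
               start = h$span[[1L]], end = h$span[[2L]],
               stringsAsFactors = FALSE)
  }))
  df$haplotype <- if (!is.null(assignment)) {
    assignment[df$haplotig]
  } else {
    "unassigned"
  }
  df$row <- stats::ave(seq_len(nrow(df)), df$chromosome, FUN = seq_along)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$row, yend = .data$row,
                   colour = .data$haplotype),
      linewidth = 3
    ) +
    ggplot2::facet_wrap(~chromosome, ncol = 1L, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = "haplotig",
                  colour = "haplotype") +
    ggplot2::theme_minimal()
}
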