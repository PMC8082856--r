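#' Synthetic polyploid simulation configuration
#'
#' Describes a virtual polyploid: `ploidy` haplotypes over a shared set of
#' chromosomes, heterozygous sites at a configurable fraction of positions,
#' and long reads drawn per haplotype at a configurable coverage with a
#' per-base substitution error rate at heterozygous positions. The defaults
#' describe the standard validation condition used throughout this package:
#' a tetraploid with a 0.5% heterozygosity level sequenced at 20X per
#' haplotype with 10% read error, on two 200-kb chromosomes.
#'
#' @param ploidy Number of haplotypes `k` (>= 1).
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp.
#' @param heterozygosity Fraction of reference positions that are
#'   heterozygous in at least one haplotype (e.g. 0.005 = 0.5%).
#' @param coverage Long-read coverage per haplotype (X).
#' @param read_length_mean,read_length_sd Read length distribution in bp
#'   (normal, truncated at 50 bp).
#' @param error_rate Per-base probability that a call at a heterozygous
#'   position is flipped to a uniformly chosen different base.
#' @param split_read_fraction Fraction of reads emitted as two
#'   same-chromosome split segments (second segment placed at an
#'   independent uniform position, emulating a structural variant between
#'   sample and reference).
#' @param p_shared Probability that a heterozygous site's alleles partition
#'   the haplotypes into two groups (a shared allele) rather than being
#'   private to a single haplotype. Shared alleles are what make polyploid
#'   phasing hard; virtual polyploids built from related strains have many.
#' @param variant_call_miss_rate Fraction of true heterozygous positions
#'   dropped by [degrade_variant_calls()] to emulate variant-calling misses.
#' @param seed Integer seed for all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(ploidy = 4L,
                       n_chromosomes = 2L,
                       chromosome_length = 200000L,
                       heterozygosity = 0.005,
                       coverage = 20,
                       read_length_mean = 20000,
                       read_length_sd = 5000,
                       error_rate = 0.10,
                       split_read_fraction = 0,
                       p_shared = 0.5,
                       variant_call_miss_rate = 0,
                       seed = 1L) {
  cfg <- list(
    ploidy = as.integer(ploidy), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    heterozygosity = heterozygosity, coverage = coverage,
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    error_rate = error_rate, split_read_fraction = split_read_fraction,
    p_shared = p_shared, variant_call_miss_rate = variant_call_miss_rate,
    seed = as.integer(seed)
  )
  stopifnot(cfg$ploidy >= 1L, cfg$chromosome_length > 0L, cfg$coverage > 0)
  for (f in c("heterozygosity", "error_rate", "split_read_fraction",
              "p_shared", "variant_call_miss_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

.haplotype_names <- function(k) sprintf("hap%02d", seq_len(k))
.chrom_names <- function(n) sprintf("chr%02d", seq_len(n))

#' Generate ground-truth haplotypes and heterozygous positions
#'
#' Samples heterozygous positions uniformly without replacement at the
#' configured heterozygosity and assigns every haplotype a base at each
#' position so that at least two distinct bases occur across haplotypes.
#' With probability `p_shared` the alleles split the haplotypes into two
#' non-empty groups; otherwise a single haplotype carries a private allele.
#'
#' @param config A [sim_config()].
#' @return List with `het_positions` (data frame `chromosome`, `position`)
#'   and `truth`, a `truth_set` data frame (`haplotype`, `chromosome`,
#'   `position`, `base`) giving every haplotype's base at every
#'   heterozygous position.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$ploidy
  haps <- .haplotype_names(k)
  per_chrom <- lapply(.chrom_names(config$n_chromosomes), function(ch) {
    n_het <- round(config$heterozygosity * config$chromosome_length)
    if (n_het < 1L) {
      warning("heterozygosity x chromosome length < 1; no sites on ", ch)
      return(NULL)
    }
    pos <- sort(sample.int(config$chromosome_length, n_het))
    base <- matrix(0L, n_het, k)
    for (i in seq_len(n_het)) {
      alleles <- sample.int(4L, 2L)
      if (k == 1L) {
        base[i, ] <- alleles[[1L]]
      } else if (stats::runif(1L) < config$p_shared) {
        grp <- sample(2L, k, replace = TRUE)
        while (length(unique(grp)) < 2L) grp <- sample(2L, k, replace = TRUE)
        base[i, ] <- alleles[grp]
      } else {
        private <- sample.int(k, 1L)
        base[i, ] <- alleles[[1L]]
        base[i, private] <- alleles[[2L]]
      }
    }
    list(chrom = ch, pos = pos, base = base)
  })
  per_chrom <- Filter(Negate(is.null), per_chrom)
  het <- do.call(rbind, lapply(per_chrom, function(x) {
    data.frame(chromosome = x$chrom, position = x$pos,
               stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, lapply(per_chrom, function(x) {
    data.frame(
      haplotype = rep(haps, each = length(x$pos)),
      chromosome = x$chrom,
      position = rep.int(x$pos, k),
      base = code_to_base(as.vector(x$base)),
      stringsAsFactors = FALSE
    )
  }))
  class(truth) <- c("truth_set", "data.frame")
  list(het_positions = het %||% data.frame(chromosome = character(),
                                           position = integer()),
       truth = truth)
}

#' Simulate reduced long reads from a truth set
#'
#' Reads are placed with uniform random starts (drawn so that coverage is
#' uniform along the whole chromosome, reads being clipped at both
#' chromosome ends), lengths drawn from a truncated normal, per haplotype
#' until the target coverage is reached. At each heterozygous position a
#' read covers, it emits its haplotype's base, flipped to a uniformly random
#' different base with probability `error_rate`. A configurable fraction of
#' reads is emitted as two same-chromosome split segments. Reads are
#' simulated directly in reduced-read space: the phasing engine never
#' consults bases between heterozygous positions, so no nucleotide-level
#' sequence is generated. Reads covering no heterozygous position are
#' dropped. Each read records its true haplotype (used only by evaluation).
#'
#' @param truth A [generate_truth()] result.
#' @param config The same [sim_config()]; reads are drawn from seed
#'   `config$seed + 1` so truth and reads are independently reproducible.
#' @return Named list of [reduced_read()] objects.
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  k <- config$ploidy
  haps <- .haplotype_names(k)
  het <- truth$het_positions
  tr <- truth$truth
  reads <- list()
  for (ch in unique(het$chromosome)) {
    pos <- het$position[het$chromosome == ch]
    tb <- matrix(
      base_to_code(tr$base[tr$chromosome == ch]),
      nrow = length(pos), ncol = k,
      dimnames = list(NULL, haps)
    )
    clen <- config$chromosome_length
    for (h in seq_len(k)) {
      target <- config$coverage * clen
      placed <- 0
      i <- 0L
      while (placed < target) {
        i <- i + 1L
        len <- max(50, round(stats::rnorm(1L, config$read_length_mean,
                                          config$read_length_sd)))
        # starts drawn over [1 - len + 1, clen] and clipped, so coverage is
        # uniform across the chromosome instead of ramping up at its start
        start0 <- sample.int(clen + len - 1L, 1L) - (len - 1L)
        start <- max(1L, start0)
        end <- min(clen, start0 + len - 1L)
        if (end < start) next
        placed <- placed + (end - start + 1L)
        id <- sprintf("sim_%s_%s_r%05d", ch, haps[[h]], i)
        is_split <- config$split_read_fraction > 0 &&
          stats::runif(1L) < config$split_read_fraction
        if (!is_split) {
          r <- .emit_segment(id, ch, start, end, pos, tb[, h],
                             config$error_rate, FALSE, haps[[h]])
          if (!is.null(r)) reads[[id]] <- r
        } else {
          bp <- start + floor((end - start) * stats::runif(1L, 0.3, 0.7))
          start2 <- sample.int(max(1L, clen - (end - bp)), 1L)
          end2 <- min(clen, start2 + (end - bp - 1L))
          for (seg in list(c(start, bp, 1L), c(start2, end2, 2L))) {
            sid <- sprintf("%s_p%d", id, seg[[3L]])
            r <- .emit_segment(sid, ch, seg[[1L]], seg[[2L]], pos, tb[, h],
                               config$error_rate, TRUE, haps[[h]])
            if (!is.null(r)) reads[[sid]] <- r
          }
        }
      }
    }
  }
  as_read_set(reads)
}

.emit_segment <- function(id, chrom, start, end, het_pos, hap_base,
                          error_rate, split, hap_name) {
  sel <- which(het_pos >= start & het_pos <= end)
  if (length(sel) == 0L) return(NULL)
  base <- hap_base[sel]
  if (error_rate > 0) {
    n_err <- stats::rbinom(1L, length(sel), error_rate)
    if (n_err > 0L) {
      at <- sample.int(length(sel), n_err)
      shift <- sample.int(3L, n_err, replace = TRUE)
      base[at] <- (base[at] - 1L + shift) %% 4L + 1L
    }
  }
  reduced_read(id, chrom, het_pos[sel], base, split = split,
               start = start, end = end, haplotype = hap_name)
}

#' Drop heterozygous positions to emulate variant-calling misses
#'
#' The phaser can only phase SNPs the variant-calling step identified; this
#' removes a seeded random fraction of the true heterozygous positions so
#' that downstream behaviour under incomplete variant calls can be studied.
#'
#' @param het_positions Data frame with `chromosome`, `position`.
#' @param miss_rate Fraction of positions to remove.
#' @param seed Optional seed.
#' @return The reduced het-position data frame.
#' @seealso [restrict_reads()] to apply the reduced set to simulated reads.
#' @export
degrade_variant_calls <- function(het_positions, miss_rate, seed = NULL) {
  stopifnot(miss_rate >= 0, miss_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(het_positions)
  n_drop <- round(miss_rate * n)
  if (n_drop == 0L) return(het_positions)
  drop <- sample.int(n, n_drop)
  het_positions[-drop, , drop = FALSE]
}

#' Restrict reads to a heterozygous-position set
#'
#' Intersects every read's calls with the given positions (used after
#' [degrade_variant_calls()]); reads left with no call are dropped.
#'
#' @param reads List of [reduced_read()] objects.
#' @param het_positions Data frame with `chromosome`, `position`.
#' @return Named list of restricted reads.
#' @export
restrict_reads <- function(reads, het_positions) {
  reads <- as_read_set(reads)
  out <- lapply(reads, function(r) {
    keep <- r$pos %in%
      het_positions$position[het_positions$chromosome == r$chrom]
    if (!any(keep)) return(NULL)
    r$pos <- r$pos[keep]
    r$base <- r$base[keep]
    if (!is.null(r$weight)) r$weight <- r$weight[keep]
    r
  })
  Filter(Negate(is.null), out)
}

#' Simulate a complete virtual polyploid dataset
#'
#' Convenience wrapper: generates truth, simulates reads, and optionally
#' degrades the variant-call set.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `het_positions`, `truth` (a `truth_set`) and
#'   `reads` (named list of [reduced_read()]).
#' @export
simulate_polyploid <- function(config = sim_config()) {
  tr <- generate_truth(config)
  reads <- simulate_reads(tr, config)
  if (config$variant_call_miss_rate > 0) {
    tr$het_positions <- degrade_variant_calls(
      tr$het_positions, config$variant_call_miss_rate,
      seed = config$seed + 2L
    )
    reads <- restrict_reads(reads, tr$het_positions)
  }
  list(config = config, het_positions = tr$het_positions,
       truth = tr$truth, reads = reads)
}
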