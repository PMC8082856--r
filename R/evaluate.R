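#' Assign haplotigs to truth haplotypes
#'
#' Each haplotig is assigned to the haplotype whose truth bases it matches at
#' the largest number of its consensus positions (a position with a tied
#' consensus matches when any tied base equals the truth base). Exact ties
#' are broken by match fraction, then by lexicographic haplotype name; a
#' haplotig with no consensus position in the truth set is assigned
#' `"unknown"` and excluded from the accuracy accounting.
#'
#' @param haplotigs List of `haplotig` objects.
#' @param truth A `truth_set` data frame (`haplotype`, `chromosome`,
#'   `position`, `base`).
#' @return Named character vector, haplotig id -> haplotype name.
#' @export
assign_haplotigs <- function(haplotigs, truth) {
  haps <- sort(unique(truth$haplotype))
  tl <- .truth_lookup(truth)
  out <- vapply(haplotigs, function(h) {
    scores <- vapply(haps, function(hp) {
      tb <- tl(hp, h$chrom, h$pos)
      ok <- !is.na(tb)
      if (!any(ok)) return(c(0, 0))
      c(sum(bitwAnd(h$consensus_mask[ok], .BITS[tb[ok]]) > 0L), sum(ok))
    }, numeric(2))
    if (all(scores[2L, ] == 0)) return("unknown")
    best <- which(scores[1L, ] == max(scores[1L, ]))
    if (length(best) > 1L) {
      frac <- scores[1L, best] / pmax(1, scores[2L, best])
      best <- best[frac == max(frac)]
    }
    haps[[best[[1L]]]]   # remaining ties: lexicographic (haps is sorted)
  }, character(1))
  names(out) <- vapply(haplotigs, `[[`, character(1), "id")
  out
}

# closure: (haplotype, chrom, positions) -> truth base codes (NA if absent)
.truth_lookup <- function(truth) {
  key <- paste(truth$haplotype, truth$chromosome, truth$position, sep = "\r")
  code <- base_to_code(truth$base)
  function(hp, chrom, pos) {
    code[match(paste(hp, chrom, pos, sep = "\r"), key)]
  }
}

#' Truth-based accuracy and contiguity metrics
#'
#' For every (haplotype, heterozygous position) pair of the truth set: TP
#' when some haplotig assigned to that haplotype calls the correct base
#' there; FN when no assigned haplotig covers the position at all. FP counts
#' every haplotig consensus position whose base set does not contain the
#' assigned haplotype's truth base (a tied position counts once, and is
#' erroneous only when no tied base matches). The three rates share the
#' denominator TP + FP + FN, so accuracy + error + missing = 100 exactly.
#' Contiguity is reported as haplotigs per haplotype (total haplotig count
#' over ploidy, genome-wide and averaged per chromosome) and as L90: the
#' minimal number of assigned haplotigs whose consensus positions cover at
#' least 90% of a haplotype's truth SNPs on a chromosome (NA when even all
#' of them cannot).
#'
#' @param haplotigs List of `haplotig` objects.
#' @param assignment Result of [assign_haplotigs()].
#' @param truth A `truth_set` data frame.
#' @return An object of class `metrics_report`: list with `rates`
#'   (accuracy/error/missing, percent), `counts` (TP/FP/FN),
#'   `haplotigs_per_haplotype`, `haplotigs_per_haplotype_by_chrom`, `l90`
#'   (data frame), `assignment`, and `n_unknown`.
#' @export
compute_metrics <- function(haplotigs, assignment, truth) {
  haps <- sort(unique(truth$haplotype))
  ploidy <- length(haps)
  tl <- .truth_lookup(truth)
  ids <- vapply(haplotigs, `[[`, character(1), "id")
  names(haplotigs) <- ids
  known <- ids[assignment[ids] != "unknown"]

  tp <- 0L
  fp <- 0L
  covered_correct <- character()  # keys of (hap, chrom, pos) hit correctly
  covered_any <- character()
  for (id in known) {
    h <- haplotigs[[id]]
    hp <- assignment[[id]]
    tb <- tl(hp, h$chrom, h$pos)
    ok <- !is.na(tb)
    good <- ok & bitwAnd(h$consensus_mask, ifelse(is.na(tb), 0L, .BITS[tb])) > 0L
    fp <- fp + sum(ok & !good)
    covered_any <- c(covered_any,
                     paste(hp, h$chrom, h$pos[ok], sep = "\r"))
    covered_correct <- c(covered_correct,
                         paste(hp, h$chrom, h$pos[good], sep = "\r"))
  }
  truth_keys <- paste(truth$haplotype, truth$chromosome, truth$position,
                      sep = "\r")
  tp <- sum(truth_keys %in% covered_correct)
  fn <- sum(!(truth_keys %in% covered_any))
  denom <- tp + fp + fn
  rates <- if (denom == 0) {
    c(accuracy = 0, error = 0, missing = 100)
  } else {
    c(accuracy = 100 * tp / denom, error = 100 * fp / denom,
      missing = 100 * fn / denom)
  }
  if (length(haplotigs) == 0L) rates <- c(accuracy = 0, error = 0, missing = 100)

  chroms <- sort(unique(truth$chromosome))
  n_by_chrom <- table(factor(
    vapply(haplotigs[known], `[[`, character(1), "chrom"), levels = chroms
  ))
  hph <- length(known) / ploidy
  hph_chrom <- mean(as.numeric(n_by_chrom) / ploidy)

  l90 <- do.call(rbind, lapply(chroms, function(ch) {
    pos_ch <- unique(truth$position[truth$chromosome == ch])
    data.frame(
      chromosome = ch, haplotype = haps,
      l90 = vapply(haps, function(hp) {
        sets <- lapply(haplotigs[known][assignment[known] == hp &
          vapply(haplotigs[known], `[[`, character(1), "chrom") == ch],
          `[[`, "pos")
        .l90(sets, pos_ch)
      }, integer(1)),
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(rates = rates, counts = c(TP = tp, FP = fp, FN = fn),
         haplotigs_per_haplotype = hph,
         haplotigs_per_haplotype_by_chrom = hph_chrom,
         l90 = l90, assignment = assignment,
         n_unknown = sum(assignment == "unknown")),
    class = "metrics_report"
  )
}

# greedy minimal haplotig count covering >= 90% of the truth positions
.l90 <- function(pos_sets, truth_pos) {
  need <- ceiling(0.9 * length(truth_pos))
  if (need == 0L) return(0L)
  covered <- logical(length(truth_pos))
  used <- 0L
  sets <- lapply(pos_sets, function(p) truth_pos %in% p)
  while (sum(covered) < need) {
    gain <- vapply(sets, function(s) sum(s & !covered), integer(1))
    if (length(gain) == 0L || max(gain) == 0L) return(NA_integer_)
    k <- which.max(gain)
    covered <- covered | sets[[k]]
    sets[[k]] <- NULL
    used <- used + 1L
  }
  used
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  accuracy %.1f%%  error %.1f%%  missing %.1f%%  (TP %d, FP %d, FN %d)\n",
              x$rates[["accuracy"]], x$rates[["error"]], x$rates[["missing"]],
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("  haplotigs per haplotype: %.2f genome-wide, %.2f per chromosome\n",
              x$haplotigs_per_haplotype, x$haplotigs_per_haplotype_by_chrom))
  cat(sprintf("  L90 = 1 for %d of %d (chromosome, haplotype) pairs; %d unassignable haplotig(s)\n",
              sum(x$l90$l90 == 1L, na.rm = TRUE), nrow(x$l90), x$n_unknown))
  invisible(x)
}

#' Windowed coverage profile of haplotigs
#'
#' Computes, for each haplotig, the mean read depth of its member reads in
#' fixed windows along the chromosome. In a well-phased region each
#' haplotype's haplotig carries about the per-haplotype share of the read
#' depth; a haplotig whose depth is twice its neighbours' typically covers a
#' haplotype present in two genome copies.
#'
#' @param clusters List of `haplotig` objects.
#' @param reads The read set behind the clusters (aligned spans are taken
#'   from the reads' `start`/`end`).
#' @param window Window size in bp (default 5000).
#' @param coverage_fraction When not `NULL`, restrict the profile to the
#'   longest haplotigs that together account for this fraction of the total
#'   member-read coverage (e.g. 0.9).
#' @return Data frame with `haplotig`, `chromosome`, `window_start`,
#'   `window_end`, `depth`.
#' @export
coverage_profile <- function(clusters, reads, window = 5000L,
                             coverage_fraction = NULL) {
  reads <- as_read_set(reads)
  if (length(clusters) == 0L) {
    return(data.frame(haplotig = character(), chromosome = character(),
                      window_start = integer(), window_end = integer(),
                      depth = numeric()))
  }
  if (!is.null(coverage_fraction)) {
    cov <- vapply(clusters, function(h) {
      sum(vapply(reads[h$members], function(r) r$end - r$start + 1,
                 numeric(1)))
    }, numeric(1))
    ord <- order(cov, decreasing = TRUE)
    keep <- ord[cumsum(cov[ord]) <= coverage_fraction * sum(cov)]
    if (length(keep) == 0L) keep <- ord[[1L]]
    clusters <- clusters[sort(keep)]
  }
  out <- lapply(clusters, function(h) {
    rs <- reads[h$members]
    lo <- min(vapply(rs, `[[`, integer(1), "start"))
    hi <- max(vapply(rs, `[[`, integer(1), "end"))
    w0 <- seq.int(as.integer(floor((lo - 1) / window)) * window + 1L, hi,
                  by = window)
    depth <- vapply(w0, function(ws) {
      we <- ws + window - 1L
      sum(vapply(rs, function(r) {
        max(0L, min(r$end, we) - max(r$start, ws) + 1L)
      }, numeric(1))) / window
    }, numeric(1))
    data.frame(haplotig = h$id, chromosome = h$chrom, window_start = w0,
               window_end = w0 + window - 1L, depth = depth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' In-cluster allele frequency distribution
#'
#' Tallies the member reads' raw (unweighted) base calls at each of the
#' cluster's positions and reports the per-position allele frequencies for
#' positions covered by at least `min_depth` reads. A pure cluster sequenced
#' with error rate e shows major-allele frequencies concentrated near 1 - e;
#' a chimera of two equally covered haplotypes is enriched at frequencies
#' near 0.5 wherever the two haplotypes disagree, which is what the flag
#' detects.
#'
#' @param cluster A `haplotig`.
#' @param reads The read set behind the cluster.
#' @param min_depth Minimal member-read depth for a position to qualify
#'   (default 20).
#' @param balance_band Major-allele frequency range regarded as balanced
#'   (default `c(0.3, 0.7)`).
#' @param flag_fraction Flag the cluster as a candidate chimera when more
#'   than this fraction of qualifying positions is balanced (default 0.2).
#' @return Data frame with `position`, `depth`, `major_freq`, plus
#'   attributes `fraction_balanced` and `chimera_flag`.
#' @export
allele_frequency_distribution <- function(cluster, reads, min_depth = 20L,
                                          balance_band = c(0.3, 0.7),
                                          flag_fraction = 0.2) {
  reads <- as_read_set(reads)
  counts <- matrix(0L, length(cluster$pos), 4L,
                   dimnames = list(NULL, .BASES))
  for (m in cluster$members) {
    r <- reads[[m]]
    i <- match(r$pos, cluster$pos)
    ij <- cbind(i, r$base)
    counts[ij] <- counts[ij] + 1L
  }
  depth <- rowSums(counts)
  sel <- depth >= min_depth
  out <- data.frame(
    position = cluster$pos[sel],
    depth = depth[sel],
    major_freq = if (any(sel)) {
      apply(counts[sel, , drop = FALSE], 1L, max) / depth[sel]
    } else {
      numeric()
    }
  )
  balanced <- out$major_freq >= balance_band[[1L]] &
    out$major_freq <= balance_band[[2L]]
  frac <- if (nrow(out)) mean(balanced) else 0
  attr(out, "fraction_balanced") <- frac
  attr(out, "chimera_flag") <- frac > flag_fraction
  out
}
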