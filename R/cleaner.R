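#' Discordance of a cluster
#'
#' The proportion of member base calls that disagree with the cluster's
#' consensus — equivalently, the summed minor allele frequencies across the
#' cluster's positions, normalised by the total number of calls. A call that
#' agrees with any tied consensus base counts as concordant; a single-read
#' cluster therefore has discordance 0.
#'
#' @param cluster A `haplotig`.
#' @param reads The read set the cluster's members refer to.
#' @return Fraction in `[0, 1]`.
#' @export
discordance <- function(cluster, reads) {
  reads <- as_read_set(reads)
  total <- 0L
  disagree <- 0L
  for (m in cluster$members) {
    r <- reads[[m]]
    i <- match(r$pos, cluster$pos)
    total <- total + length(r$pos)
    disagree <- disagree +
      sum(bitwAnd(.BITS[r$base], cluster$consensus_mask[i]) == 0L)
  }
  if (total == 0L) return(0)
  disagree / total
}

#' Step 1 of cleaning: discordance-gated merging
#'
#' Computes each raw cluster's discordance and fixes the mean discordance
#' across all input clusters as the stopping threshold, once, before any
#' merge. Then repeatedly merges the positionally overlapping same-chromosome
#' pair whose hypothetical merged discordance is lowest, provided that value
#' is below the threshold; tallies and consensus are recomputed on each
#' merge. Pairs of clusters that can merge without rising above the average
#' discordance are, by that token, unlikely to be two different haplotypes.
#'
#' @param clusters List of `haplotig` objects.
#' @param reads The read set behind the clusters.
#' @return List of `haplotig` objects (never more than the input count; the
#'   read multiset is conserved). The fixed threshold is attached as
#'   attribute `discordance_threshold`.
#' @export
merge_by_discordance <- function(clusters, reads) {
  reads <- as_read_set(reads)
  clusters <- unname(clusters)
  if (length(clusters) <= 1L) return(clusters)
  threshold <- mean(vapply(clusters, discordance, numeric(1), reads))
  repeat {
    n <- length(clusters)
    if (n <= 1L) break
    best <- NULL
    best_disc <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ci <- clusters[[i]]
        cj <- clusters[[j]]
        if (ci$chrom != cj$chrom) next
        if (length(intersect(ci$pos, cj$pos)) == 0L) next
        m <- merge_haplotigs(ci, cj)
        d <- discordance(m, reads)
        if (d < best_disc) {
          best_disc <- d
          best <- c(i, j)
        }
      }
    }
    if (is.null(best) || best_disc >= threshold) break
    merged <- merge_haplotigs(clusters[[best[[1L]]]], clusters[[best[[2L]]]])
    clusters <- c(clusters[-best], list(merged))
  }
  attr(clusters, "discordance_threshold") <- threshold
  clusters
}

#' Step 2 of cleaning: low-coverage filtering
#'
#' A cluster's coverage is the total number of heterozygous-position calls
#' its member reads contribute. Clusters are sorted by ascending coverage
#' and removed greedily from the smallest while the cumulative removed
#' coverage stays within `fraction` of the total; at least one cluster is
#' always retained. This discards the small noisy clusters that accumulate
#' at the tail of raw results.
#'
#' @param clusters List of `haplotig` objects.
#' @param reads The read set behind the clusters.
#' @param fraction Coverage budget to remove (default 0.01, the smallest 1%).
#' @return Filtered list of `haplotig` objects.
#' @export
filter_low_coverage <- function(clusters, reads, fraction = 0.01) {
  if (length(clusters) <= 1L) return(clusters)
  reads <- as_read_set(reads)
  cov <- vapply(clusters, function(h) {
    sum(lengths(lapply(reads[h$members], `[[`, "pos")))
  }, numeric(1))
  ids <- vapply(clusters, `[[`, character(1), "id")
  ord <- order(cov, ids, method = "radix")
  budget <- fraction * sum(cov)
  cum <- cumsum(cov[ord])
  drop <- ord[cum <= budget]
  if (length(drop) >= length(clusters)) {
    drop <- drop[-length(drop)]   # never remove everything
  }
  if (length(drop) == 0L) return(clusters)
  clusters[-drop]
}

#' Step 3 of cleaning: gap filling
#'
#' For each chromosome, each haplotig counts as 1X of haplotig-level
#' coverage over its span (in heterozygous-position coordinates). The mean
#' multiplicity over the chromosome, rounded half-up, gives the expected
#' haplotig count `n`. A region covered by fewer than `n` haplotigs usually
#' means a large region carries the same haplotype in two or more genome
#' copies, so the reads of both copies were clustered together: the most
#' read-covered cluster in the region has its region-overlapping reads
#' split into two balanced halves (seeded random partition), one of which
#' becomes a new haplotig over the region. Repeats until no region is below
#' `n` or no donor has at least two reads in the region.
#'
#' Only regions of at least `min_region` heterozygous positions are filled:
#' a duplicated-haplotype block shorter than the minimal informative
#' overlap cannot be phased on its own, and the few-position dips that
#' haplotig span jitter leaves at chromosome ends are not gaps.
#'
#' @param clusters List of `haplotig` objects.
#' @param reads The read set behind the clusters (weighted reads keep their
#'   weights through the split).
#' @param min_region Minimal extent, in heterozygous positions, for an
#'   under-covered region to be considered a gap (default 10).
#' @return List of `haplotig` objects; the read multiset is conserved.
#' @export
fill_gaps <- function(clusters, reads, min_region = 10L) {
  reads <- as_read_set(reads)
  clusters <- unname(clusters)
  for (ch in unique(vapply(clusters, `[[`, character(1), "chrom"))) {
    stuck <- integer()   # region start positions that cannot be filled
    n_fill <- 0L
    # the target multiplicity is fixed once, from the raw haplotig profile
    on_ch0 <- which(vapply(clusters, `[[`, character(1), "chrom") == ch)
    pos_univ <- sort(unique(unlist(lapply(clusters[on_ch0], `[[`, "pos"))))
    mult0 <- rep(0L, length(pos_univ))
    for (h in clusters[on_ch0]) {
      mult0 <- mult0 + (pos_univ >= h$span[[1L]] & pos_univ <= h$span[[2L]])
    }
    n_target <- round_half_up(mean(mult0))
    repeat {
      on_ch <- which(vapply(clusters, `[[`, character(1), "chrom") == ch)
      mult <- rep(0L, length(pos_univ))
      for (h in clusters[on_ch]) {
        mult <- mult + (pos_univ >= h$span[[1L]] & pos_univ <= h$span[[2L]])
      }
      low <- mult < n_target
      runs <- .low_runs(low)
      runs <- runs[vapply(runs, function(r) r[[2L]] - r[[1L]] + 1L,
                          integer(1)) >= min_region]
      runs <- runs[!(pos_univ[vapply(runs, `[[`, integer(1), 1L)] %in% stuck)]
      if (length(runs) == 0L) break
      filled <- FALSE
      for (run in runs) {
        region <- pos_univ[run[[1L]]:run[[2L]]]
        region_key <- pos_univ[[run[[1L]]]]
        # donor: the cluster with most member-read calls inside the region
        region_members <- lapply(clusters[on_ch], function(h) {
          h$members[vapply(reads[h$members], function(r) {
            any(r$pos %in% region)
          }, logical(1))]
        })
        region_cov <- vapply(region_members, function(mm) {
          sum(vapply(reads[mm], function(r) sum(r$pos %in% region),
                     numeric(1)))
        }, numeric(1))
        donor_k <- which.max(region_cov)
        donors <- region_members[[donor_k]]
        if (length(donors) < 2L) {
          stuck <- c(stuck, region_key)
          next
        }
        donor <- clusters[[on_ch[[donor_k]]]]
        # seeded random balanced split of the donor's region reads
        half <- sample(donors, floor(length(donors) / 2L))
        stay <- setdiff(donor$members, half)
        n_fill <- n_fill + 1L
        new_id <- sprintf("%s_fill%d", donor$id, n_fill)
        clusters[[on_ch[[donor_k]]]] <- cluster_from_reads(reads[stay],
                                                           donor$id)
        clusters <- c(clusters, list(cluster_from_reads(reads[half],
                                                        new_id)))
        # a split that cannot raise the region's multiplicity is final
        newc <- clusters[[length(clusters)]]
        if (!any(region >= newc$span[[1L]] & region <= newc$span[[2L]])) {
          stuck <- c(stuck, region_key)
        }
        filled <- TRUE
        break
      }
      if (!filled || n_fill > length(reads)) break
    }
  }
  clusters
}

# maximal runs of TRUE in a logical vector, as list(c(start, end))
.low_runs <- function(low) {
  if (!any(low)) return(list())
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

#' Three-step automated cleaning of raw phasing results
#'
#' Applies, in order: discordance-gated merging ([merge_by_discordance()]),
#' low-coverage filtering ([filter_low_coverage()]) and gap filling
#' ([fill_gaps()]). Gap filling can be disabled, which is advisable for
#' genomes with large hemizygous or collapsed regions where the haplotig
#' multiplicity profile is not informative.
#'
#' @param clusters Raw clusters from [run_phasing()] or
#'   [phase_with_stitching()].
#' @param reads The read set behind the clusters.
#' @param filter_fraction Coverage budget of the filtering step.
#' @param gap_fill Set `FALSE` to skip step 3.
#' @param min_region See [fill_gaps()].
#' @param seed Optional seed for the gap-filling read split.
#' @return List of `haplotig` objects.
#' @export
clean_haplotigs <- function(clusters, reads, filter_fraction = 0.01,
                            gap_fill = TRUE, min_region = 10L,
                            seed = NULL) {
  if (length(clusters) == 0L) return(list())
  if (!is.null(seed)) set.seed(seed)
  reads <- as_read_set(reads)
  out <- merge_by_discordance(clusters, reads)
  out <- filter_low_coverage(out, reads, filter_fraction)
  if (gap_fill) out <- fill_gaps(out, reads, min_region)
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, function(h) h$span[[1L]], integer(1)),
               method = "radix")
  out <- out[ord]
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}
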