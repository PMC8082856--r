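#' Edge SNPs of first-pass haplotigs
#'
#' Split-read alignments are too unreliable to use wholesale, but haplotig
#' edges often mark structural variants, and the split-read calls that fall
#' on those edges are exactly the ones able to connect two haplotigs
#' separated by such a variant. This collects the first and last
#' `edge_size` covered heterozygous positions of every cluster.
#'
#' @param clusters List of `haplotig` objects from a completed first pass.
#' @param edge_size Number of heterozygous positions per cluster edge
#'   (default 10, the same scale as the minimal pair overlap).
#' @return Data frame with `chromosome`, `position` — the union of all
#'   cluster edges.
#' @export
find_edge_snps <- function(clusters, edge_size = 10L) {
  rows <- lapply(clusters, function(h) {
    n <- length(h$pos)
    take <- unique(c(seq_len(min(edge_size, n)),
                     seq.int(max(1L, n - edge_size + 1L), n)))
    data.frame(chromosome = h$chrom, position = h$pos[take],
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows) %||%
                  data.frame(chromosome = character(), position = integer()))
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict split reads to edge SNPs
#'
#' Intersects each split-read segment's calls with the edge-SNP set; the
#' per-call vote weights assigned by [weight_reads()] follow the retained
#' calls. Segments left with fewer than two calls are dropped.
#'
#' @param split_reads List of [reduced_read()] objects, all with
#'   `is_split_segment = TRUE` (anything else is an error).
#' @param edge_snps Data frame from [find_edge_snps()].
#' @return Named list of restricted split reads.
#' @export
restrict_split_reads <- function(split_reads, edge_snps) {
  split_reads <- as_read_set(split_reads)
  if (!all(vapply(split_reads, `[[`, logical(1), "split"))) {
    stop("restrict_split_reads() expects split-read segments only")
  }
  out <- lapply(split_reads, function(r) {
    keep <- r$pos %in% edge_snps$position[edge_snps$chromosome == r$chrom]
    if (sum(keep) < 2L) return(NULL)
    r$pos <- r$pos[keep]
    r$base <- r$base[keep]
    if (!is.null(r$weight)) r$weight <- r$weight[keep]
    r
  })
  Filter(Negate(is.null), out)
}

#' Re-run phasing with restricted split reads included
#'
#' Runs the clustering engine from scratch on the union of the first-pass
#' reads and the edge-restricted split reads. Clusters still never combine
#' reads from different reference chromosomes, so split reads can only
#' improve the contiguity of haplotigs on the same chromosome.
#'
#' @param first_pass_reads The (weighted) reads of the first pass.
#' @param restricted_split_reads Output of [restrict_split_reads()].
#' @param context_table Context table of the full dataset (not rebuilt for
#'   this pass; restricted split reads are fragments of already-counted
#'   calls and carry their weights).
#' @param params A [phase_params()].
#' @return As [run_phasing()].
#' @export
rerun_with_split <- function(first_pass_reads, restricted_split_reads,
                             context_table, params = phase_params()) {
  run_phasing(c(as_read_set(first_pass_reads),
                .combine_split_segments(restricted_split_reads)),
              context_table, params)
}

# Segments of one underlying read that landed on the same chromosome are
# re-joined into a single call sequence for the stitching pass: only as one
# read can they connect the two haplotig edges they touch. Segments on
# different chromosomes stay separate (cross-chromosome merging is
# forbidden anyway).
.combine_split_segments <- function(segments) {
  segments <- as_read_set(segments)
  if (length(segments) == 0L) return(segments)
  parent <- sub("_p[0-9]+$", "", names(segments))
  chrom <- vapply(segments, `[[`, character(1), "chrom")
  groups <- split(seq_along(segments), paste(parent, chrom, sep = "\r"))
  out <- lapply(groups, function(ii) {
    if (length(ii) == 1L) return(segments[[ii]])
    pos <- unlist(lapply(segments[ii], `[[`, "pos"))
    base <- unlist(lapply(segments[ii], `[[`, "base"))
    weight <- unlist(lapply(segments[ii], `[[`, "weight"))
    ord <- order(pos)
    keep <- !duplicated(pos[ord])
    first <- segments[[ii[[1L]]]]
    reduced_read(
      paste0(parent[[ii[[1L]]]], "_stitch"), first$chrom,
      pos[ord][keep], base[ord][keep], split = TRUE,
      start = min(vapply(segments[ii], `[[`, integer(1), "start")),
      end = max(vapply(segments[ii], `[[`, integer(1), "end")),
      weight = if (!is.null(weight)) weight[ord][keep],
      haplotype = first$haplotype
    )
  })
  as_read_set(unname(out))
}

#' Two-pass phasing with split-read stitching
#'
#' First pass: cluster the non-split reads. Second pass: restrict the
#' split-read segments to the SNPs at the edges of the first-pass clusters
#' and re-run the engine with them included. With no split-read segments
#' (or `use_split_reads = FALSE`) the result is the first pass, unchanged.
#'
#' @param reads All reduced reads (split segments included), weighted.
#' @param context_table A [build_context_table()] over `reads`.
#' @param params A [phase_params()].
#' @param edge_size See [find_edge_snps()].
#' @param use_split_reads Set `FALSE` to disable the second pass.
#' @return As [run_phasing()]; the number of passes run is attached as
#'   attribute `passes`.
#' @export
phase_with_stitching <- function(reads, context_table = NULL,
                                 params = phase_params(), edge_size = 10L,
                                 use_split_reads = TRUE) {
  reads <- as_read_set(reads)
  is_split <- vapply(reads, `[[`, logical(1), "split")
  first <- run_phasing(reads[!is_split], context_table, params)
  if (!use_split_reads || !any(is_split)) {
    attr(first, "passes") <- 1L
    return(first)
  }
  edges <- find_edge_snps(first, edge_size)
  restricted <- restrict_split_reads(reads[is_split], edges)
  if (length(restricted) == 0L) {
    attr(first, "passes") <- 1L
    return(first)
  }
  second <- rerun_with_split(reads[!is_split], restricted,
                             context_table, params)
  attr(second, "passes") <- 2L
  second
}
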