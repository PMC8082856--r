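#' Haplotig (read cluster) objects
#'
#' A haplotig is a cluster of reduced reads together with its per-position
#' weighted vote tallies and the consensus base set derived from them. The
#' consensus at a position is the argmax set of the tallies: when two bases
#' are tied, both are part of the consensus.
#'
#' @param reads List of [reduced_read()] objects on one chromosome, normally
#'   carrying vote weights (see [weight_reads()]); unweighted calls vote
#'   with weight 1.
#' @param id Cluster identifier.
#' @return An object of class `haplotig` with fields `id`, `chrom`,
#'   `members` (read ids), `pos` (covered positions, ascending), `tallies`
#'   (length(pos) x 4 weight matrix, columns A,C,G,T), `consensus_mask`
#'   (integer base-set bitmask per position) and `span`.
#' @export
cluster_from_reads <- function(reads, id = "htg") {
  reads <- as_read_set(reads)
  stopifnot(length(reads) > 0L)
  chrom <- unique(vapply(reads, `[[`, character(1), "chrom"))
  if (length(chrom) != 1L) {
    stop("all member reads of a haplotig must be on one chromosome")
  }
  pos <- sort(unique(unlist(lapply(reads, `[[`, "pos"))))
  tallies <- matrix(0, length(pos), 4L, dimnames = list(NULL, .BASES))
  for (r in reads) {
    w <- r$weight %||% rep(1, length(r$pos))
    i <- match(r$pos, pos)
    ij <- cbind(i, r$base)
    tallies[ij] <- tallies[ij] + w
  }
  .new_haplotig(id, chrom, names(reads), pos, tallies)
}

.new_haplotig <- function(id, chrom, members, pos, tallies) {
  structure(
    list(id = id, chrom = chrom, members = members, pos = pos,
         tallies = tallies, consensus_mask = .consensus_mask(tallies),
         span = c(pos[[1L]], pos[[length(pos)]])),
    class = "haplotig"
  )
}

# argmax base set of a tally matrix, as a bitmask per row
.consensus_mask <- function(tallies) {
  mx <- pmax(tallies[, 1L], tallies[, 2L], tallies[, 3L], tallies[, 4L])
  mask <- (tallies[, 1L] == mx) * 1L + (tallies[, 2L] == mx) * 2L +
    (tallies[, 3L] == mx) * 4L + (tallies[, 4L] == mx) * 8L
  mask[mx == 0] <- 0L
  as.integer(mask)
}

#' @export
print.haplotig <- function(x, ...) {
  cat(sprintf("<haplotig> %s  %s:%d-%d  %d reads, %d positions\n",
              x$id, x$chrom, x$span[[1L]], x$span[[2L]],
              length(x$members), length(x$pos)))
  invisible(x)
}

#' Consensus calls of a haplotig as a data frame
#'
#' @param x A `haplotig`.
#' @param ... Unused.
#' @return Data frame with columns `chromosome`, `position`, `base`, sorted
#'   by position; a position with a tied consensus contributes one row per
#'   tied base.
#' @export
as.data.frame.haplotig <- function(x, ...) {
  n_bases <- vapply(x$consensus_mask, function(m) sum(bitwAnd(m, .BITS) > 0L),
                    integer(1))
  pos <- rep.int(x$pos, n_bases)
  base <- code_to_base(unlist(lapply(x$consensus_mask, mask_to_codes),
                              use.names = FALSE))
  data.frame(chromosome = x$chrom, position = pos, base = base,
             stringsAsFactors = FALSE)
}

# merge two haplotigs by summing tallies over the union of their positions
merge_haplotigs <- function(h1, h2, id = h1$id) {
  stopifnot(h1$chrom == h2$chrom)
  pos <- sort(unique(c(h1$pos, h2$pos)))
  tallies <- matrix(0, length(pos), 4L, dimnames = list(NULL, .BASES))
  tallies[match(h1$pos, pos), ] <- h1$tallies
  i2 <- match(h2$pos, pos)
  tallies[i2, ] <- tallies[i2, ] + h2$tallies
  .new_haplotig(id, h1$chrom, union(h1$members, h2$members), pos, tallies)
}

# (pos, mask) view of a read or haplotig, for similarity computations
.call_profile <- function(x) {
  if (inherits(x, "haplotig")) {
    list(chrom = x$chrom, pos = x$pos, mask = x$consensus_mask)
  } else if (inherits(x, "reduced_read")) {
    list(chrom = x$chrom, pos = x$pos, mask = .BITS[x$base])
  } else {
    stop("expected a reduced_read or haplotig, got ", class(x)[[1L]])
  }
}
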