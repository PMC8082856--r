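#' Construct a reduced read
#'
#' A reduced read is a long read (or one segment of a split read) represented
#' only by its base calls at known heterozygous SNP positions: an ordered
#' sparse vector of `(position, base)` pairs on a single chromosome. This is
#' the unit of information the phasing engine clusters; the bases between
#' heterozygous positions are never consulted.
#'
#' @param read_id Character scalar, unique read (segment) identifier.
#' @param chrom Character scalar, reference chromosome of the calls.
#' @param pos Integer vector of 1-based reference positions, strictly
#'   ascending, all members of the heterozygous-position set in use.
#' @param base Base calls, one per position: characters in `A,C,G,T` or
#'   integer codes 1:4.
#' @param split Logical, `TRUE` if this read is one segment of a split
#'   (supplementary) alignment.
#' @param start,end Optional aligned span of the read in reference
#'   coordinates (used for coverage profiles); defaults to the range of
#'   `pos`.
#' @param weight Optional numeric vector of per-call vote weights (normally
#'   assigned later by [weight_reads()]).
#' @param haplotype Optional true haplotype label (set by the simulator,
#'   consulted only by evaluation code).
#'
#' @return An object of class `reduced_read`.
#' @seealso [read_reduced_reads()], [reduce_alignments()], [simulate_reads()]
#' @export
reduced_read <- function(read_id, chrom, pos, base, split = FALSE,
                         start = NULL, end = NULL, weight = NULL,
                         haplotype = NULL) {
  pos <- as.integer(pos)
  code <- base_to_code(base)
  if (length(pos) == 0L) {
    stop("reduced read '", read_id, "' has no calls")
  }
  if (length(code) != length(pos)) {
    stop("pos and base lengths differ for read '", read_id, "'")
  }
  if (anyNA(code)) {
    stop("read '", read_id, "' has base calls outside A/C/G/T")
  }
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("calls of read '", read_id, "' must be strictly ascending by position")
  }
  structure(
    list(
      read_id = as.character(read_id),
      chrom = as.character(chrom),
      pos = pos,
      base = code,
      weight = weight,
      split = isTRUE(split),
      start = as.integer(start %||% min(pos)),
      end = as.integer(end %||% max(pos)),
      haplotype = haplotype
    ),
    class = "reduced_read"
  )
}

#' @export
print.reduced_read <- function(x, ...) {
  cat(sprintf(
    "<reduced_read> %s  %s:%d-%d  %d calls%s\n",
    x$read_id, x$chrom, x$start, x$end, length(x$pos),
    if (x$split) "  [split segment]" else ""
  ))
  n <- min(8L, length(x$pos))
  cat("  ", paste0(x$pos[seq_len(n)], ":", code_to_base(x$base[seq_len(n)]),
                   collapse = ","),
      if (length(x$pos) > n) ",...\n" else "\n", sep = "")
  invisible(x)
}

# normalise a list of reduced reads into a named list keyed by read_id
as_read_set <- function(reads) {
  if (inherits(reads, "reduced_read")) reads <- list(reads)
  ids <- vapply(reads, `[[`, character(1), "read_id")
  if (anyDuplicated(ids)) {
    stop("duplicate read ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reads) <- ids
  reads
}

#' Write reduced reads to the tab-separated interchange format
#'
#' The format has one line per read: `read_id TAB chromosome TAB
#' comma-separated pos:base tokens TAB split-flag (0/1)`. It allows the
#' phasing engine to be exercised without any alignment files.
#'
#' @param reads List of [reduced_read()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reduced_reads <- function(reads, path) {
  reads <- as_read_set(reads)
  lines <- vapply(reads, function(r) {
    paste(r$read_id, r$chrom,
          paste0(r$pos, ":", code_to_base(r$base), collapse = ","),
          if (r$split) "1" else "0",
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read reduced reads from the tab-separated interchange format
#'
#' @param path File written by [write_reduced_reads()] (the fourth split-flag
#'   column may be absent, in which case no read is marked as a split
#'   segment).
#' @return Named list of [reduced_read()] objects.
#' @export
read_reduced_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  reads <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("malformed reduced-read line ", i, " in ", path)
    }
    tok <- strsplit(f[[3]], ",", fixed = TRUE)[[1]]
    pb <- strsplit(tok, ":", fixed = TRUE)
    pos <- suppressWarnings(as.integer(vapply(pb, `[[`, character(1), 1L)))
    base <- vapply(pb, `[[`, character(1), 2L)
    if (anyNA(pos)) stop("malformed call token on line ", i, " in ", path)
    reduced_read(f[[1]], f[[2]], pos, base,
                 split = length(f) >= 4L && f[[4]] == "1")
  })
  as_read_set(reads)
}

#' Remove reads that are subsets of other reads
#'
#' A read is dropped when another retained read on the same chromosome
#' contains all of its `(position, base)` calls. Among mutually identical
#' reads exactly one representative is retained. This pre-processing step
#' shrinks the clustering problem without discarding any phasing
#' information: a subset read can never change a consensus its superset
#' would not.
#'
#' @param reads List of [reduced_read()] objects reduced against the same
#'   heterozygous-position set.
#' @return Named list of retained reads, sorted by (chromosome, first call
#'   position, read id); the operation is idempotent.
#' @export
remove_subset_reads <- function(reads) {
  reads <- as_read_set(reads)
  if (length(reads) == 0L) return(reads)
  chroms <- vapply(reads, `[[`, character(1), "chrom")
  kept <- unlist(lapply(split(seq_along(reads), chroms), function(ii) {
    ii[.keep_non_subset(reads[ii])]
  }), use.names = FALSE)
  out <- reads[sort(kept)]
  ord <- order(
    vapply(out, `[[`, character(1), "chrom"),
    vapply(out, function(r) r$pos[[1]], integer(1)),
    vapply(out, `[[`, character(1), "read_id"),
    method = "radix"
  )
  out[ord]
}

# indices of reads (single chromosome) that are not subsets of another read
.keep_non_subset <- function(reads) {
  n <- length(reads)
  if (n == 1L) return(1L)
  allpos <- sort(unique(unlist(lapply(reads, `[[`, "pos"))))
  idx <- lapply(reads, function(r) match(r$pos, allpos))
  ncalls <- lengths(idx)
  i_all <- rep.int(seq_len(n), ncalls)
  p_all <- unlist(idx, use.names = FALSE)
  c_all <- unlist(lapply(reads, `[[`, "base"), use.names = FALSE)
  # match[a, b] = number of identical (pos, base) calls shared by a and b
  match_mat <- matrix(0, n, n)
  for (b in 1:4) {
    sel <- c_all == b
    if (!any(sel)) next
    Mb <- Matrix::sparseMatrix(i = p_all[sel], j = i_all[sel], x = 1,
                               dims = c(length(allpos), n))
    match_mat <- match_mat + as.matrix(Matrix::crossprod(Mb))
  }
  # canonical order for the identical-read tie: first by this order survives
  ord <- order(vapply(reads, function(r) r$pos[[1]], integer(1)),
               vapply(reads, `[[`, character(1), "read_id"),
               method = "radix")
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  removed <- logical(n)
  for (b in seq_len(n)) {
    full <- which(match_mat[, b] == ncalls[b])   # supersets incl. b itself
    full <- full[full != b]
    if (length(full) == 0L) next
    strict <- any(ncalls[full] > ncalls[b])
    identical_earlier <- any(ncalls[full] == ncalls[b] & rank[full] < rank[b])
    removed[b] <- strict || identical_earlier
  }
  which(!removed)
}
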