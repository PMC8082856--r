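#' Build the dataset-wide context-coverage table
#'
#' Long reads are error-prone and the pipeline deliberately performs no error
#' correction, so raw per-read calls cannot be trusted equally. Instead, each
#' call is weighted by how often the whole dataset has seen that same call in
#' the same local context: the up-to-two nearest upstream and up-to-two
#' nearest downstream heterozygous calls within the read (with explicit edge
#' markers where fewer exist). A sequencing error that converts a
#' well-supported SNP into a base that is well-supported on another haplotype
#' still sits in the wrong flanking context, so its context-coverage count —
#' and hence its vote — stays near 1.
#'
#' @param reads List of [reduced_read()] objects (after subset-read removal).
#' @return An object of class `context_table`: a keyed count table mapping
#'   `(chromosome, position, base, context)` to the number of reads carrying
#'   that call in that context. Counts at a position always sum to the number
#'   of read calls at that position.
#' @seealso [vote_weight()], [weight_reads()], [write_context_table()]
#' @export
build_context_table <- function(reads) {
  reads <- as_read_set(reads)
  keys <- unlist(lapply(reads, .read_context_keys), use.names = FALSE)
  dt <- data.table::data.table(ctx_key = keys)
  tab <- dt[, list(count = .N), by = "ctx_key"]
  data.table::setkeyv(tab, "ctx_key")
  structure(list(counts = tab, n_calls = length(keys)),
            class = "context_table")
}

# one key string per call of a read: chrom \t pos \t base \t context
.read_context_keys <- function(r) {
  n <- length(r$pos)
  tok <- paste0(r$pos, ":", code_to_base(r$base))
  pad <- c("^", "^", tok, "$", "$")
  i <- seq_len(n) + 2L
  ctx <- paste(pad[i - 2L], pad[i - 1L], pad[i + 1L], pad[i + 2L], sep = ",")
  paste(r$chrom, r$pos, code_to_base(r$base), ctx, sep = "\t")
}

#' @export
print.context_table <- function(x, ...) {
  cat(sprintf("<context_table> %d distinct (call, context) keys over %d calls\n",
              nrow(x$counts), x$n_calls))
  invisible(x)
}

#' Vote weight of one call of a read
#'
#' Looks up the context-coverage count of the read's call at `position`. By
#' construction the count is at least 1 for any read that was part of the
#' dataset the table was built from.
#'
#' @param read A [reduced_read()].
#' @param position Position of the call (must be one of the read's calls).
#' @param table A [build_context_table()] result built over the same dataset.
#' @return Positive integer vote weight.
#' @export
vote_weight <- function(read, position, table) {
  stopifnot(inherits(table, "context_table"))
  i <- match(as.integer(position), read$pos)
  if (is.na(i)) {
    stop("read '", read$read_id, "' has no call at position ", position)
  }
  key <- .read_context_keys(read)[[i]]
  w <- table$counts[list(key), on = "ctx_key"]$count
  if (is.na(w)) {
    stop("context key absent from table (table/dataset mismatch) for read '",
         read$read_id, "' at position ", position)
  }
  w
}

#' Attach per-call vote weights to a set of reads
#'
#' Computes each read's context key at every call and stores the
#' corresponding context-coverage counts in the read's `weight` field. The
#' weights are fixed here, before clustering starts, and are never updated
#' during merging. Weights attach to calls, so subsetting a read's calls
#' (as the split-read stitching pass does) keeps the original weights.
#'
#' @inheritParams build_context_table
#' @param table A [build_context_table()] result; by default built from
#'   `reads` themselves.
#' @return The reads, with numeric `weight` vectors parallel to their calls.
#' @export
weight_reads <- function(reads, table = build_context_table(reads)) {
  stopifnot(inherits(table, "context_table"))
  reads <- as_read_set(reads)
  lapply(reads, function(r) {
    key <- .read_context_keys(r)
    w <- table$counts[list(key), on = "ctx_key"]$count
    if (anyNA(w)) {
      stop("context key absent from table (table/dataset mismatch) for read '",
           r$read_id, "'")
    }
    r$weight <- as.numeric(w)
    r
  })
}

#' Dump a context-coverage table to TSV (for debugging)
#'
#' @param table A [build_context_table()] result.
#' @param path Output path; columns are chromosome, position, base, context,
#'   count.
#' @return `path`, invisibly.
#' @export
write_context_table <- function(table, path) {
  stopifnot(inherits(table, "context_table"))
  parts <- data.table::tstrsplit(table$counts$ctx_key, "\t", fixed = TRUE)
  out <- data.table::data.table(
    chromosome = parts[[1]],
    position = as.integer(parts[[2]]),
    base = parts[[3]],
    context = parts[[4]],
    count = table$counts$count
  )
  data.table::setorderv(out, c("chromosome", "position", "base", "context"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
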