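#' Extract heterozygous SNP positions from a VCF
#'
#' Two selection modes are supported. `het_genotype` (the default) keeps SNP
#' records whose first-sample genotype carries at least two distinct alleles
#' (0/1, 0/1/1, 1/2, ...), the conventional notion of a heterozygous call at
#' any ploidy. `af_1` keeps records whose INFO field has `AF = 1.00`; this
#' rule matches the virtual-polyploid validation design, where each
#' constituent strain is homozygous and every variant fixed in one strain is
#' a heterozygous site of the pooled polyploid. INDEL records are skipped
#' entirely — phased blocks are built from SNPs only — and at multiallelic
#' records only single-base alleles are considered.
#'
#' @param vcf_source Path to a VCF 4.x file.
#' @param mode `"het_genotype"` or `"af_1"`.
#' @return Data frame with columns `chromosome`, `position` (1-based, as in
#'   the VCF), unique and sorted; a warning is emitted when no position
#'   matches.
#' @export
parse_het_positions <- function(vcf_source,
                                mode = c("het_genotype", "af_1")) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    warning("no records in ", vcf_source)
    return(data.frame(chromosome = character(), position = integer()))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[[1L]], " of ", vcf_source)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  # a SNP record: single-base REF and at least one single-base ALT
  is_snp <- nchar(ref) == 1L &
    vapply(alt_list, function(a) any(nchar(a) == 1L & a %in% .BASES),
           logical(1))
  keep <- if (mode == "af_1") {
    info <- fix[, "INFO"]
    is_snp & grepl("(^|;)AF=1(\\.0+)?(;|$)", ifelse(is.na(info), "", info))
  } else {
    gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                   error = function(e) NULL)
    if (is.null(gt)) {
      stop("mode 'het_genotype' needs a genotype column in ", vcf_source)
    }
    g <- gt[, 1L]
    is_het <- vapply(strsplit(ifelse(is.na(g), "", g), "[/|]"), function(a) {
      a <- a[a != "." & nzchar(a)]
      length(unique(a)) >= 2L
    }, logical(1))
    is_snp & is_het
  }
  out <- unique(data.frame(chromosome = fix[keep, "CHROM"],
                           position = pos[keep],
                           stringsAsFactors = FALSE))
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no heterozygous SNP positions found in ", vcf_source,
            " with mode '", mode, "'")
  }
  out
}

#' Read or write a heterozygous-position TSV
#'
#' Plain two-column tab-separated alternative to a VCF: `chromosome`,
#' `position` (1-based), with a header line.
#'
#' @param path File path.
#' @param het_positions Data frame with `chromosome`, `position`.
#' @return `read_het_tsv` returns the data frame; `write_het_tsv` returns
#'   `path` invisibly.
#' @export
read_het_tsv <- function(path) {
  out <- utils::read.delim(path, colClasses = c("character", "integer"))
  names(out) <- c("chromosome", "position")
  out[order(out$chromosome, out$position), , drop = FALSE]
}

#' @rdname read_het_tsv
#' @export
write_het_tsv <- function(het_positions, path) {
  utils::write.table(het_positions[, c("chromosome", "position")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce long-read alignments to calls at heterozygous positions
#'
#' Reads a SAM or BAM file, drops unmapped and secondary alignments
#' (flag bits 4 and 256) and turns every remaining alignment into a
#' [reduced_read()]: its aligned base at each heterozygous position it
#' covers. Positions deleted or soft-clipped by the alignment, and ambiguous
#' (non-ACGT) bases, are simply absent from the calls. Supplementary
#' alignments are kept; every alignment of a read that maps in more than one
#' segment becomes its own reduced read marked `is_split_segment`, with the
#' segment order appended to the read id.
#'
#' @param alignment_source Path to a SAM or BAM file with SEQ stored.
#' @param het_positions Data frame with `chromosome`, `position` (e.g. from
#'   [parse_het_positions()]).
#' @return Named list of [reduced_read()] objects; alignments on chromosomes
#'   absent from `het_positions`, without usable sequence, or covering no
#'   heterozygous position are skipped (counted in a single warning).
#' @export
reduce_alignments <- function(alignment_source, het_positions) {
  bam <- alignment_source
  if (grepl("\\.sam$", alignment_source, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment_source,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "flag", "seq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) return(list())
  qname <- S4Vectors::mcols(ga)$qname
  flags <- S4Vectors::mcols(ga)$flag
  seqs <- S4Vectors::mcols(ga)$seq
  chrom <- as.character(GenomicAlignments::seqnames(ga))
  starts <- GenomicAlignments::start(ga)
  ends <- GenomicAlignments::end(ga)
  is_suppl <- bitwAnd(flags, 2048L) > 0L
  multi <- qname %in% qname[duplicated(qname)]
  is_split <- is_suppl | multi
  seg_idx <- stats::ave(seq_along(qname), qname, FUN = seq_along)
  known_chrom <- unique(het_positions$chromosome)
  # project query bases onto reference coordinates (D -> "-", I/S removed)
  laid <- GenomicAlignments::sequenceLayer(seqs, GenomicAlignments::cigar(ga))
  skipped <- 0L
  reads <- list()
  pos_by_chrom <- split(het_positions$position, het_positions$chromosome)
  for (a in seq_along(ga)) {
    if (!(chrom[[a]] %in% known_chrom) || length(laid[[a]]) == 0L) {
      skipped <- skipped + 1L
      next
    }
    hp <- pos_by_chrom[[chrom[[a]]]]
    hp <- hp[hp >= starts[[a]] & hp <= ends[[a]]]
    if (length(hp) == 0L) {
      skipped <- skipped + 1L
      next
    }
    base <- strsplit(as.character(laid[[a]][hp - starts[[a]] + 1L]), "")[[1L]]
    ok <- base %in% .BASES
    if (!any(ok)) {
      skipped <- skipped + 1L
      next
    }
    id <- if (is_split[[a]]) {
      sprintf("%s_p%d", qname[[a]], seg_idx[[a]])
    } else {
      qname[[a]]
    }
    reads[[id]] <- reduced_read(id, chrom[[a]], hp[ok], base[ok],
                                split = is_split[[a]],
                                start = starts[[a]], end = ends[[a]])
  }
  if (skipped > 0L) {
    warning(skipped, " alignment(s) skipped (unknown chromosome, no ",
            "sequence, or no usable call at a heterozygous position)")
  }
  as_read_set(reads)
}

#' Index a FASTQ file by read id
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return A named `QualityScaledDNAStringSet` keyed by read id, for use
#'   with [write_haplotig_outputs()].
#' @export
read_fastq_index <- function(path) {
  # the constructor warns that it drops (empty) metadata columns; harmless
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write per-haplotig output files
#'
#' For every haplotig writes (i) a three-column tab-separated consensus file
#' (`chromosome`, `position`, consensus base) sorted by position, with
#' equally supported tied bases on separate lines, and (ii) when a FASTQ
#' index is supplied, a FASTQ of its member reads, ready for de novo
#' assembly or realignment.
#'
#' @param haplotigs List of `haplotig` objects.
#' @param out_dir Output directory (created if needed).
#' @param fastq_index Optional [read_fastq_index()] result; member reads
#'   absent from the index are skipped in the FASTQ output only, with a
#'   warning.
#' @return Data frame manifest with columns `haplotig`, `file`, `type`,
#'   invisibly written as `manifest.tsv` in `out_dir`.
#' @export
write_haplotig_outputs <- function(haplotigs, out_dir, fastq_index = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (h in haplotigs) {
    tsv <- file.path(out_dir, paste0(h$id, ".tsv"))
    utils::write.table(as.data.frame(h), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(haplotig = h$id, file = tsv, type = "consensus_tsv")
    if (!is.null(fastq_index)) {
      # split-read segment ids carry a _p<k> suffix absent from raw FASTQ
      wanted <- unique(sub("_p[0-9]+$", "", h$members))
      hit <- wanted %in% names(fastq_index)
      if (!all(hit)) {
        warning(sum(!hit), " member read(s) of ", h$id,
                " absent from the FASTQ index; skipped in FASTQ output")
      }
      fq <- file.path(out_dir, paste0(h$id, ".fastq"))
      recs <- fastq_index[wanted[hit]]
      S4Vectors::mcols(recs) <- NULL
      Biostrings::writeQualityScaledXStringSet(recs, fq)
      rows[[length(rows) + 1L]] <-
        data.frame(haplotig = h$id, file = fq, type = "fastq")
    }
  }
  manifest <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(haplotig = character(), file = character(), type = character())
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read or write a truth-set TSV
#'
#' Four tab-separated columns with header: `haplotype`, `chromosome`,
#' `position`, `base` — each haplotype's true base at every heterozygous
#' position (the simulator's output format, also accepted for user-provided
#' truth sets).
#'
#' @param truth A `truth_set` data frame.
#' @param path File path.
#' @return `read_truth_tsv` returns a `truth_set`; `write_truth_tsv`
#'   returns `path` invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  out <- utils::read.delim(path, colClasses = c("character", "character",
                                                "integer", "character"))
  names(out) <- c("haplotype", "chromosome", "position", "base")
  class(out) <- c("truth_set", "data.frame")
  out
}
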