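# Small construction helpers used across test files.

rr <- function(id, pos, base, chrom = "chr01", split = FALSE, weight = NULL,
               ...) {
  reduced_read(id, chrom, pos, base, split = split, weight = weight, ...)
}

# reads for k fully distinct haplotypes over `positions`, tiled so that
# consecutive reads of a haplotype overlap by `overlap` positions
tiled_haplotype_reads <- function(k = 3L, n_pos = 60L, read_len = 30L,
                                  overlap = 20L, chrom = "chr01") {
  positions <- seq.int(100L, by = 100L, length.out = n_pos)
  # haplotype h uses base h at every position: pairwise fully divergent
  reads <- list()
  starts <- seq.int(1L, n_pos - read_len + 1L, by = read_len - overlap)
  if (!(n_pos - read_len + 1L) %in% starts) {
    starts <- c(starts, n_pos - read_len + 1L)
  }
  for (h in seq_len(k)) {
    for (s in starts) {
      id <- sprintf("h%d_s%03d", h, s)
      idx <- s:(s + read_len - 1L)
      reads[[id]] <- reduced_read(id, chrom, positions[idx],
                                  rep(h, read_len),
                                  haplotype = sprintf("hap%02d", h))
    }
  }
  reads
}

# truth set for tiled_haplotype_reads()
tiled_truth <- function(k = 3L, n_pos = 60L, chrom = "chr01") {
  positions <- seq.int(100L, by = 100L, length.out = n_pos)
  out <- do.call(rbind, lapply(seq_len(k), function(h) {
    data.frame(haplotype = sprintf("hap%02d", h), chromosome = chrom,
               position = positions, base = c("A", "C", "G", "T")[h],
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("truth_set", "data.frame")
  out
}

# random small clustering instance for oracle-equivalence checks
random_instance <- function(n_reads, n_pos = 30L, k = 2L, error = 0.1) {
  positions <- sort(sample.int(5000L, n_pos))
  hap <- matrix(sample.int(4L, k * n_pos, replace = TRUE), n_pos, k)
  reads <- list()
  for (i in seq_len(n_reads)) {
    h <- sample.int(k, 1L)
    len <- sample.int(n_pos - 10L, 1L) + 10L
    s <- sample.int(n_pos - len + 1L, 1L)
    idx <- s:(s + len - 1L)
    base <- hap[idx, h]
    flip <- runif(len) < error
    base[flip] <- (base[flip] + sample.int(3L, sum(flip), replace = TRUE) - 1L) %% 4L + 1L
    id <- sprintf("r%02d", i)
    reads[[id]] <- reduced_read(id, "chr01", positions[idx], base,
                                weight = rep(1, len))
  }
  reads
}

# a diploid with a coverage gap in one haplotype, plus split reads that
# bridge the gap for that haplotype
gap_fixture <- function(split_bridge = TRUE) {
  pos <- seq(100L, 6000L, by = 100L)      # 60 het positions
  n <- length(pos)
  reads <- list()
  add <- function(id, h, idx, split = FALSE) {
    base <- if (h == 1L) "A" else "C"
    reads[[id]] <<- reduced_read(id, "chr01", pos[idx], rep(base, length(idx)),
                                 split = split,
                                 haplotype = sprintf("hap%02d", h))
  }
  starts <- seq(1L, n - 19L, by = 5L)
  for (s in starts) {
    add(sprintf("h1_%02d", s), 1L, s:(s + 19L))
    # haplotype 2 has no reads overlapping positions 26..35: a gap
    if (s + 19L < 26L || s > 35L) add(sprintf("h2_%02d", s), 2L, s:(s + 19L))
  }
  if (split_bridge) {
    for (i in 1:3) {
      add(sprintf("h2_br%d_p1", i), 2L, 10:24, split = TRUE)
      add(sprintf("h2_br%d_p2", i), 2L, 37:51, split = TRUE)
    }
  }
  reads
}
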