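# Three-step automated cleaning: discordance merging, coverage filtering,
# gap filling; read-conservation invariants.

test_that("discordance is the disagreeing fraction of member calls", {
  # 10 reads at one position: 8 A, 2 T -> consensus A, discordance 0.2
  reads <- c(
    lapply(1:8, function(i) rr(sprintf("a%d", i), 10L, "A",
                               weight = 1)),
    lapply(1:2, function(i) rr(sprintf("t%d", i), 10L, "T", weight = 1))
  )
  h <- cluster_from_reads(reads, "h")
  expect_equal(discordance(h, reads), 0.2)
  # single-read and perfectly concordant clusters are at 0
  solo <- cluster_from_reads(reads[1], "solo")
  expect_equal(discordance(solo, reads), 0)
  all_same <- cluster_from_reads(reads[1:8], "same")
  expect_equal(discordance(all_same, reads), 0)
  # a call agreeing with any tied consensus base is concordant
  tied <- cluster_from_reads(reads[c(1, 9)], "tied")
  expect_equal(discordance(tied, reads), 0)
})

test_that("discordance merging joins split halves below the threshold", {
  pos <- seq(10L, 600L, 10L)
  mk_half <- function(prefix, idx, base) {
    lapply(1:4, function(i) {
      rr(sprintf("%s%d", prefix, i), pos[idx], rep(base, length(idx)),
         weight = rep(1, length(idx)))
    })
  }
  # one haplotype split into two overlapping halves, plus a noisy distinct
  # cluster that keeps the mean discordance threshold above zero
  left <- mk_half("L", 1:35, "A")
  right <- mk_half("R", 26:60, "A")
  noisy <- c(lapply(1:3, function(i) {
    rr(sprintf("N%d", i), pos[1:30], rep("C", 30L), weight = rep(1, 30L))
  }), list(rr("N4", pos[1:30], c(rep("C", 25L), rep("G", 5L)),
              weight = rep(1, 30L))))
  reads <- c(left, right, noisy)
  clusters <- list(cluster_from_reads(left, "left"),
                   cluster_from_reads(right, "right"),
                   cluster_from_reads(noisy, "noisy"))
  out <- merge_by_discordance(clusters, reads)
  expect_equal(length(out), 2L)
  merged <- Filter(function(h) length(h$members) == 8L, out)
  expect_equal(length(merged), 1L)
  expect_setequal(merged[[1]]$members,
                  c(sprintf("L%d", 1:4), sprintf("R%d", 1:4)))
  # read multiset conserved
  expect_setequal(unlist(lapply(out, `[[`, "members")),
                  vapply(reads, `[[`, "", "read_id"))
  # threshold was fixed before merging
  expect_equal(attr(out, "discordance_threshold"),
               mean(vapply(clusters, discordance, numeric(1), reads)))
})

test_that("mutually discordant clusters are left untouched", {
  pos <- seq(10L, 300L, 10L)
  a <- lapply(1:3, function(i) rr(sprintf("a%d", i), pos, rep("A", 30L),
                                  weight = rep(1, 30L)))
  b <- lapply(1:3, function(i) rr(sprintf("b%d", i), pos, rep("C", 30L),
                                  weight = rep(1, 30L)))
  clusters <- list(cluster_from_reads(a, "a"), cluster_from_reads(b, "b"))
  out <- merge_by_discordance(clusters, c(a, b))
  expect_equal(length(out), 2L)
  single <- merge_by_discordance(clusters[1], a)
  expect_equal(length(single), 1L)
})

test_that("coverage filter removes the smallest clusters within budget", {
  # coverages 1000, 500, 5: only the 5-call cluster fits the 1% budget
  mk_cov <- function(prefix, n_reads, calls_per_read) {
    lapply(seq_len(n_reads), function(i) {
      rr(sprintf("%s%d", prefix, i), seq(10L, by = 10L,
                                         length.out = calls_per_read),
         rep("A", calls_per_read), weight = rep(1, calls_per_read))
    })
  }
  big <- mk_cov("big", 10L, 100L)
  mid <- mk_cov("mid", 5L, 100L)
  tiny <- mk_cov("tiny", 1L, 5L)
  reads <- c(big, mid, tiny)
  clusters <- list(cluster_from_reads(big, "big"),
                   cluster_from_reads(mid, "mid"),
                   cluster_from_reads(tiny, "tiny"))
  out <- filter_low_coverage(clusters, reads, fraction = 0.01)
  expect_setequal(vapply(out, `[[`, "", "id"), c("big", "mid"))
  # equal large clusters: nothing removed
  eq <- list(cluster_from_reads(big, "b1"), cluster_from_reads(mid, "b2"))
  expect_equal(length(filter_low_coverage(eq, reads)), 2L)
  # a single cluster is always retained
  expect_equal(length(filter_low_coverage(clusters[3], reads)), 1L)
})

test_that("gap filling splits the deepest donor over an under-covered region", {
  pos <- seq(10L, 600L, 10L)
  # chromosome with 3 haplotigs on the left, 2 on the right: mean ~ 2.6
  mk <- function(id, idx, base, n_reads = 10L) {
    reads <- lapply(seq_len(n_reads), function(i) {
      rr(sprintf("%s_r%d", id, i), pos[idx], rep(base, length(idx)),
         weight = rep(1, length(idx)))
    })
    reads
  }
  a <- mk("a", 1:60, "A")                 # full-length
  b <- mk("b", 1:60, "C")                 # full-length
  c_left <- mk("c", 1:35, "G")            # left two-thirds only: the right is a gap
  reads <- c(a, b, c_left)
  clusters <- list(cluster_from_reads(a, "a"), cluster_from_reads(b, "b"),
                   cluster_from_reads(c_left, "c"))
  set.seed(31)
  out <- fill_gaps(clusters, reads)
  expect_equal(length(out), 4L)
  # the read multiset is conserved and the donor was split about in half
  expect_setequal(unlist(lapply(out, `[[`, "members")),
                  vapply(reads, `[[`, "", "read_id"))
  new <- Filter(function(h) grepl("_fill", h$id), out)
  expect_equal(length(new), 1L)
  expect_equal(length(new[[1]]$members), 5L)
  # uniform multiplicity: unchanged
  flat <- list(cluster_from_reads(a, "a"), cluster_from_reads(b, "b"))
  expect_equal(length(fill_gaps(flat, c(a, b))), 2L)
})

test_that("a donor with one region read cannot be split", {
  pos <- seq(10L, 300L, 10L)
  a <- lapply(1:2, function(i) rr(sprintf("a%d", i), pos, rep("A", 30L),
                                  weight = rep(1, 30L)))
  lone <- list(rr("lone", pos[1:10], rep("C", 10L), weight = rep(1, 10L)))
  clusters <- list(cluster_from_reads(a, "a"),
                   cluster_from_reads(lone, "lone"))
  out <- fill_gaps(clusters, c(a, lone))
  # region beyond the lone read is under-covered but the only donor with
  # reads there is cluster a... which can be split; the lone cluster with a
  # single read never is
  expect_true(all(vapply(out, function(h) length(h$members) >= 1L,
                         logical(1))))
  expect_setequal(unlist(lapply(out, `[[`, "members")),
                  vapply(c(a, lone), `[[`, "", "read_id"))
})

test_that("clean() chains the steps and honours the gap-fill switch", {
  expect_equal(clean_haplotigs(list(), list()), list())
  pos <- seq(10L, 600L, 10L)
  left <- lapply(1:4, function(i) rr(sprintf("L%d", i), pos[1:35],
                                     rep("A", 35L), weight = rep(1, 35L)))
  right <- lapply(1:4, function(i) rr(sprintf("R%d", i), pos[26:60],
                                      rep("A", 35L), weight = rep(1, 35L)))
  other <- lapply(1:4, function(i) {
    calls <- rep("C", 60L)
    if (i == 1L) calls[55:60] <- "G"   # internal noise: threshold > 0
    rr(sprintf("O%d", i), pos, calls, weight = rep(1, 60L))
  })
  mixed <- list(rr("M1", pos[1:5], rep("T", 5L), weight = rep(1, 5L)))
  reads <- c(left, right, other, mixed)
  clusters <- list(cluster_from_reads(left, "l"),
                   cluster_from_reads(right, "r"),
                   cluster_from_reads(other, "o"),
                   cluster_from_reads(mixed, "m"))
  no_fill <- clean_haplotigs(clusters, reads, gap_fill = FALSE, seed = 1L)
  # halves merged; the small mixed cluster filtered out
  expect_equal(length(no_fill), 2L)
  with_fill <- clean_haplotigs(clusters, reads, gap_fill = TRUE, seed = 1L)
  expect_gte(length(with_fill), length(no_fill))
})
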