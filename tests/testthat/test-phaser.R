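# Similarity, pair gating, selection, identity maintenance, and the full
# clustering loop (including equivalence with the exhaustive oracle).

test_that("similarity is the agreeing fraction of shared positions", {
  a <- rr("a", seq(10L, 100L, by = 10L), rep("A", 10L))
  b_calls <- rep("A", 10L)
  b_calls[4] <- "C"
  b <- rr("b", seq(10L, 100L, by = 10L), b_calls)
  s <- similarity(a, b)
  expect_equal(s$similarity, 0.9)
  expect_equal(s$n_shared, 10L)
  expect_equal(similarity(a, a)$similarity, 1.0)
  disjoint <- rr("d", c(500L, 600L), c("A", "A"))
  expect_true(is.na(similarity(a, disjoint)$similarity))
  other_chrom <- rr("o", c(10L, 20L), c("A", "A"), chrom = "chr02")
  expect_true(is.na(similarity(a, other_chrom)$similarity))
  # symmetry over random pairs
  set.seed(1)
  reads <- random_instance(8)
  for (i in 1:7) {
    s1 <- similarity(reads[[i]], reads[[i + 1]])
    s2 <- similarity(reads[[i + 1]], reads[[i]])
    expect_identical(s1, s2)
  }
})

test_that("tied consensus bases count as matching when sets intersect", {
  r1 <- rr("r1", c(10L, 20L), c("A", "C"), weight = c(1, 1))
  r2 <- rr("r2", c(10L, 20L), c("A", "T"), weight = c(1, 1))
  h <- cluster_from_reads(list(r1, r2))         # position 20 tied C/T
  probe <- rr("p", c(10L, 20L), c("A", "T"))
  expect_equal(similarity(h, probe)$similarity, 1.0)
})

test_that("pair gating: minimum overlap count, similarity, and the O rule", {
  params <- phase_params()
  mk <- function(id, n, base = "A", start = 10L) {
    rr(id, seq(start, by = 10L, length.out = n), rep(base, n))
  }
  # 9 shared positions: never allowed, regardless of similarity
  expect_false(pair_allowed(mk("a", 9L), mk("b", 9L), params))
  # similarity below the S threshold
  a <- mk("a", 20L, "A")
  b <- mk("b", 20L, "C")
  expect_false(pair_allowed(a, b, params))       # S = 0 < 0.01
  # O rule: two 200-position reads sharing only 15 positions (0.075 < 0.1)
  big1 <- mk("big1", 200L)
  shifted <- mk("shifted", 200L, start = 10L + 185L * 10L)
  expect_equal(similarity(big1, shifted)$n_shared, 15L)
  expect_false(pair_allowed(big1, shifted, params))
  # but with > 100 shared positions the O rule is ignored
  big2 <- mk("big2", 2000L)
  mid <- mk("mid", 150L, start = 10L + 1850L * 10L)  # fraction 0.075 < O
  expect_equal(similarity(big2, mid)$n_shared, 150L)
  expect_true(pair_allowed(big2, mid, params))
})

test_that("best pair: highest S, then most shared positions, then seeded", {
  cand <- data.frame(similarity = c(0.9, 0.8), n_shared = c(12L, 50L))
  expect_equal(select_best_pair(cand), 1L)
  cand2 <- data.frame(similarity = c(0.9, 0.9), n_shared = c(12L, 20L))
  expect_equal(select_best_pair(cand2), 2L)
  cand3 <- data.frame(similarity = c(0.9, 0.9), n_shared = c(20L, 20L))
  set.seed(123)
  first <- select_best_pair(cand3)
  set.seed(123)
  expect_equal(select_best_pair(cand3), first)
  expect_null(select_best_pair(cand3[0, ]))
})

test_that("merged consensus is the weighted argmax set, ties included", {
  r1 <- rr("r1", c(10L, 20L), c("A", "A"), weight = c(5, 3))
  r2 <- rr("r2", c(10L, 20L), c("T", "T"), weight = c(2, 3))
  h <- merge_haplotigs(cluster_from_reads(list(r1)),
                       cluster_from_reads(list(r2)))
  df <- as.data.frame(h)
  expect_equal(df$base[df$position == 10L], "A")          # 5 vs 2
  expect_setequal(df$base[df$position == 20L], c("A", "T"))  # 3 vs 3 tie
  # single-read cluster: consensus equals the read's calls
  solo <- cluster_from_reads(list(r1))
  expect_equal(as.data.frame(solo)$base, c("A", "A"))
})

test_that("identity change: identical copies cost nothing, dissent is priced", {
  r1 <- rr("r1", seq(10L, 100L, 10L), rep("A", 10L), weight = rep(1, 10L))
  c1 <- cluster_from_reads(list(r1), "c1")
  expect_equal(identity_change(c1, c1), 0)
  # two 1-read clusters disagreeing at 1 of 10 positions, unit weights:
  # the value must equal the independent brute-force oracle's
  calls2 <- rep("A", 10L)
  calls2[5] <- "T"
  r2 <- rr("r2", seq(10L, 100L, 10L), calls2, weight = rep(1, 10L))
  c2 <- cluster_from_reads(list(r2), "c2")
  got <- identity_change(c1, c2)
  allpos <- seq(10L, 100L, 10L)
  o1 <- oracle_cluster(1L, list(r1, r2), allpos)
  o2 <- oracle_cluster(2L, list(r1, r2), allpos)
  expect_equal(got, oracle_id_change(o1, o2))
  expect_equal(got, 0.05)   # each cluster's base share halves at one of 10
  # symmetry
  expect_equal(identity_change(c2, c1), got)
  # disjoint clusters signal no overlap
  r3 <- rr("r3", c(500L, 510L), c("A", "A"), weight = c(1, 1))
  expect_true(is.na(identity_change(c1, cluster_from_reads(list(r3)))))
})

test_that("the identity gate forbids merges above the threshold", {
  # 2 of 13 positions disagree at unit weights -> change 2/26 ~ 0.077
  calls <- rep("A", 13L)
  calls2 <- calls
  calls2[c(5, 9)] <- "T"
  pos <- seq(10L, 130L, 10L)
  r1 <- rr("r1", pos, calls, weight = rep(1, 13L))
  r2 <- rr("r2", pos, calls2, weight = rep(1, 13L))
  idc <- identity_change(cluster_from_reads(list(r1)),
                         cluster_from_reads(list(r2)))
  expect_gt(idc, 0.05)
  out <- run_phasing(list(r1, r2), params = phase_params(rng_seed = 1L))
  expect_equal(length(out), 2L)    # merge forbidden: two singleton clusters
  lg <- attr(out, "merge_log")
  expect_true(any(!lg$accepted))
  expect_equal(lg$id_change[!lg$accepted][[1]], idc)
})

test_that("error-free distinct haplotypes resolve to exactly k clusters", {
  for (k in 2:4) {
    reads <- tiled_haplotype_reads(k = k)
    out <- run_phasing(reads, params = phase_params(rng_seed = 3L))
    expect_equal(length(out), k)
    labs <- lapply(out, function(h) {
      unique(vapply(reads[h$members], function(r) r$haplotype, ""))
    })
    expect_true(all(lengths(labs) == 1L))   # each cluster is one haplotype
  }
})

test_that("identical reads collapse to one cluster; far reads stay apart", {
  reads <- lapply(sprintf("r%d", 1:5), function(id) {
    rr(id, seq(10L, 200L, 10L), rep("A", 20L))
  })
  out <- run_phasing(reads, params = phase_params(rng_seed = 1L))
  expect_equal(length(out), 1L)
  expect_setequal(out[[1]]$members, sprintf("r%d", 1:5))

  far <- list(rr("a", seq(10L, 200L, 10L), rep("A", 20L)),
              rr("b", seq(5000L, 5190L, 10L), rep("A", 20L)))
  out2 <- run_phasing(far, params = phase_params(rng_seed = 1L))
  expect_equal(length(out2), 2L)   # below min_overlap_count: no pair
})

test_that("with L = 0 the clusters partition the input reads", {
  set.seed(11)
  reads <- random_instance(15, n_pos = 40L, k = 3L)
  out <- run_phasing(reads, params = phase_params(rng_seed = 11L))
  members <- unlist(lapply(out, `[[`, "members"))
  expect_setequal(members, names(reads))
  expect_equal(length(members), length(reads))   # no read in two clusters
})

test_that("the L parameter drops small clusters after termination", {
  reads <- c(
    lapply(sprintf("r%d", 1:4), function(id) {
      rr(id, seq(10L, 200L, 10L), rep("A", 20L))
    }),
    list(rr("lone", seq(2000L, 2190L, 10L), rep("C", 20L)))
  )
  out <- run_phasing(reads, params = phase_params(min_cluster_reads = 2L,
                                                  rng_seed = 1L))
  expect_equal(length(out), 1L)
  expect_equal(length(out[[1]]$members), 4L)
})

test_that("clusters never merge across chromosomes", {
  reads <- c(tiled_haplotype_reads(k = 2, chrom = "chr01"),
             tiled_haplotype_reads(k = 2, chrom = "chr02"))
  names(reads) <- NULL
  reads <- lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    r$read_id <- sprintf("%s_%s", r$chrom, r$read_id)
    r
  })
  out <- run_phasing(reads, params = phase_params(rng_seed = 2L))
  expect_equal(length(out), 4L)
  for (h in out) {
    chroms <- vapply(strsplit(h$members, "_"), `[[`, "", 1L)
    expect_equal(length(unique(chroms)), 1L)
  }
})

test_that("identical inputs and seed give identical clusterings", {
  set.seed(99)
  reads <- random_instance(20, n_pos = 50L, k = 4L)
  out1 <- run_phasing(reads, params = phase_params(rng_seed = 42L))
  out2 <- run_phasing(reads, params = phase_params(rng_seed = 42L))
  expect_identical(lapply(out1, `[[`, "members"),
                   lapply(out2, `[[`, "members"))
  expect_identical(lapply(out1, as.data.frame), lapply(out2, as.data.frame))
})

test_that("incremental engine matches the exhaustive re-scoring oracle", {
  params <- phase_params()
  n_cases <- 25L
  for (case in seq_len(n_cases)) {
    set.seed(1000L + case)
    n <- sample(4:12, 1L)
    reads <- random_instance(n, n_pos = sample(15:35, 1L),
                             k = sample(2:3, 1L))
    set.seed(case)
    engine <- run_phasing(reads, params = phase_params(rng_seed = case))
    set.seed(case)
    oracle <- oracle_phase(reads, params)
    oracle_ids <- lapply(oracle, function(ix) names(reads)[ix])
    expect_equal(
      partition_sets(lapply(engine, `[[`, "members")),
      partition_sets(oracle_ids),
      info = sprintf("case %d", case)
    )
  }
})
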