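# Independent exhaustive re-scoring oracle for the clustering engine.
# Re-derives every pair score from scratch at every step with naive loops;
# shares only the tie-break convention (canonical order by member labels,
# one RNG draw per residual tie) so runs with the same seed are comparable.

BITS4 <- c(1L, 2L, 4L, 8L)

oracle_consensus <- function(tally) {
  mask <- integer(nrow(tally))
  for (p in seq_len(nrow(tally))) {
    mx <- max(tally[p, ])
    if (mx > 0) mask[[p]] <- sum(BITS4[tally[p, ] == mx])
  }
  mask
}

oracle_cluster <- function(member_idx, reads, allpos) {
  tally <- matrix(0, length(allpos), 4L)
  for (k in member_idx) {
    r <- reads[[k]]
    w <- if (is.null(r$weight)) rep(1, length(r$pos)) else r$weight
    i <- match(r$pos, allpos)
    for (q in seq_along(i)) {
      tally[i[[q]], r$base[[q]]] <- tally[i[[q]], r$base[[q]]] + w[[q]]
    }
  }
  list(members = member_idx, tally = tally, mask = oracle_consensus(tally))
}

oracle_id_change <- function(a, b) {
  common <- which(a$mask > 0L & b$mask > 0L)
  if (length(common) == 0L) return(NA_real_)
  lost <- 0
  total <- 0
  for (p in common) {
    v1 <- sum(a$tally[p, ])
    v2 <- sum(b$tally[p, ])
    total <- total + v1 + v2
    for (bb in 1:4) {
      fm <- (a$tally[p, bb] + b$tally[p, bb]) / (v1 + v2)
      if (bitwAnd(a$mask[[p]], BITS4[[bb]]) > 0L) {
        lost <- lost + max(0, (a$tally[p, bb] / v1 - fm) * v1)
      }
      if (bitwAnd(b$mask[[p]], BITS4[[bb]]) > 0L) {
        lost <- lost + max(0, (b$tally[p, bb] / v2 - fm) * v2)
      }
    }
  }
  lost / total
}

oracle_similarity <- function(a, b) {
  shared <- which(a$mask > 0L & b$mask > 0L)
  n <- length(shared)
  if (n == 0L) return(list(s = NA_real_, n = 0L))
  m <- sum(bitwAnd(a$mask[shared], b$mask[shared]) > 0L)
  list(s = m / n, n = n)
}

# full greedy clustering with exhaustive re-scoring; returns the partition
# as a list of sorted member index vectors (single chromosome)
oracle_phase <- function(reads, params) {
  allpos <- sort(unique(unlist(lapply(reads, `[[`, "pos"))))
  clusters <- lapply(seq_along(reads), oracle_cluster, reads = reads,
                     allpos = allpos)
  gen_id <- seq_along(reads)          # unique id per cluster creation
  next_gen <- length(reads) + 1L
  labels <- seq_along(reads)          # min member index, for canonical order
  rejected <- character()             # "genA|genB" pairs that failed ID
  repeat {
    n <- length(clusters)
    if (n <= 1L) break
    cand <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        sm <- oracle_similarity(clusters[[i]], clusters[[j]])
        if (sm$n < params$min_overlap_count) next
        if (is.na(sm$s) || sm$s < params$min_similarity) next
        if (sm$n <= params$overlap_ignore_threshold) {
          smaller <- min(sum(clusters[[i]]$mask > 0L),
                         sum(clusters[[j]]$mask > 0L))
          if (sm$n / smaller < params$min_overlap_fraction) next
        }
        key <- paste(sort(c(gen_id[[i]], gen_id[[j]])), collapse = "|")
        if (key %in% rejected) next
        cand <- rbind(cand, data.frame(i = i, j = j, s = sm$s, ns = sm$n,
                                       la = min(labels[[i]], labels[[j]]),
                                       lb = max(labels[[i]], labels[[j]])))
      }
    }
    if (is.null(cand)) break
    top <- cand[cand$s == max(cand$s), , drop = FALSE]
    top <- top[top$ns == max(top$ns), , drop = FALSE]
    top <- top[order(top$la, top$lb), , drop = FALSE]
    pick <- if (nrow(top) > 1L) top[sample.int(nrow(top), 1L), ] else top
    i <- pick$i
    j <- pick$j
    idc <- oracle_id_change(clusters[[i]], clusters[[j]])
    if (idc > params$max_id_change + 1e-9) {   # same boundary epsilon
      rejected <- c(rejected,
                    paste(sort(c(gen_id[[i]], gen_id[[j]])), collapse = "|"))
      next
    }
    merged <- oracle_cluster(sort(c(clusters[[i]]$members,
                                    clusters[[j]]$members)),
                             reads, allpos)
    new_label <- min(labels[[i]], labels[[j]])
    clusters <- c(clusters[-c(i, j)], list(merged))
    labels <- c(labels[-c(i, j)], new_label)
    gen_id <- c(gen_id[-c(i, j)], next_gen)
    next_gen <- next_gen + 1L
  }
  lapply(clusters, function(cl) sort(cl$members))
}

# canonical form of a partition for comparison
partition_sets <- function(member_lists) {
  s <- vapply(member_lists, function(x) paste(sort(x), collapse = ","),
              character(1))
  sort(unname(s))
}
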