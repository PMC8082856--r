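#' Phasing parameters
#'
#' Parameters of the iterative clustering engine. The defaults were the
#' optimum of a large parameter sweep in the method's original validation and
#' are intended to be usable for any ploidy and heterozygosity level; in
#' practice only `max_id_change` should need tuning.
#'
#' @param min_similarity Minimum similarity `S` between two sequences for a
#'   merge to be considered (fraction, default 0.01).
#' @param min_overlap_fraction Minimum fraction `O` of the smaller sequence's
#'   covered heterozygous positions that must be shared (default 0.1);
#'   "smaller" means fewer covered heterozygous positions, not shorter.
#' @param min_cluster_reads `L`, clusters with fewer reads are dropped from
#'   the output after clustering terminates (default 0, keep everything).
#' @param max_id_change `ID`, the cluster-identity-maintenance threshold: a
#'   merge is forbidden when the fraction of consensus-supporting votes lost
#'   over the clusters' common region exceeds this (default 0.05).
#' @param min_overlap_count Minimal number of shared heterozygous positions
#'   for two sequences to be comparable at all (default 10).
#' @param overlap_ignore_threshold When two sequences share more than this
#'   many heterozygous positions the fractional `O` rule is ignored
#'   (default 100).
#' @param rng_seed Optional integer seed; the generator is consumed only to
#'   break exact ties in pair selection.
#' @return An object of class `phase_params`.
#' @export
phase_params <- function(min_similarity = 0.01,
                         min_overlap_fraction = 0.1,
                         min_cluster_reads = 0L,
                         max_id_change = 0.05,
                         min_overlap_count = 10L,
                         overlap_ignore_threshold = 100L,
                         rng_seed = NULL) {
  p <- list(
    min_similarity = min_similarity,
    min_overlap_fraction = min_overlap_fraction,
    min_cluster_reads = as.integer(min_cluster_reads),
    max_id_change = max_id_change,
    min_overlap_count = as.integer(min_overlap_count),
    overlap_ignore_threshold = as.integer(overlap_ignore_threshold),
    rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed)
  )
  for (f in c("min_similarity", "min_overlap_fraction", "max_id_change")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be a fraction in [0, 1]")
  }
  if (p$min_cluster_reads < 0L || p$min_overlap_count < 0L) {
    stop("counts must be >= 0")
  }
  structure(p, class = "phase_params")
}

#' Similarity between two call sequences
#'
#' Similarity is the fraction of shared heterozygous positions at which the
#' two sequences agree: `S = N_shared_variants / N_shared_positions`. Either
#' argument can be a single read or a haplotig; for a haplotig the consensus
#' base set stands in for its calls, and a shared position counts as a shared
#' variant when the two base sets intersect.
#'
#' @param a,b [reduced_read()] or `haplotig` objects.
#' @return List with `similarity` (fraction, `NA` when the sequences share no
#'   position or are on different chromosomes) and `n_shared` (number of
#'   shared positions).
#' @export
similarity <- function(a, b) {
  pa <- .call_profile(a)
  pb <- .call_profile(b)
  if (pa$chrom != pb$chrom) {
    return(list(similarity = NA_real_, n_shared = 0L))
  }
  i <- match(pa$pos, pb$pos)
  sel <- !is.na(i)
  n <- sum(sel)
  if (n == 0L) return(list(similarity = NA_real_, n_shared = 0L))
  match_n <- sum(bitwAnd(pa$mask[sel], pb$mask[i[sel]]) > 0L)
  list(similarity = match_n / n, n_shared = n)
}

#' Is a pair of sequences allowed to merge?
#'
#' Applies the three overlap gates: at least `min_overlap_count` shared
#' positions, similarity at least `min_similarity`, and — unless the shared
#' count exceeds `overlap_ignore_threshold` — the shared positions must be at
#' least fraction `min_overlap_fraction` of the positions covered by the
#' smaller of the two sequences. The identity-maintenance gate
#' ([identity_change()]) is checked separately at merge time.
#'
#' @inheritParams similarity
#' @param params A [phase_params()] object.
#' @return Logical.
#' @export
pair_allowed <- function(a, b, params = phase_params()) {
  s <- similarity(a, b)
  if (s$n_shared < params$min_overlap_count) return(FALSE)
  if (is.na(s$similarity) || s$similarity < params$min_similarity) {
    return(FALSE)
  }
  if (s$n_shared > params$overlap_ignore_threshold) return(TRUE)
  smaller <- min(length(.call_profile(a)$pos), length(.call_profile(b)$pos))
  s$n_shared / smaller >= params$min_overlap_fraction
}

#' Select the best candidate pair
#'
#' The pair with the highest similarity wins; ties are broken by the larger
#' number of shared positions, and remaining exact ties uniformly at random
#' using the current (seeded) RNG. Candidates should be listed in a
#' deterministic canonical order so the random tie-break is reproducible.
#'
#' @param candidates Data frame with columns `similarity` and `n_shared`,
#'   one row per allowed pair.
#' @return The index of the selected row, or `NULL` when there are no
#'   candidates (the termination signal).
#' @export
select_best_pair <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  best_s <- max(candidates$similarity)
  i <- which(candidates$similarity == best_s)
  if (length(i) > 1L) {
    i <- i[candidates$n_shared[i] == max(candidates$n_shared[i])]
  }
  if (length(i) > 1L) i <- i[[sample.int(length(i), 1L)]]
  i
}

#' Cluster identity change caused by a hypothetical merge
#'
#' Each cluster's identity is the per-position demographics of its weighted
#' votes: how strongly each base is supported, as a share of the votes at
#' that position. Merging two clusters pools their votes, which can dilute
#' the support share of a cluster's consensus base. A merge that increases a
#' consensus base's share is a positive change and contributes nothing; when
#' the share decreases — even if the base remains the consensus after the
#' merge — the cluster loses votes: the share drop expressed in that
#' cluster's own votes at the position,
#' `max(0, share_before - share_after) * cluster votes at p`. The identity
#' change is the total votes lost by both clusters over their common region
#' (the positions covered by both) divided by the total votes both clusters
#' hold over that region, so a read with a handful of sequencing errors
#' barely dents a deep cluster, while two internally consistent clusters
#' that disagree at a fraction d of their shared positions score about d/2
#' and are kept apart.
#'
#' @param c1,c2 `haplotig` objects on the same chromosome.
#' @return Fraction >= 0, or `NA` when the clusters share no position (such
#'   a merge is never considered).
#' @export
identity_change <- function(c1, c2) {
  stopifnot(inherits(c1, "haplotig"), inherits(c2, "haplotig"))
  if (c1$chrom != c2$chrom) return(NA_real_)
  common <- intersect(c1$pos, c2$pos)
  if (length(common) == 0L) return(NA_real_)
  i1 <- match(common, c1$pos)
  i2 <- match(common, c2$pos)
  .identity_change_core(c1$tallies[i1, , drop = FALSE],
                        c2$tallies[i2, , drop = FALSE],
                        c1$consensus_mask[i1], c2$consensus_mask[i2])
}

.identity_change_core <- function(t1, t2, m1, m2) {
  v1 <- rowSums(t1)
  v2 <- rowSums(t2)
  fm <- (t1 + t2) / (v1 + v2)
  lost <- 0
  for (b in 1:4) {
    in1 <- bitwAnd(m1, .BITS[b]) > 0L
    if (any(in1)) {
      lost <- lost +
        sum(pmax(0, (t1[in1, b] / v1[in1] - fm[in1, b]) * v1[in1]))
    }
    in2 <- bitwAnd(m2, .BITS[b]) > 0L
    if (any(in2)) {
      lost <- lost +
        sum(pmax(0, (t2[in2, b] / v2[in2] - fm[in2, b]) * v2[in2]))
    }
  }
  lost / (sum(v1) + sum(v2))
}

#' Phase reduced reads into haplotigs
#'
#' The core iterative clustering loop. Every read starts as a singleton
#' cluster whose calls vote with their context-coverage weights. At each
#' step the engine selects, among all allowed pairs (see [pair_allowed()]),
#' the pair with the highest similarity (ties: most shared positions, then
#' seeded random); if merging that pair would change the clusters' identity
#' by more than `max_id_change` the pair is forbidden and the next best pair
#' is considered. A merge unions the member reads, sums the vote tallies and
#' recomputes the consensus as the per-position argmax set (ties keep all
#' tied bases). Clusters on different chromosomes are never merged; the
#' loop ends when no allowed pair passes the identity gate. Pair scores are
#' cached and only pairs involving a newly merged cluster are rescored,
#' which is exactly equivalent to rescoring everything each step.
#'
#' @param reads List of [reduced_read()] objects (subset-filtered). If they
#'   do not carry vote weights yet, weights are assigned from
#'   `context_table`.
#' @param context_table Optional [build_context_table()] result; defaults to
#'   a table built from `reads` themselves.
#' @param params A [phase_params()] object.
#' @return List of `haplotig` objects (clusters with fewer than
#'   `max(1, min_cluster_reads)` reads are dropped), ordered by chromosome
#'   and span start and named `<chrom>_htg<k>`. The merge log — one row per
#'   considered merge with the pair, similarity, shared positions, identity
#'   change and whether it was accepted — is attached as attribute
#'   `merge_log`.
#' @export
run_phasing <- function(reads, context_table = NULL, params = phase_params()) {
  reads <- as_read_set(reads)
  if (length(reads) == 0L) return(list())
  needs_weights <- any(vapply(reads, function(r) is.null(r$weight), logical(1)))
  if (needs_weights) {
    reads <- weight_reads(reads, context_table %||% build_context_table(reads))
  }
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  chroms <- vapply(reads, `[[`, character(1), "chrom")
  out <- list()
  logs <- list()
  for (ch in sort(unique(chroms))) {
    res <- .phase_chromosome(reads[chroms == ch], params)
    out <- c(out, res$clusters)
    logs[[ch]] <- res$log
  }
  keep <- vapply(out, function(h) length(h$members), integer(1)) >=
    max(1L, params$min_cluster_reads)
  out <- out[keep]
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, function(h) h$span[[1L]], integer(1)),
               method = "radix")
  out <- out[ord]
  for (k in seq_along(out)) {
    out[[k]]$id <- sprintf("%s_htg%03d", out[[k]]$chrom, k)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  attr(out, "merge_log") <- do.call(rbind, unname(logs))
  out
}

# single-chromosome clustering engine; reads carry weights
.phase_chromosome <- function(reads, params) {
  n <- length(reads)
  allpos <- sort(unique(unlist(lapply(reads, `[[`, "pos"))))
  np <- length(allpos)
  idx <- lapply(reads, function(r) match(r$pos, allpos))
  read_ids <- names(reads)
  chrom <- reads[[1L]]$chrom

  # per-slot state; merged cluster reuses slot i, slot j dies
  tall <- vector("list", n)
  members <- vector("list", n)
  label <- seq_len(n)                # min original read index in the cluster
  active <- rep(TRUE, n)
  covcnt <- integer(n)
  cons <- matrix(0L, np, n)          # consensus bitmask per position, by slot
  for (k in seq_len(n)) {
    r <- reads[[k]]
    t <- matrix(0, np, 4L)
    t[cbind(idx[[k]], r$base)] <- r$weight %||% rep(1, length(r$pos))
    tall[[k]] <- t
    members[[k]] <- k
    covcnt[k] <- length(r$pos)
    cons[idx[[k]], k] <- .BITS[r$base]
  }

  if (n == 1L) {
    h <- .slot_haplotig(1L, chrom, allpos, tall, members, read_ids)
    return(list(clusters = list(h), log = .empty_merge_log()))
  }

  # initial pairwise shared-position and matching-call counts (sparse)
  i_all <- rep.int(seq_len(n), lengths(idx))
  p_all <- unlist(idx, use.names = FALSE)
  c_all <- unlist(lapply(reads, `[[`, "base"), use.names = FALSE)
  M <- Matrix::sparseMatrix(i = p_all, j = i_all, x = 1, dims = c(np, n))
  ns_mat <- as.matrix(Matrix::crossprod(M))
  match_mat <- matrix(0, n, n)
  for (b in 1:4) {
    sel <- c_all == b
    if (!any(sel)) next
    Mb <- Matrix::sparseMatrix(i = p_all[sel], j = i_all[sel], x = 1,
                               dims = c(np, n))
    match_mat <- match_mat + as.matrix(Matrix::crossprod(Mb))
  }
  s_mat <- match_mat / ns_mat        # NaN where no overlap
  smaller <- outer(covcnt, covcnt, pmin)
  allowed <- ns_mat >= params$min_overlap_count &
    !is.nan(s_mat) & s_mat >= params$min_similarity &
    (ns_mat > params$overlap_ignore_threshold |
       ns_mat / smaller >= params$min_overlap_fraction)
  # score matrix: -Inf marks non-candidates; upper triangle only
  sc <- s_mat
  sc[!allowed] <- -Inf
  sc[lower.tri(sc, diag = TRUE)] <- -Inf

  log_rows <- list()
  step <- 0L
  repeat {
    top <- which.max(sc)
    if (!is.finite(sc[[top]])) break
    best_s <- sc[[top]]
    tied <- which(sc == best_s)
    if (length(tied) > 1L) {
      tied <- tied[ns_mat[tied] == max(ns_mat[tied])]
      if (length(tied) > 1L) {
        # canonical order by member labels, then seeded random draw
        ti <- (tied - 1L) %% n + 1L
        tj <- (tied - 1L) %/% n + 1L
        la <- pmin(label[ti], label[tj])
        lb <- pmax(label[ti], label[tj])
        o <- order(la, lb, method = "radix")
        tied <- tied[o][sample.int(length(tied), 1L)]
      }
    }
    top <- tied[[1L]]
    i <- (top - 1L) %% n + 1L
    j <- (top - 1L) %/% n + 1L
    # identity-maintenance gate
    common <- which(cons[, i] > 0L & cons[, j] > 0L)
    idc <- .identity_change_core(
      tall[[i]][common, , drop = FALSE], tall[[j]][common, , drop = FALSE],
      cons[common, i], cons[common, j]
    )
    step <- step + 1L
    # boundary comparison with an absolute epsilon: the change is a sum of
    # small rationals and cases algebraically equal to the threshold must
    # not depend on summation order
    accept <- idc <= params$max_id_change + 1e-9
    log_rows[[step]] <- data.frame(
      step = step, chromosome = chrom,
      cluster_a = read_ids[[label[i]]], cluster_b = read_ids[[label[j]]],
      similarity = best_s, n_shared = ns_mat[[top]], id_change = idc,
      accepted = accept, stringsAsFactors = FALSE
    )
    if (!accept) {
      sc[i, j] <- -Inf
      sc[j, i] <- -Inf
      next
    }
    # merge j into i
    tall[[i]] <- tall[[i]] + tall[[j]]
    tall[j] <- list(NULL)
    members[[i]] <- c(members[[i]], members[[j]])
    label[i] <- min(label[i], label[j])
    active[j] <- FALSE
    u <- .consensus_mask(tall[[i]])
    cons[, i] <- u
    cons[, j] <- 0L
    covcnt[i] <- sum(u > 0L)
    sc[j, ] <- -Inf
    sc[, j] <- -Inf
    # rescore pairs involving the merged cluster
    match_i <- colSums(bitand_mat(cons, u) > 0L)
    shared_i <- colSums((cons > 0L) & (u > 0L))
    s_i <- match_i / shared_i
    ok <- active & seq_len(n) != i &
      shared_i >= params$min_overlap_count &
      !is.nan(s_i) & s_i >= params$min_similarity &
      (shared_i > params$overlap_ignore_threshold |
         shared_i / pmin(covcnt, covcnt[i]) >= params$min_overlap_fraction)
    ns_mat[i, ] <- shared_i
    ns_mat[, i] <- shared_i
    row_i <- ifelse(ok, s_i, -Inf)
    lo <- seq_len(n) < i
    sc[i, ] <- ifelse(lo, -Inf, row_i)   # keep upper triangle convention
    sc[, i] <- ifelse(lo, row_i, -Inf)
    sc[i, i] <- -Inf
  }

  slots <- which(active)
  clusters <- lapply(slots, .slot_haplotig, chrom = chrom, allpos = allpos,
                     tall = tall, members = members, read_ids = read_ids)
  log <- if (length(log_rows)) do.call(rbind, log_rows) else .empty_merge_log()
  list(clusters = clusters, log = log)
}

.slot_haplotig <- function(k, chrom, allpos, tall, members, read_ids) {
  t <- tall[[k]]
  covered <- which(rowSums(t) > 0)
  .new_haplotig(
    id = sprintf("%s_slot%d", chrom, k), chrom = chrom,
    members = read_ids[sort(members[[k]])],
    pos = allpos[covered],
    tallies = t[covered, , drop = FALSE]
  )
}

.empty_merge_log <- function() {
  data.frame(step = integer(), chromosome = character(),
             cluster_a = character(), cluster_b = character(),
             similarity = numeric(), n_shared = numeric(),
             id_change = numeric(), accepted = logical(),
             stringsAsFactors = FALSE)
}
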