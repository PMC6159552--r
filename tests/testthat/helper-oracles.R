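# Independent oracles used to cross-check the implementation.

# Connected components of the graph with edges {d <= threshold}, via
# brute-force union-find; labels by first appearance.
uf_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && d[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  names(labels) <- rownames(d)
  labels
}

# Best-first non-overlapping selection by exhaustive scanning: repeatedly
# pick the highest-scoring remaining hit compatible with everything already
# selected (ties: longer interval, then subject id, then start), and return
# the summed bit score.
best_first_score <- function(hits) {
  selected <- hits[0, ]
  remaining <- hits
  repeat {
    compatible <- rep(TRUE, nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      for (j in seq_len(nrow(selected))) {
        ov <- min(remaining$end[i], selected$end[j]) -
          max(remaining$start[i], selected$start[j])
        if (ov > 0) { compatible[i] <- FALSE; break }
      }
    }
    pool <- remaining[compatible, , drop = FALSE]
    if (nrow(pool) == 0) break
    len <- pool$end - pool$start
    best <- order(-pool$bit_score, -len, pool$subject_id, pool$start)[1]
    selected <- rbind(selected, pool[best, , drop = FALSE])
    keep <- !(seq_len(nrow(remaining)) %in%
                which(compatible)[best])
    remaining <- remaining[keep, , drop = FALSE]
  }
  sum(selected$bit_score)
}

# Adjusted Rand index between two labellings of the same items.
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_i * sum_j / total
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Random symmetric distance matrix with zero diagonal.
random_dist_matrix <- function(n, ids = sprintf("r%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# A small clustered reference database for recon/typer tests.
tiny_study <- function(seed, n_genomes = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  study <- simulate_study(cfg, n_genomes = n_genomes)
  refs_tbl <- dplyr::select(study$references$plasmids,
                            id = "plasmid_id", "seq")
  db <- mob_cluster_build(refs_tbl, k = cfg_k(), s = cfg_s())
  list(cfg = cfg, study = study, db = db)
}
cfg_k <- function() 21L
cfg_s <- function() 1000L

# Hand-built sketch with chosen hash values (for closed-form distance
# checks).
fake_sketch <- function(hashes, k = 21L, s = length(hashes)) {
  structure(
    list(sequence_id = NULL, k = as.integer(k), s = as.integer(s),
         hash_seed = 42L, hashes = as.numeric(sort(hashes))),
    class = "mob_sketch"
  )
}

# Random hit table on one contig.
random_hits <- function(n, contig_len = 1000) {
  starts <- sample.int(contig_len - 60, n, replace = TRUE)
  lens <- sample(10:200, n, replace = TRUE)
  tibble::tibble(
    contig_id = "c1",
    subject_id = sprintf("s%d", seq_len(n)),
    bit_score = round(runif(n, 50, 500), 1),
    start = starts,
    end = pmin(starts + lens, contig_len)
  )
}
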