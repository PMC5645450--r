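# Independent reference implementations used as oracles.  These are kept
# deliberately naive (full enumeration, elementwise loops) and separate from
# the package's code paths.

# Running-sum ES by walking the entire trajectory position by position.
# Steps are kept as integer numerators over the common denominator
# s * (n - s), so the walk is exact and the single final division makes the
# result bit-identical to any other exact evaluation of the same statistic.
brute_force_es <- function(positions, n) {
  s <- length(positions)
  step <- rep(-s, n)                   # miss: -1/(n-s) = -s / (s*(n-s))
  step[positions] <- n - s             # hit:   1/s = (n-s) / (s*(n-s))
  traj <- c(0, cumsum(step))           # numerators at positions 0..n
  max_v <- max(traj)
  min_v <- min(traj)
  if (abs(max_v) > abs(min_v)) return(max_v / (s * (n - s)))
  if (abs(min_v) > abs(max_v)) return(min_v / (s * (n - s)))
  # equal magnitude: the deviation attained at the earlier position wins
  (if (which.max(traj) <= which.min(traj)) max_v else min_v) / (s * (n - s))
}

# Every subset of size s of 1..n, scored with the brute-force walker.
exhaustive_null_es <- function(n, s) {
  apply(utils::combn(n, s), 2, function(pos) brute_force_es(sort(pos), n))
}

# Elementwise footrule.
brute_force_footrule <- function(a, b) {
  total <- 0
  for (g in names(a)) total <- total + abs(a[[g]] - b[[g]])
  total
}

# Straight-line re-implementation of the hierarchical agglomeration:
# ranks kept in a plain matrix, distances recomputed from scratch each
# round, merge done by ordering on mean rank then gene id.
reference_prl <- function(rank_vectors) {
  genes <- names(rank_vectors[[1]])
  mat <- sapply(rank_vectors, function(v) v[genes])
  if (!is.matrix(mat)) mat <- matrix(mat, ncol = length(rank_vectors))
  cols <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
  merge_two <- function(x, y) {
    m <- (x + y) / 2
    ord <- order(m, genes, method = "radix")
    r <- integer(length(m))
    r[ord] <- seq_along(m)
    r
  }
  while (length(cols) > 1) {
    best_i <- best_j <- NA
    best_d <- Inf
    for (i in seq_len(length(cols) - 1)) {
      for (j in seq(i + 1, length(cols))) {
        d <- sum(abs(cols[[i]] - cols[[j]]))
        if (d < best_d) {
          best_d <- d
          best_i <- i
          best_j <- j
        }
      }
    }
    cols[[best_i]] <- merge_two(cols[[best_i]], cols[[best_j]])
    cols[[best_j]] <- NULL
  }
  stats::setNames(cols[[1]], genes)
}

# BH step-up computed longhand from the definition.
reference_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# Random bijective ranking over a gene universe.
random_ranked_list <- function(genes) {
  stats::setNames(sample(seq_along(genes)), genes)
}

# Write a small expression corpus to temp TSVs; returns the two paths.
write_tiny_corpus <- function(values, samples, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  sp <- file.path(dir, "metadata.tsv")
  header <- paste(c("gene_id", colnames(values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], values[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), mp)
  meta_rows <- paste(samples$sample_id, samples$compound_id,
                     samples$batch_id, samples$is_vehicle, sep = "\t")
  writeLines(c("sample_id\tcompound_id\tbatch_id\tis_vehicle", meta_rows),
             sp)
  list(matrix = mp, metadata = sp)
}

tiny_corpus_parts <- function() {
  values <- matrix(c(6.0, 1.0, 3.0,
                     6.0, 1.0, 3.0,
                     8.0, 2.0, 2.5,
                     7.0, 0.5, 3.5),
                   nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("v1", "v2", "t1", "t2")))
  samples <- data.frame(
    sample_id = c("v1", "v2", "t1", "t2"),
    compound_id = c("", "", "cmpd1", "cmpd2"),
    batch_id = "b1",
    is_vehicle = c(TRUE, TRUE, FALSE, FALSE)
  )
  list(values = values, samples = samples)
}
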