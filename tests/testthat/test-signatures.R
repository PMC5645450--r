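test_that("fold changes subtract the within-batch vehicle mean", {
  parts <- tiny_corpus_parts()
  paths <- write_tiny_corpus(parts$values, parts$samples)
  corpus <- read_expression(paths$matrix, paths$metadata)
  fc <- fold_changes(corpus)
  # treatment 8.0 against vehicle values {6.0, 6.0} -> fc 2.0
  expect_equal(fc$fc[fc$experiment_id == "t1" & fc$gene_id == "gA"], 2.0)
  expect_equal(fc$fc[fc$experiment_id == "t1" & fc$gene_id == "gB"], 1.0)
  # treatment equal to the vehicle mean -> zero fold change
  expect_equal(fc$fc[fc$experiment_id == "t2" & fc$gene_id == "gC"], 0.5)
  expect_equal(fc$fc[fc$experiment_id == "t1" & fc$gene_id == "gC"], -0.5)
})

test_that("each treatment is normalized only by its own batch", {
  withr::local_seed(11)
  n_genes <- 20
  genes <- sprintf("g%02d", 1:n_genes)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:8),
    compound_id = c("", "", "cA", "cB", "", "", "cC", "cD"),
    batch_id = rep(c("b1", "b2"), each = 4),
    is_vehicle = rep(c(TRUE, TRUE, FALSE, FALSE), 2)
  )
  values <- matrix(rnorm(n_genes * 8), nrow = n_genes,
                   dimnames = list(genes, samples$sample_id))
  corpus <- cmapscreen:::validate_corpus(values, samples)
  fc <- fold_changes(corpus)

  # brute-force per-batch loop oracle
  for (i in which(!samples$is_vehicle)) {
    veh <- samples$sample_id[samples$is_vehicle &
                               samples$batch_id == samples$batch_id[i]]
    for (g in genes) {
      expected <- values[g, samples$sample_id[i]] - mean(values[g, veh])
      got <- fc$fc[fc$experiment_id == samples$sample_id[i] &
                     fc$gene_id == g]
      expect_equal(got, expected)
    }
  }
})

test_that("rank_profile sorts by descending fc with lexicographic ties", {
  expect_equal(rank_profile(c(A = 2.0, B = -1.0, C = 0.5)),
               c(A = 1L, B = 3L, C = 2L))
  # all-equal fold changes fall back to gene-id order
  expect_equal(rank_profile(c(z = 1, a = 1, m = 1)),
               c(z = 3L, a = 1L, m = 2L))
  expect_error(rank_profile(c(A = 1, B = NA)), "finite")
  expect_error(rank_profile(c(1, 2)), "named")
})

test_that("rank_profile agrees with an argsort oracle on random profiles", {
  withr::local_seed(21)
  for (rep in 1:5) {
    genes <- sprintf("g%02d", 1:50)
    fc <- stats::setNames(rnorm(50), genes)
    r <- rank_profile(fc)
    ord <- order(-fc, genes, method = "radix")
    expect_equal(names(sort(r)), genes[ord])
    expect_setequal(as.integer(r), 1:50)
  }
})

test_that("footrule distance matches its definition and is a metric", {
  a <- c(g1 = 1L, g2 = 2L, g3 = 3L, g4 = 4L)
  b <- c(g1 = 2L, g2 = 1L, g3 = 3L, g4 = 4L)
  expect_equal(footrule_distance(a, a), 0)
  expect_equal(footrule_distance(a, b), 2)
  expect_error(footrule_distance(a, c(x = 1L, y = 2L)), "universes")

  withr::local_seed(31)
  genes <- sprintf("g%02d", 1:20)
  for (rep in 1:10) {
    x <- random_ranked_list(genes)
    y <- random_ranked_list(genes)
    z <- random_ranked_list(genes)
    expect_equal(footrule_distance(x, y), brute_force_footrule(x, y))
    expect_equal(footrule_distance(x, y), footrule_distance(y, x))
    expect_equal(footrule_distance(x, x), 0)
    if (footrule_distance(x, y) == 0) expect_identical(x[genes], y[genes])
    expect_lte(footrule_distance(x, z),
               footrule_distance(x, y) + footrule_distance(y, z))
  }
})

test_that("borda_merge orders on mean rank with lexicographic ties", {
  a <- c(A = 1L, B = 2L, C = 3L)
  b <- c(A = 2L, B = 1L, C = 3L)
  merged <- borda_merge(a, b)
  # mean ranks A=1.5, B=1.5, C=3; tie broken lexicographically
  expect_equal(merged, c(A = 1L, B = 2L, C = 3L))
  expect_equal(borda_merge(a, a), a)
  withr::local_seed(41)
  genes <- sprintf("g%02d", 1:15)
  x <- random_ranked_list(genes)
  y <- random_ranked_list(genes)
  expect_equal(borda_merge(x, y), borda_merge(y, x)[names(x)])
})

test_that("prototype_ranked_list handles trivial and fixed-point cases", {
  genes <- sprintf("g%02d", 1:10)
  a <- random_ranked_list(genes)
  one <- prototype_ranked_list(list(a))
  expect_equal(unname(one[genes]), unname(a[genes]))
  expect_equal(attr(one, "n_experiments"), 1)

  three <- prototype_ranked_list(list(a, a, a))
  expect_equal(unname(three[genes]), unname(a[genes]))
  expect_equal(attr(three, "n_experiments"), 3)

  expect_error(prototype_ranked_list(list()), "non-empty")
})

test_that("hierarchical merging matches an independent reference", {
  withr::local_seed(51)
  genes <- sprintf("g%02d", 1:10)
  for (rep in 1:10) {
    lists <- replicate(3, random_ranked_list(genes), simplify = FALSE)
    got <- prototype_ranked_list(lists)
    want <- reference_prl(lists)
    expect_equal(unname(got[genes]), unname(want[genes]))
  }
  # five-way merges too
  for (rep in 1:5) {
    lists <- replicate(5, random_ranked_list(genes), simplify = FALSE)
    got <- prototype_ranked_list(lists)
    want <- reference_prl(lists)
    expect_equal(unname(got[genes]), unname(want[genes]))
  }
})

test_that("merging is invariant to input order when distances are distinct", {
  withr::local_seed(61)
  genes <- sprintf("g%02d", 1:12)
  found <- 0
  while (found < 5) {
    lists <- replicate(3, random_ranked_list(genes), simplify = FALSE)
    d <- c(footrule_distance(lists[[1]], lists[[2]]),
           footrule_distance(lists[[1]], lists[[3]]),
           footrule_distance(lists[[2]], lists[[3]]))
    if (anyDuplicated(d) > 0) next
    found <- found + 1
    base <- prototype_ranked_list(lists)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      expect_equal(unname(prototype_ranked_list(lists[perm])[genes]),
                   unname(base[genes]))
    }
  }
})

test_that("the merged list tracks the latent ranking better than replicates", {
  withr::local_seed(71)
  genes <- sprintf("g%03d", 1:100)
  wins <- 0
  for (trial in 1:20) {
    latent_scores <- rnorm(100)
    latent <- rank_profile(stats::setNames(latent_scores, genes))
    reps <- replicate(5, rank_profile(stats::setNames(
      latent_scores + rnorm(100, 0, 0.5), genes)), simplify = FALSE)
    prl <- prototype_ranked_list(reps)
    d_prl <- footrule_distance(latent, prl)
    d_reps <- vapply(reps, footrule_distance, numeric(1), a = latent)
    if (d_prl <= stats::median(d_reps)) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("tidy signature table agrees with the matrix fast path", {
  sim <- simulate_corpus(simulation_config(
    n_genes = 40, n_compounds = 8, replicates = c(1, 3), n_batches = 2,
    vehicles_per_batch = 2, n_up_regulators = 2, n_down_regulators = 1,
    off_target_effect_genes = 5, n_signal_targets = 0, n_noise_targets = 2,
    noise_set_size = 3, signal_set_size = 3, seed = 81
  ))
  sigs <- sim$corpus |> fold_changes() |> rank_profiles() |>
    prototype_signatures()
  scores <- score_compounds(sigs, sim$truth$query_gene)
  ranking_tidy <- rank_compounds(scores)
  ranking_fast <- run_screen(sim$corpus, sim$truth$query_gene)
  expect_equal(tibble::as_tibble(ranking_tidy),
               tibble::as_tibble(ranking_fast))
  # every signature is a bijection onto 1..G
  per_cmpd <- split(sigs$rank, sigs$compound_id)
  for (r in per_cmpd) expect_setequal(r, 1:40)
  # replicate counts carried through
  counts <- unique(sigs[, c("compound_id", "n_experiments")])
  truth_counts <- sim$truth$replicate_counts
  expect_equal(counts$n_experiments[match(truth_counts$compound_id,
                                          counts$compound_id)],
               truth_counts$n_experiments)
})
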