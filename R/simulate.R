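# Seeded generator for a Connectivity-Map-like corpus with known ground
# truth: batched instruments with vehicle controls, per-compound replicate
# experiments, planted regulator compounds that shift the query gene, and
# planted drug-target sets concentrated among those regulators.

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the study conditions exercised throughout the package:
#' 1000 genes, 300 compounds with 3 replicate experiments each spread over 5
#' batches, 20 up- and 20 down-regulators shifting the query gene by twice
#' the assay noise SD, and one planted signal target set of 15 compounds at
#' purity 0.8 among 20 random noise sets.
#'
#' @param n_genes Number of genes.
#' @param n_compounds Number of compounds.
#' @param replicates Experiments per compound: a single count, or a length-2
#'   range `c(lo, hi)` sampled uniformly per compound.
#' @param n_batches Number of instrument batches.
#' @param vehicles_per_batch Vehicle-control samples per batch (>= 1).
#' @param baseline_mean,baseline_sd Per-gene baseline intensities are drawn
#'   `Normal(baseline_mean, baseline_sd)` (log2 scale).
#' @param noise_sd Per-sample measurement noise SD (log2 scale).
#' @param batch_sd SD of the additive per-batch, per-gene offset.  Additive
#'   offsets are exactly what within-batch vehicle normalization removes, so
#'   this makes the normalization step testable rather than decorative.
#' @param n_up_regulators,n_down_regulators Planted compounds shifting the
#'   query gene up / down.
#' @param query_effect Log2 shift of the query gene under regulator
#'   compounds (sign from the regulator's direction).
#' @param off_target_effect_genes Number of additional genes co-shifted per
#'   regulator compound (shift SD `off_target_sd`), so signatures have
#'   realistic multi-gene structure rather than a single moved gene.
#' @param off_target_sd SD of the off-target shifts.
#' @param n_signal_targets Planted target sets concentrated among
#'   regulators (directions alternate up, down, up, ...).
#' @param n_noise_targets Target sets drawn uniformly from all compounds.
#' @param signal_set_size,noise_set_size Members per set.
#' @param signal_purity Fraction of a signal set's members drawn from
#'   same-direction regulators (`ceiling(purity * size)`, capped at the
#'   number of such regulators); the rest are drawn uniformly.
#' @param query_gene Identifier given to the query gene.
#' @param seed Integer seed driving all randomness.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_compounds = 300,
                              replicates = 3,
                              n_batches = 5,
                              vehicles_per_batch = 6,
                              baseline_mean = 8,
                              baseline_sd = 2,
                              noise_sd = 1,
                              batch_sd = 0.5,
                              n_up_regulators = 20,
                              n_down_regulators = 20,
                              query_effect = 2,
                              off_target_effect_genes = 50,
                              off_target_sd = 1,
                              n_signal_targets = 1,
                              n_noise_targets = 20,
                              signal_set_size = 15,
                              noise_set_size = 15,
                              signal_purity = 0.8,
                              query_gene = "g0001",
                              seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$replicates) == 1) cfg$replicates <- rep(cfg$replicates, 2)
  with(cfg, {
    stopifnot(
      n_genes >= 2, n_compounds >= 1, n_batches >= 1,
      vehicles_per_batch >= 1,
      all(replicates >= 1), replicates[1] <= replicates[2],
      noise_sd > 0, baseline_sd > 0, batch_sd >= 0,
      n_up_regulators + n_down_regulators <= n_compounds,
      signal_set_size <= n_compounds, noise_set_size <= n_compounds,
      signal_purity > 0, signal_purity <= 1,
      off_target_effect_genes < n_genes
    )
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a drug-screen corpus with known ground truth
#'
#' Per batch, every sample is `baseline + batch offset + Normal(0,
#' noise_sd)` noise, gene-wise.  Regulator compounds additionally shift the
#' query gene by `+/- query_effect` and a compound-specific random set of
#' off-target genes by `Normal(0, off_target_sd)` amounts.  Signal target
#' sets draw most of their members from same-direction regulators; noise
#' sets are uniform.  All randomness flows from the single seed, so the same
#' configuration always yields the same corpus.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list of class `sim_corpus`:
#'   * `corpus` — a `drug_corpus` (expression matrix + sample metadata);
#'   * `target_sets` — tibble `target_id`, `source`, `members`, `set_size`;
#'   * `truth` — ground truth: `query_gene`, `regulators` (tibble
#'     `compound_id`, `direction`, `effect`), `signal_targets` (tibble
#'     `target_id`, `direction`), `replicate_counts`, `batch_offsets`,
#'     `seed`.
#' @export
simulate_corpus <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- seed
  withr::with_seed(as.integer(config$seed), simulate_corpus_impl(config))
}

simulate_corpus_impl <- function(cfg) {
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  if (!cfg$query_gene %in% gene_ids) {
    gene_ids[1] <- cfg$query_gene
    gene_ids <- gene_ids[str_order(gene_ids)]
  }
  compound_ids <- sprintf("c%04d", seq_len(cfg$n_compounds))
  batch_ids <- sprintf("b%02d", seq_len(cfg$n_batches))

  baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  batch_off <- matrix(rnorm(cfg$n_genes * cfg$n_batches, 0, cfg$batch_sd),
                      nrow = cfg$n_genes,
                      dimnames = list(gene_ids, batch_ids))

  n_reg <- cfg$n_up_regulators + cfg$n_down_regulators
  reg_ids <- if (n_reg > 0) sample(compound_ids, n_reg) else character(0)
  reg_dir <- rep(c("up", "down"),
                 c(cfg$n_up_regulators, cfg$n_down_regulators))
  regulators <- tibble::tibble(
    compound_id = reg_ids,
    direction = reg_dir,
    effect = ifelse(reg_dir == "up", cfg$query_effect, -cfg$query_effect)
  )

  # per-compound effect vectors (query-gene shift + off-target shifts)
  qi <- match(cfg$query_gene, gene_ids)
  effects <- matrix(0, nrow = cfg$n_genes, ncol = cfg$n_compounds,
                    dimnames = list(gene_ids, compound_ids))
  for (i in seq_len(nrow(regulators))) {
    cid <- regulators$compound_id[i]
    effects[qi, cid] <- regulators$effect[i]
    if (cfg$off_target_effect_genes > 0) {
      ot <- sample(setdiff(seq_len(cfg$n_genes), qi),
                   cfg$off_target_effect_genes)
      effects[ot, cid] <- rnorm(cfg$off_target_effect_genes, 0,
                                cfg$off_target_sd)
    }
  }

  rep_counts <- if (cfg$replicates[1] == cfg$replicates[2]) {
    rep(cfg$replicates[1], cfg$n_compounds)
  } else {
    sample(seq(cfg$replicates[1], cfg$replicates[2]), cfg$n_compounds,
           replace = TRUE)
  }
  exp_compound <- rep(compound_ids, rep_counts)
  n_exp <- length(exp_compound)
  exp_batch <- batch_ids[sample.int(cfg$n_batches, n_exp, replace = TRUE)]

  n_veh <- cfg$n_batches * cfg$vehicles_per_batch
  veh_batch <- rep(batch_ids, each = cfg$vehicles_per_batch)
  sample_ids <- sprintf("s%05d", seq_len(n_veh + n_exp))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    compound_id = c(rep("", n_veh), exp_compound),
    batch_id = c(veh_batch, exp_batch),
    is_vehicle = c(rep(TRUE, n_veh), rep(FALSE, n_exp))
  )

  noise <- matrix(rnorm(cfg$n_genes * nrow(samples), 0, cfg$noise_sd),
                  nrow = cfg$n_genes)
  values <- baseline + batch_off[, samples$batch_id, drop = FALSE] + noise
  trt <- which(!samples$is_vehicle)
  values[, trt] <- values[, trt] +
    effects[, samples$compound_id[trt], drop = FALSE]
  dimnames(values) <- list(gene_ids, sample_ids)

  target_sets <- simulate_target_sets(cfg, compound_ids, regulators)

  truth <- list(
    query_gene = cfg$query_gene,
    regulators = regulators,
    signal_targets = target_sets$signal_truth,
    replicate_counts = tibble::tibble(compound_id = compound_ids,
                                      n_experiments = rep_counts),
    batch_offsets = batch_off,
    seed = as.integer(cfg$seed)
  )
  structure(list(corpus = new_drug_corpus(values, samples),
                 target_sets = target_sets$sets,
                 truth = truth),
            class = "sim_corpus")
}

simulate_target_sets <- function(cfg, compound_ids, regulators) {
  sets <- list()
  signal_truth <- tibble::tibble(target_id = character(0),
                                 direction = character(0))
  if (cfg$n_signal_targets > 0) {
    dirs <- rep(c("up", "down"), length.out = cfg$n_signal_targets)
    for (i in seq_len(cfg$n_signal_targets)) {
      pool <- regulators$compound_id[regulators$direction == dirs[i]]
      n_sig <- min(ceiling(cfg$signal_purity * cfg$signal_set_size),
                   length(pool))
      core <- if (n_sig > 0) sample(pool, n_sig) else character(0)
      rest <- sample(setdiff(compound_ids, core),
                     cfg$signal_set_size - n_sig)
      id <- sprintf("T_SIGNAL_%s_%02d", toupper(dirs[i]), i)
      sets[[id]] <- list(source = "referenced",
                         members = sort(c(core, rest)))
      signal_truth <- dplyr::bind_rows(
        signal_truth, tibble::tibble(target_id = id, direction = dirs[i])
      )
    }
  }
  if (cfg$n_noise_targets > 0) {
    for (i in seq_len(cfg$n_noise_targets)) {
      id <- sprintf("T_NULL_%03d", i)
      sets[[id]] <- list(
        source = if (i %% 2 == 0) "predicted" else "referenced",
        members = sort(sample(compound_ids, cfg$noise_set_size))
      )
    }
  }
  tb <- tibble::tibble(
    target_id = names(sets),
    source = vapply(sets, `[[`, character(1), "source"),
    members = lapply(sets, `[[`, "members"),
    set_size = lengths(lapply(sets, `[[`, "members"))
  )
  list(sets = tb, signal_truth = signal_truth)
}

#' @export
print.sim_corpus <- function(x, ...) {
  print(x$corpus)
  cat("  target sets: ", nrow(x$target_sets),
      " (", nrow(x$truth$signal_targets), " planted signal)\n", sep = "")
  invisible(x)
}

#' Write a deterministic miniature corpus to disk
#'
#' Emits a small fixture (50 genes, 20 compounds, 2 batches, 1-3 replicates
#' per compound) in the exact dialects the readers consume —
#' `matrix.tsv`, `metadata.tsv`, `targets.gmt` — plus the ground truth as
#' `truth.yaml`.  The same seed always produces byte-identical files.  The
#' packaged copy lives under `system.file("extdata", package =
#' "cmapscreen")`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 20240401).
#' @return Invisibly, the `sim_corpus` that was written.
#' @export
write_fixture <- function(dir, seed = 20240401L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulation_config(
    n_genes = 50, n_compounds = 20, replicates = c(1, 3), n_batches = 2,
    vehicles_per_batch = 2, n_up_regulators = 4, n_down_regulators = 4,
    query_effect = 3, noise_sd = 1, batch_sd = 0.5,
    off_target_effect_genes = 10, n_signal_targets = 1, n_noise_targets = 5,
    signal_set_size = 5, noise_set_size = 5, signal_purity = 0.8,
    seed = seed
  )
  sim <- simulate_corpus(cfg)
  write_expression(sim$corpus,
                   file.path(dir, "matrix.tsv"),
                   file.path(dir, "metadata.tsv"))
  write_gmt(sim$target_sets, file.path(dir, "targets.gmt"))
  truth <- list(
    query_gene = sim$truth$query_gene,
    seed = as.integer(seed),
    regulators = lapply(seq_len(nrow(sim$truth$regulators)), function(i) {
      as.list(sim$truth$regulators[i, ])
    }),
    signal_targets = lapply(seq_len(nrow(sim$truth$signal_targets)),
                            function(i) {
                              as.list(sim$truth$signal_targets[i, ])
                            })
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(sim)
}
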