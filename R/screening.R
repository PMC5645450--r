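# Scoring compounds by the query gene's rank within each signature, and
# ordering the compound library from strongest up- to strongest
# down-regulator of the query gene.

#' Score compounds by the query gene's rank in their signatures
#'
#' Each compound's score is the rank of the query gene within its prototype
#' signature (rank 1 = the signature's most up-regulated gene).  The
#' normalized score `(G - query_rank) / (G - 1)` maps rank 1 to 1 and rank G
#' to 0 for cross-library comparison; it is monotone in the rank and carries
#' no additional meaning.
#'
#' @param signatures A tibble `compound_id`, `gene_id`, `rank` as returned
#'   by [prototype_signatures()].
#' @param query_gene Identifier of the query gene; must be present in every
#'   signature's gene universe.
#' @return A tibble `compound_id`, `query_rank`, `normalized_score`.
#' @export
score_compounds <- function(signatures, query_gene) {
  stopifnot(all(c("compound_id", "gene_id", "rank") %in% names(signatures)))
  n_genes <- length(unique(signatures$gene_id))
  hit <- signatures[signatures$gene_id == query_gene, , drop = FALSE]
  missing <- setdiff(unique(signatures$compound_id), hit$compound_id)
  if (length(missing) > 0 || nrow(hit) == 0) {
    stop("query gene '", query_gene, "' absent from signature universe",
         call. = FALSE)
  }
  tibble::tibble(
    compound_id = hit$compound_id,
    query_rank = as.integer(hit$rank),
    normalized_score = (n_genes - hit$rank) / (n_genes - 1)
  )
}

#' Order the compound library by query-gene up-regulation
#'
#' Compounds are sorted by ascending query rank — the rank-space equivalent
#' of descending query-gene fold change, since the merged signatures retain
#' only ranks — with ties broken lexicographically by compound id.  Position
#' 1 is the strongest up-regulator of the query gene.
#'
#' @param scores A tibble as returned by [score_compounds()]; one row per
#'   compound.
#' @return A `compound_ranking` tibble: `position`, `compound_id`,
#'   `query_rank`, `normalized_score`.
#' @export
rank_compounds <- function(scores) {
  stopifnot(all(c("compound_id", "query_rank") %in% names(scores)))
  if (anyDuplicated(scores$compound_id) > 0) {
    stop("duplicate compound ids in scores", call. = FALSE)
  }
  ord <- str_order(scores$query_rank, scores$compound_id)
  out <- tibble::tibble(
    position = seq_len(nrow(scores)),
    compound_id = scores$compound_id[ord],
    query_rank = as.integer(scores$query_rank[ord]),
    normalized_score = if ("normalized_score" %in% names(scores)) {
      scores$normalized_score[ord]
    } else {
      rep(NA_real_, nrow(scores))
    }
  )
  structure(out, class = c("compound_ranking", class(out)))
}

#' Extract the strongest up- or down-regulating compounds
#'
#' @param ranking A `compound_ranking`.
#' @param k Number of compounds, `1 <= k <= N`.
#' @param direction `"up"` for the top of the ranking; `"down"` for the
#'   bottom, returned reversed so that the first element is the strongest
#'   down-regulator.
#' @return A character vector of `k` compound ids.
#' @export
top_compounds <- function(ranking, k, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(ranking, "compound_ranking"))
  n <- nrow(ranking)
  if (k < 1 || k > n) stop("`k` must be in 1..", n, call. = FALSE)
  if (direction == "up") {
    ranking$compound_id[seq_len(k)]
  } else {
    rev(ranking$compound_id[seq(n - k + 1, n)])
  }
}

#' Run the full compound screen on an expression corpus
#'
#' Chains the screen's stages on matrix fast paths: within-batch vehicle
#' fold changes, per-experiment ranking, per-compound prototype-ranked-list
#' merging, query-gene scoring, and compound ordering.  Identical in result
#' to composing [fold_changes()], [rank_profiles()],
#' [prototype_signatures()], [score_compounds()] and [rank_compounds()].
#'
#' @param corpus A `drug_corpus`.
#' @param query_gene Query gene identifier (must be a matrix row).
#' @param merge Signature merging method, see [prototype_ranked_list()].
#' @return A `compound_ranking` tibble.
#' @examples
#' sim <- simulate_corpus(simulation_config(
#'   n_genes = 50, n_compounds = 10, n_batches = 2, seed = 1
#' ))
#' run_screen(sim$corpus, sim$truth$query_gene)
#' @export
run_screen <- function(corpus, query_gene,
                       merge = c("footrule-borda", "mean-rank")) {
  merge <- match.arg(merge)
  stopifnot(inherits(corpus, "drug_corpus"))
  if (!query_gene %in% rownames(corpus$values)) {
    stop("query gene '", query_gene, "' absent from expression matrix",
         call. = FALSE)
  }
  fcm <- fold_change_matrix(corpus)
  meta <- attr(fcm, "experiments")
  gene_ids <- rownames(fcm)
  n_genes <- length(gene_ids)
  rank_one <- function(fc) {
    ord <- str_order(-fc, gene_ids)
    r <- integer(n_genes)
    r[ord] <- seq_len(n_genes)
    r
  }
  ranks <- apply(fcm, 2, rank_one)
  compounds <- unique(meta$compound_id)
  query_idx <- match(query_gene, gene_ids)
  query_rank <- vapply(unname(compounds), function(cid) {
    cols <- which(meta$compound_id == cid)
    lists <- lapply(cols, function(j) {
      stats::setNames(ranks[, j], gene_ids)
    })
    sig <- prototype_merge_aligned(lists, method = merge)
    as.integer(sig[[query_idx]])
  }, integer(1), USE.NAMES = FALSE)
  rank_compounds(tibble::tibble(
    compound_id = compounds,
    query_rank = query_rank,
    normalized_score = (n_genes - query_rank) / (n_genes - 1)
  ))
}
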