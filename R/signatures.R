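# Ranked-list primitives and prototype-ranked-list (PRL) merging.
#
# A ranked list is represented as a named integer vector: names are gene
# identifiers, values are ranks 1..G forming a bijection, with rank 1 = most
# up-regulated.  Tie-breaking is lexicographic on gene id everywhere, so a
# fixed input always yields the same output.

validate_ranked_list <- function(x, arg = "x") {
  if (is.null(names(x)) || anyDuplicated(names(x)) > 0) {
    stop("`", arg, "` must be a named vector with unique gene identifiers",
         call. = FALSE)
  }
  r <- as.integer(x)
  if (anyNA(r) || !setequal(r, seq_along(r))) {
    stop("`", arg, "` ranks must be a bijection onto 1..", length(x),
         call. = FALSE)
  }
  stats::setNames(r, names(x))
}

# Align b onto a's gene order; error if the universes differ.
align_universe <- function(a, b) {
  if (length(a) != length(b) || !setequal(names(a), names(b))) {
    stop("ranked lists are defined over different gene universes",
         call. = FALSE)
  }
  b[names(a)]
}

#' Rank a fold-change profile into a 1..G ranked gene list
#'
#' Genes are sorted by decreasing fold change, with ties broken by
#' ascending gene identifier (lexicographic, C locale), and assigned ranks
#' 1..G in that order.  Rank 1 is the most up-regulated gene.
#'
#' @param fc Named numeric vector of fold changes (log-scale differences),
#'   names are gene identifiers.  All values must be finite.
#' @return Named integer vector of ranks (a bijection onto `1..length(fc)`),
#'   names in the same order as `fc`.
#' @examples
#' rank_profile(c(A = 2.0, B = -1.0, C = 0.5))
#' @export
rank_profile <- function(fc) {
  if (is.null(names(fc)) || anyDuplicated(names(fc)) > 0) {
    stop("`fc` must be named with unique gene identifiers", call. = FALSE)
  }
  if (!all(is.finite(fc))) stop("`fc` contains non-finite values", call. = FALSE)
  ord <- str_order(-fc, names(fc))
  r <- integer(length(fc))
  r[ord] <- seq_along(fc)
  stats::setNames(r, names(fc))
}

#' Spearman footrule distance between two ranked lists
#'
#' The L1 distance on permutations: the sum over genes of the absolute
#' difference between the two ranks.
#'
#' @param a,b Ranked lists (named integer rank vectors over the same gene
#'   universe, as produced by [rank_profile()]).
#' @return A single non-negative number.
#' @examples
#' a <- rank_profile(c(g1 = 3, g2 = 2, g3 = 1))
#' b <- rank_profile(c(g1 = 2, g2 = 3, g3 = 1))
#' footrule_distance(a, b)
#' @export
footrule_distance <- function(a, b) {
  a <- validate_ranked_list(a, "a")
  b <- validate_ranked_list(b, "b")
  sum(abs(a - align_universe(a, b)))
}

#' Borda merge of two ranked lists
#'
#' Genes are ordered by ascending mean of their two ranks, ties broken
#' lexicographically by gene identifier, and re-assigned ranks 1..G.
#'
#' @inheritParams footrule_distance
#' @return A ranked list over the same gene universe, gene order following `a`.
#' @export
borda_merge <- function(a, b) {
  a <- validate_ranked_list(a, "a")
  b <- validate_ranked_list(b, "b")
  borda_merge_aligned(a, align_universe(a, b))
}

# Internal: operands already aligned and validated.
borda_merge_aligned <- function(a, b) {
  m <- (a + b) / 2
  ord <- str_order(m, names(a))
  r <- integer(length(a))
  r[ord] <- seq_along(a)
  stats::setNames(r, names(a))
}

#' Merge replicate ranked lists into a prototype ranked list
#'
#' Hierarchical rank aggregation in the Kruskal/Borda style: the pair of
#' current lists at minimal Spearman footrule distance is replaced by its
#' Borda merge, repeatedly, until a single consensus list remains.  Distance
#' ties are resolved in favour of the pair whose members appear first in the
#' input order, so the procedure is deterministic.  With
#' `method = "mean-rank"` all lists are instead Borda-aggregated in one step
#' on their mean rank.
#'
#' @param experiments A list of one or more ranked lists (named integer rank
#'   vectors over a common gene universe).
#' @param method `"footrule-borda"` (default, hierarchical nearest-pair
#'   agglomeration) or `"mean-rank"` (single-step mean-rank Borda).
#' @return A ranked list with attribute `n_experiments` recording how many
#'   lists were merged.
#' @examples
#' a <- rank_profile(c(g1 = 3, g2 = 2, g3 = 1))
#' b <- rank_profile(c(g1 = 2, g2 = 3, g3 = 1))
#' prototype_ranked_list(list(a, b))
#' @export
prototype_ranked_list <- function(experiments,
                                  method = c("footrule-borda", "mean-rank")) {
  method <- match.arg(method)
  if (!is.list(experiments) || length(experiments) == 0) {
    stop("`experiments` must be a non-empty list of ranked lists",
         call. = FALSE)
  }
  lists <- lapply(seq_along(experiments), function(i) {
    validate_ranked_list(experiments[[i]], paste0("experiments[[", i, "]]"))
  })
  ref <- lists[[1]]
  lists <- c(list(ref), lapply(lists[-1], function(x) align_universe(ref, x)))
  out <- prototype_merge_aligned(lists, method)
  attr(out, "n_experiments") <- length(experiments)
  out
}

# Internal workhorse on pre-aligned rank vectors.
prototype_merge_aligned <- function(lists, method = "footrule-borda") {
  if (length(lists) == 1) return(lists[[1]])
  if (method == "mean-rank") {
    m <- rowMeans(do.call(cbind, lists))
    ord <- str_order(m, names(lists[[1]]))
    r <- integer(length(m))
    r[ord] <- seq_along(m)
    return(stats::setNames(r, names(lists[[1]])))
  }
  while (length(lists) > 1) {
    k <- length(lists)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        d <- sum(abs(lists[[i]] - lists[[j]]))
        if (d < best_d) {  # strict: first-seen pair wins distance ties
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- borda_merge_aligned(lists[[best[1]]], lists[[best[2]]])
    lists[[best[1]]] <- merged
    lists[[best[2]]] <- NULL
  }
  lists[[1]]
}

#' Per-experiment fold changes against within-batch vehicle controls
#'
#' For every non-vehicle sample, the fold change of each gene is the sample's
#' log-scale value minus the mean value across the vehicle-control samples of
#' the same batch.  This is the additive (log-scale) analogue of a ratio to
#' vehicle, and exactly removes any batch effect that acts as a shared
#' per-batch offset.
#'
#' @param corpus A [drug_corpus] (see [read_expression()]).
#' @return A tibble with one row per (gene, treatment sample):
#'   `experiment_id`, `compound_id`, `batch_id`, `gene_id`, `fc`.
#' @seealso [rank_profiles()] for the ranked form, [run_screen()] for the
#'   full screen.
#' @export
fold_changes <- function(corpus) {
  stopifnot(inherits(corpus, "drug_corpus"))
  fcm <- fold_change_matrix(corpus)
  meta <- attr(fcm, "experiments")
  tibble::tibble(
    experiment_id = rep(meta$experiment_id, each = nrow(fcm)),
    compound_id   = rep(meta$compound_id, each = nrow(fcm)),
    batch_id      = rep(meta$batch_id, each = nrow(fcm)),
    gene_id       = rep(rownames(fcm), times = ncol(fcm)),
    fc            = as.vector(fcm)
  )
}

# Internal matrix form used by the pipeline: genes x treatment samples,
# with an "experiments" attribute (tibble experiment_id/compound_id/batch_id).
fold_change_matrix <- function(corpus) {
  values <- corpus$values
  samples <- corpus$samples
  veh <- samples[samples$is_vehicle, , drop = FALSE]
  trt <- samples[!samples$is_vehicle, , drop = FALSE]
  if (any(!unique(trt$batch_id) %in% veh$batch_id)) {
    stop("batch without vehicle-control samples", call. = FALSE)
  }
  veh_mean <- vapply(
    split(veh$sample_id, veh$batch_id),
    function(ids) rowMeans(values[, ids, drop = FALSE]),
    numeric(nrow(values))
  )
  fcm <- values[, trt$sample_id, drop = FALSE] -
    veh_mean[, trt$batch_id, drop = FALSE]
  colnames(fcm) <- trt$sample_id
  attr(fcm, "experiments") <- tibble::tibble(
    experiment_id = trt$sample_id,
    compound_id   = trt$compound_id,
    batch_id      = trt$batch_id
  )
  fcm
}

#' Rank every experiment's fold-change profile
#'
#' Applies [rank_profile()] to each treatment experiment in a long
#' fold-change table.
#'
#' @param fc_tbl A tibble as returned by [fold_changes()].
#' @return A tibble `experiment_id`, `compound_id`, `batch_id`, `gene_id`,
#'   `rank` with one bijective ranking per experiment.
#' @export
rank_profiles <- function(fc_tbl) {
  stopifnot(all(c("experiment_id", "gene_id", "fc") %in% names(fc_tbl)))
  fc_tbl |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::mutate(rank = as.integer(
      rank_profile(stats::setNames(.data$fc, .data$gene_id))
    )) |>
    dplyr::ungroup() |>
    dplyr::select(-"fc")
}

#' Merge each compound's replicate rankings into one signature per compound
#'
#' Groups ranked experiment profiles by compound and applies
#' [prototype_ranked_list()] within each group, yielding one prototype
#' ranked list (the compound's signature) per compound.
#'
#' @param ranked_tbl A tibble as returned by [rank_profiles()].
#' @param method Passed to [prototype_ranked_list()].
#' @return A tibble `compound_id`, `gene_id`, `rank`, `n_experiments`.
#' @export
prototype_signatures <- function(ranked_tbl,
                                 method = c("footrule-borda", "mean-rank")) {
  method <- match.arg(method)
  stopifnot(all(c("experiment_id", "compound_id", "gene_id", "rank")
                %in% names(ranked_tbl)))
  by_compound <- split(ranked_tbl, ranked_tbl$compound_id)
  purrr::list_rbind(purrr::imap(by_compound, function(tb, cid) {
    lists <- lapply(split(tb, tb$experiment_id), function(e) {
      stats::setNames(e$rank, e$gene_id)
    })
    # split() orders groups by factor level; restore first-appearance order
    lists <- lists[unique(tb$experiment_id)]
    sig <- prototype_ranked_list(lists, method = method)
    tibble::tibble(
      compound_id = cid,
      gene_id = names(sig),
      rank = as.integer(sig),
      n_experiments = length(lists)
    )
  }))
}
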