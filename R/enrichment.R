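# KS-type running-sum set enrichment over a compound ranking, with a
# matched-size permutation null, two-tailed empirical p-values and BH FDR.

ranking_ids <- function(ranking) {
  if (inherits(ranking, "compound_ranking") || is.data.frame(ranking)) {
    ranking$compound_id
  } else if (is.character(ranking)) {
    ranking
  } else {
    stop("`ranking` must be a compound_ranking or a character vector",
         call. = FALSE)
  }
}

#' Running-sum enrichment score of a compound set in a ranking
#'
#' The unweighted Kolmogorov-Smirnov-type statistic: walking the ranking
#' from position 1 to N, the running sum gains `1/s` at each set member
#' ("hit") and loses `1/(N-s)` at each non-member, where `s` is the set size
#' after intersection with the ranking.  The enrichment score is the running
#' sum's maximal deviation from zero: positive when members concentrate at
#' the top of the ranking (query-gene up-regulators), negative when they
#' concentrate at the bottom.  If the maximal positive and negative
#' deviations tie in magnitude, the one attained earlier in the walk is
#' returned.
#'
#' @param ranking A `compound_ranking` or a character vector of compound ids
#'   in rank order.
#' @param members Character vector of set member compound ids; intersected
#'   with the ranking before scoring.  The intersection must be non-empty
#'   and strictly smaller than the ranking.
#' @return A single number in `[-1, 1]`.
#' @examples
#' running_sum_es(paste0("c", 1:10), c("c1", "c2", "c3"))  # 1: all at top
#' @export
running_sum_es <- function(ranking, members) {
  ids <- ranking_ids(ranking)
  pos <- sort(match(intersect(members, ids), ids))
  es_from_positions(pos, length(ids))
}

# Core statistic on sorted hit positions.  The running sum is piecewise
# linear and decreasing between hits, so its extremes occur only at hit
# positions (just after the increment) or just before a hit; the trajectory
# ends at exactly zero.  O(s) instead of O(N).  All candidate values are
# integer multiples of 1 / (s * (n - s)), so extremes and magnitude ties are
# resolved in exact integer arithmetic, with a single division at the end.
es_from_positions <- function(pos, n) {
  s <- length(pos)
  if (s == 0) stop("set has no members in the ranking universe",
                   call. = FALSE)
  if (s >= n) stop("set covers the whole ranking universe", call. = FALSE)
  i <- seq_len(s)
  denom <- s * (n - s)
  hit_num <- i * (n - s) - (pos - i) * s        # value at position pos[i]
  pre_num <- (i - 1) * (n - s) - (pos - i) * s  # value at position pos[i]-1
  max_v <- max(hit_num)
  min_v <- min(pre_num, 0)                      # trajectory ends at 0
  if (max_v <= 0) return(min_v / denom)
  if (min_v >= 0) return(max_v / denom)
  if (max_v > -min_v) return(max_v / denom)
  if (-min_v > max_v) return(min_v / denom)
  # tie in magnitude: return the deviation attained at the earlier position
  pos_max <- pos[which.max(hit_num)]
  pos_min <- (pos - 1)[which.min(pre_num)]
  (if (pos_max <= pos_min) max_v else min_v) / denom
}

#' Permutation null distribution of the enrichment score
#'
#' Draws `n_perm` uniformly random compound sets of exactly `set_size`
#' members from a ranking of `n` compounds (without replacement within a
#' draw) and scores each with [running_sum_es()].  Because the null set is
#' uniform, the distribution depends only on `(n, set_size)`, never on which
#' compounds are ranked where.
#'
#' @param n Number of ranked compounds.
#' @param set_size Size of each random set, `1 <= set_size < n`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the ambient RNG state is left untouched.
#' @return Numeric vector of `n_perm` null enrichment scores with attributes
#'   `n`, `set_size`, `n_perm`, `seed`.
#' @export
null_distribution <- function(n, set_size, n_perm = 10000, seed = NULL) {
  if (set_size < 1 || set_size >= n) {
    stop("`set_size` must be in 1..(n-1)", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort.int(sample.int(n, set_size)), n)
    }, numeric(1))
  }
  es <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(es, n = n, set_size = set_size, n_perm = n_perm, seed = seed)
}

#' Two-tailed empirical p-value against a permutation null
#'
#' `p = (#\{|null| >= |observed|\} + 1) / (n_perm + 1)`: two-tailed via the
#' absolute value, with the add-one correction so that a finite permutation
#' sample never yields p = 0.  The smallest attainable p is
#' `1 / (n_perm + 1)`.
#'
#' @param es_observed Observed enrichment score.
#' @param null Numeric vector of null scores (see [null_distribution()]).
#' @return A p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(es_observed, null) {
  if (length(null) == 0) stop("empty null distribution", call. = FALSE)
  (sum(abs(null) >= abs(es_observed)) + 1) / (length(null) + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' ascending p-values `p_(i)` become `min_{j >= i} p_(j) * m / j`, capped at
#' 1, mapped back to input order.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, elementwise `>= p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of every drug-target set over the compound ranking
#'
#' For each target set: intersect its members with the ranked compound
#' universe (sets left empty are dropped with a warning, as are sets
#' covering the whole universe), compute the running-sum enrichment score,
#' and an empirical two-tailed p-value against `n_perm` random sets of the
#' same size.  FDR is controlled by Benjamini-Hochberg across all tested
#' targets in one family by default; `family_by_source = TRUE` corrects
#' referenced and predicted associations separately.
#'
#' Randomness policy: with `cache_nulls = TRUE` (the reference behaviour)
#' one null distribution is drawn per distinct post-intersection set size,
#' seeded from `(seed, set_size)`; with `cache_nulls = FALSE` each target
#' gets its own null seeded from `(seed, target_id)`.  Either way results do
#' not depend on the order in which targets are listed.
#'
#' @param ranking A `compound_ranking` (or character vector of compound ids
#'   in rank order).
#' @param target_sets Tibble `target_id`, `source`, `members` as returned by
#'   [read_gmt()] or [simulate_corpus()].
#' @param n_perm Permutations per null (default 10000).
#' @param seed Master integer seed for the permutation nulls.
#' @param family_by_source Split the BH family by association source.
#' @param cache_nulls Share one null per distinct set size (default) or draw
#'   per-target nulls.
#' @return An `enrichment_result` tibble `target_id`, `source`, `set_size`,
#'   `es`, `p_value`, `fdr`, `direction`, sorted by ascending FDR then
#'   p-value then target id.  `direction` is `"up"` for positive scores
#'   (members concentrate among query-gene up-regulators), `"down"`
#'   otherwise.
#' @export
enrich_all <- function(ranking, target_sets, n_perm = 10000, seed = 1L,
                       family_by_source = FALSE, cache_nulls = TRUE) {
  ids <- ranking_ids(ranking)
  stopifnot(all(c("target_id", "source", "members") %in% names(target_sets)))
  if (anyDuplicated(target_sets$target_id) > 0) {
    stop("duplicate target ids", call. = FALSE)
  }
  kept_members <- lapply(target_sets$members, function(m) {
    m[m %in% ids]
  })
  sizes <- lengths(kept_members)
  invalid <- sizes == 0 | sizes >= length(ids)
  if (any(invalid)) {
    warning("dropping ", sum(invalid), " target sets with no usable members ",
            "in the screened universe: ",
            paste(head(target_sets$target_id[invalid], 5), collapse = ", "),
            call. = FALSE)
  }
  keep <- which(!invalid)
  if (length(keep) == 0) stop("no valid target sets after intersection",
                              call. = FALSE)
  ts <- target_sets[keep, , drop = FALSE]
  members <- kept_members[keep]
  sizes <- sizes[keep]

  es <- vapply(members, function(m) {
    es_from_positions(sort.int(match(m, ids)), length(ids))
  }, numeric(1))

  if (cache_nulls) {
    nulls <- lapply(
      stats::setNames(nm = sort(unique(sizes))),
      function(s) {
        null_distribution(length(ids), as.integer(s), n_perm,
                          seed = derive_seed(seed, paste0("size:", s)))
      }
    )
    p <- vapply(seq_along(es), function(i) {
      permutation_pvalue(es[i], nulls[[as.character(sizes[i])]])
    }, numeric(1))
  } else {
    p <- vapply(seq_along(es), function(i) {
      nd <- null_distribution(length(ids), sizes[i], n_perm,
                              seed = derive_seed(seed,
                                                 paste0("target:",
                                                        ts$target_id[i])))
      permutation_pvalue(es[i], nd)
    }, numeric(1))
  }

  fdr <- if (family_by_source) {
    stats::ave(p, ts$source, FUN = bh_adjust)
  } else {
    bh_adjust(p)
  }

  out <- tibble::tibble(
    target_id = ts$target_id,
    source = ts$source,
    set_size = as.integer(sizes),
    es = es,
    p_value = p,
    fdr = fdr,
    direction = ifelse(es > 0, "up", "down")
  )
  out <- out[str_order(out$fdr, out$p_value, out$target_id), , drop = FALSE]
  structure(out,
            class = c("enrichment_result", class(tibble::tibble())),
            n_perm = n_perm, seed = seed, n_compounds = length(ids),
            family_by_source = family_by_source, cache_nulls = cache_nulls)
}
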