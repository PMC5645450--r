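# broom-style tidiers and ggplot2 methods for screen results.

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [enrich_all()].
#' @param ... Unused.
#' @return A plain tibble with one row per tested target set.
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an enrichment run
#'
#' @param x An `enrichment_result` from [enrich_all()].
#' @param alpha FDR threshold used for the `n_significant` count.
#' @param ... Unused.
#' @return A one-row tibble: `n_targets`, `n_significant`, `n_up`, `n_down`,
#'   `n_compounds`, `n_perm`, `seed`.
#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_targets = nrow(x),
    n_significant = sum(x$fdr < alpha),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_compounds = attr(x, "n_compounds"),
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed")
  )
}

#' Plot enrichment scores and significance per target set
#'
#' Horizontal bars of the running-sum enrichment score per target, ordered
#' by FDR, filled by direction, with targets passing the FDR threshold
#' marked.
#'
#' @param object An `enrichment_result` from [enrich_all()].
#' @param alpha FDR threshold highlighted in the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$target_id <- factor(df$target_id, levels = rev(df$target_id))
  df$significant <- df$fdr < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$es, y = .data$target_id,
                                   fill = .data$direction,
                                   alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                labels = c(`TRUE` = paste0("FDR < ", alpha),
                                           `FALSE` = "n.s."),
                                name = NULL) +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac")) +
    ggplot2::labs(x = "running-sum enrichment score", y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Plot the query-gene rank profile of a compound ranking
#'
#' Query-gene rank against ranking position; planted or otherwise
#' highlighted compounds can be marked via `highlight`.
#'
#' @param object A `compound_ranking` from [rank_compounds()].
#' @param highlight Optional character vector of compound ids to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.compound_ranking <- function(object, highlight = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$highlight <- df$compound_id %in% (highlight %||% character(0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$query_rank,
                                   colour = .data$highlight)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "compound position (1 = strongest up-regulator)",
                  y = "query-gene rank within signature") +
    ggplot2::theme_minimal()
}

#' Plot the running-sum trajectory of one target set
#'
#' The full walk of the running sum over the compound ranking, with hit
#' positions as a rug and the enrichment score marked.
#'
#' @param ranking A `compound_ranking` or character vector of compound ids
#'   in rank order.
#' @param members Compound ids of the target set.
#' @return A ggplot object.
#' @export
plot_running_sum <- function(ranking, members) {
  ids <- ranking_ids(ranking)
  n <- length(ids)
  hits <- ids %in% members
  s <- sum(hits)
  step <- ifelse(hits, 1 / s, -1 / (n - s))
  traj <- tibble::tibble(position = 0:n, running_sum = c(0, cumsum(step)))
  es <- running_sum_es(ids, members)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$position,
                                     y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = es, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::geom_rug(data = tibble::tibble(position = which(hits)),
                      ggplot2::aes(x = .data$position), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(x = "ranking position", y = "running sum",
                  subtitle = sprintf("ES = %.3f", es)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
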