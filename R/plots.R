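#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   scale_x_log10 scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' CQ diagnostic plot
#'
#' Male versus female alignment counts on log scales, coloured by filter
#' verdict when the records have been filtered (otherwise by CQ value).
#' M-linked sequences sit on the male axis; the autosomal cloud lies along
#' the diagonal.
#'
#' @param object a `cq_tbl` from [compute_cq()] / [apply_cq_filter()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cq_tbl
#' @export
autoplot.cq_tbl <- function(object, ...) {
  df <- mutate(as_tibble(object),
               male1 = .data$male_count + 1, female1 = .data$female_count + 1)
  p <- if ("pass" %in% names(df)) {
    ggplot(df, aes(x = .data$male1, y = .data$female1, colour = .data$pass))
  } else {
    ggplot(df, aes(x = .data$male1, y = .data$female1, colour = .data$cq))
  }
  p +
    geom_point(alpha = 0.7) +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "male alignments + 1", y = "female alignments + 1",
         colour = if ("pass" %in% names(df)) "passes CQ filter" else "CQ") +
    theme_minimal()
}

#' Gate funnel of a screen report
#'
#' Bar chart of how many references survive each gate of the screen, from
#' the full reference set down to the final candidate list.
#'
#' @param object a `screen_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot screen_report
#' @export
autoplot.screen_report <- function(object, ...) {
  s <- glance(object)
  funnel <- tibble(
    gate = factor(c("references", "CQ filter", "both gates", "final candidates"),
                  levels = c("references", "CQ filter", "both gates",
                             "final candidates")),
    n = c(s$n_references, s$n_cq_pass, s$n_both_gates, s$n_final)
  )
  ggplot(funnel, aes(x = .data$gate, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "references remaining") +
    theme_minimal()
}

#' Stage profile of selected references
#'
#' Expression across the developmental design for a handful of references,
#' one line per reference, replicates shown as points — the visual
#' counterpart of the staged presence/absence filter.
#'
#' @param expr expression table with an attached sample sheet.
#' @param ref_ids references to draw (default: first 5).
#' @return a ggplot object.
#' @export
plot_stage_profile <- function(expr, ref_ids = head(expr$ref_id, 5)) {
  sheet <- sample_sheet(expr)
  long <- expr |>
    as_tibble() |>
    filter(.data$ref_id %in% ref_ids) |>
    tidyr::pivot_longer(-"ref_id", names_to = "sample_id", values_to = "value") |>
    left_join(sheet, by = "sample_id") |>
    mutate(stage = factor(.data$stage, levels = STAGE_LEVELS))
  ggplot(long, aes(x = .data$stage, y = .data$value,
                   colour = .data$ref_id, group = .data$ref_id)) +
    geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    labs(x = "stage", y = if (is_normalized(expr)) "TMM-scale abundance" else "raw abundance",
         colour = "reference") +
    theme_minimal()
}
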