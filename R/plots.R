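#' Scatter plot of the entropy-difference profile
#'
#' One point per alignment column; large positive values mark columns
#' conserved preferentially in the transferase group. Candidate columns
#' (e.g. from [rank_candidates()]) can be highlighted.
#'
#' @param profile Tibble from [entropy_profile()].
#' @param candidates Optional tibble with a `column` column to highlight.
#' @return A ggplot object.
#' @export
plot_entropy_profile <- function(profile, candidates = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$column,
                                             y = .data$delta)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "alignment column",
                  y = "entropy difference (other - tr, log10 units)") +
    ggplot2::theme_minimal()
  if (!is.null(candidates)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::semi_join(profile, candidates, by = "column"),
      colour = "red", size = 1.6)
  }
  p
}

#' Entropy difference against distance from the catalytic triad
#'
#' Joins a per-column entropy profile to per-residue triad distances of a
#' reference structure via the alignment-column/residue mapping, then plots
#' delta against distance.
#'
#' @param profile Tibble from [entropy_profile()].
#' @param aln The [labeled_alignment()] the profile came from.
#' @param s A `structure_model` of the reference protein.
#' @param reference_id Alignment id of the reference sequence.
#' @return A ggplot object; the joined data sits in its `data` slot.
#' @export
plot_triad_profile <- function(profile, aln, s, reference_id) {
  dist <- triad_distance_profile(s)
  mapping <- purrr::map(profile$column, function(col) {
    hit <- column_to_residue(aln, reference_id, col)
    if (nrow(hit) == 0) {
      tibble::tibble(column = as.integer(col), residue_index = NA_integer_)
    } else hit[, c("column", "residue_index")]
  }) |> purrr::list_rbind()
  df <- profile |>
    dplyr::left_join(mapping, by = "column") |>
    dplyr::left_join(dist, by = c(residue_index = "residue_number")) |>
    dplyr::filter(!is.na(.data$triad_distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$triad_distance,
                                   y = .data$delta)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from catalytic triad (Angstrom)",
                  y = "entropy difference (other - tr, log10 units)") +
    ggplot2::theme_minimal()
}

#' Bar chart of reasonable-model counts per variant
#'
#' Mean with one-sd error bars per variant; treatments flagged significant
#' by the Dunnett comparison are starred.
#'
#' @param summary Tibble with columns `variant_id`, `mean`, `sd` (e.g. from
#'   `run_pose_pipeline()$summary` or `glance()` of [count_reasonable()]).
#' @param dunnett Optional `gelp_dunnett` whose group names match
#'   `variant_id`.
#' @return A ggplot object.
#' @export
plot_reasonable_counts <- function(summary, dunnett = NULL) {
  df <- dplyr::mutate(summary, label = "")
  if (!is.null(dunnett)) {
    sig <- dunnett$table$group[dunnett$table$significant]
    df$label[df$variant_id %in% sig] <- "*"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant_id, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                    y = .data$mean + .data$sd + 1),
                       size = 6) +
    ggplot2::labs(x = NULL, y = "reasonable models (mean ± sd)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_reasonable_counts
#' @param object A `gelp_dunnett`.
#' @param ... Unused.
#' @method autoplot gelp_dunnett
#' @export
autoplot.gelp_dunnett <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$diff)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "difference vs control") +
    ggplot2::theme_minimal()
}
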