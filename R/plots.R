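#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, threshold = 0.80, ...) {
  top <- object[object$residue != "-", ] |>
    dplyr::group_by(.data$column) |>
    dplyr::slice_max(.data$frequency, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(pos = dplyr::coalesce(.data$ref_pos, .data$column))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$pos, y = .data$frequency)) +
    ggplot2::geom_col(
      ggplot2::aes(fill = .data$frequency > threshold),
      show.legend = FALSE
    ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "Reference position", y = "Modal residue frequency",
      title = "Conservation profile"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot logo_matrix
#' @export
autoplot.logo_matrix <- function(object, ...) {
  dat <- object[!is.na(object$residue), , drop = FALSE]
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = factor(.data$ref_pos), y = .data$frequency)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high, group = .data$residue),
      width = 0.2, colour = "grey50",
      position = ggplot2::position_dodge(width = 0.8)
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$residue, group = .data$residue),
      position = ggplot2::position_dodge(width = 0.8), size = 3
    ) +
    ggplot2::labs(
      x = "Reference position", y = "Residue frequency",
      title = sprintf(
        "Residue-type distribution (%d%% credible intervals)",
        round(100 * (attr(object, "conf_level") %||% 0.95))
      )
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot otu_clustering
#' @export
autoplot.otu_clustering <- function(object, ...) {
  dat <- dplyr::arrange(object$sizes, dplyr::desc(.data$size)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "OTU rank", y = "Abundance",
      title = sprintf(
        "%d OTUs at cutoff %.3g (%s linkage)",
        object$n_otus, object$cutoff, object$linkage
      )
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot coevolved_sets
#' @export
autoplot.coevolved_sets <- function(object, ...) {
  if (nrow(object) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::labs(title = "No coevolved sets detected") +
        ggplot2::theme_void()
    )
  }
  dat <- dplyr::mutate(
    tidy(object),
    pos = dplyr::coalesce(.data$ref_pos, .data$column)
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = factor(.data$pos), y = factor(.data$set))
  ) +
    ggplot2::geom_tile(fill = "grey90", colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue)) +
    ggplot2::labs(
      x = "Reference position", y = "Coevolved set",
      title = "Coevolved residue sets"
    ) +
    ggplot2::theme_minimal()
}
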