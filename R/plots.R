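#' Plot a peak list, optionally annotated with panel markers
#'
#' Draws the centroided spectrum as vertical segments; when a panel is
#' supplied, peaks matching marker alleles are coloured by locus and
#' labelled.
#'
#' @param peaks A peak list.
#' @param panel Optional `zooms_panel` for annotation.
#' @param params Matching parameters used for annotation.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(peaks, panel = NULL, params = match_params()) {
  df <- tibble::tibble(mz = peaks$mz, intensity = peaks$intensity)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity),
                          linewidth = 0.4, colour = "grey30") +
    ggplot2::labs(x = "m/z (Da)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    m <- match_peaks(peaks, panel, params)$matches
    if (nrow(m) > 0) {
      ann <- m |>
        dplyr::distinct(.data$peak_mz, .data$marker, .data$intensity) |>
        dplyr::group_by(.data$peak_mz) |>
        dplyr::summarise(
          marker = paste(sort(unique(.data$marker)), collapse = "/"),
          intensity = .data$intensity[1], .groups = "drop")
      p <- p +
        ggplot2::geom_segment(
          data = ann,
          ggplot2::aes(x = .data$peak_mz, xend = .data$peak_mz, y = 0,
                       yend = .data$intensity, colour = .data$marker),
          linewidth = 0.7) +
        ggplot2::geom_text(
          data = ann,
          ggplot2::aes(x = .data$peak_mz, y = .data$intensity,
                       label = .data$marker, colour = .data$marker),
          angle = 90, hjust = -0.1, size = 2.8, show.legend = FALSE) +
        ggplot2::labs(colour = "marker")
    }
  }
  p
}

#' Plot the marker-mass matrix of a panel
#'
#' Tile plot of nominal marker masses by taxon and locus; visibility is
#' shown by tile alpha and diagnostic alleles are outlined.
#'
#' @param panel A `zooms_panel`.
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  a <- panel$alleles[!is.na(panel$alleles$nominal_mz), , drop = FALSE]
  a$marker <- factor(a$marker, levels = panel$loci$marker)
  ggplot2::ggplot(a, ggplot2::aes(x = .data$marker, y = .data$taxon)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$nominal_mz,
                                    alpha = .data$visibility),
                       colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$nominal_mz),
                       size = 2, colour = "black") +
    ggplot2::scale_alpha_manual(values = c(maldi_visible = 1,
                                           msms_only = 0.45)) +
    ggplot2::labs(x = "marker locus", y = NULL, fill = "m/z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method
autoplot.zooms_classification <- function(object, ...) {
  ev <- object$evidence
  if (nrow(ev) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = sprintf("%s: %s", object$sample_id,
                                           object$status)))
  }
  ev$n_support <- lengths(strsplit(ev$supporting, ";", fixed = TRUE))
  ev$n_conflict <- lengths(strsplit(ev$conflicting, ";", fixed = TRUE))
  long <- tidyr::pivot_longer(
    ev[, c("marker", "anchored", "n_support", "n_conflict")],
    cols = c("n_support", "n_conflict"),
    names_to = "kind", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$n,
                                     fill = .data$kind,
                                     alpha = .data$anchored)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(
      title = sprintf("%s: %s%s", object$sample_id, object$status,
                      if (!is.na(object$label))
                        sprintf(" (%s)", object$label) else ""),
      x = "marker locus", y = "taxa", fill = NULL, alpha = "anchored") +
    ggplot2::theme_minimal()
}
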