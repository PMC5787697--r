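#' Plot a boundary coverage metaprofile against its backgrounds
#'
#' Line chart of per-base coverage density around exon boundaries, with the
#' shuffled-exon and random-region background profiles overlaid.
#'
#' @param profile A \code{meta_profile} from \code{\link{profile_coverage}}.
#' @param background_shuffle,background_random Optional background
#'   \code{meta_profile}s.
#' @param path Optional output path (PNG or SVG by extension).
#' @return The ggplot object, invisibly.
#' @export
plot_boundary_profile <- function(profile, background_shuffle = NULL,
                                  background_random = NULL, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(offset = profile$offset, density = profile$density,
                   set = "boundaries")
  if (!is.null(background_shuffle)) {
    df <- rbind(df, data.frame(offset = background_shuffle$offset,
                               density = background_shuffle$density,
                               set = "shuffled exons"))
  }
  if (!is.null(background_random)) {
    df <- rbind(df, data.frame(offset = background_random$offset,
                               density = background_random$density,
                               set = "random regions"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = offset, y = density,
                                        colour = set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("offset from %s boundary (bp; intron side > 0)",
                              toupper(profile$type)),
                  y = "coverage per boundary", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 4)
  invisible(p)
}

#' Plot a positional splicing map
#'
#' Density (solid) and permutation significance (dotted, right axis as
#' -log10 p) per map region for one or two event classes.
#'
#' @param maps Named list of \code{positional_map} objects (e.g. enhanced,
#'   silenced), each with a \code{p_value} column.
#' @param path Optional output path.
#' @return The ggplot object, invisibly.
#' @export
plot_splicing_map <- function(maps, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- do.call(rbind, lapply(names(maps), function(nm) {
    m <- as.data.frame(maps[[nm]])
    m$class <- nm
    m
  }))
  df$region <- factor(df$region, levels = splicemap_regions)
  scale <- max(df$density) / max(-log10(df$p_value), 1e-9)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = offset, colour = class)) +
    ggplot2::geom_line(ggplot2::aes(y = density)) +
    ggplot2::geom_line(ggplot2::aes(y = -log10(p_value) * scale),
                       linetype = "dotted") +
    ggplot2::facet_wrap(~region, nrow = 1, scales = "free_x") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~. / scale, name = "-log10 p")) +
    ggplot2::labs(x = "offset (bp, transcript orientation)",
                  y = "fraction of events with a peak") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 10, height = 3.5)
  invisible(p)
}
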