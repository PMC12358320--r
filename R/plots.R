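#' Plot a simulated trajectory
#'
#' Infection frequency over generations, with the deterministic interior
#' equilibrium (evaluated at the median fitness) as a dashed reference line
#' when one exists.
#'
#' @param object A [simulate_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot symdrift_trajectory
#' @export
autoplot.symdrift_trajectory <- function(object, ...) {
  gg <- ggplot2::ggplot(as_tibble(object),
                        ggplot2::aes(x = .data$generation, y = .data$p)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Infection frequency p") +
    ggplot2::theme_minimal()
  params <- attr(object, "params")
  if (!is.null(params)) {
    eq <- equilibrium(params)
    if (is.finite(eq$p_hat)) {
      gg <- gg + ggplot2::geom_hline(yintercept = eq$p_hat,
                                     linetype = "dashed", colour = "grey40")
    }
  }
  gg
}

#' Plot a replicate set
#'
#' Per-replicate post-burn-in means with one-SD whiskers and the pooled mean
#' as a horizontal reference.
#'
#' @param object A [run_replicates()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot symdrift_replicates
#' @export
autoplot.symdrift_replicates <- function(object, ...) {
  d <- object$replicates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$replicate, y = .data$p_bar)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$p_bar - .data$p_sd, 0),
                   ymax = pmin(.data$p_bar + .data$p_sd, 1)),
      colour = "#2c7fb8"
    ) +
    ggplot2::geom_hline(yintercept = object$pooled$p_dbar,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Replicate", y = "Post-burn-in mean frequency") +
    ggplot2::theme_minimal()
}

#' Heat-map of pooled grid summaries
#'
#' Tiles of a pooled statistic over the transmission-failure and fitness
#' axes, faceted by CI strength (and by the presence of low transmitters
#' when both levels occur).
#'
#' @param grid_summary A [run_grid()] result.
#' @param stat Column to fill by: `"p_dbar"` (pooled mean frequency) or
#'   `"p_sd_bar"` (mean per-replicate SD).
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(grid_summary, stat = c("p_dbar", "p_sd_bar")) {
  stat <- match.arg(stat)
  d <- dplyr::mutate(
    as_tibble(grid_summary),
    mu = factor(.data$mu), fitness = factor(.data$fitness),
    sh = paste0("sh = ", .data$sh)
  )
  gg <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$mu, y = .data$fitness, fill = .data[[stat]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = if (stat == "p_dbar") c(0, 1) else NULL) +
    ggplot2::labs(x = "Transmission failure mu", y = "Relative fitness F",
                  fill = stat) +
    ggplot2::theme_minimal()
  if (length(unique(d$low_transmitters)) > 1) {
    gg + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$low_transmitters),
      cols = ggplot2::vars(.data$sh),
      labeller = ggplot2::label_both
    )
  } else {
    gg + ggplot2::facet_wrap(ggplot2::vars(.data$sh))
  }
}

#' @importFrom rlang .data
NULL
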