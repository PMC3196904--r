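#' Plot position-specific residue frequencies
#'
#' A sequence-logo-style stacked view of the repeat array: at each of the
#' 16 consensus positions the residues are stacked by frequency.
#'
#' @param object A `position_frequency_table`.
#' @param min_frequency Residues rarer than this at a position are pooled
#'   into "other".
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.position_frequency_table <- function(object, min_frequency = 0.02,
                                              ...) {
  df <- tidy(object)
  df <- df[df$frequency > 0, ]
  df$residue <- ifelse(df$frequency < min_frequency, "other", df$residue)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$position, .data$residue),
    frequency = sum(.data$frequency), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$frequency,
                                   fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(
      data = df[df$frequency >= 0.15, ],
      ggplot2::aes(label = .data$residue),
      position = ggplot2::position_stack(vjust = 0.5), size = 3
    ) +
    ggplot2::labs(x = "repeat position", y = "frequency",
                  title = "Residue frequencies over the 16-aa repeat") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Ramachandran-style plot of a geometry report
#'
#' @param object A `geometry_report` from [validate_geometry()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geometry_report <- function(object, ...) {
  df <- object$torsions
  df <- df[!is.na(df$phi) & !is.na(df$psi), ]
  df$kind <- ifelse(!is.na(df$register) & df$register %in% c(5:8, 13:16),
                    "strand", "turn")
  ggplot2::ggplot(df, ggplot2::aes(.data$phi, .data$psi,
                                   colour = .data$kind,
                                   shape = .data$resname == "GLY")) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(16, 17),
                                labels = c("other", "Gly"), name = NULL) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi~"(deg)"), y = expression(psi~"(deg)"),
                  colour = NULL, title = "Backbone torsions") +
    ggplot2::theme_minimal()
}

#' Plot a slice through a water-density map
#'
#' Shows the map values on the plane through the grid maximum,
#' perpendicular to the chosen axis, in map-sigma units.
#'
#' @param object A `density_grid`.
#' @param axis Axis perpendicular to the slice (`"x"`, `"y"` or `"z"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_grid <- function(object, axis = c("x", "y", "z"), ...) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  peak <- arrayInd(which.max(object$values), dim(object$values))
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ai]] <- peak[ai]
  sl <- do.call(`[`, c(list(object$values), idx))
  other <- setdiff(1:3, ai)
  d <- dim(object$values)
  df <- expand.grid(a = seq_len(d[other[1]]), b = seq_len(d[other[2]]))
  df$value <- as.vector(sl)
  df$a <- object$origin[other[1]] + (df$a - 1) * object$spacing
  df$b <- object$origin[other[2]] + (df$b - 1) * object$spacing
  df$sigma <- (df$value - object$map_mean) / object$map_sd
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$sigma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(c("x", "y", "z")[other[1]], "(A)"),
                  y = paste(c("x", "y", "z")[other[2]], "(A)"),
                  fill = expression(sigma),
                  title = paste("Density slice through the peak,",
                                axis, "axis")) +
    ggplot2::theme_minimal()
}

#' Plot a lattice registration
#'
#' Lattice net oxygens and the fitted water sites, projected onto the
#' plane of the net.
#'
#' @param object A converged `registration_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.registration_result <- function(object, ...) {
  if (!isTRUE(object$converged)) stop("registration did not converge")
  nrm <- object$net$normal
  ax <- setdiff(1:3, which(nrm == 1))
  lab <- c("x", "y", "z")
  net <- object$net$waters
  fit <- object$sites_fitted
  df <- dplyr::bind_rows(
    tibble::tibble(a = net[[lab[ax[1]]]], b = net[[lab[ax[2]]]],
                   what = "ice lattice"),
    tibble::tibble(a = fit[[lab[ax[1]]]], b = fit[[lab[ax[2]]]],
                   what = "fitted sites")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, colour = .data$what,
                                   size = .data$what)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_manual(values = c(`ice lattice` = 1.2,
                                          `fitted sites` = 2.5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(lab[ax[1]], "(A)"), y = paste(lab[ax[2]], "(A)"),
                  colour = NULL, size = NULL,
                  title = sprintf("Site-to-lattice fit, RMSD %.2f A over %d pairs",
                                  object$rmsd, nrow(object$matched_pairs))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
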