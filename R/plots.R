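# ggplot2 displays for the main result objects.

#' Plot a PMF profile
#'
#' @param profile pmf_profile.
#' @return ggplot object.
#' @export
plot_pmf <- function(profile) {
  df <- data.frame(z = profile$z_centers, G = profile$G)
  ggplot2::ggplot(df[!is.na(df$G), ], ggplot2::aes(x = z, y = G)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "channel axis z (Å)", y = "PMF (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a temporal pore radius profile as a heat map
#'
#' @param trp temporal_radius_profile.
#' @return ggplot object.
#' @export
plot_temporal_profile <- function(trp) {
  e <- trp$time_bin_edges_ns
  mid <- (e[-1] + e[-length(e)]) / 2
  df <- expand.grid(time_ns = mid, z = trp$z_grid)
  df$radius <- as.vector(trp$radius)
  ggplot2::ggplot(df, ggplot2::aes(x = time_ns, y = z, fill = radius)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "radius (Å)") +
    ggplot2::labs(x = "time (ns)", y = "channel axis z (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a contact map or difference map
#'
#' @param cm contact_matrix, or a signed difference matrix from
#'   [contact_difference_map()].
#' @return ggplot object.
#' @export
plot_contact_map <- function(cm) {
  m <- if (inherits(cm, "contact_matrix")) cm$frequency else cm
  df <- expand.grid(resA = rownames(m), resB = colnames(m))
  df$value <- as.vector(m)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = resB, y = resA, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "monomer B residue", y = "monomer A residue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (inherits(cm, "contact_matrix"))
    gg + ggplot2::scale_fill_gradient(name = "frequency", low = "white",
                                      high = "darkred")
  else
    gg + ggplot2::scale_fill_gradient2(name = "Δ frequency")
}
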