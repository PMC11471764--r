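#' Plot an unfolding trajectory
#'
#' `type = "floppy"` draws the floppy-mode count against the mean
#' coordination number (the unfolding order parameter; the x axis is
#' reversed so the run reads left to right), `"q"` the decay of the native
#' contact fraction, `"criterion"` the breaking criterion per event.
#'
#' @param object An `unfolding_trajectory`.
#' @param type One of `"floppy"`, `"q"`, `"criterion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot unfolding_trajectory
#' @export
autoplot.unfolding_trajectory <- function(object,
                                          type = c("floppy", "q", "criterion"),
                                          ...) {
  type <- match.arg(type)
  ev <- tibble::as_tibble(object)
  switch(type,
    floppy = ggplot2::ggplot(ev, ggplot2::aes(.data$z, .data$f)) +
      ggplot2::geom_step() +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "mean coordination number ⟨z⟩",
                    y = "floppy modes f"),
    q = ggplot2::ggplot(ev, ggplot2::aes(.data$step, .data$q)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "bond-breaking event", y = "native contact fraction Q"),
    criterion = ggplot2::ggplot(ev, ggplot2::aes(.data$step, .data$criterion)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "bond-breaking event", y = "breaking criterion")
  ) + ggplot2::theme_minimal()
}

#' Plot a per-residue shear field
#' @param object A `shear_field`.
#' @param log Plot `log10(s)` instead of `s` (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shear_field
#' @export
autoplot.shear_field <- function(object, log = FALSE, ...) {
  df <- tidy(object)
  if (log) df$s <- log10(pmax(df$s, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(.data$residue, .data$s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue",
                  y = if (log) "log10 shear energy" else "shear energy s") +
    ggplot2::theme_minimal()
}

#' Residue-vs-Q shear heat map of an unfolding run
#'
#' Stacks shear fields computed at several stages of unfolding into the
#' classic residue-by-Q heat map: unfolding initiates where shear is high
#' at large Q and delocalizes as Q drops.
#'
#' @param fields A list of `shear_field` objects (each labelled with the Q
#'   of its network state).
#' @param log Colour by `log10(s)` (default TRUE).
#' @return A ggplot object.
#' @export
plot_shear_heatmap <- function(fields, log = TRUE) {
  df <- purrr::map_dfr(fields, tidy)
  df$value <- if (log) log10(pmax(df$s, 1e-300)) else df$s
  ggplot2::ggplot(df, ggplot2::aes(.data$residue, factor(round(.data$q, 3)),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 name = if (log) "log10 s" else "s") +
    ggplot2::labs(x = "residue", y = "native contact fraction Q") +
    ggplot2::theme_minimal()
}

#' Heat maps of family pathway correlation and TM-score matrices
#' @param object A `family_comparison`.
#' @param ... Unused.
#' @return A ggplot object (facetted when TM-scores are present).
#' @method autoplot family_comparison
#' @export
autoplot.family_comparison <- function(object, ...) {
  ids <- object$protein_ids
  long <- function(m, what) {
    idx <- which(upper.tri(m) | lower.tri(m), arr.ind = TRUE)
    tibble::tibble(a = factor(ids[idx[, 1]], levels = ids),
                   b = factor(ids[idx[, 2]], levels = ids),
                   value = m[idx], what = what)
  }
  df <- long(object$correlation, "pathway correlation")
  if (!is.null(object$tm_scores)) {
    df <- dplyr::bind_rows(df, long(object$tm_scores, "TM-score"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~what) +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
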