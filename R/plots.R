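#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   scale_color_gradient theme_minimal
NULL

#' Plot a free energy surface
#' @param object An `fes_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fes_result <- function(object, ...) {
  ggplot(object[!is.na(object$F), ], aes(x = .data$q, y = .data$F)) +
    geom_line() +
    labs(x = "l (Å)", y = "F (kcal/mol)") +
    theme_minimal()
}

#' Plot a binned committor with its free-energy profile
#' @param object A `committor_result` tibble.
#' @param ... Unused.
#' @return A ggplot: F(l) colored by the committor.
#' @export
autoplot.committor_result <- function(object, ...) {
  d <- object[!is.na(object$F), ]
  ggplot(d, aes(x = .data$bin_mid, y = .data$F, color = .data$p_c)) +
    geom_point() +
    scale_color_gradient(low = "#2166ac", high = "#b2182b", limits = c(0, 1),
                         name = "P_c") +
    labs(x = "l (Å)", y = "F (kcal/mol)") +
    theme_minimal()
}

#' Plot per-particle coefficient magnitudes of a trained model
#'
#' The flat analogue of a porcupine plot: which particles carry the
#' discriminant displacement.
#'
#' @param object A `poslda_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poslda_model <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$particle, y = .data$magnitude)) +
    geom_col() +
    labs(x = "particle", y = "|v| per particle (Å per Å)") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
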