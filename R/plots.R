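#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_vline
#'   geom_hline labs autoplot
NULL

#' Plot a many-body expansion
#'
#' Bars of the K-body contributions to a cluster interaction energy.
#'
#' @param object a `dc4_mbe`.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.dc4_mbe <- function(object, ...) {
  ggplot(tidy.dc4_mbe(object), aes(x = factor(.data$k), y = .data$epsilon)) +
    geom_col() +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = "K", y = expression(epsilon[K] ~ "(kcal/mol)"),
         title = sprintf("Many-body expansion: %s", object$label),
         subtitle = sprintf("interaction energy %.3f kcal/mol",
                            object$interaction_energy))
}

#' Plot a sensitivity-versus-error table
#'
#' Self-consistent and density-corrected errors against density
#' sensitivity, with the DS/DI cutoff marked.
#'
#' @param tab output of [sensitivity_error_table()].
#' @param cutoff DS/DI cutoff to mark, kcal/mol.
#' @return A ggplot.
#' @export
plot_sensitivity_errors <- function(tab, cutoff = 2.0) {
  long <- tidyr::pivot_longer(tab, c("sc_error", "dc_error"),
                              names_to = "variant", values_to = "error")
  long$variant <- ifelse(long$variant == "sc_error",
                         "self-consistent", "density-corrected")
  ggplot(long, aes(x = .data$s_tilde, y = abs(.data$error),
                   colour = .data$variant)) +
    geom_point() +
    geom_vline(xintercept = cutoff, linetype = "dashed") +
    labs(x = expression(tilde(S) ~ "(kcal/mol)"),
         y = "|error| (kcal/mol)", colour = NULL)
}

#' Plot a dimer distance scan
#'
#' Interaction energy against O-O distance for computed and reference
#' curves.
#'
#' @param scan tibble with columns `r_oo`, `computed`, `reference`
#'   (kcal/mol).
#' @return A ggplot.
#' @export
plot_dimer_scan <- function(scan) {
  long <- tidyr::pivot_longer(scan, c("computed", "reference"),
                              names_to = "curve", values_to = "energy")
  ggplot(long, aes(x = .data$r_oo, y = .data$energy, colour = .data$curve)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "O–O distance (Å)",
         y = "interaction energy (kcal/mol)", colour = NULL)
}
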