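#' Plot the degree distribution of an association network
#'
#' Degree density on log-log axes with the fitted power-law regression line.
#'
#' @param net Network from [build_network()].
#' @return A ggplot object.
#' @export
plot_degree_density <- function(net) {
  dd <- degree_density(net)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$k, y = .data$pk)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "degree density pk") +
    ggplot2::theme_minimal()
  fit <- tryCatch(power_law_fit(dd), error = function(e) NULL)
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                                  linetype = "dashed", colour = "grey40")
  }
  p
}

#' @export
#' @rdname plot_degree_density
#' @param object A `lncmod_topology_fit` from [power_law_fit()].
#' @param ... Unused.
#' @method autoplot lncmod_topology_fit
autoplot.lncmod_topology_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = log10(.data$k), y = log10(.data$pk))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "log10 k", y = "log10 pk",
      subtitle = sprintf("slope = %.2f, r2 = %.3f, p = %.2g",
                         object$slope, object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of a signature's risk groups
#'
#' Step survival curves of the high- and low-score groups for overall or
#' progression-free survival, annotated with the log-rank p-value.
#'
#' @param signature An `lncmod_signature` from [module_score()] or
#'   [pooled_signature()].
#' @param clinical Clinical tibble the signature was evaluated on.
#' @param endpoint `"os"` or `"pfs"`.
#' @return A ggplot object.
#' @export
plot_signature_km <- function(signature, clinical, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  dat <- left_join(signature$scores, clinical, by = "sample_id")
  tm <- dat[[paste0(endpoint, "_time")]]
  ev <- dat[[paste0(endpoint, "_event")]]
  curves <- bind_rows(lapply(c("low", "high"), function(g) {
    sel <- dat$group == g
    mutate(km_curve(tm[sel], ev[sel]), group = g)
  }))
  pval <- if (endpoint == "os") signature$os$logrank_p else signature$pfs_logrank_p
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "score group",
                  subtitle = sprintf("%s, log-rank p = %.3g", toupper(endpoint), pval)) +
    ggplot2::theme_minimal()
}

#' Time-dependent AUC profile of one or more signatures
#'
#' @param signatures A single `lncmod_signature` or a named list of them
#'   (e.g. `run$signatures`).
#' @return A ggplot object.
#' @export
plot_time_auc <- function(signatures) {
  if (inherits(signatures, "lncmod_signature")) {
    signatures <- setNames(list(signatures), signatures$signature_id)
  }
  dat <- bind_rows(lapply(signatures, function(s) {
    mutate(s$auc, signature_id = s$signature_id)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$auc,
                                    colour = .data$signature_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "time (days)", y = "AUC", colour = "signature") +
    ggplot2::theme_minimal()
}

#' Forest plot of signature hazard ratios
#'
#' Adjusted hazard ratios (high versus low score group) with 95% confidence
#' intervals for a list of signatures.
#'
#' @param signatures Named list of `lncmod_signature` objects.
#' @return A ggplot object.
#' @export
plot_forest <- function(signatures) {
  dat <- bind_rows(lapply(signatures, glance))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hr, y = .data$signature_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (high vs low)", y = NULL) +
    ggplot2::theme_minimal()
}
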