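#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_step geom_pointrange facet_wrap labs scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Plot the moving-horizon discovery history
#'
#' Two linked views of a run: the active-term count per window (structure
#' converging toward the true sparsity) or the coefficient-of-variation
#' traces per thresholding step against the pruning tolerance.
#'
#' @param object a `mhode_history`.
#' @param type `"terms"` or `"cv"`.
#' @param psi tolerance line drawn on the CV panel.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mhode_history <- function(object, type = c("terms", "cv"), psi = 1, ...) {
  type <- match.arg(type)
  if (type == "terms") {
    d <- tidy.mhode_history(object)
    ggplot(d, aes(x = .data$window, y = .data$n_active)) +
      geom_step() + geom_point(size = 1) +
      labs(x = "window", y = "active (term, state) pairs",
           title = "Dictionary size across the moving horizon") +
      theme_minimal()
  } else {
    if (nrow(object$cv) == 0) stop_mhode("no thresholding steps recorded", "argument")
    d <- dplyr::mutate(object$cv, cv = pmin(.data$cv, 1e3))
    ggplot(d, aes(x = .data$step, y = .data$cv,
                  group = interaction(.data$name, .data$state_name))) +
      geom_line(alpha = 0.4) +
      geom_point(aes(shape = .data$pruned), size = 1.5) +
      geom_hline(yintercept = psi, linetype = 2) +
      scale_y_log10() +
      facet_wrap(~state_name) +
      labs(x = "thresholding step", y = "coefficient of variation",
           title = "CV traces and pruning decisions") +
      theme_minimal()
  }
}

#' Plot a discovered model's coefficient estimates
#'
#' Point estimates with empirical percentile intervals, faceted by state
#' equation.
#'
#' @param object a `mhode_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mhode_model <- function(object, ...) {
  d <- object$coefficients
  ggplot(d, aes(x = .data$term, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    geom_hline(yintercept = 0, linetype = 3) +
    facet_wrap(~state, scales = "free") +
    labs(x = NULL, y = "coefficient",
         title = "Aggregated coefficients with 95% empirical intervals") +
    theme_minimal()
}

#' Overlay measured data and a model simulation
#'
#' @param ts measured [timeseries()].
#' @param sim simulated [timeseries()] on any grid.
#' @return a ggplot object.
#' @export
plot_fit <- function(ts, sim) {
  tall <- function(x, kind) {
    d <- tibble::as_tibble(as.data.frame(x))
    d <- tidyr::pivot_longer(d[, c(attr(x, "mh_time"), state_names(x))],
                             -dplyr::all_of(attr(x, "mh_time")),
                             names_to = "state", values_to = "value")
    names(d)[1] <- "t"
    d$kind <- kind
    d
  }
  d <- dplyr::bind_rows(tall(ts, "measured"), tall(sim, "discovered"))
  ggplot(d, aes(x = .data$t, y = .data$value, color = .data$kind)) +
    geom_line(data = ~dplyr::filter(.x, .data$kind == "discovered")) +
    geom_point(data = ~dplyr::filter(.x, .data$kind == "measured"),
               size = 0.3, alpha = 0.4) +
    facet_wrap(~state, scales = "free_y", ncol = 1) +
    labs(x = "time", y = "state", color = NULL) +
    theme_minimal()
}
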