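# broom-style accessors and plots for the registry object.

#' Tidy a registry into one of its component tables
#'
#' @param x A `crc_registry`.
#' @param what Which table: `"estimates"` (default; neighbors unnested into
#'   a `neighbor_id`/`similarity` pair is *not* done — the list column is
#'   kept), `"assignments"`, `"recommendations"`, `"stats"`, `"encoded"`,
#'   `"patients"` or `"log"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy crc_registry
#' @export
tidy.crc_registry <- function(x, what = c("estimates", "assignments",
                                          "recommendations", "stats",
                                          "encoded", "patients", "log"),
                              ...) {
  what <- match.arg(what)
  out <- switch(what,
                estimates = x$estimates,
                assignments = x$assignments,
                recommendations = x$recommendations,
                stats = x$stats,
                encoded = x$encoded,
                patients = x$patients,
                log = x$log)
  tibble::as_tibble(out)
}

#' One-row summary of a registry
#'
#' @param x A `crc_registry`.
#' @param ... Unused.
#' @return A tibble with patient counts, the high-risk share, the overall
#'   mean survival estimate and the revision counter.
#' @method glance crc_registry
#' @export
glance.crc_registry <- function(x, ...) {
  alive <- tolower(as.character(x$patients$vital_status)) == "alive"
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_alive = sum(alive, na.rm = TRUE),
    n_deceased = sum(!alive, na.rm = TRUE),
    n_high_risk = sum(x$assignments$group == "high"),
    mean_survival_percent = if (nrow(x$estimates) > 0) {
      mean(x$estimates$percent)
    } else {
      NA_real_
    },
    estimator_mode = x$config$mode,
    k = x$config$k,
    revision = x$revision
  )
}

#' Plot survival estimates by risk stratum
#'
#' Boxplots of the per-patient survival-percent estimates, one box per risk
#' stratum, with the per-stratum mean marked.
#'
#' @param object A `crc_registry`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_registry
#' @export
autoplot.crc_registry <- function(object, ...) {
  est <- object$estimates
  if (nrow(est) == 0) {
    stop("registry has no survival estimates to plot", call. = FALSE)
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$stratum, y = .data$percent)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red3",
                          shape = 18, size = 3) +
    ggplot2::labs(x = "risk stratum", y = "estimated survival (%)",
                  title = "Case-based survival estimates by risk stratum") +
    ggplot2::theme_minimal()
}

#' Heatmap of a patient similarity matrix
#'
#' @param sim Matrix from [similarity_matrix()].
#' @return A ggplot object.
#' @export
plot_similarity <- function(sim) {
  df <- tibble::as_tibble(sim, rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "similarity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
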