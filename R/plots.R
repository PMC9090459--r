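# ggplot2 displays for recordings, RAP traces and ROC curves.

#' @export
autoplot.icp_recording <- function(object, max_points = 20000, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) > max_points)
    df <- df[round(seq(1, nrow(df), length.out = max_points)), ]
  ev <- rec_events(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60,
                                        y = .data$icp_mmhg)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "time (min)", y = "ICP (mmHg)",
                  title = paste0("ICP recording: ", rec_patient_id(object)))
  if (nrow(ev) > 0)
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time_s / 60),
                                 linetype = "dashed", colour = "firebrick") +
      ggplot2::geom_text(data = ev,
                         ggplot2::aes(x = .data$time_s / 60, y = Inf,
                                      label = .data$label),
                         angle = 90, vjust = -0.3, hjust = 1.1, size = 2.8,
                         colour = "firebrick")
  p
}

#' Plot a RAP trace over its windowed inputs
#'
#' Shows mean ICP, AMP and the RAP moving correlation on aligned panels, the
#' standard display for drainage monitoring.
#'
#' @param windows Window table from [window_stats()].
#' @param series RAP series from [compute_rap()].
#' @param events Optional event tibble drawn as dashed verticals.
#' @return A ggplot object.
#' @export
plot_rap_trace <- function(windows, series, events = NULL) {
  long <- dplyr::bind_rows(
    tibble::tibble(t = (windows$t_start + windows$t_end) / 2,
                   value = windows$mean_icp, panel = "mean ICP (mmHg)"),
    tibble::tibble(t = (windows$t_start + windows$t_end) / 2,
                   value = windows$amp, panel = "AMP (mmHg)"),
    tibble::tibble(t = series$t_mid[series$valid],
                   value = series$rap[series$valid], panel = "RAP"))
  long$panel <- factor(long$panel,
                       levels = c("mean ICP (mmHg)", "AMP (mmHg)", "RAP"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t / 60, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
  if (!is.null(events) && nrow(events) > 0)
    p <- p + ggplot2::geom_vline(data = events,
                                 ggplot2::aes(xintercept = .data$time_s / 60),
                                 linetype = "dashed", colour = "firebrick")
  p
}

#' @export
autoplot.shunt_model_eval <- function(object, ...) {
  curves <- purrr::imap(setNames(object$roc, object$model), function(cv, nm) {
    if (is.null(cv)) return(NULL)
    dplyr::mutate(cv, model = nm)
  })
  df <- dplyr::bind_rows(purrr::compact(curves))
  labs <- sprintf("%s (AUC %.3f)", object$model, object$auc)
  df$model <- factor(df$model, levels = object$model,
                     labels = labs[match(levels(factor(df$model,
                                                       levels = object$model)),
                                         object$model)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = NULL,
                  title = "ROC curves of the predictive models")
}
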