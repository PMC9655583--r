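#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col facet_wrap labs
#' @export
ggplot2::autoplot

#' Tidy a training history into per-epoch validation metrics
#'
#' @param x A `dsn_fit` or `dsn_history`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: validation `acc`, `spe`, `pre`,
#'   `recall`, `f1`, `auc`, `ap` and confusion counts.
#' @method tidy dsn_fit
#' @export
tidy.dsn_fit <- function(x, ...) tidy(x$history, ...)

#' @rdname tidy.dsn_fit
#' @method tidy dsn_history
#' @export
tidy.dsn_history <- function(x, ...) as_tibble(x$epochs)

#' One-row summary of a fitted network
#'
#' @param x A `dsn_fit`.
#' @param ... Unused.
#' @return Tibble with `mode`, `epochs`, `steps`, `best_epoch`, the best
#'   validation metric, final training loss, and parameter count.
#' @method glance dsn_fit
#' @export
glance.dsn_fit <- function(x, ...) {
  metric <- x$config$selection_metric
  tibble(
    mode = x$model$mode,
    epochs = x$config$epochs,
    steps = nrow(x$history$steps),
    best_epoch = x$best_epoch,
    best_val_metric = x$history$epochs[[metric]][x$best_epoch],
    selection_metric = metric,
    final_total_loss = utils::tail(x$history$steps$total, 1),
    n_parameters = par_reduce(x$model$params,
                              function(acc, p) acc + length(p))
  )
}

#' Plot training-loss trajectories
#'
#' Per-step curves of the loss components and the weighted total.
#'
#' @param object A `dsn_history` (or `dsn_fit`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dsn_history
#' @export
autoplot.dsn_history <- function(object, ...) {
  if (inherits(object, "dsn_fit")) object <- object$history
  long <- tidyr::pivot_longer(
    object$steps,
    cols = c("recon", "difference", "similarity", "source_cls",
             "target_cls", "total"),
    names_to = "term", values_to = "loss")
  long <- long[!is.na(long$loss), , drop = FALSE]
  ggplot(long, aes(x = .data$step, y = .data$loss)) +
    geom_line() +
    facet_wrap(~term, scales = "free_y") +
    labs(x = "optimisation step", y = "loss")
}

#' @rdname autoplot.dsn_history
#' @method autoplot dsn_fit
#' @export
autoplot.dsn_fit <- function(object, ...) autoplot.dsn_history(object, ...)

#' Plot a motif's position frequency matrix
#'
#' Stacked per-position base frequencies (a logo without glyph scaling).
#'
#' @param object An `rnadsn_motif`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rnadsn_motif
#' @export
autoplot.rnadsn_motif <- function(object, ...) {
  df <- as_tibble(object$pfm)
  df$position <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(RNA_BASES),
                              names_to = "base", values_to = "freq")
  ggplot(long, aes(x = .data$position, y = .data$freq, fill = .data$base)) +
    geom_col() +
    labs(x = "motif position", y = "frequency",
         title = sprintf("%s (support %d)", object$consensus, object$support))
}

#' Plot per-position attribution weights
#'
#' Bar height is the attribution of the realised base at each window
#' position; positive bars push the prediction toward "modified".
#'
#' @param object An `attribution_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attribution_map
#' @export
autoplot.attribution_map <- function(object, ...) {
  df <- tibble(position = seq_len(nrow(object$attributions)) - 1L,
               weight = rowSums(object$attributions),
               base = strsplit(object$window, "")[[1]])
  ggplot(df, aes(x = .data$position, y = .data$weight, fill = .data$base)) +
    geom_col() +
    labs(x = "window position (0-based)", y = "attribution")
}
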