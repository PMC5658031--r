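# broom-style accessors and plotting for fitted models and decoy sets.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training log of a fitted autoencoder
#' @param x An `sda_model`.
#' @param ... Unused.
#' @return Tibble with columns `phase`, `layer`, `epoch`, `loss`.
#' @export
tidy.sda_model <- function(x, ...) x$training_log

#' One-row model summary
#' @param x An `sda_model`.
#' @param ... Unused.
#' @return Tibble with the architecture and final losses.
#' @export
glance.sda_model <- function(x, ...) {
  log <- x$training_log
  ft <- log$loss[log$phase == "finetune"]
  tibble::tibble(
    input_dim = x$input_dim,
    n_layers = length(x$layers),
    widths = paste(x$widths, collapse = "/"),
    n_epochs_logged = nrow(log),
    final_finetune_loss = if (length(ft)) ft[length(ft)] else NA_real_,
    scale_N = if (!is.null(x$scale)) x$scale$N else NA_real_
  )
}

#' Training-loss curves
#' @param object An `sda_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss, faceted by training phase.
#' @export
autoplot.sda_model <- function(object, ...) {
  log <- object$training_log
  if (!nrow(log)) stop("model has no training log yet")
  log$curve <- ifelse(log$phase == "pretrain",
                      paste0("pretrain layer ", log$layer), "finetune")
  ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (normalized units)")
}

#' @importFrom ggplot2 .data
NULL

#' Tidy a decoy set
#' @param x A `decoy_set`.
#' @param ... Unused.
#' @return Tibble with `decoy_id` and `rmsd_to_native` (Angstrom).
#' @export
tidy.decoy_set <- function(x, ...) {
  tibble::tibble(
    decoy_id = vapply(x$decoys, function(d) d$id, character(1)),
    rmsd_to_native = x$rmsd_to_native
  )
}

#' Histogram of decoy RMSDs to the native
#' @param object A `decoy_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoy_set <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rmsd_to_native)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "CA RMSD to native (Å)", y = "decoys")
}
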