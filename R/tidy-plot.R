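# Broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a noise-sweep result
#'
#' Pivots a [noise_sweep()] table to one row per (noise level, outcome)
#' with the outcome fraction.
#'
#' @param x A `bn_sweep`.
#' @param ... Unused.
#' @return A tibble with columns `task`, (`arm`,) `noise`, `outcome`,
#'   `fraction`, `n`.
#' @export
tidy.bn_sweep <- function(x, ...) {
  keys <- intersect(c("task", "arm", "noise", "n"), names(x))
  long <- tidyr::pivot_longer(
    dplyr::select(
      tibble::as_tibble(x), dplyr::all_of(keys),
      dplyr::all_of(c("frac_correct", "frac_incorrect", "frac_no_decision"))
    ),
    dplyr::starts_with("frac_"),
    names_to = "outcome", values_to = "fraction", names_prefix = "frac_"
  )
  long$outcome <- factor(long$outcome,
    levels = c("correct", "incorrect", "no_decision"),
    labels = c("Correct", "Incorrect", "NoDecision")
  )
  long
}

#' Summarise a noise-sweep result
#'
#' @param x A `bn_sweep`.
#' @param ... Unused.
#' @return A one-row tibble per (task, arm): the largest noise level with
#'   all trials correct (`perfect_to`), and the correct fraction at the
#'   lowest and highest levels tested.
#' @export
glance.bn_sweep <- function(x, ...) {
  keys <- intersect(c("task", "arm"), names(x))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), dplyr::across(dplyr::all_of(keys))),
    perfect_to = {
      ok <- .data$frac_correct == 1
      if (!length(ok) || !ok[1]) NA_real_ else .data$noise[max(which(cumall(ok)))]
    },
    correct_at_min = .data$frac_correct[which.min(.data$noise)],
    correct_at_max = .data$frac_correct[which.max(.data$noise)],
    .groups = "drop"
  )
}

# Cumulative all: TRUE prefix of a logical vector.
cumall <- function(x) cumsum(!x) == 0

#' Tidy a trained network's weights
#'
#' @param x A `bn_network`.
#' @param ... Unused.
#' @return A tibble with one row per synapse of every plastic connection:
#'   `connection`, `source_neuron`, `target_neuron`, `weight`.
#' @export
tidy.bn_network <- function(x, ...) {
  purrr::map_dfr(names(x$conns), function(nm) {
    cn <- x$conns[[nm]]
    if (!cn$plastic) {
      return(NULL)
    }
    tibble::tibble(
      connection = nm,
      target_neuron = rep(seq_len(nrow(cn$W)), ncol(cn$W)),
      source_neuron = rep(seq_len(ncol(cn$W)), each = nrow(cn$W)),
      weight = as.numeric(cn$W)
    )
  })
}

#' One-row summary of a network
#'
#' @param x A `bn_network`.
#' @param ... Unused.
#' @return A one-row tibble: group/connection/neuron counts, binarization
#'   state, and hardware-check status (if a report is attached).
#' @export
glance.bn_network <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    n_neurons = network_size(x),
    n_connections = length(x$conns),
    binarized = x$binarized,
    hardware_ok = if (is.null(x$hardware_report)) NA else all(x$hardware_report$pass)
  )
}

#' Stacked-outcome plot of a noise sweep
#'
#' Mirrors the layout of the noise-robustness figures: outcome fractions as
#' lines against the noise level, faceted by arm for ablation results.
#'
#' @param object A `bn_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_sweep <- function(object, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$noise * 100, y = .data$fraction * 100,
    colour = .data$outcome, linetype = .data$outcome
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Noise on the retina (%)", y = "Trials (%)",
      colour = "Outcome", linetype = "Outcome"
    ) +
    ggplot2::ylim(0, 100)
  if ("arm" %in% names(long)) p <- p + ggplot2::facet_wrap(~arm)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
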