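# broom-style accessors and ggplot2 visualisations for traces and diagnostics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior trace
#'
#' @param x An `hp_trace`.
#' @param ... Unused.
#' @return The retained samples as a tibble (`generation`, `log_joint`,
#'   `tree_length`).
#' @export
tidy.hp_trace <- function(x, ...) {
  x$samples
}

#' One-row summary of a posterior trace
#'
#' @param x An `hp_trace`.
#' @param ... Unused.
#' @return A one-row tibble: retained sample count, mean/median/variance of
#'   tree length, mean log joint, cold-chain acceptance rate and swap
#'   acceptance.
#' @export
glance.hp_trace <- function(x, ...) {
  tl <- tree_length_summary(x)
  tibble::tibble(
    n_samples = nrow(x$samples),
    mean_log_joint = mean(x$samples$log_joint),
    mean_tree_length = tl$mean,
    median_tree_length = tl$median,
    var_tree_length = tl$variance,
    acceptance_rate = x$acceptance$rate[1],
    swap_rate = if (x$swaps[["attempted"]] > 0) {
      x$swaps[["accepted"]] / x$swaps[["attempted"]]
    } else {
      NA_real_
    }
  )
}

#' Trace plot of a posterior sample
#'
#' Log joint density and total tree length against generation.
#'
#' @param object An `hp_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_trace <- function(object, ...) {
  df <- object$samples
  long <- rbind(
    data.frame(generation = df$generation, value = df$log_joint,
               quantity = "log joint"),
    data.frame(generation = df$generation, value = df$tree_length,
               quantity = "tree length")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare split frequencies of two runs
#'
#' Scatter of per-split posterior frequencies from two traces; points on the
#' diagonal indicate agreement.
#'
#' @param table_a,table_b `hp_split_table` objects (from
#'   [split_frequencies()]) built with a common reference taxon.
#' @return A ggplot object.
#' @export
plot_split_comparison <- function(table_a, table_b) {
  keys <- union(table_a$split, table_b$split)
  fa <- stats::setNames(rep(0, length(keys)), keys)
  fb <- fa
  fa[table_a$split] <- table_a$frequency
  fb[table_b$split] <- table_b$frequency
  df <- data.frame(split = keys, run_a = fa, run_b = fb)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run_a, y = .data$run_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "split frequency (run A)",
                  y = "split frequency (run B)") +
    ggplot2::theme_minimal()
}

#' Heat maps of a posterior landscape scan
#'
#' @param scan Output of [landscape_scan()].
#' @param quantity One of `"log_joint"`, `"rf_to_reference"`, `"tree_length"`.
#' @return A ggplot object.
#' @export
plot_landscape <- function(scan, quantity = c("log_joint", "rf_to_reference",
                                              "tree_length")) {
  quantity <- match.arg(quantity)
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$x1, y = .data$x2,
                                     fill = .data[[quantity]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "tangent x1", y = "tangent x2", fill = quantity) +
    ggplot2::theme_minimal()
}

#' Topology spread of proposals by scale
#'
#' @param draws Output of [neighborhood_sample()].
#' @return A ggplot object (RF distance distributions per proposal scale).
#' @export
plot_neighborhood <- function(draws) {
  draws$scale <- factor(draws$scale)
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$scale, y = .data$rf)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = stats::median, geom = "point") +
    ggplot2::labs(x = "proposal scale", y = "RF distance to reference") +
    ggplot2::theme_minimal()
}
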