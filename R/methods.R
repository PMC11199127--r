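#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @export
tidy.ccm_curve <- function(x, ...) {
  tibble::tibble(library_size = x$library_size, skill = x$skill)
}

#' @export
glance.ccm_curve <- function(x, ...) {
  tibble::tibble(final_skill = attr(x, "final_skill"),
                 converged = attr(x, "converged"),
                 n_sizes = nrow(x))
}

#' @export
tidy.ccm_windows <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.ccm_windows <- function(x, ...) {
  tibble::tibble(mean_skill = attr(x, "mean_skill"),
                 n_converged = attr(x, "n_converged"),
                 n_windows = nrow(x))
}

#' @export
tidy.eccm_profile <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      cols = c("skill_xy", "skill_yx"),
                      names_to = "direction", values_to = "skill")
}

#' @export
glance.eccm_profile <- function(x, ...) {
  tibble::tibble(opt_lag_xy = attr(x, "opt_lag_xy"),
                 opt_lag_yx = attr(x, "opt_lag_yx"),
                 peak_xy = attr(x, "peak_xy"),
                 peak_yx = attr(x, "peak_yx"),
                 classification = attr(x, "classification"))
}

#' @export
tidy.causal_network <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.causal_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(network_nodes(x)), n_edges = nrow(x),
                 mean_skill = mean(x$mean_skill, na.rm = TRUE))
}

#' @export
tidy.bayes_net <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(v) {
    tab <- x$cpds[[v]]
    df <- as.data.frame.table(tab, responseName = "probability",
                              stringsAsFactors = FALSE)
    names(df)[1] <- "state"
    parents <- setdiff(names(dimnames(tab)), v)
    tibble::tibble(
      node = v,
      state = as.integer(df$state),
      parent_config = if (length(parents) == 0) NA_character_ else
        do.call(paste, c(lapply(parents, function(p) paste0(p, "=", df[[p]])),
                         sep = ",")),
      probability = df$probability
    )
  })
}

#' @export
glance.bayes_net <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 target = x$target,
                 n_train = nrow(x$train), n_test = nrow(x$test))
}

#' @export
autoplot.ccm_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$library_size, .data$skill)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "library size", y = "cross-map skill (ρ)",
                  subtitle = if (attr(object, "converged"))
                    "converged" else "not converged") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eccm_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$shift, .data$skill,
                               colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "cross-map shift (samples)", y = "skill (ρ)",
                  subtitle = attr(object, "classification")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.causal_network <- function(object, seed = 42, ...) {
  g <- as_igraph_network(object)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  edges <- tibble::as_tibble(unclass(object))
  edges <- dplyr::left_join(edges, nodes, by = c(source = "name"))
  edges <- dplyr::left_join(edges, nodes, by = c(target = "name"),
                            suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$mean_skill),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(.data$x, .data$y, label = .data$name)) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::theme_void()
}

#' @export
autoplot.causal_dag <- function(object, ...) autoplot.causal_network(object, ...)

#' Bar plot of sensitivity contributions
#'
#' @param contributions Output of [variable_contributions()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(contributions) {
  ggplot2::ggplot(contributions,
                  ggplot2::aes(stats::reorder(.data$variable,
                                              .data$contribution),
                               .data$contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contribution (|mean residual| sum)") +
    ggplot2::theme_minimal()
}

#' @export
print.causal_network <- function(x, ...) {
  cat("<causal_network> ", nrow(x), " edges, ",
      length(network_nodes(x)), " nodes\n", sep = "")
  NextMethod()
}

#' @export
print.bayes_net <- function(x, ...) {
  cat("<bayes_net> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, target: ", x$target, "\n", sep = "")
  invisible(x)
}
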