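#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_tile geom_text
#'   geom_col geom_histogram geom_point scale_fill_gradient labs theme_minimal
#'   coord_equal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.glm_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("beta0", "beta1", "beta2"),
    estimate = as.numeric(x$beta),
    std.error = as.numeric(x$se),
    statistic = as.numeric(sm[, 3]),
    p.value = as.numeric(sm[, 4])
  )
}

#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma2 = x$sigma2, n = x$n,
                 kappa = x$kappa)
}

#' @export
glance.decoding_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, n = x$n)
}

#' @export
tidy.decoding_report <- function(x, ...) x$per_class

#' Per-class tuned-neuron counts
#' @param x a `tuning_result`.
#' @param ... unused.
#' @export
glance.tuning_result <- function(x, ...) {
  cnt <- function(col) sum(x[[col]], na.rm = TRUE)
  tibble::tibble(
    n_neurons = nrow(x),
    n_acceleration = cnt("is_acceleration_tuned"),
    n_position = cnt("is_position_tuned"),
    n_path = cnt("is_path_tuned"),
    n_conj_accel_position = cnt("conj_accel_position"),
    n_conj_accel_path = cnt("conj_accel_path")
  )
}

#' @export
autoplot.nav_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, colour = .data$time)) +
    geom_path() +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)", colour = "time (s)") +
    theme_minimal()
}

#' @export
autoplot.decoding_report <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("truth", "pred", "n")
  ggplot(cm, aes(x = .data$pred, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = sprintf("accuracy %.1f%%", 100 * object$accuracy)) +
    theme_minimal()
}

#' @export
autoplot.tuning_result <- function(object, ...) {
  g <- glance(object)
  df <- tibble::tibble(
    class = c("acceleration", "position", "path", "conj accel+pos", "conj accel+path"),
    n = c(g$n_acceleration, g$n_position, g$n_path,
          g$n_conj_accel_position, g$n_conj_accel_path)
  )
  ggplot(df, aes(x = .data$class, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "neurons flagged") +
    theme_minimal()
}

#' @export
autoplot.dprime_result <- function(object, ...) {
  df <- object[is.finite(object$d_prime), , drop = FALSE]
  ggplot(df, aes(x = .data$d_prime)) +
    geom_histogram(bins = 40, fill = "steelblue") +
    facet_wrap(~region) +
    labs(x = "d'", y = "neurons") +
    theme_minimal()
}

#' Plot the cross-cortical map of tuned cells
#'
#' Scatter of neuron image-plane centroids coloured by tuned class, the
#' salt-and-pepper view of the functional map.
#'
#' @param map output of [export_spatial_map()].
#' @export
plot_spatial_map <- function(map) {
  cls <- rep("untuned", nrow(map))
  cls[map$is_position_tuned %in% TRUE] <- "position"
  cls[map$is_path_tuned %in% TRUE] <- "path"
  cls[map$is_acceleration_tuned %in% TRUE] <- "acceleration"
  cls[map$conj_accel_position %in% TRUE | map$conj_accel_path %in% TRUE] <- "conjunctive"
  map$class <- cls
  ggplot(map, aes(x = .data$cx, y = .data$cy, colour = .data$class)) +
    geom_point(alpha = 0.8) +
    coord_equal() +
    labs(x = "image x (μm)", y = "image y (μm)") +
    theme_minimal()
}
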