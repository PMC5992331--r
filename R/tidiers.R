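# broom-style summaries for solver results.

#' @method tidy lp_result
#' @export
tidy.lp_result <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(variable = character(0), value = numeric(0)))
  }
  tibble::tibble(variable = names(x$x) %||% seq_along(x$x), value = x$x)
}

#' @method glance lp_result
#' @export
glance.lp_result <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value)
}

#' @method tidy yield_result
#' @export
tidy.yield_result <- function(x, ...) {
  v <- x$x %||% x$limit_direction
  if (is.null(v)) {
    return(tibble::tibble(variable = character(0), value = numeric(0)))
  }
  tibble::tibble(
    variable = names(v) %||% seq_along(v),
    value = v,
    role = if (is.null(x$x)) "limit_direction" else "witness"
  )
}

#' @method glance yield_result
#' @export
glance.yield_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    optimal_yield = x$optimal_yield,
    attained = x$status == "optimal_attained",
    t_star = x$t_star
  )
}

#' Plot annotated generators in yield space
#'
#' @param object an annotated, optionally partitioned `generator_set`.
#' @param ... unused.
#' @return a ggplot of generator yield pairs (requires a `yield` annotation
#'   and a second yield passed via `spec2`), or rate values when only rates
#'   are annotated.
#' @method autoplot generator_set
#' @export
autoplot.generator_set <- function(object, ...) {
  tab <- tidy(object)
  if (!is.null(tab$rate) && !is.null(tab$yield)) {
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$rate, y = .data$yield))
  } else if (!is.null(tab$rate)) {
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$id, y = .data$rate))
  } else {
    stop("annotate_generators() first", call. = FALSE)
  }
  aes_extra <- if (!is.null(tab$region)) {
    ggplot2::aes(color = .data$region)
  } else {
    ggplot2::aes(color = .data$kind)
  }
  p + ggplot2::geom_point(aes_extra, size = 2.5) +
    ggplot2::theme_minimal()
}
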