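# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a two-group ANOVA result
#'
#' @param x A `"phnr_anova"` object.
#' @param ... Unused.
#' @return One-row tibble with `f_stat`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
tidy.phnr_anova <- function(x, ...) {
  tibble::tibble(f_stat = x$f_stat, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value)
}

#' @rdname tidy.phnr_anova
#' @export
glance.phnr_anova <- function(x, ...) tidy.phnr_anova(x)

#' Tidy an eccentricity-fit result
#'
#' @param x An `"ecc_fit"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: one row with `kind`, `r_squared`, `space`, `n`.
#' @export
tidy.ecc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.ecc_fit
#' @export
glance.ecc_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, r_squared = x$r_squared, space = x$space,
                 n = length(x$y))
}

#' Tidy a power/sample-size result
#'
#' @param x A `"power_result"` object.
#' @param ... Unused.
#' @return One-row tibble with `n_per_group`, `achieved_power`,
#'   `effect_size`, `planning_sd`, `planning_sd_value`, `alpha`, `power`.
#' @export
tidy.power_result <- function(x, ...) {
  tibble::tibble(n_per_group = x$n_per_group,
                 achieved_power = x$achieved_power,
                 effect_size = x$effect_size, planning_sd = x$planning_sd,
                 planning_sd_value = x$planning_sd_value,
                 alpha = x$alpha, power = x$power)
}

#' @rdname tidy.power_result
#' @export
glance.power_result <- function(x, ...) tidy.power_result(x)
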