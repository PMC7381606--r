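#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quantile fit into one row per coefficient
#'
#' @param x A `quantile_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (inference columns are `NA` until [mcmb_standard_errors()] is run;
#'   the t statistic and p-value are reported for the slope, the gradient
#'   parameter of interest).
#' @method tidy quantile_fit
#' @export
tidy.quantile_fit <- function(x, ...) {
  out <- tibble(
    term = c("intercept", "slope"),
    estimate = unname(x$coefficients),
    std.error = NA_real_,
    statistic = NA_real_,
    p.value = NA_real_
  )
  if (!is.null(x$mcmb)) {
    out$std.error <- unname(x$mcmb$se[c("intercept", "slope")])
    out$statistic[2] <- x$mcmb$t
    out$p.value[2] <- x$mcmb$p
  }
  out
}

#' One-row summary of a quantile fit
#'
#' @param x A `quantile_fit`.
#' @param ... Unused.
#' @return Tibble `tau`, `n`, `loss`, `age_col`, `convention`,
#'   `n_resamples`, `seed`.
#' @method glance quantile_fit
#' @export
glance.quantile_fit <- function(x, ...) {
  tibble(
    tau = x$tau, n = x$n, loss = x$loss,
    age_col = x$age_col %||% NA_character_,
    convention = x$convention,
    n_resamples = if (is.null(x$mcmb)) NA_integer_ else x$mcmb$n_resamples,
    seed = if (is.null(x$mcmb)) NA_integer_ else x$mcmb$seed
  )
}

#' Tidy an HPD envelope into one row per coefficient per age column
#'
#' @param x An `hpd_envelope` from [fit_hpd_envelope()].
#' @param ... Unused.
#' @return Row-bound [tidy.quantile_fit()] outputs with an `age_col`
#'   column.
#' @method tidy hpd_envelope
#' @export
tidy.hpd_envelope <- function(x, ...) {
  purrr::map2(x, names(x), function(f, nm) mutate(tidy(f), age_col = nm)) |>
    bind_rows()
}

#' Tidy a D-statistic result
#'
#' @param x A `dstat_result`.
#' @param ... Unused.
#' @return One-row tibble with the scaled statistic, the observed change
#'   sum, both null means and both permutation p-values.
#' @method tidy dstat_result
#' @export
tidy.dstat_result <- function(x, ...) {
  tibble(
    D = x$D, d_obs = x$d_obs,
    mean_d_random = mean(x$d_random),
    mean_d_brownian = mean(x$d_brownian),
    p_random = x$p_random, p_brownian = x$p_brownian
  )
}

#' One-row summary of a D-statistic run
#'
#' @param x A `dstat_result`.
#' @param ... Unused.
#' @return Tibble `D`, `prevalence`, `n_perm`, `identifiable`, `seed`.
#' @method glance dstat_result
#' @export
glance.dstat_result <- function(x, ...) {
  tibble(D = x$D, prevalence = x$prevalence, n_perm = x$n_perm,
         identifiable = x$identifiable, seed = x$seed)
}
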