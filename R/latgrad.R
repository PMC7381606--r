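#' Mean latitude per species from presence cells, with northern truncation
#'
#' Computes each species' mean latitudinal position as the unweighted mean of
#' its presence-cell center latitudes, after dropping cells north of
#' `truncate_north_of` (the truncation focuses the analysis on the
#' southward-expansion gradient; sampling is sparser toward the north).
#' Species whose cells are all truncated away get no latitude and drop out
#' of latitude-conditioned analyses downstream.
#'
#' @param cells Tibble of presence cells: `species`, `lat`, `lon` (signed
#'   decimal degrees, south negative).
#' @param truncate_north_of Truncation latitude in signed degrees; cells with
#'   `lat > truncate_north_of` are dropped. Default `0` (the equator); `15`
#'   reproduces the northern-sensitivity setting.
#' @param weight Cell weighting: `"none"` (unweighted mean of cell-center
#'   latitudes, the default) or `"cos"` (cosine-latitude weights, so equal
#'   ground areas count equally).
#' @return Tibble `species`, `mean_latitude`, `n_cells`, `truncation`.
#' @export
species_latitudes <- function(cells, truncate_north_of = 0,
                              weight = c("none", "cos")) {
  weight <- match.arg(weight)
  cells <- as_tibble(cells)
  stopifnot(all(c("species", "lat") %in% names(cells)))
  cells |>
    mutate(species = normalize_species_names(.data$species)) |>
    filter(.data$lat <= truncate_north_of) |>
    mutate(w = if (weight == "cos") cos(.data$lat * pi / 180) else 1) |>
    group_by(.data$species) |>
    summarise(mean_latitude = sum(.data$w * .data$lat) / sum(.data$w),
              n_cells = n(), .groups = "drop") |>
    mutate(truncation = truncate_north_of)
}

#' Attach pair mean latitudes to a sister-pair table
#'
#' A pair's latitude is the mean of its two species' mean latitudes. When
#' only one species has a latitude (no range data for the other), that
#' species' mean is used alone (`latitude_source = "single_species"`); when
#' neither has one the pair is flagged `"missing"` and is excluded from the
#' regression by [fit_age_gradient()].
#'
#' Latitudes can come from [species_latitudes()] and/or from a
#' `mean_latitude` column of the species table (precomputed means bypass
#' truncation, with a warning).
#'
#' @param pairs Pair table from [find_biome_sister_pairs()].
#' @param latitudes Tibble with `species` and `mean_latitude`.
#' @param precomputed Set to `TRUE` to silence the truncation-bypass warning
#'   when `latitudes` holds precomputed means rather than cell summaries.
#' @return `pairs` with `mean_latitude` and `latitude_source` filled in.
#' @export
attach_pair_latitudes <- function(pairs, latitudes, precomputed = !("n_cells" %in% names(latitudes))) {
  pairs <- as_tibble(pairs)
  latitudes <- as_tibble(latitudes)
  stopifnot(all(c("species", "mean_latitude") %in% names(latitudes)))
  if (isTRUE(precomputed)) {
    warning("using precomputed mean latitudes: truncation rule not applied",
            call. = FALSE)
  }
  latitudes <- latitudes |>
    mutate(species = normalize_species_names(.data$species)) |>
    filter(!is.na(.data$mean_latitude))
  lat_a <- latitudes$mean_latitude[match(pairs$species_a, latitudes$species)]
  lat_b <- latitudes$mean_latitude[match(pairs$species_b, latitudes$species)]
  both <- !is.na(lat_a) & !is.na(lat_b)
  one <- xor(is.na(lat_a), is.na(lat_b))
  pairs |>
    mutate(
      mean_latitude = dplyr::case_when(
        both ~ (lat_a + lat_b) / 2,
        one ~ dplyr::coalesce(lat_a, lat_b),
        TRUE ~ NA_real_
      ),
      latitude_source = dplyr::case_when(
        both ~ "both_species",
        one ~ "single_species",
        TRUE ~ "missing"
      )
    )
}

#' Fit the age-latitude quantile gradient on a sister-pair table
#'
#' Fits the \eqn{\tau}-quantile regression of pair divergence age on pair
#' mean latitude ([fit_quantile_regression()]), the model behind the
#' biome-age gradient: the upper conditional quantile of within-biome sister
#' ages tracks how long the biome has been present at each latitude, while
#' younger splits below the quantile line carry no information about its
#' first spread. Optionally runs the Markov chain marginal bootstrap for
#' coefficient uncertainty.
#'
#' @param pairs Pair table with `mean_latitude` attached; rows with missing
#'   latitude or age are dropped (counted in `glance()`).
#' @param tau Quantile level; the customary settings are 0.90 and 0.95
#'   (the top 10% and 5% of oldest ages).
#' @param age_col Age column to fit: `"age_ma"` (point estimates),
#'   `"hpd_upper"` or `"hpd_lower"`.
#' @param lat_col Latitude column (signed degrees, south negative).
#' @param n_resamples MCMB resamples; `0` skips the bootstrap.
#' @param seed Seed for the bootstrap chain.
#' @param method `"quantile"` (default) fits the tau-quantile line on all
#'   retained pairs; `"oldest_subset"` is a sensitivity mode that instead
#'   takes the oldest `(1 - tau)` fraction of pairs and fits ordinary least
#'   squares through them, with classical standard errors in `$ols`.
#' @param convention Latitude sign convention of `lat_col`:
#'   `"signed"` (south negative; the default used throughout) or
#'   `"degrees_south"` (positive southward).
#' @return A `quantile_fit` (see [fit_quantile_regression()]) with
#'   `convention`, `age_col` and `n_dropped` recorded.
#' @export
fit_age_gradient <- function(pairs, tau = 0.90, age_col = "age_ma",
                             lat_col = "mean_latitude",
                             n_resamples = 999, seed = 1,
                             convention = "signed",
                             method = c("quantile", "oldest_subset")) {
  pairs <- as_tibble(pairs)
  method <- match.arg(method)
  stopifnot(age_col %in% names(pairs), lat_col %in% names(pairs))
  convention <- match.arg(convention, c("signed", "degrees_south"))
  ok <- !is.na(pairs[[age_col]]) & !is.na(pairs[[lat_col]])
  x <- pairs[[lat_col]][ok]
  y <- pairs[[age_col]][ok]
  if (method == "oldest_subset") {
    keep <- y >= stats::quantile(y, tau, names = FALSE)
    ols <- stats::lm(y[keep] ~ x[keep])
    sm <- summary(ols)$coefficients
    fit <- structure(
      list(coefficients = c(intercept = unname(stats::coef(ols)[1]),
                            slope = unname(stats::coef(ols)[2])),
           tau = tau, loss = NA_real_, n = sum(keep), basis = NULL,
           x = x[keep], y = y[keep], convention = convention,
           mcmb = NULL, method = method,
           ols = list(se = c(intercept = sm[1, 2], slope = sm[2, 2]),
                      t = sm[2, 3], p = sm[2, 4])),
      class = "quantile_fit"
    )
    fit$age_col <- age_col
    fit$n_dropped <- sum(!ok)
    return(fit)
  }
  fit <- fit_quantile_regression(x, y, tau)
  fit$convention <- convention
  fit$age_col <- age_col
  fit$n_dropped <- sum(!ok)
  fit$method <- method
  if (n_resamples > 0) {
    fit <- mcmb_standard_errors(fit, n_resamples = n_resamples, seed = seed)
  }
  fit
}

#' Predict biome establishment age at given latitudes
#'
#' Evaluates the fitted quantile line, `intercept + slope * latitude`, at the
#' requested latitudes: under the gradient model this is the estimated age of
#' the biome where it is found at that latitude. When an MCMB chain is
#' available a central 95% bootstrap interval is attached. Latitudes outside
#' the span of the fitted data are extrapolations and are flagged (with a
#' warning).
#'
#' @param fit A `quantile_fit` (usually from [fit_age_gradient()]).
#' @param latitude Numeric vector of latitudes in the fit's convention.
#' @return Tibble `latitude`, `age_ma`, `lower`, `upper` (NA without a
#'   bootstrap chain), `extrapolated`.
#' @export
predict_biome_age <- function(fit, latitude) {
  stopifnot(inherits(fit, "quantile_fit"))
  a <- fit$coefficients["intercept"]
  b <- fit$coefficients["slope"]
  rng <- range(fit$x)
  extra <- latitude < rng[1] | latitude > rng[2]
  if (any(extra)) {
    warning(sum(extra), " latitude(s) outside the fitted span [",
            sprintf("%.3g, %.3g", rng[1], rng[2]), "]: extrapolation",
            call. = FALSE)
  }
  out <- tibble(
    latitude = latitude,
    age_ma = unname(a + b * latitude),
    lower = NA_real_, upper = NA_real_,
    extrapolated = extra
  )
  if (!is.null(fit$mcmb)) {
    ch <- fit$mcmb$chain
    pred <- outer(ch[, "intercept"], rep(1, length(latitude))) +
      outer(ch[, "slope"], latitude)
    qs <- apply(pred, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
  }
  out
}

#' Quantile fits through the point ages and their HPD bounds
#'
#' Fits the same \eqn{\tau}-quantile line three times on identical pairs,
#' using the point age, the upper HPD bound and the lower HPD bound as the
#' response, to bracket how dating uncertainty propagates into the gradient.
#' Because HPD columns are pointwise ordered, the three predicted ages are
#' ordered (upper >= mean >= lower) at every observed latitude.
#'
#' @inheritParams fit_age_gradient
#' @return Named list of class `hpd_envelope` with `quantile_fit` elements
#'   `age_mean`, `age_hpd_upper`, `age_hpd_lower`.
#' @export
fit_hpd_envelope <- function(pairs, tau = 0.90, lat_col = "mean_latitude",
                             n_resamples = 0, seed = 1,
                             convention = "signed") {
  pairs <- as_tibble(pairs)
  if (!all(c("hpd_lower", "hpd_upper") %in% names(pairs)) ||
      all(is.na(pairs$hpd_lower))) {
    stop("pairs carry no HPD bounds; use fit_age_gradient() on the point ages",
         call. = FALSE)
  }
  ok <- stats::complete.cases(pairs[, c(lat_col, "age_ma", "hpd_lower", "hpd_upper")])
  sub <- pairs[ok, , drop = FALSE]
  fits <- list(
    age_mean = fit_age_gradient(sub, tau, "age_ma", lat_col, n_resamples,
                                seed, convention),
    age_hpd_upper = fit_age_gradient(sub, tau, "hpd_upper", lat_col,
                                     n_resamples, seed, convention),
    age_hpd_lower = fit_age_gradient(sub, tau, "hpd_lower", lat_col,
                                     n_resamples, seed, convention)
  )
  structure(fits, class = "hpd_envelope")
}

#' Report a fitted slope in either latitude convention
#'
#' The engine fits in signed degrees (south negative); figures in the
#' degrees-south convention (positive southward) flip the slope's sign.
#' The returned tibble records which convention produced the number.
#'
#' @param fit A `quantile_fit`.
#' @param convention `"signed"` or `"degrees_south"`.
#' @return One-row tibble `slope`, `intercept`, `convention`.
#' @export
report_slope <- function(fit, convention = c("signed", "degrees_south")) {
  convention <- match.arg(convention)
  b <- unname(fit$coefficients["slope"])
  a <- unname(fit$coefficients["intercept"])
  if (convention != fit$convention) b <- -b
  tibble(slope = b, intercept = a, convention = convention)
}
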