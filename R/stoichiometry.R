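#' Balanced stoichiometry of sulfate-coupled n-alkane oxidation
#'
#' Complete oxidation of an n-alkane \eqn{C_nH_{2n+2}} with sulfate as the
#' terminal electron acceptor follows
#' \deqn{C_nH_{2n+2} + (0.75n + 0.25)\,SO_4^{2-} \rightarrow
#'       n\,HCO_3^- + (0.75n + 0.25)\,HS^- + H_2O + (0.25n - 0.25)\,H^+.}
#' The coefficients conserve charge and electrons: an alkane carries
#' \eqn{6n + 2} transferable electrons (mean carbon oxidation state
#' \eqn{-(2n+2)/n}, oxidized to +4 in bicarbonate) and each sulfate accepts 8,
#' so the sulfate (and sulfide) coefficient is \eqn{(6n+2)/8 = 0.75n + 0.25}.
#'
#' @param n Integer vector of carbon-chain lengths (\eqn{n \ge 1}).
#'
#' @return A tibble with one row per element of `n` and columns `n`,
#'   `coeff_sulfate`, `coeff_dic`, `coeff_sulfide`, `coeff_water`,
#'   `coeff_proton` (moles per mole alkane) and `ratio_dic_sulfate`, the
#'   theoretical ratio of DIC production to sulfate reduction for complete
#'   oxidation.
#'
#' @examples
#' alkane_stoichiometry(c(6, 14))
#' @export
alkane_stoichiometry <- function(n) {
  assert_carbon_number(n)
  n <- as.numeric(n)
  tibble(
    n = n,
    coeff_sulfate = 0.75 * n + 0.25,
    coeff_dic = n,
    coeff_sulfide = 0.75 * n + 0.25,
    coeff_water = 1,
    coeff_proton = 0.25 * n - 0.25,
    ratio_dic_sulfate = n / (0.75 * n + 0.25)
  )
}

#' Theoretical DIC:sulfate ratio for complete alkane oxidation
#'
#' The ratio of dissolved inorganic carbon produced to sulfate reduced when
#' all alkane carbon is oxidized: \eqn{n / (0.75n + 0.25)}. For petroleum
#' alkanes \eqn{n = 5..14} this lies between 1.25 and ~1.30 and approaches
#' 4/3 from below as \eqn{n} grows.
#'
#' @inheritParams alkane_stoichiometry
#' @return Numeric vector of ratios (dimensionless), one per element of `n`.
#' @examples
#' theoretical_ratio(5)   # 1.25
#' theoretical_ratio(14)  # ~1.302
#' @export
theoretical_ratio <- function(n) {
  assert_carbon_number(n)
  n / (0.75 * n + 0.25)
}

#' Predicted DIC:sulfate ratio with biomass carbon assimilation
#'
#' When a fraction `f` of the alkane carbon is assimilated into biomass
#' (mean carbon oxidation state `z`) instead of being fully oxidized, less
#' DIC is produced per electron transferred to sulfate. Electron bookkeeping
#' per mole of alkane gives
#' \deqn{r(n, f, z) = \frac{8 n (1-f)}{(1-f)(6n+2) + f(2n + 2 + z n)},}
#' which reduces to [theoretical_ratio()] at `f = 0`: each of the
#' \eqn{(1-f)n} fully oxidized carbons releases its share of the
#' \eqn{(6n+2)} alkane electrons, each assimilated carbon releases only the
#' electrons needed to reach oxidation state `z`, and all released electrons
#' are drawn to sulfate (8 per mole).
#'
#' @inheritParams alkane_stoichiometry
#' @param f Fraction of alkane carbon assimilated into biomass, in `[0, 1)`.
#' @param z Mean carbon oxidation state of biomass. The default `0`
#'   corresponds to carbohydrate-like biomass (CH2O equivalents).
#' @return Numeric vector of predicted DIC:sulfate ratios.
#' @examples
#' predicted_ratio(6, f = 0)      # equals theoretical_ratio(6)
#' predicted_ratio(6, f = 0.107)  # ~1.21, as measured in hexane cultures
#' @export
predicted_ratio <- function(n, f, z = 0) {
  assert_carbon_number(n)
  assert_fraction(f)
  8 * n * (1 - f) / ((1 - f) * (6 * n + 2) + f * (2 * n + 2 + z * n))
}

#' Infer the assimilated-carbon fraction from a measured DIC:sulfate ratio
#'
#' Inverts the forward model of [predicted_ratio()]: solving
#' \eqn{r(n, f, z) = r} for `f` gives the closed form
#' \deqn{f = \frac{r(6n+2) - 8n}{r\,n\,(4 - z) - 8n},}
#' the fraction of carbon released from alkane oxidation that is assimilated
#' into biomass rather than oxidized to DIC. Measured ratios of 1.21 (hexane)
#' and 1.09 (tetradecane) yield ~10% and ~35% assimilation at `z = 0`.
#'
#' @inheritParams predicted_ratio
#' @param r Measured DIC production to sulfate reduction ratio. Must be
#'   positive, at most [theoretical_ratio()] for this `n` (larger ratios have
#'   no physical solution), and below the singular value \eqn{8/(4-z)}
#'   (2 for `z = 0`).
#' @return A tibble with columns `n`, `r`, `z`, `f` (the inferred fraction),
#'   and `f_pct_rounded` (`f` as a percentage rounded to the nearest 5
#'   percentage points, for comparison with "around X\%" statements).
#' @examples
#' infer_assimilation(6, r = 1.21)   # ~10%
#' infer_assimilation(14, r = 1.09)  # ~35%
#' @export
infer_assimilation <- function(n, r, z = 0) {
  assert_carbon_number(n)
  if (!is.numeric(r) || any(is.na(r)) || any(r <= 0)) {
    abort("`r` must be a positive measured DIC:sulfate ratio.")
  }
  res <- tibble(n = as.numeric(n), r = r, z = z)
  singular <- 8 / (4 - res$z)
  if (any(res$r >= singular)) {
    abort("`r` at or beyond the singular ratio 8/(4 - z): no finite solution.")
  }
  rmax <- theoretical_ratio(res$n)
  if (any(res$r > rmax + 1e-12)) {
    abort("ratio exceeds complete-oxidation maximum: no non-negative assimilated fraction exists.")
  }
  f <- (res$r * (6 * res$n + 2) - 8 * res$n) / (res$r * res$n * (4 - res$z) - 8 * res$n)
  # clamp the tiny negative round-off when r equals the theoretical ratio
  f[f < 0 & f > -1e-12] <- 0
  res$f <- f
  res$f_pct_rounded <- 5 * round(100 * f / 5)
  res
}

#' Measured DIC:sulfate ratio from culture trajectories
#'
#' Estimates the ratio of DIC produced to sulfate reduced per replicate,
#' optionally corrected with an abiotic control.
#'
#' With `method = "endpoint"` (default) the ratio uses first-to-last
#' differences: \eqn{(\Delta DIC - \Delta DIC_{ctrl}) /
#' (-\Delta SO_4 + \Delta SO_{4,ctrl})}. With `method = "regression"` the
#' whole trajectory is used instead of the two endpoints: when a
#' `sulfide_mM` column is present, DIC and sulfate are each regressed on
#' sulfide (the common reaction-progress variable) and the ratio is the
#' negated quotient of the two slopes — because both regressions share the
#' same predictor, errors-in-variables attenuation cancels in the quotient;
#' without sulfide, the ratio is the through-origin least-squares slope of
#' produced DIC on consumed sulfate. The regression estimator is markedly
#' less sensitive to measurement noise than the endpoint differences.
#'
#' @param series Culture time series: a data frame with columns `time_d`,
#'   `replicate`, `dic_mM`, `sulfate_mM` (plus any others); at least two time
#'   points per replicate.
#' @param control Optional matched abiotic control series with the same
#'   columns. Control corrections use its replicate-averaged trajectory.
#' @param method `"endpoint"` or `"regression"` (see Details).
#' @return A tibble of class `ratio_measurement`, one row per replicate with
#'   columns `replicate`, `delta_dic`, `delta_sulfate` (endpoint changes, mM)
#'   and `ratio`. Summary statistics are available via [glance()].
#' @examples
#' ts <- tibble::tibble(
#'   time_d = c(0, 30), replicate = "a",
#'   dic_mM = c(10, 20), sulfate_mM = c(20, 12)
#' )
#' measured_ratio(ts)           # ratio 1.25
#' glance(measured_ratio(ts))   # mean, sd, n_replicates
#' @export
measured_ratio <- function(series, control = NULL, method = c("endpoint", "regression")) {
  method <- match.arg(method)
  assert_culture_series(series, require = c("dic_mM", "sulfate_mM"))
  counts <- dplyr::count(series, .data$replicate)
  if (any(counts$n < 2)) {
    abort("each replicate needs at least two time points with DIC and sulfate values.")
  }

  # control trajectory averaged over control replicates, on the control's grid
  ctrl_fun <- function(col) function(t) rep(0, length(t))
  if (!is.null(control)) {
    assert_culture_series(control, require = c("dic_mM", "sulfate_mM"))
    ctrl <- control |>
      dplyr::group_by(.data$time_d) |>
      dplyr::summarise(
        dic_mM = mean(.data$dic_mM),
        sulfate_mM = mean(.data$sulfate_mM),
        .groups = "drop"
      )
    ctrl_fun <- function(col) {
      function(t) {
        stats::approx(ctrl$time_d, ctrl[[col]] - ctrl[[col]][1], xout = t, rule = 2)$y
      }
    }
  }
  ctrl_ddic <- ctrl_fun("dic_mM")
  ctrl_dsulf <- ctrl_fun("sulfate_mM")

  per_rep <- series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$time_d, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      t0 <- d$time_d[1]
      t1 <- d$time_d[nrow(d)]
      ddic <- d$dic_mM[nrow(d)] - d$dic_mM[1] - (ctrl_ddic(t1) - ctrl_ddic(t0))
      dsulf <- d$sulfate_mM[nrow(d)] - d$sulfate_mM[1] - (ctrl_dsulf(t1) - ctrl_dsulf(t0))
      ratio <- if (method == "endpoint") {
        ddic / (-dsulf)
      } else if ("sulfide_mM" %in% names(d)) {
        dic_c <- d$dic_mM - (ctrl_ddic(d$time_d) - ctrl_ddic(t0))
        sulf_c <- d$sulfate_mM - (ctrl_dsulf(d$time_d) - ctrl_dsulf(t0))
        b_dic <- unname(coef(lm(dic_c ~ d$sulfide_mM))[2])
        b_sulf <- unname(coef(lm(sulf_c ~ d$sulfide_mM))[2])
        -b_dic / b_sulf
      } else {
        produced <- d$dic_mM - d$dic_mM[1] - (ctrl_ddic(d$time_d) - ctrl_ddic(t0))
        consumed <- -(d$sulfate_mM - d$sulfate_mM[1]) + (ctrl_dsulf(d$time_d) - ctrl_dsulf(t0))
        unname(coef(lm(produced ~ 0 + consumed))[1])
      }
      tibble(delta_dic = ddic, delta_sulfate = dsulf, ratio = ratio)
    }) |>
    dplyr::ungroup()
  if (any(per_rep$delta_sulfate >= 0)) {
    abort("no net sulfate reduction: sulfate did not decrease over the series.")
  }
  structure(per_rep, class = c("ratio_measurement", class(per_rep)))
}

#' @describeIn measured_ratio One-row summary: `mean_ratio`, `sd_ratio`
#'   (sample sd; `NA` for a single replicate) and `n_replicates`.
#' @param x A `ratio_measurement` object.
#' @param ... Unused.
#' @method glance ratio_measurement
#' @export
glance.ratio_measurement <- function(x, ...) {
  tibble(
    mean_ratio = mean(x$ratio),
    sd_ratio = if (nrow(x) > 1) sd(x$ratio) else NA_real_,
    n_replicates = nrow(x)
  )
}

#' Hydrogen equivalent of a sulfate-reduction load
#'
#' If hydrogen were the sole electron carrier between the alkane oxidizer
#' and the sulfate reducer, each mole of sulfate reduced (8 electrons) would
#' require 4 moles of H2 (2 electrons each). `hydrogen_equivalent()` returns
#' that expected H2 amount; `hydrogen_fraction()` expresses a measured H2
#' amount as a percentage of it, the quantity used to argue that hydrogen is
#' not the main electron carrier when the fraction is small.
#'
#' @param sulfate_reduced Non-negative amount of sulfate reduced (mM).
#' @return `hydrogen_equivalent()`: mM H2 (4 x sulfate reduced).
#' @examples
#' hydrogen_equivalent(2)        # 8 mM
#' hydrogen_fraction(0.2, 2)     # 2.5 (%)
#' @export
hydrogen_equivalent <- function(sulfate_reduced) {
  if (!is.numeric(sulfate_reduced) || any(is.na(sulfate_reduced)) || any(sulfate_reduced < 0)) {
    abort("`sulfate_reduced` must be non-negative (mM).")
  }
  4 * sulfate_reduced
}

#' @rdname hydrogen_equivalent
#' @param h2_measured Measured H2 (mM).
#' @return `hydrogen_fraction()`: measured H2 as a percentage of the
#'   hydrogen-sole-carrier expectation.
#' @export
hydrogen_fraction <- function(h2_measured, sulfate_reduced) {
  expected <- hydrogen_equivalent(sulfate_reduced)
  if (any(expected == 0)) {
    abort("expected H2 is zero; fraction undefined.")
  }
  100 * h2_measured / expected
}
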