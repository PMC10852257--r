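# Zone-structured synthetic climate-yield generator.
#
# Each attribute is drawn independently from a truncated normal whose
# *post-truncation* mean and sd equal the zone profile's values: the parent
# (mu, sigma) are solved numerically so that truncation at the physical
# bounds (RR, Sun, ET, Yield >= 0; humidities in [0, 100]) does not shift
# the stated moments. Dependence between attributes enters only through
# plant_rule().

# Moments of N(mu, sigma) truncated to [lower, upper].
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a)
  pb <- stats::dnorm(b)
  apa <- ifelse(is.finite(a), a * pa, 0)
  bpb <- ifelse(is.finite(b), b * pb, 0)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Parent (mu, sigma) whose [lower, upper]-truncated normal has the target
# mean and sd. Identity when the bounds are > 8 sigma away.
match_truncnorm <- function(mean, sd, lower, upper) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  if (a < -8 && b > 8) return(c(mu = mean, sigma = sd))
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (mom[1] - mean)^2 / sd^2 + (mom[2] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-6) {
    rlang::warn(paste0("could not match truncated-normal moments (mean ", mean,
                       ", sd ", sd, ", bounds [", lower, ", ", upper,
                       "]); using unmatched parameters"))
    return(c(mu = mean, sigma = sd))
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF sampler for N(mu, sigma) truncated to [lower, upper].
rtruncnorm <- function(n, mu, sigma, lower = -Inf, upper = Inf) {
  if (sigma == 0) return(rep(min(max(mu, lower), upper), n))
  plo <- stats::pnorm(lower, mu, sigma)
  phi <- stats::pnorm(upper, mu, sigma)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sigma)
}

sample_attribute <- function(n, mean, sd, lower, upper) {
  par <- match_truncnorm(mean, sd, lower, upper)
  rtruncnorm(n, par[["mu"]], par[["sigma"]], lower, upper)
}

zone_seeds <- function(seed, zones) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(zones)), zones)
}

profile_rows <- function(profile, zone) {
  rows <- profile[profile$zone == zone, , drop = FALSE]
  stats::setNames(split(rows, seq_len(nrow(rows))), rows$attribute)
}

#' Generate synthetic monthly climate-yield records
#'
#' Emulates per-zone station-month data: 12 records per year per zone, each
#' attribute drawn from a truncated normal matching the profile's mean and
#' sd. Attributes are mutually independent except minimum humidity, which by
#' default is generated as `0.9 * Umax + noise` so that the downstream
#' correlation filter has a redundant predictor to drop.
#'
#' @param profile Profile tibble (`zone`, `attribute`, `mean`, `sd`), e.g.
#'   from [profile_from_thresholds()]. May cover several zones.
#' @param start_year,end_year Inclusive year span.
#' @param seed Master integer seed; per-zone streams are derived from it, so
#'   identical inputs give identical output.
#' @param umin `"correlated"` (default): `Umin = 0.9 Umax + N(0, umin_sd)`,
#'   clamped to `[0, Umax]`; `"profile"`: drawn independently from the
#'   profile's own `Umin` row (which must then exist).
#' @param umin_sd Noise sd for the correlated Umin mechanism, in percent.
#' @return Tibble with one row per zone-month: `zone`, `year`, `month`,
#'   `Tmin`, `Tmax`, `Umin`, `Umax`, `RR`, `Sun`, `ET` and, when the profile
#'   has a `Yield` row, `yield_kg_ha`.
#' @examples
#' prof <- profile_from_thresholds(benin_thresholds())
#' rec <- generate_monthly_records(prof, 2000, 2001, seed = 1)
#' @export
generate_monthly_records <- function(profile, start_year, end_year, seed,
                                     umin = c("correlated", "profile"),
                                     umin_sd = 2) {
  umin <- match.arg(umin)
  if (start_year > end_year) rlang::abort("start_year must be <= end_year")
  zones <- unique(profile$zone)
  seeds <- zone_seeds(seed, zones)
  n <- 12L * (end_year - start_year + 1L)
  grid <- tidyr::expand_grid(year = start_year:end_year, month = 1:12)

  purrr::map(zones, function(z) {
    set.seed(seeds[[z]])
    rows <- profile_rows(profile, z)
    out <- dplyr::mutate(grid, zone = z, .before = 1)
    gen_attrs <- c("Tmin", "Tmax", "Umax", "RR", "Sun", "ET",
                   if (umin == "profile") "Umin", if ("Yield" %in% names(rows)) "Yield")
    for (attr in gen_attrs) {
      if (is.null(rows[[attr]])) {
        rlang::abort(paste0("profile for zone ", z, " lacks attribute ", attr))
      }
      bounds <- attribute_bounds(attr)
      out[[attribute_column(attr)]] <-
        sample_attribute(n, rows[[attr]]$mean, rows[[attr]]$sd,
                         bounds$lower, bounds$upper)
    }
    if (umin == "correlated") {
      out$Umin <- pmin(pmax(0.9 * out$Umax + stats::rnorm(n, 0, umin_sd), 0), out$Umax)
    }
    cols <- c("zone", "year", "month", "Tmin", "Tmax", "Umin", "Umax",
              "RR", "Sun", "ET", intersect("yield_kg_ha", names(out)))
    out[cols]
  }) |>
    dplyr::bind_rows()
}

#' Generate synthetic daily climate records
#'
#' One row per calendar day per zone, drawn from the same moment-matched
#' truncated normals as [generate_monthly_records()]. Intended to exercise
#' the daily-to-monthly aggregation path; day-to-day values are independent
#' (no weather autocorrelation), so monthly means of this output are less
#' dispersed than the profile sd.
#'
#' @inheritParams generate_monthly_records
#' @return Tibble: `zone`, `date`, `Tmin`, `Tmax`, `Umin`, `Umax`, `RR`,
#'   `Sun`, `ET`.
#' @export
generate_daily_records <- function(profile, start_year, end_year, seed,
                                   umin = c("correlated", "profile"),
                                   umin_sd = 2) {
  umin <- match.arg(umin)
  if (start_year > end_year) rlang::abort("start_year must be <= end_year")
  zones <- unique(profile$zone)
  seeds <- zone_seeds(seed, zones)
  dates <- seq(as.Date(paste0(start_year, "-01-01")),
               as.Date(paste0(end_year, "-12-31")), by = "day")
  n <- length(dates)

  purrr::map(zones, function(z) {
    set.seed(seeds[[z]] %% (.Machine$integer.max - 1L) + 1L)
    rows <- profile_rows(profile, z)
    out <- tibble::tibble(zone = z, date = dates)
    gen_attrs <- c("Tmin", "Tmax", "Umax", "RR", "Sun", "ET",
                   if (umin == "profile") "Umin")
    for (attr in gen_attrs) {
      if (is.null(rows[[attr]])) {
        rlang::abort(paste0("profile for zone ", z, " lacks attribute ", attr))
      }
      bounds <- attribute_bounds(attr)
      out[[attr]] <- sample_attribute(n, rows[[attr]]$mean, rows[[attr]]$sd,
                                      bounds$lower, bounds$upper)
    }
    if (umin == "correlated") {
      out$Umin <- pmin(pmax(0.9 * out$Umax + stats::rnorm(n, 0, umin_sd), 0), out$Umax)
    }
    out[c("zone", "date", "Tmin", "Tmax", "Umin", "Umax", "RR", "Sun", "ET")]
  }) |>
    dplyr::bind_rows()
}

#' Generate synthetic annual yields
#'
#' Annual yield is 12 x a monthly-scale draw, so that disaggregation by
#' [attach_monthly_yield()] (annual / 12) returns values on the profile's
#' monthly scale.
#'
#' @inheritParams generate_monthly_records
#' @return Tibble: `zone`, `year`, `annual_yield_kg_ha`.
#' @export
generate_annual_yields <- function(profile, start_year, end_year, seed) {
  zones <- unique(profile$zone)
  seeds <- zone_seeds(seed + 1L, zones)
  years <- start_year:end_year
  purrr::map(zones, function(z) {
    set.seed(seeds[[z]])
    rows <- profile_rows(profile, z)
    if (is.null(rows[["Yield"]])) {
      rlang::abort(paste0("profile for zone ", z, " lacks attribute Yield"))
    }
    monthly <- sample_attribute(length(years), rows[["Yield"]]$mean,
                                rows[["Yield"]]$sd, 0, Inf)
    tibble::tibble(zone = z, year = years, annual_yield_kg_ha = 12 * monthly)
  }) |>
    dplyr::bind_rows()
}

parse_items <- function(items) {
  parts <- strsplit(items, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    rlang::abort(paste0("malformed item(s): ", paste(items[bad], collapse = ", "),
                        " (expected \"attribute=category\")"))
  }
  out <- tibble::tibble(item = items,
                        attribute = purrr::map_chr(parts, 1),
                        category = purrr::map_chr(parts, 2))
  bad_cat <- !out$category %in% c("low", "medium", "high")
  if (any(bad_cat)) {
    rlang::abort(paste0("unknown category in item(s): ",
                        paste(items[bad_cat], collapse = ", ")))
  }
  out
}

# Numeric band of a category, intersected with the attribute's physical range.
category_band <- function(attribute, category, low_cut, high_cut) {
  b <- attribute_bounds(attribute)
  switch(category,
    low = c(b$lower, low_cut),
    medium = c(low_cut, high_cut),
    high = c(high_cut, b$upper)
  )
}

# Sample values inside a category band: the zone's N(mean, sd) conditioned
# on the band, i.e. plain truncation (no moment matching — a narrow band
# cannot carry the full-distribution moments).
sample_in_band <- function(n, mean, sd, band) {
  if (band[1] > band[2] || (band[1] == band[2] && n > 0)) {
    rlang::abort("empty or zero-width category band; rule infeasible")
  }
  # guard open endpoints: nudge strictly inside by a relative epsilon
  eps <- 1e-9 * max(1, abs(band[is.finite(band)]), na.rm = TRUE)
  lo <- if (is.finite(band[1])) band[1] + eps else band[1]
  hi <- if (is.finite(band[2])) band[2] - eps else band[2]
  rtruncnorm(n, mean, sd, lo, hi)
}

sample_out_of_band <- function(n, attribute, category, mean, sd, low_cut, high_cut) {
  others <- setdiff(c("low", "medium", "high"), category)
  bands <- lapply(others, category_band, attribute = attribute,
                  low_cut = low_cut, high_cut = high_cut)
  mass <- vapply(bands, function(b) {
    max(stats::pnorm(b[2], mean, sd) - stats::pnorm(b[1], mean, sd), 0)
  }, numeric(1))
  ok <- vapply(bands, function(b) b[2] > b[1], logical(1))
  if (!any(ok)) rlang::abort("no alternative category band available")
  mass[!ok] <- 0
  if (sum(mass) == 0) mass[ok] <- 1
  pick <- sample(seq_along(bands), n, replace = TRUE, prob = mass)
  vapply(seq_len(n), function(i) {
    sample_in_band(1, mean, sd, bands[[pick[i]]])
  }, numeric(1))
}

#' Plant an association rule into synthetic records
#'
#' Rewrites attribute values of a single zone's records so that, after
#' discretization with `thresholds`, the itemset antecedent u {consequent}
#' occurs in exactly `ceiling(target_support * n)` records and, among records
#' containing the whole antecedent, the fraction also containing the
#' consequent equals `target_confidence` to within 1/n. Values are sampled
#' inside (or outside) the category's numeric band, so marginal
#' distributions stay close to the zone profile.
#'
#' @param records Monthly records of one zone.
#' @param antecedent Character vector of items `"attribute=category"`,
#'   nonempty, attributes distinct from the consequent's.
#' @param consequent Single item, default `"Yield=high"`.
#' @param target_support Desired support of antecedent u consequent, in (0, 1].
#' @param target_confidence Desired confidence, in (0, 1]; must be >=
#'   `target_support` and representable as k/m with m <= n to within 1/n,
#'   otherwise an infeasibility error is raised.
#' @param thresholds Threshold table covering the zone.
#' @param seed Integer seed for record selection and band sampling.
#' @return The records tibble with rewritten values, same rows and order.
#' @export
plant_rule <- function(records, antecedent, consequent = "Yield=high",
                       target_support, target_confidence, thresholds, seed) {
  zone <- unique(records$zone)
  if (length(zone) != 1) rlang::abort("plant_rule() operates on a single zone")
  if (length(antecedent) < 1) rlang::abort("antecedent must be nonempty")
  if (target_support > target_confidence) {
    rlang::abort("infeasible: target_support must be <= target_confidence")
  }
  items <- parse_items(c(antecedent, consequent))
  if (anyDuplicated(items$attribute)) {
    rlang::abort("antecedent/consequent attributes must be distinct")
  }
  th <- thresholds[thresholds$zone == zone, , drop = FALSE]
  validate_thresholds(th)
  missing_attr <- setdiff(items$attribute, th$attribute)
  if (length(missing_attr) > 0) {
    rlang::abort(paste0("thresholds for zone ", zone, " lack attribute(s): ",
                        paste(missing_attr, collapse = ", ")))
  }
  prof <- profile_from_thresholds(th)

  n <- nrow(records)
  k <- as.integer(ceiling(target_support * n))
  if (k < 1 || k > n) rlang::abort("infeasible target_support for this record count")
  m_cand <- k:n
  err <- abs(k / m_cand - target_confidence)
  m <- m_cand[which.min(err)]
  if (min(err) > 1 / n + 1e-12) {
    rlang::abort(paste0("infeasible: no antecedent count m in [", k, ", ", n,
                        "] puts confidence k/m within 1/n of ", target_confidence))
  }

  set.seed(seed)
  chosen <- sample.int(n, m)           # records that will carry the antecedent
  with_conseq <- chosen[seq_len(k)]    # ... of which these also carry the consequent
  without_conseq <- setdiff(chosen, with_conseq)
  outside <- setdiff(seq_len(n), chosen)

  lookup <- function(attr) {
    list(cut = th[th$attribute == attr, , drop = FALSE],
         prof = prof[prof$attribute == attr, , drop = FALSE])
  }
  set_in <- function(rows, attr, cat) {
    if (length(rows) == 0) return(invisible())
    L <- lookup(attr)
    band <- category_band(attr, cat, L$cut$low_cut, L$cut$high_cut)
    records[[attribute_column(attr)]][rows] <<-
      sample_in_band(length(rows), L$prof$mean, L$prof$sd, band)
  }
  set_out <- function(rows, attr, cat) {
    if (length(rows) == 0) return(invisible())
    L <- lookup(attr)
    records[[attribute_column(attr)]][rows] <<-
      sample_out_of_band(length(rows), attr, cat, L$prof$mean, L$prof$sd,
                         L$cut$low_cut, L$cut$high_cut)
  }

  ante <- items[items$item %in% antecedent, , drop = FALSE]
  cons <- items[items$item == consequent, , drop = FALSE]
  for (i in seq_len(nrow(ante))) {
    set_in(chosen, ante$attribute[i], ante$category[i])
  }
  set_in(with_conseq, cons$attribute, cons$category)
  set_out(without_conseq, cons$attribute, cons$category)

  # Outside the chosen set the full antecedent must not occur: knock the
  # first antecedent attribute out of its planted category wherever it lands
  # in it by chance.
  L1 <- lookup(ante$attribute[1])
  col1 <- attribute_column(ante$attribute[1])
  cats <- discretize(records[[col1]][outside], L1$cut$low_cut, L1$cut$high_cut)
  clash <- outside[cats == ante$category[1]]
  set_out(clash, ante$attribute[1], ante$category[1])

  records
}
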