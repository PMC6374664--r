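#' Estimated catch biomass from a subsample count
#'
#' Converts a nightly drift-net count to grams of catch biomass:
#' count x individual dry mass (mg), scaled up by the inverse subsample
#' fraction and converted to grams. Taxa counted in full on site (e.g.
#' larval sturgeon) use `subsample_fraction = 1`.
#'
#' @param count nonnegative counts.
#' @param dry_mass_mg individual dry mass in mg (> 0).
#' @param subsample_fraction fraction of the cod-end contents counted,
#'   in (0, 1]; the survey default is 0.05.
#' @return estimated catch biomass in grams (vectorized).
#' @export
estimate_catch_biomass <- function(count, dry_mass_mg,
                                   subsample_fraction = 0.05) {
  if (any(subsample_fraction <= 0) || any(subsample_fraction > 1)) {
    stop("`subsample_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (any(count < 0) || any(dry_mass_mg <= 0)) {
    stop("counts must be nonnegative and dry masses positive", call. = FALSE)
  }
  count * dry_mass_mg / subsample_fraction / 1000
}

#' Aggregate per-family biomass to ESU level
#'
#' Sums member-family catch biomass within each (night, ESU); total
#' biomass per night is conserved.
#'
#' @param survey data.frame with `night`, `family`, `esu`, and either
#'   `biomass_g` (grams passthrough) or `count` +
#'   `individual_dry_mass_mg` + `subsample_fraction` (counts mode, see
#'   [estimate_catch_biomass()]). A `period` column, if present, is
#'   carried through.
#' @return data.frame with `night`, (`period`,) `esu`, `biomass_g`.
#' @export
aggregate_biomass_to_esu <- function(survey) {
  if (any(is.na(survey$esu) | survey$esu == "")) {
    bad <- unique(survey$family[is.na(survey$esu) | survey$esu == ""])
    stop("families without an ESU mapping: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"biomass_g" %in% names(survey)) {
    survey$biomass_g <- estimate_catch_biomass(survey$count,
                                               survey$individual_dry_mass_mg,
                                               survey$subsample_fraction)
  }
  keys <- c("night", if ("period" %in% names(survey)) "period", "esu")
  out <- stats::aggregate(survey["biomass_g"], survey[keys], sum)
  out <- out[order(out$night, out$esu), c(keys, "biomass_g")]
  rownames(out) <- NULL
  out
}

#' Per-period mean nightly catch biomass
#'
#' Arithmetic mean of the nightly ESU biomass across the nights of each
#' period (one value per night, averaged within period).
#'
#' @param esu_nightly data.frame from [aggregate_biomass_to_esu()] with
#'   a `period` column.
#' @return data.frame with `period`, `esu`, `mean_biomass_g`.
#' @export
period_average_biomass <- function(esu_nightly) {
  stopifnot(all(c("night", "period", "esu", "biomass_g") %in% names(esu_nightly)))
  if (nrow(esu_nightly) == 0) stop("empty survey", call. = FALSE)
  # a night with no record for an ESU is a zero catch, not a missing
  # value: complete the (night, esu) grid before averaging
  grid <- expand.grid(night = unique(esu_nightly$night),
                      esu = unique(esu_nightly$esu),
                      stringsAsFactors = FALSE)
  grid$period <- esu_nightly$period[match(grid$night, esu_nightly$night)]
  m <- merge(grid, esu_nightly, all.x = TRUE)
  m$biomass_g[is.na(m$biomass_g)] <- 0
  out <- stats::aggregate(list(mean_biomass_g = m$biomass_g),
                          m[c("period", "esu")], mean)
  out <- out[order(out$period, out$esu), ]
  rownames(out) <- NULL
  out
}

#' Availability proportions from an ESU biomass vector
#'
#' Normalizes a biomass vector over the surveyed ESUs to availability
#' proportions n_i for the selectivity indices. ESUs with zero measured
#' biomass are floored at `zero_floor` of the total before
#' normalization, so selection indices stay finite for prey that were
#' eaten on nights when the survey caught none of them; floored entries
#' are flagged.
#'
#' @param biomass named nonnegative vector of ESU biomass (grams) for
#'   one night or period; at least one entry must be positive.
#' @param zero_floor floor for zero entries, as a fraction of total
#'   biomass (default 0.001).
#' @return named proportion vector summing to 1, with attributes `m`
#'   (number of ESUs) and `floored` (logical vector).
#' @export
availability_proportions <- function(biomass, zero_floor = 0.001) {
  if (any(biomass < 0)) stop("biomass must be nonnegative", call. = FALSE)
  total <- sum(biomass)
  if (total == 0) stop("all-zero biomass vector", call. = FALSE)
  floored <- biomass == 0
  x <- biomass
  x[floored] <- zero_floor * total
  n <- x / sum(x)
  attr(n, "m") <- length(n)
  attr(n, "floored") <- floored
  n
}

#' Read a drift-survey table
#'
#' Reads a TSV shaped like the packaged drift survey: one row per
#' (night, family) with `night`, `period`, `family`, `esu`,
#' `individual_dry_mass_mg`, and either `biomass_g` (mode "grams") or
#' `count` + `subsample_fraction` (mode "counts").
#'
#' @param path TSV path.
#' @param mode "grams" (nightly biomass already estimated) or "counts"
#'   (convert via [estimate_catch_biomass()]).
#' @return data.frame of class `drift_survey`.
#' @export
read_drift_survey <- function(path, mode = c("grams", "counts")) {
  mode <- match.arg(mode)
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("night", "family", "esu",
            if (mode == "grams") "biomass_g" else c("count", "subsample_fraction",
                                                    "individual_dry_mass_mg"))
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("drift table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "counts") {
    x$biomass_g <- estimate_catch_biomass(x$count, x$individual_dry_mass_mg,
                                          x$subsample_fraction)
  }
  class(x) <- c("drift_survey", "data.frame")
  x
}
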