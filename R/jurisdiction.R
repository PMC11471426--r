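# Jurisdiction-level summaries: presence calls, species turnover, and
# elevation-shift tests within state boundaries.

jurisdiction_counts <- function(map, jurisdictions) {
  stopifnot(inherits(map, "binary_niche_map"),
            inherits(jurisdictions, "jurisdiction_set"))
  if (!identical(dim(map$mask), dim(jurisdictions$assignment))) {
    stop("jurisdictions do not tile this map's grid")
  }
  counts <- tabulate(jurisdictions$assignment[map$mask], nbins = jurisdictions$n)
  stats::setNames(counts, jurisdictions$ids)
}

#' Per-jurisdiction presence from a binary niche map
#'
#' A species is present in a jurisdiction when strictly more than
#' `min_pixels` suitable cells fall inside it (default 50).
#'
#' @param map a `binary_niche_map`.
#' @param jurisdictions a `jurisdiction_set` tiling the same grid.
#' @param min_pixels presence threshold (strict >).
#' @return data.frame: jurisdiction, pixels, present.
#' @export
state_presence <- function(map, jurisdictions, min_pixels = 50) {
  counts <- jurisdiction_counts(map, jurisdictions)
  data.frame(jurisdiction = jurisdictions$ids, pixels = as.integer(counts),
             present = counts > min_pixels, row.names = NULL)
}

#' Species gained, lost and maintained per jurisdiction
#'
#' Compares presence calls between two scenarios for a set of species:
#' maintained = present in both, lost = present only in the recent scenario,
#' gained = present only in the future one, absent = neither.
#'
#' @param recent_maps,future_maps named lists of `binary_niche_map`s (same
#'   species in each).
#' @param jurisdictions a `jurisdiction_set`.
#' @param min_pixels presence threshold (strict >).
#' @return data.frame: species, jurisdiction, pixels_recent, pixels_future,
#'   pct_change (within-state percent change in suitable area, from the
#'   unrounded ratio, NA where the species had no recent pixels), and
#'   status in {gained, lost, maintained, absent}.
#' @export
state_turnover <- function(recent_maps, future_maps, jurisdictions,
                           min_pixels = 50) {
  rs <- vapply(recent_maps, `[[`, "", "species_id")
  fs <- vapply(future_maps, `[[`, "", "species_id")
  if (!identical(sort(rs), sort(fs))) stop("species sets differ between scenarios")
  future_maps <- future_maps[match(rs, fs)]
  rows <- list()
  for (i in seq_along(recent_maps)) {
    cr <- jurisdiction_counts(recent_maps[[i]], jurisdictions)
    cf <- jurisdiction_counts(future_maps[[i]], jurisdictions)
    pr <- cr > min_pixels; pf <- cf > min_pixels
    status <- ifelse(pr & pf, "maintained",
              ifelse(pr & !pf, "lost",
              ifelse(!pr & pf, "gained", "absent")))
    pct <- ifelse(cr > 0, 100 * (cf - cr) / cr, NA_real_)
    rows[[i]] <- data.frame(species = rs[i], jurisdiction = jurisdictions$ids,
                            pixels_recent = as.integer(cr),
                            pixels_future = as.integer(cf),
                            pct_change = pct,
                            status = status, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Elevation shift of a species' niche within a jurisdiction
#'
#' Compares the elevation distribution of suitable cells inside the
#' jurisdiction between two scenarios using the interquartile overlap rule:
#' disjoint \[q25, q75\] intervals with the future interval higher mean a
#' significant `increase`, disjoint and lower a `decrease`, overlapping
#' intervals are `similar`. Quantiles use the linear-interpolation
#' convention. The median change is q50(future) - q50(recent) in meters.
#'
#' @param recent_map,future_map `binary_niche_map`s of one species.
#' @param jurisdictions a `jurisdiction_set`.
#' @param jurisdiction_id which jurisdiction to test.
#' @param dem elevation matrix (m) on the same grid.
#' @return list: class ("increase", "decrease", "similar" or
#'   "not_comparable"), median_change_m, and the per-scenario q25/q50/q75.
#' @export
elevation_shift <- function(recent_map, future_map, jurisdictions,
                            jurisdiction_id, dem) {
  j <- match(jurisdiction_id, jurisdictions$ids)
  if (is.na(j)) stop("unknown jurisdiction: ", jurisdiction_id)
  inside <- jurisdictions$assignment == j
  er <- dem[recent_map$mask & inside]
  ef <- dem[future_map$mask & inside]
  if (!length(er) || !length(ef)) {
    return(list(class = "not_comparable", median_change_m = NA_real_,
                recent = c(q25 = NA, q50 = NA, q75 = NA),
                future = c(q25 = NA, q50 = NA, q75 = NA)))
  }
  qr <- stats::quantile(er, c(0.25, 0.5, 0.75), names = FALSE)
  qf <- stats::quantile(ef, c(0.25, 0.5, 0.75), names = FALSE)
  cls <- if (qf[1] > qr[3]) "increase" else if (qf[3] < qr[1]) "decrease" else "similar"
  list(class = cls, median_change_m = qf[2] - qr[2],
       recent = c(q25 = qr[1], q50 = qr[2], q75 = qr[3]),
       future = c(q25 = qf[1], q50 = qf[2], q75 = qf[3]))
}
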