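#' Remove records with large coordinate uncertainty
#'
#' Records whose stated coordinate uncertainty exceeds `max_km` are
#' removed; the boundary value is kept (strictly-greater-than rule).
#' Records with no stated uncertainty are retained by default.
#'
#' @param occ an `occurrence_df`.
#' @param max_km uncertainty cutoff in kilometres (default 10).
#' @param keep_missing retain records with missing uncertainty (default
#'   `TRUE`).
#' @return Filtered `occurrence_df`.
#' @export
filter_uncertainty <- function(occ, max_km = 10, keep_missing = TRUE) {
  stopifnot(max_km > 0)
  u <- occ$uncertainty_m
  keep <- ifelse(is.na(u), keep_missing, u <= max_km * 1000)
  occ[keep, , drop = FALSE]
}

#' Collapse duplicate records at a locality
#'
#' Keeps exactly one record per unique (taxon, lon, lat) after rounding
#' coordinates to 1e-4 degrees (~11 m); within a duplicate set the record
#' with the earliest event date is kept (dateless records sort last).
#'
#' @param occ an `occurrence_df`.
#' @return Deduplicated `occurrence_df`.
#' @export
dedupe_localities <- function(occ) {
  if (nrow(occ) == 0L) return(occ)
  key <- paste(occ$taxon, round(occ$lon, 4), round(occ$lat, 4), sep = "|")
  d <- occ$event_date
  ord <- order(key, ifelse(is.na(d), Inf, as.numeric(d)))
  occ <- occ[ord, , drop = FALSE]
  res <- occ[!duplicated(key[ord]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restrict records to each taxon's breeding window
#'
#' Migratory taxa are filtered to the calendar months of their breeding
#' season — typically April–July in the Northern Hemisphere and
#' October–January in the Southern Hemisphere (the latter wraps the year
#' boundary). Residents are left unfiltered. Dateless records are dropped
#' for migratory taxa and kept for residents by default.
#'
#' @param occ an `occurrence_df`.
#' @param windows named list mapping each taxon to either the string
#'   `"resident"` or an integer vector of months (1–12). Helpers
#'   [breeding_window_north()] and [breeding_window_south()] give the two
#'   standard windows.
#' @param keep_dateless_residents keep dateless records of residents
#'   (default `TRUE`).
#' @return Filtered `occurrence_df`.
#' @export
filter_breeding_window <- function(occ, windows,
                                   keep_dateless_residents = TRUE) {
  if (nrow(occ) == 0L) return(occ)
  missing <- setdiff(unique(occ$taxon), names(windows))
  if (length(missing))
    stop("no breeding window assigned for taxon/taxa: ",
         paste(missing, collapse = ", "))
  keep <- logical(nrow(occ))
  mo <- as.integer(format(occ$event_date, "%m"))
  for (tx in unique(occ$taxon)) {
    sel <- occ$taxon == tx
    w <- windows[[tx]]
    if (identical(w, "resident")) {
      keep[sel] <- !is.na(mo[sel]) | keep_dateless_residents
    } else {
      keep[sel] <- !is.na(mo[sel]) & mo[sel] %in% as.integer(w)
    }
  }
  occ[keep, , drop = FALSE]
}

#' @rdname filter_breeding_window
#' @export
breeding_window_north <- function() 4:7

#' @rdname filter_breeding_window
#' @export
breeding_window_south <- function() c(10:12, 1)

#' Clip records to a taxon's accessible area
#'
#' Removes records falling outside the M polygon (boundary points are
#' kept). Records of other taxa are untouched.
#'
#' @param occ an `occurrence_df`.
#' @param area an [accessible_area]; applied to records of `area$taxon`,
#'   or to all records when `all_taxa = TRUE`.
#' @param all_taxa clip every record regardless of taxon (default `FALSE`).
#' @return Clipped `occurrence_df`; the removed count is attached as
#'   attribute `n_removed`.
#' @export
clip_to_m <- function(occ, area, all_taxa = FALSE) {
  sel <- if (all_taxa) rep(TRUE, nrow(occ)) else occ$taxon == area$taxon
  if (!any(sel)) {
    attr(occ, "n_removed") <- 0L
    return(occ)
  }
  inside <- point_in_area(area, cbind(occ$lon[sel], occ$lat[sel]))
  drop_idx <- which(sel)[!inside]
  res <- if (length(drop_idx)) occ[-drop_idx, , drop = FALSE] else occ
  rownames(res) <- NULL
  attr(res, "n_removed") <- length(drop_idx)
  res
}

#' Haversine great-circle distance in kilometres
#' @param p,q two-column lon/lat matrices (recycled pairwise by geosphere).
#' @return Distances in km (Earth radius 6371 km).
#' @export
dist_km <- function(p, q) {
  geosphere::distHaversine(p, q, r = 6371) # r in km -> result in km
}

#' Spatially thin occurrence records
#'
#' Greedy thinning: records are visited in a seed-shuffled order and a
#' record is accepted iff it lies at least `min_km` (great-circle) from
#' every record already accepted. The retained set therefore satisfies the
#' pairwise distance constraint exactly and is reproducible given the
#' seed. Thinning reduces spatial autocorrelation and the over-weighting
#' of heavily birded sites.
#'
#' @param occ an `occurrence_df` (thin each taxon separately if it holds
#'   several taxa).
#' @param min_km minimum pairwise distance in kilometres.
#' @param seed integer seed controlling the visiting order.
#' @return Thinned `occurrence_df`.
#' @export
thin_spatial <- function(occ, min_km, seed = 1L) {
  stopifnot(min_km > 0)
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  ord <- with_seed_if(seed, sample.int(n))
  pts <- cbind(occ$lon, occ$lat)[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept) == 0L ||
        all(dist_km(pts[kept, , drop = FALSE],
                    pts[rep(i, length(kept)), , drop = FALSE]) >= min_km))
      kept <- c(kept, i)
  }
  res <- occ[sort(ord[kept]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full occurrence-cleaning pipeline for one taxon
#'
#' Applies, in order: uncertainty filter, locality deduplication, breeding
#' window filter, accessible-area clip, spatial thinning. Each step's
#' before/after counts are recorded in a prep log.
#'
#' @param occ an `occurrence_df` (single taxon).
#' @param area optional [accessible_area] for the taxon.
#' @param windows optional breeding-window list (see
#'   [filter_breeding_window()]); omit to skip date filtering.
#' @param max_uncert_km uncertainty cutoff in km (default 10).
#' @param thin_km thinning distance in km (default 20); `NULL` skips.
#' @param seed seed for thinning.
#' @return A list with `records` (the cleaned `occurrence_df`) and
#'   `prep_log` (data frame of step, n_before, n_after).
#' @export
prep_occurrences <- function(occ, area = NULL, windows = NULL,
                             max_uncert_km = 10, thin_km = 20, seed = 1L) {
  log <- data.frame(step = character(0), n_before = integer(0),
                    n_after = integer(0))
  step <- function(name, f, x) {
    nb <- nrow(x); y <- f(x)
    log[nrow(log) + 1L, ] <<- list(name, nb, nrow(y))
    y
  }
  occ <- step("uncertainty", function(x)
    filter_uncertainty(x, max_km = max_uncert_km), occ)
  occ <- step("dedupe", dedupe_localities, occ)
  if (!is.null(windows))
    occ <- step("breeding_window", function(x)
      filter_breeding_window(x, windows), occ)
  if (!is.null(area))
    occ <- step("m_clip", function(x) clip_to_m(x, area), occ)
  if (!is.null(thin_km))
    occ <- step("thin", function(x)
      thin_spatial(x, min_km = thin_km, seed = seed), occ)
  stopifnot(all(log$n_after <= log$n_before))
  list(records = occ, prep_log = log)
}
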