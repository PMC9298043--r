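#' Photosynthetic discrimination from plant and atmospheric delta-13C
#'
#' `Delta = (d_atm - (d_plant - f_post)) / (1 + (d_plant - f_post)/1000)`:
#' converts the measured isotope ratio of plant material (bulk leaf or
#' tree-ring alpha-cellulose), corrected for post-photosynthetic
#' fractionation, into discrimination relative to the atmospheric CO2 it
#' assimilated.
#'
#' @param d13c_atm atmospheric delta-13CO2, per mil.
#' @param d13c_pm plant-material delta-13C, per mil.
#' @param f_post post-photosynthetic fractionation, per mil (default 2.1,
#'   the standard bulk-leaf to alpha-cellulose offset).
#' @return Delta13C, per mil.
#' @export
#' @examples
#' delta_from_d13c(-8, -24, 2.1)  # ~18.58
delta_from_d13c <- function(d13c_atm, d13c_pm, f_post = 2.1) {
  corrected <- d13c_pm - f_post
  if (any(abs(1 + corrected / 1000) < 1e-12))
    stop("singular input: corrected plant delta-13C equals -1000 per mil")
  (d13c_atm - corrected) / (1 + corrected / 1000)
}

#' Apparent post-photosynthetic fractionation from paired tissues
#'
#' `f_post = d13C_wood - d13C_leaf` for same-site, same-year pairs; when
#' the wood measurement is bulk rather than alpha-cellulose, a constant
#' correction (default 1.1 per mil) is added to express the offset
#' relative to alpha-cellulose.
#'
#' @param leaf_d13c bulk-leaf delta-13C, per mil.
#' @param wood_d13c wood delta-13C, per mil.
#' @param wood_is_bulk logical; is the wood measurement bulk (not
#'   alpha-cellulose)?
#' @param bulk_correction per mil correction for bulk wood (default 1.1).
#' @return apparent f_post, per mil.
#' @export
apparent_fpost <- function(leaf_d13c, wood_d13c, wood_is_bulk = FALSE,
                           bulk_correction = 1.1) {
  wood_d13c - leaf_d13c + ifelse(wood_is_bulk, bulk_correction, 0)
}

#' Per-site apparent post-photosynthetic fractionation estimates
#'
#' Loads the shipped table of apparent f_post values estimated at
#' eddy-covariance sites from two flux networks (per site, species and
#' measurement years), and optionally summarises each network's mean and
#' SD.
#'
#' @param summarise logical; return per-network mean/SD instead of the
#'   per-entry table.
#' @return data.frame of per-entry values, or of per-network summaries
#'   (`network`, `n`, `mean_fpost`, `sd_fpost`).
#' @export
fpost_site_estimates <- function(summarise = FALSE) {
  file <- system.file("extdata", "fpost_sites.csv", package = "isocanopy")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!summarise) return(tab)
  agg <- do.call(rbind, lapply(split(tab, tab$network), function(g)
    data.frame(network = g$network[1], n = nrow(g),
               mean_fpost = mean(g$f_post), sd_fpost = stats::sd(g$f_post))))
  rownames(agg) <- NULL
  agg
}

#' Isotope chronology constructor
#'
#' A yearly delta-13C record for one site/species/tissue, with the
#' matched atmospheric delta-13CO2 series.
#'
#' @param site site identifier.
#' @param years measurement years (strictly increasing).
#' @param d13c_pm plant-material delta-13C, per mil.
#' @param d13c_atm atmospheric delta-13CO2 matched by year, per mil.
#' @param species species code.
#' @param tissue one of `"bulk-leaf"`, `"bulk-wood"`, `"alpha-cellulose"`.
#' @param f_post applied post-photosynthetic fractionation, per mil.
#' @return object of class `isotope_record`.
#' @export
isotope_record <- function(site, years, d13c_pm, d13c_atm,
                           species = NA_character_,
                           tissue = c("alpha-cellulose", "bulk-leaf",
                                      "bulk-wood"),
                           f_post = 2.1) {
  tissue <- match.arg(tissue)
  stopifnot(length(years) == length(d13c_pm),
            length(d13c_atm) %in% c(1, length(years)))
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  ok <- is.na(d13c_pm) | (d13c_pm > -40 & d13c_pm < -15)
  if (!all(ok)) stop("delta-13C outside plausible plant range (-40, -15)")
  structure(list(site = site, species = species, tissue = tissue,
                 years = years, d13c_pm = d13c_pm,
                 d13c_atm = rep_len(d13c_atm, length(years)),
                 f_post = f_post),
            class = "isotope_record")
}

#' Discrimination series from an isotope record
#' @param record an [isotope_record()].
#' @return data.frame with `year` and `delta13C` (per mil).
#' @export
record_delta <- function(record) {
  data.frame(year = record$years,
             delta13C = delta_from_d13c(record$d13c_atm, record$d13c_pm,
                                        record$f_post))
}

#' Select chronologies with sufficient in-window coverage
#'
#' Retains, in input order, the records with at least `min_years`
#' non-missing values inside the analysis window.
#'
#' @param records list of [isotope_record()] objects.
#' @param window_start,window_end analysis window, years (default
#'   1979-2012).
#' @param min_years minimum number of non-missing years (default 25).
#' @return filtered list of records.
#' @export
select_chronologies <- function(records, window_start = 1979,
                                window_end = 2012, min_years = 25) {
  keep <- vapply(records, function(r) {
    inwin <- r$years >= window_start & r$years <= window_end
    sum(inwin & !is.na(r$d13c_pm)) >= min_years
  }, logical(1))
  records[keep]
}

#' Screen an eddy-covariance flux record
#'
#' Applies, in order: (1) keep rows flagged good-quality, (2) drop vapor
#' pressure deficit below 0.01 kPa (instrument errors), (3) drop nighttime
#' rows (daytime flag when present, otherwise PPFD > 0), (4) drop
#' calendar days with precipitation together with the following calendar
#' day (non-transpirational water fluxes). GPP is converted to
#' g C m-2 day-1 and ET (kg H2O m-2 day-1) derived from LE; May-September
#' growing-season means are aggregated per year.
#'
#' @param flux data.frame with columns `timestamp` (POSIXct), `GPP`
#'   (umol CO2 m-2 s-1), `LE` (W m-2), `qc_flag` (0 = good), `PPFD`, `D`
#'   (kPa), `precip` (mm per step) and optionally `daytime` (logical).
#' @param latent_heat latent heat of vaporization, J kg-1.
#' @return list with `screened` (surviving rows, plus `GPP_gC_day` and
#'   `ET_kg_day` columns), `season_means` (per-year May-September means of
#'   GPP and ET; zero-row with attribute `empty_season = TRUE` when
#'   nothing survives), and `n_removed` (per-rule removal counts, applied
#'   sequentially).
#' @export
screen_flux <- function(flux, latent_heat = 2.45e6) {
  req <- c("timestamp", "GPP", "LE", "qc_flag", "PPFD", "D", "precip")
  if (!all(req %in% names(flux)))
    stop("flux record missing columns: ",
         paste(setdiff(req, names(flux)), collapse = ", "))
  n0 <- nrow(flux)
  counts <- c(bad_flag = 0, low_D = 0, night = 0, rain = 0)

  keep <- flux$qc_flag == 0
  counts["bad_flag"] <- sum(!keep)
  f <- flux[keep, , drop = FALSE]

  keep <- f$D >= 0.01
  counts["low_D"] <- sum(!keep)
  f <- f[keep, , drop = FALSE]

  day <- if ("daytime" %in% names(f)) f$daytime else f$PPFD > 0
  counts["night"] <- sum(!day)
  f <- f[day, , drop = FALSE]

  # rain rule needs the full record's calendar: a day with any precip and
  # the next calendar day are excluded
  all_days <- as.Date(flux$timestamp)
  rain_days <- unique(all_days[flux$precip > 0])
  excluded <- unique(c(rain_days, rain_days + 1))
  keep <- !(as.Date(f$timestamp) %in% excluded)
  counts["rain"] <- sum(!keep)
  f <- f[keep, , drop = FALSE]

  f$GPP_gC_day <- f$GPP * 1e-6 * 12 * 86400      # umol CO2 -> g C per day
  f$ET_kg_day <- f$LE / latent_heat * 86400      # W m-2 -> kg H2O per day

  if (nrow(f) == 0) {
    sm <- data.frame(year = integer(0), GPP = numeric(0), ET = numeric(0))
    attr(sm, "empty_season") <- TRUE
  } else {
    mon <- as.integer(format(f$timestamp, "%m"))
    yr <- as.integer(format(f$timestamp, "%Y"))
    gs <- mon >= 5 & mon <= 9
    if (!any(gs)) {
      sm <- data.frame(year = integer(0), GPP = numeric(0), ET = numeric(0))
      attr(sm, "empty_season") <- TRUE
    } else {
      sm <- do.call(rbind, lapply(split(which(gs), yr[gs]), function(idx)
        data.frame(year = yr[idx[1]], GPP = mean(f$GPP_gC_day[idx]),
                   ET = mean(f$ET_kg_day[idx]))))
      rownames(sm) <- NULL
    }
  }
  list(screened = f, season_means = sm, n_removed = counts,
       n_input = n0, n_retained = nrow(f))
}

#' Read isotope chronologies from a delimited file
#'
#' Expects columns `site`, `species`, `tissue`, `year`, `d13c`; the
#' atmospheric series file has columns `year`, `d13c_atm`. Records are
#' joined on exact year.
#'
#' @param path chronology file path (CSV).
#' @param atm_path atmospheric delta-13CO2 series path (CSV).
#' @param f_post applied post-photosynthetic fractionation, per mil.
#' @return list of [isotope_record()] objects.
#' @export
read_isotope_records <- function(path, atm_path, f_post = 2.1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  atm <- utils::read.csv(atm_path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$site), function(g) {
    g <- g[order(g$year), , drop = FALSE]
    m <- match(g$year, atm$year)
    if (anyNA(m)) stop("no atmospheric delta-13CO2 for year(s): ",
                       paste(g$year[is.na(m)], collapse = ", "))
    isotope_record(g$site[1], g$year, g$d13c, atm$d13c_atm[m],
                   species = g$species[1], tissue = g$tissue[1],
                   f_post = f_post)
  })
}
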