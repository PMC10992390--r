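#' Deployment-level fish count tables
#'
#' A `count_table` holds one row per baited-video deployment: the site, the
#' calendar year, a station label (stations are spatially fixed, so a label
#' is reused across years within its site), the summed MaxN count over the
#' indicator taxa, a binary disturbance flag (0 = background/"before",
#' 1 = disturbed/"after"), and optional environmental covariates.
#'
#' @param records data frame with columns `site_id`, `year`, `station_id`,
#'   `count` and optionally `disturbance_flag` (defaults to 0) plus any of
#'   the covariate columns `current`, `visibility` (ordinal 0--5),
#'   `tidal_amplitude` (metres, >= 0), `depth` (metres, > 0),
#'   `time_of_day` (minutes since midnight). `count` may be `NA` throughout
#'   (a design skeleton before counts exist).
#' @param baseline_year integer year used as the reference for
#'   baseline-relative indicators. Defaults to the earliest year present.
#' @param taxa optional character vector naming the indicator taxa whose
#'   MaxN values were summed into `count`.
#'
#' @return An object of class `count_table`: the validated records with
#'   attributes `baseline_year` and `taxa`.
#' @seealso [read_count_table()], [expand_design()]
#' @export
count_table <- function(records, baseline_year = NULL, taxa = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  attr(records, "out.attrs") <- NULL
  required <- c("site_id", "year", "station_id", "count")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("count table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(records$disturbance_flag)) records$disturbance_flag <- 0L

  records$site_id <- as.character(records$site_id)
  records$station_id <- as.character(records$station_id)
  records$year <- validate_integerish(records$year, "year")
  records$disturbance_flag <- validate_integerish(records$disturbance_flag,
                                                  "disturbance_flag")
  bad <- which(!records$disturbance_flag %in% c(0L, 1L))
  if (length(bad) > 0) {
    stop("disturbance_flag must be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(is.na(records$count))) {
    records$count <- validate_integerish(records$count, "count",
                                         allow_na = TRUE)
    bad <- which(!is.na(records$count) & records$count < 0)
    if (length(bad) > 0) {
      stop("count must be a non-negative integer; offending row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (cv in c("current", "visibility")) {
    if (!is.null(records[[cv]])) {
      v <- records[[cv]]
      bad <- which(!is.na(v) & !v %in% 0:5)
      if (length(bad) > 0) {
        stop(cv, " must be an ordinal score in 0..5; offending row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!is.null(records$tidal_amplitude) &&
      any(records$tidal_amplitude < 0, na.rm = TRUE)) {
    stop("tidal_amplitude must be >= 0", call. = FALSE)
  }
  if (!is.null(records$depth) && any(records$depth <= 0, na.rm = TRUE)) {
    stop("depth must be > 0", call. = FALSE)
  }

  key <- paste(records$site_id, records$year, records$station_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site_id, year, station_id) triple(s) at row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }

  if (is.null(baseline_year)) baseline_year <- min(records$year)
  baseline_year <- as.integer(baseline_year)

  rownames(records) <- NULL
  structure(records,
            baseline_year = baseline_year,
            taxa = taxa,
            class = c("count_table", "data.frame"))
}

validate_integerish <- function(x, name, allow_na = FALSE) {
  xn <- suppressWarnings(as.numeric(x))
  bad <- which((is.na(xn) & !(allow_na & is.na(x))) |
                 (!is.na(xn) & xn != round(xn)))
  if (length(bad) > 0) {
    stop(name, " must be integer-valued; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(round(xn))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d deployment(s), %d site(s), years %s, baseline %d\n",
              nrow(x), length(unique(x$site_id)),
              paste(range(x$year), collapse = "-"),
              attr(x, "baseline_year")))
  if (!is.null(attr(x, "taxa"))) {
    cat("  indicator taxa:", paste(attr(x, "taxa"), collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
baseline_year <- function(x) attr(x, "baseline_year")

#' Read and write count tables
#'
#' Count tables are exchanged as plain comma-separated text with a header
#' row; one row per deployment. `read_count_table()` validates on read and
#' rejects malformed rows with row-indexed messages; the pair of functions
#' round-trips any valid table losslessly.
#'
#' @param path file path of a CSV with at least the columns `site_id`,
#'   `year`, `station_id`, `count`.
#' @param baseline_year,taxa passed to [count_table()].
#' @return `read_count_table()` returns a validated [count_table()];
#'   `write_count_table()` invisibly returns `path`.
#' @export
read_count_table <- function(path, baseline_year = NULL, taxa = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  count_table(df, baseline_year = baseline_year, taxa = taxa)
}

#' @rdname read_count_table
#' @param x a `count_table` (or data frame coercible to one).
#' @export
write_count_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monitoring sampling designs
#'
#' A `sampling_design` describes which (site, year) combinations are
#' sampled, how many fixed stations each site carries, and any post-hoc
#' exclusions of individual deployments (e.g. an obstructed field of view).
#'
#' @param sites character vector of site labels.
#' @param years integer vector of calendar years.
#' @param stations_per_site positive integer; station labels are
#'   `"st1" ... "st<k>"` and are reused across years within a site
#'   (stations are spatially fixed).
#' @param inclusion optional data frame with columns `site_id`, `year`
#'   listing the sampled combinations; defaults to the full crossing.
#' @param exclusions optional data frame with columns `site_id`, `year`,
#'   `station_id` of deployments removed post hoc.
#' @return An object of class `sampling_design`.
#' @seealso [expand_design()], [study_design()]
#' @export
sampling_design <- function(sites, years, stations_per_site = 5L,
                            inclusion = NULL, exclusions = NULL) {
  stopifnot(length(sites) >= 1, length(years) >= 1,
            stations_per_site >= 1)
  sites <- as.character(sites)
  years <- as.integer(years)
  if (anyDuplicated(sites)) stop("duplicate site labels", call. = FALSE)
  if (anyDuplicated(years)) stop("duplicate years", call. = FALSE)
  if (is.null(inclusion)) {
    inclusion <- expand.grid(site_id = sites, year = years,
                             stringsAsFactors = FALSE)
  }
  inclusion$site_id <- as.character(inclusion$site_id)
  inclusion$year <- as.integer(inclusion$year)
  if (!all(inclusion$site_id %in% sites) || !all(inclusion$year %in% years)) {
    stop("inclusion refers to unknown site or year", call. = FALSE)
  }
  if (!is.null(exclusions)) {
    exclusions$site_id <- as.character(exclusions$site_id)
    exclusions$year <- as.integer(exclusions$year)
    exclusions$station_id <- as.character(exclusions$station_id)
    inc_key <- paste(inclusion$site_id, inclusion$year)
    bad <- !paste(exclusions$site_id, exclusions$year) %in% inc_key
    if (any(bad)) {
      stop("exclusion refers to a (site, year) not in the design: ",
           paste(paste(exclusions$site_id[bad], exclusions$year[bad]),
                 collapse = "; "), call. = FALSE)
    }
  }
  structure(list(sites = sites, years = years,
                 stations_per_site = as.integer(stations_per_site),
                 inclusion = inclusion, exclusions = exclusions),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(paste0("sampling_design: %d site(s) x years %s, %d station(s)",
                     "/site, %d included (site,year) cell(s), %d exclusion(s)",
                     " -> %d deployment(s)\n"),
              length(x$sites), paste(range(x$years), collapse = "-"),
              x$stations_per_site, nrow(x$inclusion),
              if (is.null(x$exclusions)) 0L else nrow(x$exclusions),
              design_size(x)))
  invisible(x)
}

#' @rdname expand_design
#' @export
design_size <- function(design) {
  nrow(design$inclusion) * design$stations_per_site -
    if (is.null(design$exclusions)) 0L else nrow(design$exclusions)
}

#' Expand a sampling design into a deployment table
#'
#' Enumerates one record per included (site, year, station), drops the
#' exclusions, and returns a [count_table()] skeleton with `count = NA`.
#' The record count always equals
#' `sum(stations_per_site over included cells) - n_exclusions`
#' (also available directly as `design_size()`).
#'
#' @param design a [sampling_design()].
#' @param baseline_year passed to [count_table()].
#' @return A [count_table()] with `NA` counts.
#' @export
expand_design <- function(design, baseline_year = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  stations <- paste0("st", seq_len(design$stations_per_site))
  rec <- design$inclusion[rep(seq_len(nrow(design$inclusion)),
                              each = design$stations_per_site), ]
  rec$station_id <- rep(stations, nrow(design$inclusion))
  if (!is.null(design$exclusions)) {
    key <- paste(rec$site_id, rec$year, rec$station_id, sep = "\r")
    exkey <- paste(design$exclusions$site_id, design$exclusions$year,
                   design$exclusions$station_id, sep = "\r")
    rec <- rec[!key %in% exkey, ]
  }
  rec$count <- NA_integer_
  rec$disturbance_flag <- 0L
  rec <- rec[order(rec$site_id, rec$year, rec$station_id), ]
  count_table(rec[, c("site_id", "year", "station_id", "count",
                      "disturbance_flag")],
              baseline_year = baseline_year)
}

#' The default five-site monitoring design
#'
#' The sampling layout of the motivating coral-reef monitoring program:
#' five sites with five fixed video stations each, sampled annually
#' 2018--2022, except one site visited only in 2020 and 2022 for logistical
#' reasons; two deployments are excluded post hoc (obstructed field of
#' view), leaving 108 usable deployments. Which two deployments were
#' dropped is not identifiable from the published record, so the default
#' exclusions are a synthetic but design-equivalent choice and can be
#' overridden.
#'
#' @param exclusions data frame of post-hoc exclusions; the default removes
#'   two stations of the first site in 2019.
#' @return A [sampling_design()] expanding to 108 records.
#' @export
study_design <- function(exclusions = data.frame(
                           site_id = "S1", year = c(2019L, 2019L),
                           station_id = c("st4", "st5"))) {
  sites <- paste0("S", 1:5)
  years <- 2018:2022
  inclusion <- rbind(
    expand.grid(site_id = sites[1:4], year = years,
                stringsAsFactors = FALSE),
    data.frame(site_id = "S5", year = c(2020L, 2022L))
  )
  sampling_design(sites, years, stations_per_site = 5L,
                  inclusion = inclusion, exclusions = exclusions)
}

#' Traffic-light health categories on the fold-change scale
#'
#' Health status is read off the ratio of a year's modelled mean abundance
#' to the baseline year's ("fold change"). Categories are contiguous
#' half-open bands `[lower, upper)` jointly covering (0, Inf), so exactly
#' one category contains any positive fold change; a draw exactly on a
#' boundary belongs to the higher-health band (a fold change of 0.9 -- a
#' 10% decline -- is still "very good", which allows increases or small
#' declines of less than 10%).
#'
#' @param categories character vector of category names, ordered from worst
#'   to best health.
#' @param lower numeric vector of inclusive lower fold-change bounds, the
#'   first of which must be 0; upper bounds are implied by contiguity, the
#'   last being `Inf`.
#' @param colours display colours, one per category.
#' @return An object of class `health_categories`: a data frame with
#'   columns `category`, `lower`, `upper`, `colour`.
#' @examples
#' hc <- health_categories()
#' hc
#' @export
health_categories <- function(categories = c("poor", "fair", "good",
                                             "very_good"),
                              lower = c(0, 0.5, 0.7, 0.9),
                              colours = c("red", "yellow", "lightgreen",
                                          "darkgreen")) {
  stopifnot(length(categories) == length(lower),
            length(colours) == length(categories))
  if (lower[1] != 0) stop("first lower bound must be 0", call. = FALSE)
  if (any(diff(lower) <= 0)) {
    stop("lower bounds must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(category = as.character(categories),
                       lower = lower,
                       upper = c(lower[-1], Inf),
                       colour = as.character(colours),
                       stringsAsFactors = FALSE),
            class = c("health_categories", "data.frame"))
}

#' @rdname health_categories
#' @param fold positive fold-change value(s).
#' @param spec a `health_categories` object.
#' @return `classify_fold()` returns the category name containing each
#'   value of `fold`.
#' @export
classify_fold <- function(fold, spec = health_categories()) {
  stopifnot(all(fold > 0))
  idx <- findInterval(fold, spec$lower)  # half-open [lower, upper)
  spec$category[idx]
}
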