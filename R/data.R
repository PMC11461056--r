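#' Assemble and validate a joint survey data table
#'
#' Bundles the annual survey series the joint Gompertz state-space model
#' consumes: abundances of the three focal species, herring biomass, the two
#' climate covariates and the three fishing-mortality indices. Values must be
#' strictly positive where observed; abundance cells may be `NA` (missing
#' survey estimates are skipped in the observation likelihood).
#'
#' @param year integer calendar years, strictly increasing with step 1.
#' @param cod NEA cod abundance (1e6 individuals).
#' @param cap capelin abundance (1e9 individuals).
#' @param pcod polar cod abundance (1e9 individuals).
#' @param herring herring biomass (1e6 tonnes).
#' @param st Kola-transect sea temperature (deg C).
#' @param ice winter (Dec-May) sea-ice index (1e5 km^2), strictly positive.
#' @param f_cod,f_cap,f_pcod fishing mortality indices (dimensionless).
#' @return a `data.frame` of class `fish_data`.
#' @export
fish_data <- function(year, cod, cap, pcod, herring, st, ice,
                      f_cod, f_cap, f_pcod) {
  d <- data.frame(year = year, cod = cod, cap = cap, pcod = pcod,
                  herring = herring, st = st, ice = ice,
                  f_cod = f_cod, f_cap = f_cap, f_pcod = f_pcod)
  rownames(d) <- NULL
  class(d) <- c("fish_data", "data.frame")
  validate_fish_data(d)
  d
}

gbs_columns <- c("year", "cod", "cap", "pcod", "herring", "st", "ice",
                 "f_cod", "f_cap", "f_pcod")

#' Validate a joint survey data table
#'
#' Checks the invariants of the data model: required columns, integer years
#' strictly increasing with step 1 and no duplicates, strictly positive
#' abundances/biomass/ice where observed, complete covariate series.
#'
#' @param d a data.frame with the columns of [fish_data()].
#' @return `d`, invisibly, with class `fish_data`; errors name the offending
#'   row and column.
#' @export
validate_fish_data <- function(d) {
  miss <- setdiff(gbs_columns, names(d))
  if (length(miss))
    stop("fish_data: missing column(s): ", paste(miss, collapse = ", "))
  yr <- d$year
  if (any(is.na(yr)) || any(yr != round(yr)))
    stop("fish_data: column 'year' must be integer calendar years")
  if (anyDuplicated(yr))
    stop("fish_data: duplicate year at row ",
         which(duplicated(yr))[1], " (year ", yr[which(duplicated(yr))[1]], ")")
  if (length(yr) > 1 && any(diff(yr) != 1))
    stop("fish_data: years must be strictly increasing with step 1 (row ",
         which(diff(yr) != 1)[1] + 1, ")")
  for (col in c("cod", "cap", "pcod", "herring", "ice")) {
    bad <- which(!is.na(d[[col]]) & d[[col]] <= 0)
    if (length(bad))
      stop("fish_data: non-positive value in column '", col,
           "' at row ", bad[1], " (year ", yr[bad[1]], ")")
  }
  for (col in c("herring", "st", "ice", "f_cod", "f_cap", "f_pcod")) {
    bad <- which(is.na(d[[col]]))
    if (length(bad))
      stop("fish_data: covariate column '", col, "' has missing value at row ",
           bad[1], " (year ", yr[bad[1]], "); covariate series must be complete")
  }
  if (!inherits(d, "fish_data")) class(d) <- c("fish_data", "data.frame")
  invisible(d)
}

#' Abundance table view of a data set
#'
#' @param d a [fish_data()] table.
#' @return data.frame with years, the three species abundances, herring
#'   biomass and the fishing indices.
#' @export
abundance_table <- function(d) {
  validate_fish_data(d)
  d[c("year", "cod", "cap", "pcod", "herring", "f_cod", "f_cap", "f_pcod")]
}

#' Climate series view of a data set, with z-scored columns
#'
#' Returns the raw and standardized climate covariates over the modelled
#' window. The z-scored columns carry `center`/`scale` attributes so scenario
#' series can be mapped onto the same scale as the training data.
#'
#' @param d a [fish_data()] table.
#' @return data.frame with columns `year`, `ice`, `st`, `z_ice`, `z_st`.
#' @export
climate_series <- function(d) {
  validate_fish_data(d)
  out <- d[c("year", "ice", "st")]
  out$z_ice <- zscore(d$ice)
  out$z_st <- zscore(d$st)
  out
}

#' Read a joint survey data CSV
#'
#' Reads the tidy schema (`year, cod, cap, pcod, herring, st, ice, f_cod,
#' f_cap, f_pcod`; empty cells = missing observations), validates every
#' data-model invariant, and reports missing abundance cells.
#'
#' @param path path to a CSV file; lines starting with `#` are ignored.
#' @param quiet suppress the missing-observation report.
#' @return a [fish_data()] table.
#' @export
read_fish_data <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("read_fish_data: no such file: ", path)
  d <- read.csv(path, comment.char = "#")
  miss <- setdiff(gbs_columns, names(d))
  if (length(miss))
    stop("read_fish_data: ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  d <- d[gbs_columns]
  class(d) <- c("fish_data", "data.frame")
  validate_fish_data(d)
  n_miss <- vapply(d[c("cod", "cap", "pcod")], function(x) sum(is.na(x)), 0L)
  if (!quiet && sum(n_miss) > 0)
    message("read_fish_data: ", sum(n_miss), " missing observation(s): ",
            paste(names(n_miss)[n_miss > 0], n_miss[n_miss > 0],
                  sep = "=", collapse = ", "))
  d
}

#' Write a joint survey data CSV
#'
#' @param d a [fish_data()] table.
#' @param path output file path.
#' @param provenance optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_fish_data <- function(d, path, provenance = NULL) {
  validate_fish_data(d)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ",
                      vapply(provenance, format, "")), con)
  write.csv(as.data.frame(d), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
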