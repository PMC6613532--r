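#' Binary species-by-band incidence matrices
#'
#' The incidence matrix is the substrate of every null model in the
#' package: a binary matrix with one row per species and one column per
#' 1-degree latitudinal band, column labels being band lower edges in
#' degrees S (ascending).
#'
#' @name incidence
NULL

new_incidence <- function(values, domain) {
  storage.mode(values) <- "integer"
  structure(values, class = c("incidence", "matrix"), domain = domain)
}

#' Coerce a binary matrix to an incidence matrix
#'
#' @param x A binary (0/1) matrix, species in rows, sites/bands in columns.
#' @param domain Optional [band_domain()]; when omitted, a generic domain of
#'   `ncol(x)` unit bands starting at 0 is attached.
#' @return An `incidence` object.
#' @export
as_incidence <- function(x, domain = NULL) {
  x <- as.matrix(x)
  if (!all(x %in% c(0L, 1L))) {
    stop("Incidence matrices must be binary (entries 0/1).", call. = FALSE)
  }
  if (is.null(domain)) domain <- band_domain(0L, ncol(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("sp", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- as.character(domain$bands)
  new_incidence(x, domain)
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("<incidence> %d species x %d bands, fill %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Tidy an incidence matrix to long format
#'
#' @param x An `incidence` object.
#' @param ... Unused.
#' @return A tibble with columns `species`, `band` (integer lower edge,
#'   degrees S) and `present` (0/1).
#' @method tidy incidence
#' @export
tidy.incidence <- function(x, ...) {
  tibble::tibble(
    species = rep(rownames(x), times = ncol(x)),
    band = rep(as.integer(colnames(x)), each = nrow(x)),
    present = as.integer(x)
  )
}

#' Build an incidence matrix from species latitudinal ranges
#'
#' Each species occupies every band whose half-open interval `[k, k + 1)`
#' intersects its latitudinal extent `[lat_min, lat_max]` (interval fill).
#' A range touching the south limit is clamped into the last band; point
#' ranges (extent 0) occupy exactly one band, so no species row is all
#' zeros.
#'
#' @param ranges A data frame with columns `species`, `lat_min`, `lat_max`
#'   (degrees S magnitudes, or signed decimal degrees with `signed = TRUE`).
#' @param domain A [band_domain()].
#' @param signed Are latitudes signed decimal degrees (negative = S)?
#' @return An `incidence` matrix, one row per species in input order.
#' @examples
#' rng <- tibble::tibble(species = "a", lat_min = 38, lat_max = 41)
#' m <- ranges_to_incidence(rng, band_domain(18, 56))
#' sum(m) # 4 bands: 38, 39, 40, 41
#' @export
ranges_to_incidence <- function(ranges, domain = band_domain(), signed = FALSE) {
  ranges <- validate_ranges(ranges, signed = signed)
  bad <- ranges$lat_min < domain$north_limit | ranges$lat_max > domain$south_limit
  if (any(bad)) {
    stop("Ranges outside the domain ", format(domain), ": ",
         paste(ranges$species[bad], collapse = ", "), call. = FALSE)
  }
  lo <- band_of(ranges$lat_min, domain)
  hi <- band_of(ranges$lat_max, domain)
  vals <- matrix(0L, nrow(ranges), domain$n_bands,
                 dimnames = list(ranges$species, as.character(domain$bands)))
  for (i in seq_len(nrow(ranges))) {
    vals[i, (lo[i] - domain$north_limit + 1L):(hi[i] - domain$north_limit + 1L)] <- 1L
  }
  new_incidence(vals, domain)
}

#' Build an incidence matrix from occurrence records
#'
#' With `fill = FALSE` only bands actually containing a record are marked;
#' with `fill = TRUE` the per-species latitudinal extremes are derived
#' first and the full interval between them is filled, which is identical
#' to [ranges_to_incidence()] on [derive_ranges()] of the records.
#'
#' @param records A data frame with columns `species` and `latitude`
#'   (degrees S magnitude, or signed with `signed = TRUE`).
#' @param domain A [band_domain()].
#' @param fill Interval-fill between each species' extreme records?
#' @param signed Are latitudes signed decimal degrees (negative = S)?
#' @return An `incidence` matrix, one row per species (first-appearance order).
#' @export
records_to_incidence <- function(records, domain = band_domain(),
                                 fill = FALSE, signed = FALSE) {
  records <- validate_records(records, signed = signed)
  if (fill) {
    return(ranges_to_incidence(derive_ranges(records), domain))
  }
  bands <- band_of(records$latitude, domain)
  if (anyNA(bands)) {
    stop("Records outside the domain ", format(domain), ": ",
         paste(unique(records$species[is.na(bands)]), collapse = ", "),
         call. = FALSE)
  }
  species <- unique(records$species)
  vals <- matrix(0L, length(species), domain$n_bands,
                 dimnames = list(species, as.character(domain$bands)))
  vals[cbind(match(records$species, species),
             bands - domain$north_limit + 1L)] <- 1L
  new_incidence(vals, domain)
}

#' Derive per-species latitudinal ranges from occurrence records
#'
#' @param records A data frame with columns `species` and `latitude`.
#' @param signed Are latitudes signed decimal degrees (negative = S)?
#' @return A tibble with `species`, `lat_min`, `lat_max`, `midpoint`
#'   (mean of the extremes) and `extent` (their difference, degrees).
#' @export
derive_ranges <- function(records, signed = FALSE) {
  records <- validate_records(records, signed = signed)
  records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(lat_min = min(.data$latitude),
                     lat_max = max(.data$latitude),
                     .groups = "drop") |>
    dplyr::mutate(midpoint = (.data$lat_min + .data$lat_max) / 2,
                  extent = .data$lat_max - .data$lat_min)
}

#' Annotate a range table with midpoint and extent
#'
#' @param ranges A data frame with `species`, `lat_min`, `lat_max`.
#' @param signed Are latitudes signed decimal degrees (negative = S)?
#' @return The input as a tibble with `midpoint` and `extent` columns added.
#' @export
range_summary <- function(ranges, signed = FALSE) {
  validate_ranges(ranges, signed = signed) |>
    dplyr::mutate(midpoint = (.data$lat_min + .data$lat_max) / 2,
                  extent = .data$lat_max - .data$lat_min)
}

validate_ranges <- function(ranges, signed = FALSE) {
  need <- c("species", "lat_min", "lat_max")
  miss <- setdiff(need, names(ranges))
  if (length(miss)) {
    stop("Range table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ranges <- tibble::as_tibble(ranges)
  ranges$lat_min <- as_degrees_south(ranges$lat_min, signed)
  ranges$lat_max <- as_degrees_south(ranges$lat_max, signed)
  if (signed) { # signed S latitudes reverse the min/max roles
    tmp <- ranges$lat_min
    ranges$lat_min <- pmin(ranges$lat_min, ranges$lat_max)
    ranges$lat_max <- pmax(tmp, ranges$lat_max)
  }
  bad <- ranges$lat_min > ranges$lat_max
  if (any(bad)) {
    stop("lat_min > lat_max for: ", paste(ranges$species[bad], collapse = ", "),
         call. = FALSE)
  }
  ranges
}

validate_records <- function(records, signed = FALSE) {
  need <- c("species", "latitude")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("Record table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("No occurrence records supplied.", call. = FALSE)
  records <- tibble::as_tibble(records)
  records$latitude <- as_degrees_south(records$latitude, signed)
  records
}

#' Pack an incidence matrix by marginal totals
#'
#' Reorders rows by decreasing row sum (common species on top) and columns
#' by decreasing column sum (richest bands on the left). Ties keep their
#' original relative order (stable sort), so packing is deterministic and
#' idempotent.
#'
#' @param m An `incidence` matrix (or plain binary matrix).
#' @return The packed `incidence` matrix.
#' @export
pack_matrix <- function(m) {
  domain <- attr(m, "domain") %||% band_domain(0L, ncol(m))
  m <- unclass(m)
  ro <- order(rowSums(m), decreasing = TRUE)       # order() is stable
  co <- order(colSums(m), decreasing = TRUE)
  new_incidence(m[ro, co, drop = FALSE], domain)
}

#' Species richness per latitudinal band
#'
#' @param m An `incidence` matrix.
#' @return A tibble with `band` (integer lower edge, degrees S) and
#'   `richness` (column sum), in band order.
#' @export
richness_per_band <- function(m) {
  tibble::tibble(
    band = as.integer(colnames(m)),
    richness = as.integer(colSums(unclass(m)))
  )
}
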