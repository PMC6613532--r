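#' Bounded latitudinal band domain
#'
#' Defines the hard geometric limits of the study gradient as a set of
#' contiguous 1-degree latitudinal bands. Latitudes are handled as positive
#' degrees South, so the default Chilean domain runs from 18 (north limit)
#' to 56 (south limit) and contains 38 bands. Band `k` covers the half-open
#' interval `[k, k + 1)` degrees S; a latitude exactly at the south limit is
#' assigned to the last band so that no phantom 39th band exists.
#'
#' @param north_limit Northern edge of the domain, integer degrees S.
#' @param south_limit Southern edge of the domain, integer degrees S
#'   (must exceed `north_limit`).
#' @return An object of class `band_domain`: a list with `north_limit`,
#'   `south_limit`, `width` (always 1), `n_bands` and the integer vector
#'   `bands` of band lower edges in degrees S, ascending.
#' @examples
#' dom <- band_domain(18, 56)
#' dom$n_bands # 38
#' @export
band_domain <- function(north_limit = 18, south_limit = 56) {
  north_limit <- as.integer(north_limit)
  south_limit <- as.integer(south_limit)
  if (north_limit >= south_limit) {
    stop("`north_limit` must be strictly less than `south_limit` (degrees S).",
         call. = FALSE)
  }
  structure(
    list(
      north_limit = north_limit,
      south_limit = south_limit,
      width = 1L,
      n_bands = south_limit - north_limit,
      bands = seq.int(north_limit, south_limit - 1L)
    ),
    class = "band_domain"
  )
}

#' @export
print.band_domain <- function(x, ...) {
  cat(sprintf("<band_domain> %d-%d degrees S, %d bands of %d degree\n",
              x$north_limit, x$south_limit, x$n_bands, x$width))
  invisible(x)
}

#' @export
format.band_domain <- function(x, ...) {
  sprintf("%d:%d S", x$north_limit, x$south_limit)
}

# Map a latitude (degrees S magnitude) to its band lower edge, clamping the
# exact south limit into the last band. Out-of-domain values return NA.
band_of <- function(lat, domain) {
  out <- floor(lat)
  out[lat == domain$south_limit] <- domain$south_limit - 1
  out[lat < domain$north_limit | lat > domain$south_limit] <- NA_real_
  as.integer(out)
}

# Normalise latitudes that may arrive as signed decimal degrees
# (negative = S) into positive degrees-S magnitudes.
as_degrees_south <- function(lat, signed = FALSE) {
  if (signed) -lat else lat
}
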