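#' Read and write the package's CSV formats
#'
#' Plain-CSV interchange for the four tabular inputs/outputs: occurrence
#' records (`species,latitude`), species ranges (`species,lat_min,lat_max`),
#' incidence matrices (first column `species`, remaining columns one band
#' each) and per-band covariate tables (first column `band`). All readers
#' validate the header and report malformed rows with their line numbers
#' via readr's parsing problems.
#'
#' @param path File path.
#' @param signed Are latitudes signed decimal degrees (negative = S)?
#' @return `read_ranges()` / `read_records()` return validated tibbles;
#'   `read_incidence()` returns an `incidence` matrix;
#'   `read_covariates()` returns a tibble with integer `band` first.
#' @name macronull_io
NULL

read_checked <- function(path, need) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs)) {
    stop("Malformed rows in ", path, " at line(s): ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname macronull_io
#' @export
read_ranges <- function(path, signed = FALSE) {
  validate_ranges(read_checked(path, c("species", "lat_min", "lat_max")),
                  signed = signed)
}

#' @rdname macronull_io
#' @export
read_records <- function(path, signed = FALSE) {
  validate_records(read_checked(path, c("species", "latitude")),
                   signed = signed)
}

#' @rdname macronull_io
#' @param x Object to write (a range/record/covariate data frame, or an
#'   `incidence` matrix).
#' @export
write_ranges <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname macronull_io
#' @export
write_records <- write_ranges

#' @rdname macronull_io
#' @export
write_covariates <- write_ranges

#' @rdname macronull_io
#' @param domain Optional [band_domain()] for the matrix being read; by
#'   default it is reconstructed from the band column labels.
#' @export
read_incidence <- function(path, domain = NULL) {
  x <- read_checked(path, "species")
  species <- x$species
  vals <- as.matrix(x[setdiff(names(x), "species")])
  rownames(vals) <- species
  bands <- suppressWarnings(as.integer(colnames(vals)))
  if (anyNA(bands)) stop("Incidence CSV band columns must be integer band labels.",
                         call. = FALSE)
  if (is.null(domain)) domain <- band_domain(min(bands), max(bands) + 1L)
  as_incidence(vals, domain)
}

#' @rdname macronull_io
#' @export
write_incidence <- function(x, path) {
  out <- tibble::as_tibble(as.data.frame(unclass(x)), .name_repair = "minimal")
  names(out) <- colnames(x)
  out <- dplyr::bind_cols(tibble::tibble(species = rownames(x)), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname macronull_io
#' @export
read_covariates <- function(path, domain = NULL) {
  x <- read_checked(path, "band")
  x$band <- as.integer(x$band)
  if (!is.null(domain)) {
    miss <- setdiff(domain$bands, x$band)
    if (length(miss)) {
      stop("Covariate table missing band(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    x <- x[match(domain$bands, x$band), , drop = FALSE]
  }
  if (anyNA(x)) {
    bad <- x$band[!stats::complete.cases(x)]
    stop("Covariate table has missing cells in band(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}
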