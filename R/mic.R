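#' MIC frequency distribution
#'
#' @param mic Positive, strictly increasing MIC values (mg/L).
#' @param frequency Relative frequencies, non-negative, summing to 1 within
#'   1e-9 (set `normalize = TRUE` to rescale raw counts).
#' @param normalize Rescale frequencies to sum to 1?
#'
#' @return A tibble of class `mic_distribution` with columns `mic`,
#'   `frequency`.
#' @examples
#' mic_distribution(c(2, 4, 8), c(0.2, 0.5, 0.3))
#' @export
mic_distribution <- function(mic, frequency, normalize = FALSE) {
  if (length(mic) != length(frequency) || length(mic) == 0L) {
    abort("mic and frequency must be non-empty and of equal length")
  }
  if (any(mic <= 0)) abort("MICs must be positive")
  if (is.unsorted(mic, strictly = TRUE)) {
    abort("MICs must be strictly increasing")
  }
  if (any(frequency < 0)) abort("frequencies must be non-negative")
  if (normalize) frequency <- frequency / sum(frequency)
  if (abs(sum(frequency) - 1) > 1e-9) {
    abort("frequencies must sum to 1 (within 1e-9); see `normalize`")
  }
  out <- tibble::tibble(mic = as.numeric(mic),
                        frequency = as.numeric(frequency))
  class(out) <- c("mic_distribution", class(out))
  out
}

#' Read an MIC distribution from CSV or JSON
#'
#' CSV files need columns `mic` and `frequency`; JSON files an object or
#' records with the same fields. The package bundles a clearly synthetic
#' example distribution shaped like a P. aeruginosa amikacin wild-type
#' population (`system.file("extdata", "mic_pa_synthetic.csv", package =
#' "amikelder")`); it is a stand-in, not surveillance data.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param normalize Rescale frequencies to sum to 1?
#'
#' @return A [mic_distribution()].
#' @export
read_mic_distribution <- function(path, normalize = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE)
  } else if (ext == "json") {
    raw <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    abort("unsupported MIC distribution format; use .csv or .json")
  }
  if (!all(c("mic", "frequency") %in% names(raw))) {
    abort("MIC distribution file must have 'mic' and 'frequency' columns")
  }
  raw <- dplyr::arrange(raw, .data$mic)
  mic_distribution(raw$mic, raw$frequency, normalize = normalize)
}
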