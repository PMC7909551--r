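#' Build a renal-function dosing nomogram from a PTA grid
#'
#' For each creatinine clearance in the grid, selects among the regimens
#' whose joint attainment (efficacy and safety on the same draw) meets
#' `pta_threshold` the one with the lowest dose, tie-broken by the longest
#' interval — encoding the extended-interval aminoglycoside rationale: when a
#' dose satisfies both targets at several intervals, the longest interval
#' maximises the safety margin without losing first-dose efficacy. Cells
#' where no regimen qualifies are reported as `NA` (no recommendation).
#'
#' @param grid A [pta_table()] result.
#' @param mic The MIC (mg/L) at which to read the joint attainment.
#' @param pta_threshold Joint PTA threshold (%), default 90.
#' @param fta An optional [fta_table()] result; with `fta_threshold`,
#'   regimens must additionally meet the fractional-target-attainment bar.
#' @param fta_threshold Optional FTA threshold (%), e.g. 85.
#'
#' @return A tibble of class `amik_nomogram`: `ccr`, `renal_function`,
#'   `dose`, `interval`, `joint_pct`, `label` (`"1800 mg q72h"` style, `NA`
#'   when no regimen qualifies).
#' @examples
#' grid <- pta_table(population_model(), doses = c(800, 1800),
#'                   ccr_values = c(40, 90), mics = 8, n = 200, seed = 1)
#' build_nomogram(grid, mic = 8)
#' @export
build_nomogram <- function(grid, mic, pta_threshold = 90,
                           fta = NULL, fta_threshold = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    abort("grid must be a non-empty PTA table")
  }
  rows <- dplyr::filter(grid, .data$mic == .env$mic)
  if (nrow(rows) == 0L) {
    abort(sprintf("grid contains no rows for MIC %g", mic))
  }
  if (!is.null(fta_threshold)) {
    if (is.null(fta)) {
      abort("fta_threshold requires an fta table")
    }
    rows <- dplyr::inner_join(rows, fta,
                              by = c("ccr", "dose", "interval"))
  }
  out <- rows |>
    dplyr::group_by(.data$ccr) |>
    dplyr::group_modify(function(df, key) {
      ok <- df$joint_pct >= pta_threshold
      if (!is.null(fta_threshold)) ok <- ok & df$fta_pct >= fta_threshold
      cand <- df[ok, , drop = FALSE]
      if (nrow(cand) == 0L) {
        return(tibble::tibble(dose = NA_real_, interval = NA_real_,
                              joint_pct = NA_real_))
      }
      cand <- cand[order(cand$dose, -cand$interval), ]
      tibble::tibble(dose = cand$dose[1], interval = cand$interval[1],
                     joint_pct = cand$joint_pct[1])
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ccr) |>
    dplyr::mutate(
      renal_function = renal_function_label(.data$ccr),
      label = ifelse(
        is.na(.data$dose), NA_character_,
        sprintf("%g mg q%gh", .data$dose, .data$interval)
      )
    ) |>
    dplyr::select("ccr", "renal_function", "dose", "interval",
                  "joint_pct", "label")
  class(out) <- c("amik_nomogram", class(out))
  attr(out, "mic") <- mic
  attr(out, "pta_threshold") <- pta_threshold
  attr(out, "fta_threshold") <- fta_threshold
  out
}

# Display labels for CCr decades (mL/min).
renal_function_label <- function(ccr) {
  dplyr::case_when(
    ccr < 30 ~ "Kidney failure",
    ccr < 50 ~ "Severe impairment",
    ccr < 70 ~ "Moderate impairment",
    ccr < 90 ~ "Mild impairment",
    TRUE ~ "Normal"
  )
}

#' Render a nomogram as a Markdown table
#'
#' @param x An `amik_nomogram`.
#' @param ... Unused.
#' @return A character vector of Markdown lines (invisibly printed by
#'   `print()`).
#' @export
format.amik_nomogram <- function(x, ...) {
  lines <- c(
    sprintf(
      "| Renal function | CCr (mL/min) | Recommended regimen (MIC %g mg/L) |",
      attr(x, "mic")
    ),
    "|---|---|---|",
    sprintf(
      "| %s | %g | %s |",
      x$renal_function, x$ccr,
      ifelse(is.na(x$label), "NA", x$label)
    )
  )
  lines
}

#' @export
print.amik_nomogram <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a nomogram (or any result tibble) to CSV
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}
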