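#' Read a plate-reader run and its layout
#'
#' Reads a long-format run CSV (`well,time_min,channel,value`) and a layout
#' CSV (`well,strain,role,replicate`), validates them, and joins them into
#' one long tibble, one row per (well, timepoint, channel). Roles are
#' `test`, `control`, or `blank`; blank wells carry no strain.
#'
#' @param run_file Path to the run CSV.
#' @param layout_file Path to the layout CSV.
#' @param plate_id Plate identifier attached to every row; defaults to the
#'   run file name without extension.
#' @param sampling_tolerance Maximal relative deviation of sampling
#'   intervals from their median before a warning is raised (default 5%).
#' @return A tibble with columns `plate`, `well`, `strain`, `role`,
#'   `replicate`, `time_min`, `channel`, `value`, time-sorted within well.
#' @export
read_plate <- function(run_file, layout_file, plate_id = NULL,
                       sampling_tolerance = 0.05) {
  run <- readr::read_csv(run_file, show_col_types = FALSE,
                         col_types = readr::cols(
                           well = readr::col_character(),
                           time_min = readr::col_double(),
                           channel = readr::col_character(),
                           value = readr::col_double()))
  layout <- readr::read_csv(layout_file, show_col_types = FALSE,
                            col_types = readr::cols(
                              well = readr::col_character(),
                              strain = readr::col_character(),
                              role = readr::col_character(),
                              replicate = readr::col_integer()))
  if (is.null(plate_id)) {
    plate_id <- sub("\\.[^.]*$", "", basename(run_file))
  }
  join_plate(run, layout, plate_id, sampling_tolerance)
}

#' Assemble a plate tibble from in-memory run and layout tables
#'
#' Same validation and joining as [read_plate()], for data already in R
#' (e.g. straight from [generate_plate()]).
#'
#' @param run Tibble with columns `well`, `time_min`, `channel`, `value`.
#' @param layout Tibble with columns `well`, `strain`, `role`, `replicate`.
#' @inheritParams read_plate
#' @return See [read_plate()].
#' @export
join_plate <- function(run, layout, plate_id = "plate1",
                       sampling_tolerance = 0.05) {
  need <- c("well", "time_min", "channel", "value")
  if (!all(need %in% names(run))) {
    stop("run table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  needl <- c("well", "strain", "role", "replicate")
  if (!all(needl %in% names(layout))) {
    stop("layout table must have columns ", paste(needl, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(layout$role), c("test", "control", "blank"))
  if (length(bad_role)) {
    stop("unknown roles in layout: ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(layout$well)) {
    stop("layout assigns some wells more than once", call. = FALSE)
  }
  dup <- duplicated(run[c("well", "time_min", "channel")])
  if (any(dup)) {
    stop("duplicate (well, time, channel) rows in run data, e.g. well ",
         run$well[dup][1], " at t = ", run$time_min[dup][1], call. = FALSE)
  }
  missing_layout <- setdiff(unique(run$well), layout$well)
  if (length(missing_layout)) {
    stop("wells present in run data but missing from layout: ",
         paste(utils::head(missing_layout, 5), collapse = ", "), call. = FALSE)
  }
  missing_data <- setdiff(layout$well, unique(run$well))
  if (length(missing_data)) {
    warning("layout wells with no data: ",
            paste(missing_data, collapse = ", "), call. = FALSE)
  }
  plate <- dplyr::inner_join(run, layout, by = "well") |>
    dplyr::mutate(plate = plate_id, .before = 1) |>
    dplyr::arrange(.data$well, .data$channel, .data$time_min) |>
    dplyr::select("plate", "well", "strain", "role", "replicate",
                  "time_min", "channel", "value") |>
    tibble::as_tibble()
  # uniform sampling check, per well and channel
  gaps <- plate |>
    dplyr::group_by(.data$well, .data$channel) |>
    dplyr::summarise(dev = {
      d <- diff(.data$time_min)
      if (length(d) < 2) 0 else max(abs(d - stats::median(d))) / stats::median(d)
    }, .groups = "drop")
  if (any(gaps$dev > sampling_tolerance)) {
    warning("non-uniform sampling beyond ",
            round(100 * sampling_tolerance), "% tolerance in well(s) ",
            paste(utils::head(unique(gaps$well[gaps$dev > sampling_tolerance]), 5),
                  collapse = ", "),
            "; no resampling is performed", call. = FALSE)
  }
  plate
}

#' Subtract the media-blank background
#'
#' At each timepoint and channel, the mean over all blank wells is
#' subtracted from every well on the plate (blanks included, whose values
#' become residuals around zero).
#'
#' @param plate A plate tibble from [read_plate()] / [join_plate()].
#' @return The plate tibble with background-corrected `value`s.
#' @export
subtract_blanks <- function(plate) {
  if (!any(plate$role == "blank")) {
    stop("plate has no blank wells; cannot subtract background", call. = FALSE)
  }
  blanks <- plate |>
    dplyr::filter(.data$role == "blank") |>
    dplyr::group_by(.data$plate, .data$time_min, .data$channel) |>
    dplyr::summarise(blank_mean = mean(.data$value), .groups = "drop")
  plate |>
    dplyr::left_join(blanks, by = c("plate", "time_min", "channel")) |>
    dplyr::mutate(value = .data$value - .data$blank_mean) |>
    dplyr::select(-"blank_mean")
}

#' Align per-replicate baselines within each strain
#'
#' For every strain and channel, each replicate well is additively shifted
#' so that its mean over the first `baseline_minutes` of measurements
#' matches the grand mean of those first-window means across the strain's
#' replicates. This removes well-to-well background offsets without
#' changing the strain-level mean. Blank wells and single-replicate strains
#' are left unchanged.
#'
#' @param plate A plate tibble (normally after [subtract_blanks()]).
#' @param baseline_minutes Length of the initial baseline window
#'   (default 60, the first hour).
#' @return The plate tibble with aligned `value`s.
#' @export
align_baselines <- function(plate, baseline_minutes = 60) {
  if (min(plate$time_min) + baseline_minutes > max(plate$time_min)) {
    stop("series shorter than the ", baseline_minutes,
         "-minute baseline window", call. = FALSE)
  }
  t0 <- min(plate$time_min)
  shifts <- plate |>
    dplyr::filter(.data$role != "blank",
                  .data$time_min <= t0 + baseline_minutes) |>
    dplyr::group_by(.data$plate, .data$strain, .data$channel, .data$well) |>
    dplyr::summarise(well_mean = mean(.data$value), .groups = "drop_last") |>
    dplyr::mutate(shift = mean(.data$well_mean) - .data$well_mean) |>
    dplyr::ungroup() |>
    dplyr::select("plate", "well", "channel", "shift")
  plate |>
    dplyr::left_join(shifts, by = c("plate", "well", "channel")) |>
    dplyr::mutate(value = .data$value +
                    dplyr::coalesce(.data$shift, 0)) |>
    dplyr::select(-"shift")
}
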