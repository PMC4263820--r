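# broom-style tidiers and ggplot2 methods for creep runs.

#' Tidy a creep run
#'
#' Long-format view of the metric time series: one row per (time, metric).
#'
#' @param x A `creep_run`.
#' @param ... Unused.
#' @return A tibble with columns `case`, `time`, `hold_time`, `metric`,
#'   `value`.
#' @export
tidy.creep_run <- function(x, ...) {
  x$series |>
    pivot_longer(-c("time", "hold_time"), names_to = "metric",
                 values_to = "value") |>
    mutate(case = x$case, .before = 1L)
}

#' One-row summary of a creep run
#'
#' The headline quantities of a run: end-of-ramp and end-of-hold femoral
#' displacement and their percent increase, total contact areas, meniscus-path
#' and medial load shares, condyle-centre fluid support ratio, peak tibial
#' compressive stress, and the worst conservation error.
#'
#' @param x A `creep_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.creep_run <- function(x, ...) {
  s <- x$series
  ramp <- s[1L, ]
  end <- s[nrow(s), ]
  part_ramp <- interface_load_partition(x, ramp$time)
  part_end <- interface_load_partition(x, end$time)
  fsr <- x$probes |>
    filter(startsWith(.data$probe, "condyle_centre"),
           !is.na(.data$fluid_support_ratio)) |>
    group_by(.data$time) |>
    summarise(fsr = mean(.data$fluid_support_ratio), .groups = "drop")
  tibble(
    case = x$case,
    displacement_ramp_mm = ramp$displacement_mm,
    displacement_end_mm = end$displacement_mm,
    creep_increase_pct = creep_increase_pct(ramp$displacement_mm,
                                            end$displacement_mm),
    area_ramp_mm2 = ramp$area_total_mm2,
    area_end_mm2 = end$area_total_mm2,
    meniscus_share_ramp = part_ramp$meniscus_share,
    meniscus_share_end = part_end$meniscus_share,
    medial_share_ramp = part_ramp$medial_share,
    fsr_condyle_ramp = if (nrow(fsr)) first(fsr$fsr) else NA_real_,
    fsr_condyle_end = if (nrow(fsr)) last(fsr$fsr) else NA_real_,
    peak_stress_ramp_MPa = ramp$peak_stress_tibial_MPa,
    peak_stress_end_MPa = end$peak_stress_tibial_MPa,
    conservation_max_rel_err = max(s$conservation_rel_err),
    free_travel_mm = x$free_travel
  )
}

#' Plot a creep run
#'
#' Four-panel overview: femoral settlement, total contact area, interface
#' load partition and compartment split over (log) time.
#'
#' @param object A `creep_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.creep_run <- function(object, ...) {
  s <- object$series
  keep <- c(displacement_mm = "displacement [mm]",
            area_total_mm2 = "contact area [mm²]",
            force_meniscus_path_N = "meniscus-path force [N]",
            force_direct_N = "direct force [N]",
            force_medial_N = "medial force [N]",
            force_lateral_N = "lateral force [N]")
  d <- s |>
    select("time", all_of(names(keep))) |>
    pivot_longer(-"time", names_to = "metric", values_to = "value") |>
    mutate(metric = keep[.data$metric])
  ggplot(d, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.6) +
    scale_x_log10() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "time [s]", y = NULL,
         title = paste0("Creep response (", object$case, ")")) +
    theme_bw()
}

#' Plot the interface load partition over time
#'
#' @param run A `creep_run`.
#' @return A ggplot object.
#' @export
plot_load_partition <- function(run) {
  s <- run$series |>
    select("time", meniscus_path = "force_meniscus_path_N",
           direct = "force_direct_N") |>
    pivot_longer(-"time", names_to = "interface", values_to = "force_N")
  ggplot(s, aes(.data$time, .data$force_N, colour = .data$interface)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "time [s]", y = "transmitted force [N]",
         colour = "interface") +
    theme_bw()
}

#' Plot probe fluid support ratios over time
#'
#' @param run A `creep_run`.
#' @return A ggplot object.
#' @export
plot_fluid_support <- function(run) {
  d <- run$probes |> filter(!is.na(.data$fluid_support_ratio))
  ggplot(d, aes(.data$time, .data$fluid_support_ratio,
                colour = .data$probe)) +
    geom_line() +
    geom_point(size = 0.6) +
    scale_x_log10() +
    labs(x = "time [s]", y = "fluid support ratio", colour = "probe") +
    theme_bw()
}
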