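#' @title Foraging success and efficiency metrics
#' @name foraging_metrics
#' @description
#' Per-dive success is Bernoulli: 1 when the dive holds at least one
#' capture event. Two efficiency indices are computed per dive: the
#' Foraging Efficiency Index (FEI, captures per unit total VeDBA) and
#' Dive Efficiency (DE, captures per second of dive). Both are
#' log-transformed on successful dives only (log of zero is undefined;
#' the untransformed zero-inflated columns are always exported too).
#' Group summaries use the animal as the sampling unit: per-animal means
#' first, then mean and SE across animals.
NULL

#' Score dives with capture counts, success and efficiency indices
#'
#' @param dives Typed dive table (after [classify_all()] and
#'   [per_dive_vedba()]).
#' @param events Capture events from [consolidate_events()] (or truth
#'   events with a `dive_idx` column).
#' @param animal_id,colony,sex Metadata labels attached to every row.
#' @param predator_context Optional per-dive context label
#'   (none/seabirds/multi); NA when no video context exists.
#' @return A `dive_metrics` data frame, one row per dive.
#' @export
score_dives <- function(dives, events, animal_id = "animal1",
                        colony = NA_character_, sex = NA_character_,
                        predator_context = NA_character_) {
  nc <- tabulate(factor(events$dive_idx, levels = dives$index),
                 nbins = nrow(dives))
  out <- data.frame(
    animal_id = animal_id, colony = colony, sex = sex,
    dive_index = dives$index,
    type = if (!is.null(dives$type)) dives$type else NA_character_,
    max_depth_m = dives$max_depth_m,
    duration_s = dives$duration_s,
    bottom_s = if (!is.null(dives$bottom_s)) dives$bottom_s else NA_real_,
    total_vedba = if (!is.null(dives$total_vedba)) dives$total_vedba
      else NA_real_,
    mean_vedba = if (!is.null(dives$mean_vedba)) dives$mean_vedba
      else NA_real_,
    n_captures = nc,
    success = as.integer(nc >= 1),
    predator_context = predator_context)
  out$fei <- ifelse(is.na(out$total_vedba), NA_real_,
                    nc / out$total_vedba)
  out$de <- nc / out$duration_s
  out$log_fei <- ifelse(nc >= 1 & !is.na(out$fei), log(out$fei), NA_real_)
  out$log_de <- ifelse(nc >= 1, log(out$de), NA_real_)
  class(out) <- c("dive_metrics", "data.frame")
  out
}

#' Capture rates and success fractions by group
#'
#' Means are computed per animal first; the reported mean and SE are taken
#' across animals (the animal is the sampling unit, respecting repeated
#' measures within birds).
#'
#' @param metrics A `dive_metrics` table (possibly several animals bound
#'   together).
#' @param by Grouping column(s), default `"type"`.
#' @return data.frame with per-group `n_animals`, `n_dives`,
#'   `capture_rate` (mean captures/dive), `capture_rate_se`,
#'   `pct_successful`, `pct_successful_se`.
#' @export
capture_rates <- function(metrics, by = "type") {
  dt <- data.table::as.data.table(metrics)
  per_animal <- dt[, .(rate = mean(n_captures), succ = mean(success),
                       nd = .N),
                   by = c(by, "animal_id")]
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  out <- per_animal[, .(n_animals = .N, n_dives = sum(nd),
                        capture_rate = mean(rate),
                        capture_rate_se = se(rate),
                        pct_successful = 100 * mean(succ),
                        pct_successful_se = 100 * se(succ)),
                    by = by]
  as.data.frame(out)
}

#' Correlation between capture depth and host-dive maximum depth
#'
#' @param events Capture events with `dive_idx` and `depth_m`.
#' @param dives Typed dive table.
#' @param type Dive type to restrict to (default benthic).
#' @return Pearson correlation coefficient.
#' @export
capture_depth_correlation <- function(events, dives, type = "benthic") {
  sel <- dives[!is.null(dives$type) & dives$type == type, , drop = FALSE]
  ev <- events[events$dive_idx %in% sel$index, , drop = FALSE]
  if (nrow(ev) < 3)
    stop(sprintf("insufficient data: %d %s capture events (need >= 3)",
                 nrow(ev), type))
  maxd <- sel$max_depth_m[match(ev$dive_idx, sel$index)]
  cor(ev$depth_m, maxd)
}

#' Grouped dive and foraging summary table
#'
#' One row per colony x sex x dive type with dive counts, total prey,
#' percent successful dives, mean capture depth, mean bottom time,
#' per-animal-mean capture rate, and mean/total VeDBA.
#'
#' @param metrics A `dive_metrics` table.
#' @param events Capture events (for mean capture depth); may be NULL.
#' @param by Grouping columns.
#' @return data.frame summary.
#' @export
summary_table <- function(metrics, events = NULL,
                          by = c("colony", "sex", "type")) {
  by <- intersect(by, names(metrics))
  dt <- data.table::as.data.table(metrics)
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  pa <- dt[, .(rate = mean(n_captures)), by = c(by, "animal_id")]
  rates <- pa[, .(capture_rate = mean(rate), capture_rate_se = se(rate)),
              by = by]
  base <- dt[, .(n_dives = .N, total_prey = sum(n_captures),
                 pct_successful = 100 * mean(success),
                 mean_bottom_time_s = mean(bottom_s, na.rm = TRUE),
                 mean_vedba_g = mean(mean_vedba, na.rm = TRUE),
                 total_vedba_g = mean(total_vedba, na.rm = TRUE)),
             by = by]
  out <- merge(base, rates, by = by, sort = TRUE)
  if (!is.null(events) && nrow(events) > 0) {
    key <- dt[, c(by, "dive_index", "animal_id"), with = FALSE]
    evd <- data.table::as.data.table(events)
    if (!("animal_id" %in% names(evd)))
      evd$animal_id <- metrics$animal_id[1]
    evd <- merge(evd, key,
                 by.x = c("dive_idx", "animal_id"),
                 by.y = c("dive_index", "animal_id"))
    cd <- evd[, .(mean_capture_depth_m = mean(depth_m)), by = by]
    out <- merge(out, cd, by = by, all.x = TRUE)
  } else {
    out$mean_capture_depth_m <- NA_real_
  }
  as.data.frame(out)
}

#' Export the model-ready per-dive table
#'
#' One row per non-excluded dive with the response columns (`success`,
#' `n_captures`, `fei`, `de`, `log_fei`, `log_de`) and predictors
#' (`animal_id`, `colony`, `sex`, `type`, `max_depth_m`, `duration_s`,
#' `predator_context`), ready for external mixed-model software.
#'
#' @param metrics A `dive_metrics` table.
#' @param path Optional CSV output path.
#' @return The exported data frame (invisibly when `path` is given).
#' @export
export_model_table <- function(metrics, path = NULL) {
  keep <- is.na(metrics$type) | metrics$type %in% c("benthic", "pelagic")
  cols <- c("animal_id", "colony", "sex", "type", "max_depth_m",
            "duration_s", "predator_context", "success", "n_captures",
            "fei", "de", "log_fei", "log_de")
  out <- as.data.frame(metrics)[keep, cols]
  rownames(out) <- NULL
  if (!is.null(path)) {
    data.table::fwrite(out, path)
    return(invisible(out))
  }
  out
}
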