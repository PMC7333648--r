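#' @title Acceleration processing and VeDBA
#' @name accel_processing
#' @description
#' Tri-axial acceleration records are data frames with columns `time`
#' (POSIXct, 25 Hz nominal) and `ax_g`, `ay_g`, `az_g` (surge, heave,
#' sway, in g). The static (gravitational/postural) component is a 1 s
#' centred running mean per axis; the dynamic component is raw minus
#' static. VeDBA is the per-sample Euclidean norm of the three dynamic
#' axes and serves as a whole-body activity proxy.
NULL

.centred_running_mean <- function(x, w) {
  # shrinking windows at the record boundaries
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(1, seq_len(n) - h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Split raw acceleration into static and dynamic components
#'
#' @param accel Acceleration data frame (`time`, `ax_g`, `ay_g`, `az_g`).
#' @param window_s Running-mean window in seconds (default 1).
#' @param sample_hz Sampling rate; inferred from timestamps when NULL.
#' @return An `accel_derived` list: `time`, `static` and `dynamic`
#'   (n x 3 matrices), `sample_hz`.
#' @export
split_static_dynamic <- function(accel, window_s = 1, sample_hz = NULL) {
  stopifnot(is.data.frame(accel),
            all(c("time", "ax_g", "ay_g", "az_g") %in% names(accel)))
  if (is.null(sample_hz)) {
    dt <- median(diff(as.numeric(accel$time)))
    sample_hz <- 1 / dt
  }
  w <- as.integer(round(window_s * sample_hz))
  if (w < 3)
    stop("running-mean window must span at least 3 samples; got ", w)
  raw <- as.matrix(accel[, c("ax_g", "ay_g", "az_g")])
  static <- apply(raw, 2, .centred_running_mean, w = w)
  structure(list(time = accel$time, static = static,
                 dynamic = raw - static, sample_hz = sample_hz),
            class = "accel_derived")
}

#' Vectorial dynamic body acceleration
#'
#' `VeDBA = sqrt(x_dyn^2 + y_dyn^2 + z_dyn^2)` per sample.
#'
#' @param dynamic n x 3 matrix of dynamic acceleration (g), or an
#'   `accel_derived` object.
#' @return Numeric vector of per-sample VeDBA (g). When given an
#'   `accel_derived`, the object is returned with a `vedba` element added.
#' @export
compute_vedba <- function(dynamic) {
  if (inherits(dynamic, "accel_derived")) {
    dynamic$vedba <- compute_vedba(dynamic$dynamic)
    return(dynamic)
  }
  if (is.data.frame(dynamic)) dynamic <- as.matrix(dynamic)
  if (!is.matrix(dynamic) || ncol(dynamic) != 3)
    stop("dynamic acceleration must have exactly 3 aligned axes")
  sqrt(rowSums(dynamic^2))
}

#' Per-dive VeDBA totals
#'
#' Sums (and averages) per-sample VeDBA over each dive window. Dives with
#' no acceleration samples are flagged `missing_effort` and retained.
#'
#' @param dives A `dive_table`.
#' @param derived An `accel_derived` with a `vedba` element, or a data
#'   frame with columns `time`, `vedba_g`.
#' @return The dive table with `total_vedba`, `mean_vedba`,
#'   `missing_effort` columns.
#' @export
per_dive_vedba <- function(dives, derived) {
  if (inherits(derived, "accel_derived")) {
    if (is.null(derived$vedba))
      stop("run compute_vedba() on the accel_derived first")
    vt <- as.numeric(derived$time)
    vv <- derived$vedba
  } else {
    vt <- as.numeric(derived$time)
    vv <- derived$vedba_g
  }
  cs <- cumsum(c(0, vv))
  # number of samples with time < t, via binary search on the sorted clock;
  # 0.1 ms slack absorbs POSIXct floating-point noise (~1e-7 s) while
  # staying far below any realistic sampling interval
  i0 <- findInterval(as.numeric(dives$start) - 1e-4, vt)
  i1 <- findInterval(as.numeric(dives$end) - 1e-4, vt)
  nsamp <- i1 - i0
  tot <- cs[i1 + 1] - cs[i0 + 1]
  dives$total_vedba <- ifelse(nsamp > 0, tot, NA_real_)
  dives$mean_vedba <- ifelse(nsamp > 0, tot / nsamp, NA_real_)
  dives$missing_effort <- nsamp <= 0
  dives
}
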