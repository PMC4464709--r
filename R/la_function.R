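#' Left-atrial time-volume curve
#'
#' A tibble (`frame`, `time_ms`, `volume_ml`, `complete`) covering one full
#' cardiac cycle, the substrate for the LA functional indices. Times must be
#' strictly increasing and volumes positive. The curve is treated as
#' periodic: indices are invariant to rotating the starting frame.
#'
#' @param frames integer frame indices.
#' @param times frame times, ms, strictly increasing.
#' @param volumes LA volumes, ml, positive.
#' @param rr_ms cardiac cycle length, ms (default: span implied by frames).
#' @param complete logical flag per frame (contours present on all planes).
#' @return a tibble of class `la_tv_curve`.
#' @export
tv_curve <- function(frames, times, volumes, rr_ms = NULL, complete = TRUE) {
  if (any(diff(times) <= 0))
    abort("times must be strictly increasing", class = "atriarecon_curve_error")
  if (any(volumes <= 0))
    abort("volumes must be positive", class = "atriarecon_curve_error")
  if (is.null(rr_ms)) rr_ms <- length(frames) * mean(diff(times))
  x <- tibble(frame = as.integer(frames), time_ms = as.numeric(times),
              volume_ml = as.numeric(volumes),
              complete = rep_len(complete, length(frames)))
  structure(x, rr_ms = rr_ms, class = c("la_tv_curve", class(x)))
}

#' Locate the cardiac phase landmarks on a time-volume curve
#'
#' Finds the frames of maximal volume (end of atrial filling), minimal
#' volume (end of atrial contraction, after the maximum in cyclic order) and
#' the pre-contraction volume. The pre-contraction frame separates passive
#' emptying (early, conduit) from active emptying (late, booster pump): when
#' not supplied it is taken as the flattest point of the curve (minimal
#' |dV/dt|, central differences on the periodic curve) strictly between the
#' maximum and the minimum, excluding the two frames adjacent to either
#' endpoint. When no atrial contraction exists the pre-contraction frame may
#' coincide with the minimum (pass `pre_a_frame = NA`).
#'
#' @param curve a [tv_curve()] with at least 8 frames.
#' @param pre_a_frame optional frame index overriding the heuristic; `NA`
#'   encodes "no atrial contraction" (pre-contraction = minimum).
#' @return a list `i_max`, `i_min`, `i_pre_a` (frame values), plus
#'   `confidence` (`"ok"` or `"low"` when the curve has no clear shoulder).
#' @export
locate_phases <- function(curve, pre_a_frame = NULL) {
  stopifnot(inherits(curve, "la_tv_curve"))
  v <- curve$volume_ml
  n <- length(v)
  if (n < 8) abort("need at least 8 frames", class = "atriarecon_curve_error")
  if ((max(v) - min(v)) < 0.01 * mean(v))
    abort("no cardiac variation in the volume curve",
          class = "atriarecon_curve_error")
  i_max <- which.max(v)
  i_min <- which.min(v)

  if (!is.null(pre_a_frame) && !is.na(pre_a_frame)) {
    i_pre <- match(pre_a_frame, curve$frame)
    if (is.na(i_pre)) abort("pre_a_frame not in curve", class = "atriarecon_curve_error")
    return(list(i_max = curve$frame[i_max], i_min = curve$frame[i_min],
                i_pre_a = curve$frame[i_pre], confidence = "ok"))
  }
  if (!is.null(pre_a_frame) && is.na(pre_a_frame)) {
    return(list(i_max = curve$frame[i_max], i_min = curve$frame[i_min],
                i_pre_a = curve$frame[i_min], confidence = "ok"))
  }

  # cyclic interior of (i_max .. i_min), excluding 2 frames at each end
  span <- (i_min - i_max) %% n
  if (span < 5) {
    return(list(i_max = curve$frame[i_max], i_min = curve$frame[i_min],
                i_pre_a = curve$frame[i_min], confidence = "low"))
  }
  interior <- ((i_max - 1 + 2:(span - 2)) %% n) + 1
  slope <- (v[(seq_len(n)) %% n + 1] - v[(seq_len(n) - 2) %% n + 1]) / 2
  i_pre <- interior[which.min(abs(slope[interior]))]
  conf <- if (min(abs(slope[interior])) > 0.25 * max(abs(slope[interior]))) "low" else "ok"
  list(i_max = curve$frame[i_max], i_min = curve$frame[i_min],
       i_pre_a = curve$frame[i_pre], confidence = conf)
}

#' Functional indices from printed or prescribed landmark volumes
#'
#' Direct evaluation of the LA functional-index formulas from the three
#' landmark volumes (and optionally the LV stroke volume), without a curve:
#' total emptying (conduit) volume `v_max - v_min`, passive emptying
#' `v_max - v_pre_a`, active emptying `v_pre_a - v_min`, total emptying
#' fraction `100 * total / v_max`, passive/active fractions as percent of
#' total emptying, and "passive LA flow" `lv_sv - total_emptying`. A missing
#' pre-contraction volume (`NA`) encodes absent atrial contraction: passive
#' emptying equals total emptying and the passive fraction is 100%.
#'
#' @param v_max,v_min maximal and minimal LA volume, ml.
#' @param v_pre_a pre-contraction LA volume, ml, or `NA`.
#' @param lv_sv LV stroke volume, ml (optional).
#' @param t_max,t_pre_a,t_min optional phase times, ms, enabling the mean
#'   passive filling / active contraction rates (ml/ms).
#' @return an object of class `la_indices` (see [tidy.la_indices()]).
#' @examples
#' la_indices_from_volumes(82.6, 43.6, 64.4, lv_sv = 104)
#' @export
la_indices_from_volumes <- function(v_max, v_min, v_pre_a = NA, lv_sv = NULL,
                                    t_max = NA, t_pre_a = NA, t_min = NA) {
  if (v_min > v_max) abort("v_min exceeds v_max", class = "atriarecon_curve_error")
  no_contraction <- is.na(v_pre_a)
  if (no_contraction) v_pre_a <- v_min
  if (v_pre_a < v_min || v_pre_a > v_max)
    abort("v_pre_a must lie between v_min and v_max", class = "atriarecon_curve_error")
  total <- v_max - v_min
  passive <- v_max - v_pre_a
  active <- v_pre_a - v_min
  dur_p <- (t_pre_a - t_max)
  dur_a <- (t_min - t_pre_a)
  structure(list(
    v_max = v_max, v_min = v_min,
    v_pre_a = if (no_contraction) NA_real_ else v_pre_a,
    total_emptying = total,
    passive_emptying = passive,
    active_emptying = active,
    total_ef = 100 * total / v_max,
    passive_fraction = 100 * passive / total,
    active_fraction = 100 * active / total,
    passive_rate = if (is.na(dur_p) || dur_p <= 0) NA_real_ else passive / dur_p,
    active_rate = if (no_contraction || is.na(dur_a) || dur_a <= 0) NA_real_ else active / dur_a,
    lv_sv = if (is.null(lv_sv)) NA_real_ else lv_sv,
    passive_la_flow = if (is.null(lv_sv)) NA_real_ else lv_sv - total,
    no_contraction = no_contraction
  ), class = "la_indices")
}

#' Left-atrial functional indices from a time-volume curve
#'
#' Locates the phase landmarks with [locate_phases()] and evaluates the
#' index formulas of [la_indices_from_volumes()], including the mean passive
#' filling and active contraction rates (phase volume over phase duration,
#' ml/ms). Rates of an absent phase are `NA`.
#'
#' @param curve a [tv_curve()].
#' @param pre_a_frame optional pre-contraction frame (`NA`: no contraction).
#' @param lv_sv LV stroke volume, ml (optional; enables "passive LA flow").
#' @return an object of class `la_indices`.
#' @export
la_indices <- function(curve, pre_a_frame = NULL, lv_sv = NULL) {
  ph <- locate_phases(curve, pre_a_frame = pre_a_frame)
  at <- function(f) which(curve$frame == f)
  v <- curve$volume_ml; t <- curve$time_ms
  rr <- attr(curve, "rr_ms")
  # phase durations on the periodic curve
  dt_cyc <- function(f0, f1) (t[at(f1)] - t[at(f0)]) %% rr
  no_con <- ph$i_pre_a == ph$i_min
  out <- la_indices_from_volumes(
    v_max = v[at(ph$i_max)], v_min = v[at(ph$i_min)],
    v_pre_a = if (no_con) NA else v[at(ph$i_pre_a)],
    lv_sv = lv_sv)
  dp <- dt_cyc(ph$i_max, ph$i_pre_a)
  da <- dt_cyc(ph$i_pre_a, ph$i_min)
  if (dp > 0) out$passive_rate <- out$passive_emptying / dp
  if (!no_con && da > 0) out$active_rate <- out$active_emptying / da
  out$phases <- ph
  out
}

#' @export
print.la_indices <- function(x, ...) {
  cat("<la_indices>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an `la_indices` object
#'
#' @param x an `la_indices` object.
#' @param ... unused.
#' @return a tibble with columns `index`, `value`, `unit`.
#' @export
tidy.la_indices <- function(x, ...) {
  tibble(
    index = c("LA max volume", "LA min volume", "LA pre-contraction volume",
              "Total conduit volume", "Passive emptying volume",
              "Active emptying volume", "Total LA EF",
              "Passive emptying fraction", "Active emptying fraction",
              "Passive LA filling rate", "Active LA contraction rate",
              "LV stroke volume", "Passive LA flow"),
    value = c(x$v_max, x$v_min, x$v_pre_a, x$total_emptying,
              x$passive_emptying, x$active_emptying, x$total_ef,
              x$passive_fraction, x$active_fraction, x$passive_rate,
              x$active_rate, x$lv_sv, x$passive_la_flow),
    unit = c("ml", "ml", "ml", "ml", "ml", "ml", "%", "%", "%",
             "ml/ms", "ml/ms", "ml", "ml")
  )
}

#' One-row summary of an `la_indices` object
#'
#' @param x an `la_indices` object.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.la_indices <- function(x, ...) {
  tibble(v_max = x$v_max, v_min = x$v_min, v_pre_a = x$v_pre_a,
         total_emptying = x$total_emptying, total_ef = x$total_ef,
         passive_fraction = x$passive_fraction,
         active_fraction = x$active_fraction,
         passive_la_flow = x$passive_la_flow)
}

#' Plot a left-atrial time-volume curve
#'
#' @param object a [tv_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.la_tv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$volume_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$complete), show.legend = FALSE) +
    ggplot2::labs(x = "time (ms)", y = "LA volume (ml)") +
    ggplot2::theme_minimal()
}
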