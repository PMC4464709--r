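#' Bland-Altman agreement analysis
#'
#' Agreement between a measurement and a reference: mean and SD of the
#' paired differences `a - b`, limits of agreement at mean ± 2 SD (the
#' convention used on the package's plots), percent differences relative to
#' the pairwise mean `(a + b) / 2`, and the linear regression of `a` on `b`.
#'
#' @param a measured values.
#' @param b reference values (same length, same units).
#' @return an object of class `bland_altman`; see [glance.bland_altman()].
#' @examples
#' ba <- bland_altman(c(51.0, 45.7, 55.3), c(54, 51, 61))
#' glance(ba)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    abort("a and b must have equal length", class = "atriarecon_stats_error")
  n <- length(a)
  if (n < 2) abort("need at least 2 pairs", class = "atriarecon_stats_error")
  d <- a - b
  pct <- 100 * d / ((a + b) / 2)
  fit <- lm(a ~ b)
  # summary.lm warns on an exact fit (identical series); r2 = 1 is correct
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    a = a, b = b, n = n,
    mean_diff = mean(d), sd_diff = sd(d),
    loa_low = mean(d) - 2 * sd(d), loa_high = mean(d) + 2 * sd(d),
    mean_pct_diff = mean(pct), sd_pct_diff = sd(pct),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), r2 = r2
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d: %.2f +/- %.2f (%.1f%% +/- %.1f%%), r2 = %.3f\n",
              x$n, x$mean_diff, x$sd_diff, x$mean_pct_diff, x$sd_pct_diff, x$r2))
  invisible(x)
}

#' One-row summary of a Bland-Altman analysis
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         mean_pct_diff = x$mean_pct_diff, sd_pct_diff = x$sd_pct_diff,
         slope = x$slope, intercept = x$intercept, r2 = x$r2)
}

#' Per-pair Bland-Altman table
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return a tibble with `mean`, `diff`, `pct_diff` per pair.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(a = x$a, b = x$b, mean = (x$a + x$b) / 2, diff = x$a - x$b,
         pct_diff = 100 * (x$a - x$b) / ((x$a + x$b) / 2))
}

#' Bland-Altman plot
#'
#' @param object a [bland_altman()] object.
#' @param ... unused.
#' @return a ggplot: differences vs pairwise means, solid mean line and
#'   dashed ± 2 SD limits.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "pairwise mean", y = "difference") +
    ggplot2::theme_minimal()
}

#' Paired t-test on two measurement series
#'
#' Thin wrapper around [stats::t.test()] (paired, two-sided) returning the
#' statistic, degrees of freedom and p-value. Zero-variance differences are
#' flagged as an error (undefined t).
#'
#' @param a,b paired measurements.
#' @return a list `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    abort("a and b must have equal length", class = "atriarecon_stats_error")
  d <- a - b
  if (sd(d) < 1e-12)
    abort("zero-variance differences: paired t undefined",
          class = "atriarecon_stats_error")
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-way repeated-measures ANOVA on a complete 2x2 within-subject design
#'
#' Fits `value ~ a * m + Error(subject/(a * m))` with [stats::aov()] and
#' extracts the within-subject main effects and the interaction. For the
#' 2x2 case the interaction test is algebraically identical to a paired
#' t-test on the per-subject double difference, which serves as the
#' independent oracle in the test-suite.
#'
#' @param data a data frame.
#' @param subject,a,m,value column names (strings) for subject id, the two
#'   within factors and the response. Defaults `"subject"`, `"alignment"`,
#'   `"method"`, `"value"`.
#' @return a list with `F_interaction`, `df_interaction`, `p_interaction`
#'   and a tibble `effects` of all within-subject effects.
#' @export
rm_anova_2x2 <- function(data, subject = "subject", a = "alignment",
                         m = "method", value = "value") {
  df <- data.frame(
    subject = factor(data[[subject]]),
    a = factor(data[[a]]),
    m = factor(data[[m]]),
    value = as.numeric(data[[value]])
  )
  if (nlevels(df$a) != 2 || nlevels(df$m) != 2)
    abort("both within factors must have exactly 2 levels",
          class = "atriarecon_stats_error")
  counts <- table(df$subject, df$a, df$m)
  if (any(counts != 1))
    abort("design must be complete: one value per subject x cell",
          class = "atriarecon_stats_error")
  if (nlevels(df$subject) < 3)
    abort("need at least 3 subjects", class = "atriarecon_stats_error")
  fit <- aov(value ~ a * m + Error(subject / (a * m)), data = df)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- which(trimws(rownames(tab)) == term)
    out <- c(F = tab[i, "F value"], df1 = tab[i, "Df"], p = tab[i, "Pr(>F)"])
    if (tab[i, "Sum Sq"] < 1e-12) { # identically zero effect: F = 0 by convention
      out["F"] <- 0; out["p"] <- 1
    }
    out
  }
  ia <- pull("Error: subject:a:m", "a:m")
  ea <- pull("Error: subject:a", "a")
  em <- pull("Error: subject:m", "m")
  list(
    F_interaction = unname(ia["F"]),
    df_interaction = c(unname(ia["df1"]), nlevels(df$subject) - 1),
    p_interaction = unname(ia["p"]),
    effects = tibble(
      term = c(sprintf("%s", a), sprintf("%s", m), sprintf("%s:%s", a, m)),
      F = unname(c(ea["F"], em["F"], ia["F"])),
      p = unname(c(ea["p"], em["p"], ia["p"])))
  )
}

#' Endocardial border sharpness of a chamber wall
#'
#' Casts 8 rays at 45 degree spacing from a point inside the chamber, finds
#' where each ray crosses the traced wall contour, samples the image
#' intensity profile at 0.25-pixel steps in a ±10-pixel window around the
#' crossing (bilinear interpolation), and measures the edge-transition
#' width between the 20% and 80% points of the intensity swing. Sharpness
#' per profile is the reciprocal width in 1/pixels, capped at 1; the EBS is
#' the mean over the usable rays. Rays leaving the image before crossing
#' the wall are dropped and flagged.
#'
#' @param image numeric matrix (row, col).
#' @param contour `n x 2` `(row, col)` closed wall contour, pixels.
#' @param center length-2 `(row, col)` point inside the contour.
#' @param window half-width of the profile window, pixels (default 10).
#' @return a list of class `ebs_measure`: `ebs`, `per_profile` (length 8,
#'   `NA` for dropped rays), `n_used`, `dropped`.
#' @export
endocardial_border_sharpness <- function(image, contour, center, window = 10) {
  contour <- as.matrix(contour)
  if (signed_distance_2d(contour, center) <= 0)
    abort("center must lie inside the contour", class = "atriarecon_stats_error")
  angles <- (0:7) * pi / 4
  nr <- nrow(image); nc <- ncol(image)

  bilinear <- function(r, cl) {
    ok <- r >= 1 & r <= nr & cl >= 1 & cl <= nc
    out <- rep(NA_real_, length(r))
    if (!any(ok)) return(out)
    r <- pmin(pmax(r[ok], 1), nr - 1e-9); cl <- pmin(pmax(cl[ok], 1), nc - 1e-9)
    r0 <- floor(r); c0 <- floor(cl)
    fr <- r - r0; fc <- cl - c0
    r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
    out[ok] <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
      fr * (1 - fc) * image[cbind(r1, c0)] +
      (1 - fr) * fc * image[cbind(r0, c1)] +
      fr * fc * image[cbind(r1, c1)]
    out
  }

  per <- rep(NA_real_, 8)
  for (k in 1:8) {
    dir <- c(sin(angles[k]), cos(angles[k])) # (row, col) step
    # wall crossing: first sign change of the contour signed distance
    tt <- seq(0, max(nr, nc), by = 0.25)
    q <- cbind(center[1] + tt * dir[1], center[2] + tt * dir[2])
    sd <- signed_distance_2d(contour, q)
    cross <- which(sd[-1] <= 0 & sd[-length(sd)] > 0)
    if (length(cross) == 0) next
    t_wall <- tt[cross[1]]
    ts <- seq(t_wall - window, t_wall + window, by = 0.25)
    prof <- bilinear(center[1] + ts * dir[1], center[2] + ts * dir[2])
    if (anyNA(prof)) next # ray exits image: drop
    lo <- min(prof); hi <- max(prof)
    if (hi - lo < 1e-12) next
    p20 <- lo + 0.2 * (hi - lo)
    p80 <- lo + 0.8 * (hi - lo)
    # positions where the (monotone-trend) profile crosses the two levels
    cross_at <- function(level) {
      s <- prof - level
      i <- which(s[-1] * s[-length(s)] <= 0 & abs(diff(s)) > 0)
      if (length(i) == 0) return(NA_real_)
      i <- i[1]
      ts[i] + 0.25 * s[i] / (s[i] - s[i + 1])
    }
    t20 <- cross_at(p20); t80 <- cross_at(p80)
    if (is.na(t20) || is.na(t80) || t20 == t80) {
      per[k] <- 1 # step edge: transition below sampling resolution
    } else {
      per[k] <- min(1, 1 / abs(t80 - t20))
    }
  }
  used <- !is.na(per)
  if (!any(used))
    abort("no usable EBS profiles", class = "atriarecon_stats_error")
  if (any(!used))
    warn(sprintf("%d of 8 EBS rays dropped (no wall crossing inside image)",
                 sum(!used)))
  structure(list(ebs = mean(per[used]), per_profile = per,
                 n_used = sum(used), dropped = sum(!used)),
            class = "ebs_measure")
}

#' @export
print.ebs_measure <- function(x, ...) {
  cat(sprintf("<ebs_measure> EBS = %.4f /pixel over %d profiles\n",
              x$ebs, x$n_used))
  invisible(x)
}
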