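#' GC skew and replication origin/terminus localisation
#'
#' Computes the per-window GC skew (G - C)/(G + C) in sliding windows
#' (skew 0 where G + C = 0) and its cumulative sum along the contig. Under
#' the leading-strand G-excess convention the replication origin lies at
#' the cumulative minimum and the terminus at the cumulative maximum;
#' positions are reported at window centres (0-based bp). A sequence with
#' no G/C signal is reported as degenerate with a warning and NA extrema.
#'
#' @param seq contig sequence (>= 2 windows long)
#' @param window window width in bp
#' @param step step between window starts in bp
#' @return list: windows (data.frame start, center, g, c, skew, cumulative),
#'   ori_pos, ter_pos, degenerate
#' @export
gc_skew <- function(seq, window = 10000, step = 1000) {
  L <- nchar(seq)
  .assert(L >= 2 * window, "sequence (%d bp) shorter than two windows", L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  cg <- cumsum(chars == "G")
  cc <- cumsum(chars == "C")
  starts <- seq.int(1L, L - window + 1L, by = step)
  g <- cg[starts + window - 1L] - ifelse(starts > 1L, cg[starts - 1L], 0L)
  c_ <- cc[starts + window - 1L] - ifelse(starts > 1L, cc[starts - 1L], 0L)
  tot <- g + c_
  skew <- ifelse(tot > 0L, (g - c_) / tot, 0)
  cum <- cumsum(skew)
  centers <- (starts - 1L) + window / 2
  degenerate <- all(skew == 0)
  if (degenerate) {
    warning("gc_skew: no G/C signal; ori/ter undefined", call. = FALSE)
    ori <- ter <- NA_real_
  } else {
    ori <- centers[which.min(cum)]
    ter <- centers[which.max(cum)]
  }
  list(windows = data.frame(start = starts - 1L, center = centers, g = g,
                            c = c_, skew = skew, cumulative = cum),
       ori_pos = ori, ter_pos = ter, degenerate = degenerate)
}

# Expand polynomial coefficients from the rescaled variable u = (x - a)/b
# back to the original variable x via binomial expansion.
.rescale_coefficients <- function(coef_u, a, b) {
  d <- length(coef_u) - 1L
  out <- numeric(d + 1L)
  for (k in 0:d) {
    ck <- coef_u[k + 1L]
    if (ck == 0) next
    for (j in 0:k) {
      out[j + 1L] <- out[j + 1L] + ck * choose(k, j) * (-a)^(k - j) / b^k
    }
  }
  out
}

#' Fit a polynomial trend of methylation fraction along the genome
#'
#' Least-squares polynomial of the stated degree (quartic by default, the
#' shape used for across-genome methylation trends between ori and ter).
#' Positions are rescaled to \[0, 1\] internally for numerical conditioning;
#' coefficients are reported in both the scaled and the original bp
#' parameterisation.
#'
#' @param positions genomic bp positions (at least degree + 1 distinct)
#' @param fractions methylation fractions at those positions
#' @param degree polynomial degree
#' @return list: coefficients_scaled (intercept first, in u = (pos - a)/b),
#'   coefficients_bp (in original positions), fitted, rms_residual,
#'   scale (a, b), degree
#' @export
fit_trend <- function(positions, fractions, degree = 4) {
  .assert(length(positions) == length(fractions),
          "positions and fractions differ in length")
  .assert(length(positions) >= degree + 1,
          "need at least degree + 1 = %d points, got %d", degree + 1,
          length(positions))
  a <- min(positions)
  b <- max(positions) - a
  .assert(b > 0, "all positions identical")
  u <- (positions - a) / b
  fit <- stats::lm(fractions ~ stats::poly(u, degree, raw = TRUE))
  coef_u <- unname(stats::coef(fit))
  coef_u[is.na(coef_u)] <- 0
  list(coefficients_scaled = coef_u,
       coefficients_bp = .rescale_coefficients(coef_u, a, b),
       fitted = unname(stats::fitted(fit)),
       rms_residual = sqrt(mean(stats::residuals(fit)^2)),
       scale = list(a = a, b = b), degree = degree)
}

#' Evaluate a fitted trend at new positions
#'
#' @param fit output of [fit_trend()]
#' @param positions bp positions
#' @return fitted values
#' @export
predict_trend <- function(fit, positions) {
  u <- (positions - fit$scale$a) / fit$scale$b
  drop(outer(u, 0:fit$degree, `^`) %*% fit$coefficients_scaled)
}
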