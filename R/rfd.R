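#' Replication fork directionality from strand-specific Okazaki reads
#'
#' OK-seq sequences Okazaki fragments strand-specifically; the replication
#' fork directionality \code{RFD = (R - F) / (R + F)} per bin ascends through
#' zero at initiation zones and descends through zero at termination zones.
#'
#' @param F_counts,R_counts Equal-length per-bin forward/reverse-strand
#'   Okazaki read counts.
#' @return An \code{rfd_track}: list with \code{F}, \code{R}, \code{rfd}
#'   (NA where F + R = 0).
#' @export
compute_rfd <- function(F_counts, R_counts) {
  stopifnot(length(F_counts) == length(R_counts))
  tot <- F_counts + R_counts
  rfd <- ifelse(tot > 0, (R_counts - F_counts) / tot, NA_real_)
  structure(list(F = F_counts, R = R_counts, rfd = rfd), class = "rfd_track")
}

#' Reference initiation and termination zones from smoothed RFD
#'
#' A LOESS fit smooths the RFD profile; ascending zero-crossings (negative to
#' positive) anchor initiation zones and descending crossings anchor
#' termination zones. Only IZs flanked by a TZ on both sides are retained,
#' guaranteeing every kept IZ sits inside a complete fork unit.
#'
#' @param rfd An \code{rfd_track}.
#' @param loess_span LOESS span over the bin index (default 0.02; about 20 bins
#'   of context on a 1000-bin chromosome).
#' @return List with integer bin vectors \code{iz_bins}, \code{tz_bins} (the
#'   bin just left of each crossing) and the smoothed profile
#'   \code{smoothed}.
#' @export
reference_iz_tz <- function(rfd, loess_span = 0.02) {
  r <- rfd$rfd
  n <- length(r)
  idx <- seq_len(n)
  ok <- !is.na(r)
  if (sum(ok) < 10) stop("too few informative RFD bins")
  fit <- stats::loess(r[ok] ~ idx[ok], span = loess_span,
                      degree = 2, family = "gaussian")
  sm <- rep(NA_real_, n)
  sm[ok] <- stats::predict(fit)
  s <- sign(sm)
  # transitions between consecutive non-zero, non-NA signs
  iz <- integer(0); tz <- integer(0)
  last_sign <- 0; last_i <- 0L
  for (i in idx) {
    if (is.na(s[i]) || s[i] == 0) next
    if (last_sign != 0 && s[i] != last_sign) {
      if (last_sign < 0) iz <- c(iz, last_i) else tz <- c(tz, last_i)
    }
    last_sign <- s[i]; last_i <- i
  }
  # keep IZs flanked by TZs on both sides
  if (length(iz) > 0) {
    flanked <- vapply(iz, function(b) any(tz < b) && any(tz > b), logical(1))
    iz <- iz[flanked]
  }
  list(iz_bins = iz, tz_bins = tz, smoothed = sm)
}
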