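#' Digitized Kaplan-Meier curve container
#'
#' Bundles one trial arm's extracted KM coordinates, numbers-at-risk table
#' and total sample size — the raw unit of data for curve-based meta-analysis.
#' Points are passed through [clean_curve()] on construction.
#'
#' @param points Data frame with columns `time` (months) and `surv`
#'   (survival probability).
#' @param risk_table Data frame with columns `time` and `n_at_risk`
#'   (nonincreasing nonnegative integers).
#' @param total_n Total number of subjects in the arm.
#' @param study_id,arm_label Identifiers carried into reconstructed records.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param line `"first"` or `"second"` line of therapy.
#' @param total_events Optional reported total number of events.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(points, risk_table, total_n,
                            study_id = "study", arm_label = "arm",
                            endpoint = c("OS", "PFS"),
                            line = c("first", "second"),
                            total_events = NULL) {
  endpoint <- match.arg(endpoint)
  line <- match.arg(line)
  points <- clean_curve(points)
  risk_table <- as.data.frame(risk_table)
  stopifnot(all(c("time", "n_at_risk") %in% names(risk_table)))
  risk_table <- risk_table[order(risk_table$time), , drop = FALSE]
  if (nrow(risk_table) < 1L) stop("risk table needs at least one entry")
  if (any(diff(risk_table$n_at_risk) > 0)) {
    stop("`n_at_risk` must be nonincreasing in time")
  }
  stopifnot(length(total_n) == 1L, total_n >= max(risk_table$n_at_risk))
  structure(list(points = points, risk_table = risk_table,
                 total_n = as.integer(total_n),
                 study_id = study_id, arm_label = arm_label,
                 endpoint = endpoint, line = line,
                 total_events = if (is.null(total_events)) NULL else as.integer(total_events)),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized %s curve: %s / %s, %d points, n = %d>\n",
              x$endpoint, x$study_id, x$arm_label, nrow(x$points), x$total_n))
  invisible(x)
}

#' Repair digitized curve coordinates
#'
#' Graphical extraction introduces small vertical jitter and occasional
#' duplicated clicks. `clean_curve()` clamps survival to \[0, 1\], merges
#' duplicate times (keeping the lower survival), clips to a nonincreasing
#' step (running minimum) and prepends the origin (0, 1) when absent. The
#' operation is idempotent.
#'
#' @param points Data frame with columns `time` and `surv`.
#' @return Cleaned data frame, times strictly increasing, surv nonincreasing.
#' @export
clean_curve <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("time", "surv") %in% names(points)))
  keep <- is.finite(points$time) & is.finite(points$surv) & points$time >= 0
  points <- points[keep, c("time", "surv")]
  if (nrow(points) < 1L) stop("no valid curve points after cleaning")
  points$surv <- pmin(1, pmax(0, points$surv))
  points <- points[order(points$time, points$surv), , drop = FALSE]
  points <- points[!duplicated(points$time, fromLast = FALSE), , drop = FALSE]
  if (points$time[1] > 0) {
    points <- rbind(data.frame(time = 0, surv = 1), points)
  }
  points$surv <- cummin(points$surv)
  rownames(points) <- NULL
  points
}

#' Kaplan-Meier estimate of reconstructed or synthetic IPD
#'
#' Standard product-limit estimator (via [survival::survfit()]) returning
#' the step curve, beginning at (0, 1), and a numbers-at-risk table on a
#' requested time grid.
#'
#' @param ipd Data frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @param risk_times Optional time grid for the risk table; defaults to the
#'   step times.
#' @return List with `points` (data frame `time`, `surv`), `risk_table`
#'   (data frame `time`, `n_at_risk`) and `n` (number of records).
#' @export
km_estimate <- function(ipd, risk_times = NULL) {
  ipd <- as.data.frame(ipd)
  stopifnot(all(c("time", "event") %in% names(ipd)), nrow(ipd) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  pts <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
  if (is.null(risk_times)) risk_times <- pts$time
  sm <- summary(fit, times = risk_times, extend = TRUE)
  rt <- data.frame(time = sm$time, n_at_risk = sm$n.risk)
  list(points = pts, risk_table = rt, n = nrow(ipd))
}

step_surv <- function(points, t) {
  # left-continuous KM step lookup: value of the last coordinate at or before t
  idx <- findInterval(t, points$time)
  ifelse(idx < 1, 1, points$surv[pmax(idx, 1)])
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Interval-based reconstruction in the spirit of Guyot et al. (2012): within
#' each numbers-at-risk interval the number of censorings is solved so that
#' the implied number at risk matches the next risk-table entry, censoring
#' times are spread uniformly over the interval, and event counts at each
#' digitized coordinate are chosen so the product-limit estimate of the
#' output reproduces the digitized survival steps. Event counts are rounded
#' with carry-forward of the fractional remainder to prevent drift. Beyond
#' the last risk-table entry a constant censoring rate estimated from the
#' last observed interval is assumed (or, when `total_events` is recorded on
#' the curve, censorings are chosen to match it). Ties place events before
#' censorings, the standard KM convention.
#'
#' @param curve A [digitized_curve()].
#' @return Data frame of `total_n` rows with columns `time`, `event`,
#'   `study_id`, `arm` (pseudo-IPD).
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  pts <- curve$points
  t <- pts$time; S <- pts$surv; K <- length(t)
  rt <- curve$risk_table
  if (rt$time[1] > 0) {
    rt <- rbind(data.frame(time = 0, n_at_risk = curve$total_n), rt)
  }
  if (rt$n_at_risk[1] > curve$total_n) {
    stop("risk table inconsistent: more at risk than total_n")
  }
  trisk <- rt$time; nrisk <- rt$n_at_risk; I <- length(trisk)
  coord_int <- findInterval(t, trisk)        # drop at trisk[i] comes out of nrisk[i]
  d <- numeric(K)                            # events at coordinate k
  resid_k <- numeric(K)                      # real-valued event count minus d
  cen_by_int <- vector("list", I)            # censoring times per interval
  n_now <- nrisk[1]
  km_last <- 1                               # running reconstructed KM value
  last_rate <- 0                             # censorings / month / subject at risk
  for (i in seq_len(I)) {
    ks <- which(coord_int == i)
    ks <- ks[t[ks] > 0]                      # origin carries no drops
    t_lo <- trisk[i]
    t_hi <- if (i < I) trisk[i + 1] else max(t[K], t_lo) + 1e-9
    S_lo <- step_surv(pts, t_lo)
    S_hi <- if (i < I) step_surv(pts, t_hi) else S[K]
    target <- if (i < I) nrisk[i + 1] else NA_integer_
    if (i < I) {
      ncen <- max(0L, round(n_now * S_hi / max(S_lo, 1e-12)) - nrisk[i + 1])
    } else if (!is.null(curve$total_events)) {
      ncen <- max(0L, round(n_now * (1 - S_hi / max(S_lo, 1e-12))) -
                       (curve$total_events - round(sum(d))))
    } else {
      ncen <- min(n_now, round(last_rate * n_now * (t_hi - t_lo)))
    }
    ct <- numeric(0); d_i <- numeric(0); km <- km_last; n_k <- n_now
    for (iter in 1:30) {
      ncen <- max(0L, min(n_now, ncen))
      ct <- if (ncen > 0) t_lo + seq_len(ncen) * (t_hi - t_lo) / (ncen + 1) else numeric(0)
      n_k <- n_now; carry <- 0; km <- km_last
      d_i <- numeric(length(ks)); r_i <- numeric(length(ks))
      for (m in seq_along(ks)) {
        k <- ks[m]
        raw <- n_k * (1 - S[k] / max(km, 1e-12))
        dk <- max(0, min(n_k, round(raw + carry)))
        carry <- carry + raw - dk
        if (dk > 0 && n_k > 0) km <- km * (1 - dk / n_k)
        d_i[m] <- dk; r_i[m] <- raw - dk
        # censorings in the gap before this coordinate leave the risk set
        # only now: digitization shifts events to the next grid time, so
        # gap censorings are treated as tied there, events first
        prev <- if (m > 1) t[ks[m - 1]] else -Inf
        c_k <- sum(ct >= prev & ct < t[k])
        n_k <- n_k - dk - c_k
      }
      if (length(ks)) n_k <- n_k - sum(ct >= t[ks[length(ks)]])
      if (length(ks) == 0) n_k <- n_now - ncen
      gap <- if (is.na(target)) {
        if (is.null(curve$total_events)) 0
        else round(sum(d) + sum(d_i)) - curve$total_events
      } else n_k - target
      if (gap == 0) break
      ncen_new <- max(0L, min(n_now, ncen + gap))
      if (ncen_new == ncen) break
      ncen <- ncen_new
    }
    d[ks] <- d_i
    resid_k[ks] <- r_i
    cen_by_int[[i]] <- ct
    km_last <- km
    if (i < I && t_hi > t_lo && n_now > 0) {
      last_rate <- ncen / n_now / (t_hi - t_lo)
    }
    n_now <- if (is.na(target)) n_k else target
  }
  # Global event reconciliation: when the reported event total is known,
  # convert censorings <-> events inside individual intervals (keeping every
  # risk-table count intact) at the coordinates whose real-valued event
  # counts sat closest to the rounding boundary.
  if (!is.null(curve$total_events)) {
    mids <- (trisk + c(trisk[-1], max(t))) / 2
    for (pass in 1:(4 * curve$total_n)) {
      D <- curve$total_events - sum(d)
      if (abs(D) <= 2) break                 # reported totals are honoured to +/- 2;
                                             # forcing closer degrades the curve match
      if (D > 0) {
        ok <- which(t > 0 & lengths(cen_by_int)[pmax(coord_int, 1)] > 0)
        if (!length(ok)) break
        k <- ok[which.max(resid_k[ok])]
        iv <- coord_int[k]
        drop_j <- which.min(abs(cen_by_int[[iv]] - t[k]))
        cen_by_int[[iv]] <- cen_by_int[[iv]][-drop_j]
        d[k] <- d[k] + 1; resid_k[k] <- resid_k[k] - 1
      } else {
        ok <- which(d > 0)
        if (!length(ok)) break
        k <- ok[which.min(resid_k[ok])]
        iv <- coord_int[k]
        cen_by_int[[iv]] <- c(cen_by_int[[iv]], min(t[k] + 1e-6, mids[iv] + 1e-6))
        d[k] <- d[k] - 1; resid_k[k] <- resid_k[k] + 1
      }
    }
  }
  cen_times <- unlist(cen_by_int)
  ev_times <- rep(t[d > 0], times = d[d > 0])
  # anyone still at risk after the last coordinate is administratively censored
  leftover <- curve$total_n - length(ev_times) - length(cen_times)
  if (leftover < 0) {
    # trim late censorings first (rounding overflow)
    cen_times <- cen_times[seq_len(max(0, length(cen_times) + leftover))]
    leftover <- curve$total_n - length(ev_times) - length(cen_times)
  }
  end_t <- max(t)
  out <- data.frame(
    time = c(ev_times, cen_times, rep(end_t, leftover)),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cen_times) + leftover))
  )
  out <- out[order(out$time, -out$event), , drop = FALSE]
  out$study_id <- curve$study_id
  out$arm <- curve$arm_label
  rownames(out) <- NULL
  out
}

#' Compare a reconstruction against its source curve
#'
#' Re-estimates the KM curve from reconstructed records and measures the
#' absolute survival-probability deviation on the original digitized time
#' grid; when the source curve records a total event count, the
#' reconstructed event count is compared too.
#'
#' @param original A [digitized_curve()].
#' @param reconstructed Data frame from [reconstruct_ipd()].
#' @return List with `max_abs_dev`, `mean_abs_dev`, `n_records`,
#'   `n_events`, and `event_diff` (NA when no reference count).
#' @export
validate_reconstruction <- function(original, reconstructed) {
  stopifnot(inherits(original, "digitized_curve"))
  km <- km_estimate(reconstructed)
  grid <- original$points$time
  dev <- abs(step_surv(km$points, grid) - original$points$surv)
  list(
    max_abs_dev = max(dev),
    mean_abs_dev = mean(dev),
    n_records = nrow(reconstructed),
    n_events = sum(reconstructed$event),
    event_diff = if (is.null(original$total_events)) NA_integer_
                 else sum(reconstructed$event) - original$total_events
  )
}

# ---- CSV dialects ----------------------------------------------------------

#' Read and write the curve, risk-table and IPD CSV dialects
#'
#' All files are comma-separated UTF-8 with '.' decimal and a header row.
#' Curve files carry `time,survival`; risk tables `time,n_at_risk`; IPD files
#' `time,event,study_id,arm` plus any covariate columns.
#'
#' @param path File path.
#' @param ipd IPD data frame to write.
#' @name curve_io
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "survival") %in% names(df))) {
    stop(sprintf("%s: expected columns `time,survival`", path))
  }
  data.frame(time = df$time, surv = df$survival)
}

#' @rdname curve_io
#' @export
read_risk_table_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "n_at_risk") %in% names(df))) {
    stop(sprintf("%s: expected columns `time,n_at_risk`", path))
  }
  df[c("time", "n_at_risk")]
}

#' @rdname curve_io
#' @export
read_ipd_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "event") %in% names(df))) {
    stop(sprintf("%s: expected at least columns `time,event`", path))
  }
  df
}

#' @rdname curve_io
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(ipd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
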