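# Ecological outcome metrics: frequency f = A_a / (A_a + A_b) and
# productivity p = A_a / A_S on any abundance basis, plus flow-cytometry
# gating and growth-curve doubling times.

#' Abundance record
#'
#' @param genotype Genotype label.
#' @param abundance Non-negative quantity.
#' @param basis Measurement basis: `"area_um2"`, `"volume_um3"`, `"cells"` or
#'   `"cfu"`.
#' @return An `abundance_record`.
#' @export
abundance_record <- function(genotype, abundance,
                             basis = c("area_um2", "volume_um3", "cells",
                                       "cfu")) {
  basis <- match.arg(basis)
  stopifnot(abundance >= 0)
  structure(list(genotype = genotype, abundance = abundance, basis = basis),
            class = "abundance_record")
}

#' Frequency of a genotype in a two-way competition
#'
#' f = A_a / (A_a + A_b), the share of total abundance held by genotype a.
#' Both records must use the same basis.
#'
#' @param a,b [abundance_record()]s of the two competing genotypes.
#' @return List with per-genotype `frequencies` (summing to 1) and `basis`.
#' @export
frequency <- function(a, b) {
  stopifnot(inherits(a, "abundance_record"), inherits(b, "abundance_record"))
  if (!identical(a$basis, b$basis)) stop("abundance basis mismatch")
  tot <- a$abundance + b$abundance
  if (tot <= 0) stop("zero total abundance")
  f <- c(a$abundance / tot, b$abundance / tot)
  names(f) <- c(a$genotype, b$genotype)
  list(frequencies = f, basis = a$basis)
}

#' Productivity of a genotype relative to a no-interference control
#'
#' p = A_a / A_S, where A_S is the abundance reached by a susceptible
#' genotype grown at the same starting density and spatial pattern but
#' without interference competition. The reference must be supplied
#' explicitly; it is never inferred.
#'
#' @param a [abundance_record()] of the focal genotype.
#' @param reference [abundance_record()] of the matched no-interference
#'   control (A_S > 0, same basis).
#' @return Productivity p (scalar).
#' @export
productivity <- function(a, reference) {
  stopifnot(inherits(a, "abundance_record"),
            inherits(reference, "abundance_record"))
  if (!identical(a$basis, reference$basis)) stop("abundance basis mismatch")
  if (reference$abundance <= 0) stop("reference abundance A_S must be > 0")
  a$abundance / reference$abundance
}

#' Per-genotype pixel areas of a genotype mask
#'
#' @param mask A [genotype_mask()].
#' @return Named numeric: A and B areas in um^2.
#' @export
mask_areas <- function(mask) {
  stopifnot(inherits(mask, "genotype_mask"))
  px2 <- mask$pixel_size^2
  c(A = sum(mask$labels == GT_A) * px2, B = sum(mask$labels == GT_B) * px2)
}

#' Frequency of genotype A from a genotype mask (area basis)
#'
#' @param mask A [genotype_mask()].
#' @return The area-based frequency of genotype A.
#' @export
frequency_from_mask <- function(mask) {
  ar <- mask_areas(mask)
  frequency(abundance_record("A", ar[["A"]]),
            abundance_record("B", ar[["B"]]))$frequencies[["A"]]
}

#' Gate flow-cytometry events and count genotypes
#'
#' Keeps only events inside the core of the cell population: the axis-aligned
#' box containing the central `core_quantile` of events in forward and side
#' scatter. Within the gate, events with fluorescence above
#' `fluor_threshold` are assigned to genotype 1, the rest to genotype 2, and
#' only the first `n_keep` gated events (in acquisition order) are counted.
#'
#' @param events Data frame with columns `fsc`, `ssc`, `fluor` (finite,
#'   >= 0).
#' @param core_quantile Central scatter quantile defining the gate
#'   (default 0.9).
#' @param fluor_threshold Fluorescence cut between the genotypes (default
#'   2^9.5 = 724.08).
#' @param n_keep Number of gated events used for counting (default 3000). If
#'   fewer events pass the gate, all are used and a warning is recorded.
#' @return List with `counts` (genotype1/genotype2), `frequency_1` (Eq.-7
#'   frequency of genotype 1 on the cell-count basis), `n_used`, `gate`
#'   (scatter box), `warning` (NULL or message).
#' @export
gate_flow_events <- function(events, core_quantile = 0.9,
                             fluor_threshold = 2^9.5, n_keep = 3000L) {
  stopifnot(all(c("fsc", "ssc", "fluor") %in% names(events)),
            fluor_threshold > 0, n_keep >= 1,
            core_quantile > 0, core_quantile <= 1)
  if (!all(is.finite(as.matrix(events[c("fsc", "ssc", "fluor")])))) {
    stop("non-finite flow events")
  }
  tail_q <- (1 - core_quantile) / 2
  qf <- stats::quantile(events$fsc, c(tail_q, 1 - tail_q), names = FALSE)
  qs <- stats::quantile(events$ssc, c(tail_q, 1 - tail_q), names = FALSE)
  inside <- events$fsc >= qf[1] & events$fsc <= qf[2] &
    events$ssc >= qs[1] & events$ssc <= qs[2]
  if (!any(inside)) stop("no events pass the core gate")
  gated <- events[inside, , drop = FALSE]
  warn <- NULL
  if (nrow(gated) < n_keep) {
    warn <- sprintf("only %d gated events available (requested %d)",
                    nrow(gated), n_keep)
    warning(warn)
  }
  used <- utils::head(gated, n_keep)
  n1 <- sum(used$fluor > fluor_threshold)
  n2 <- nrow(used) - n1
  f1 <- if (nrow(used) > 0) {
    frequency(abundance_record("g1", n1, "cells"),
              abundance_record("g2", n2, "cells"))$frequencies[["g1"]]
  } else NA_real_
  list(counts = c(genotype1 = n1, genotype2 = n2), frequency_1 = f1,
       n_used = nrow(used),
       gate = list(fsc = qf, ssc = qs, core_quantile = core_quantile),
       warning = warn)
}

#' Doubling time from a growth curve
#'
#' Least-squares slope of ln(OD) against time over the exponential-phase
#' window `od_low <= OD <= od_high` (defaults 0.2-0.7); doubling time =
#' ln(2) / slope.
#'
#' @param times Time points in minutes (strictly increasing).
#' @param od Background-subtracted optical densities (>= 0).
#' @param od_low,od_high Exponential-phase OD window.
#' @return List with `doubling_min`, `slope` (per minute) and `n_points`.
#' @export
doubling_time <- function(times, od, od_low = 0.2, od_high = 0.7) {
  stopifnot(length(times) == length(od), !is.unsorted(times, strictly = TRUE),
            all(od >= 0))
  win <- od >= od_low & od <= od_high
  if (sum(win) < 3) stop("fewer than 3 points in the OD window")
  fit <- stats::lm(log(od[win]) ~ times[win])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive growth slope in the OD window")
  }
  list(doubling_min = log(2) / slope, slope = slope, n_points = sum(win))
}
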