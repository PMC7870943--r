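# Segregation index SI(h): per-pixel genotype assignment by dual Otsu
# thresholding, local kin fractions over square neighbourhoods via
# summed-area tables, global SI, SI(h) profiles and reference comparison.

#' Assign per-pixel genotypes from a two-channel micrograph
#'
#' Each channel is thresholded separately with Otsu's method. A pixel is A if
#' only channel 1 exceeds its threshold, B if only channel 2 exceeds, and
#' NONE if both exceed (ambiguous) or neither exceeds (background).
#'
#' @param img A [micrograph()].
#' @param thresholds Optional explicit `c(t1, t2)` overriding Otsu (required
#'   for constant channels, where Otsu is undefined).
#' @return A [genotype_mask()].
#' @export
assign_pixel_genotypes <- function(img, thresholds = NULL) {
  stopifnot(inherits(img, "micrograph"))
  if (is.null(thresholds)) {
    thresholds <- c(otsu_threshold(img$ch1), otsu_threshold(img$ch2))
  }
  stopifnot(length(thresholds) == 2)
  a <- img$ch1 > thresholds[1]
  b <- img$ch2 > thresholds[2]
  labels <- matrix(GT_NONE, nrow(a), ncol(a))
  labels[a & !b] <- GT_A
  labels[b & !a] <- GT_B
  genotype_mask(labels, img$pixel_size)
}

# summed-area table with a zero top row/left column so that box sums are
# S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1]
.integral_image <- function(ind) {
  nr <- nrow(ind); nc <- ncol(ind)
  m <- matrix(apply(ind, 2L, cumsum), nr, nc)
  m <- matrix(t(apply(m, 1L, cumsum)), nr, nc)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- m
  S
}

.box_sum <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}

#' Local segregation index map
#'
#' For every A- or B-type focal pixel i, `s_i(h)` is the fraction of the
#' A/B-type pixels within h rows or columns of i (the `(2h+1) x (2h+1)`
#' square neighbourhood, clipped at the image borders) that share i's
#' genotype. NONE pixels are never counted and receive no value. The focal
#' pixel is included in its own neighbourhood by default, so `N_i >= 1` and
#' `s_i` is defined at every focal pixel.
#'
#' @param mask A [genotype_mask()].
#' @param h Neighbourhood half-width in pixels (>= 1).
#' @param include_self Count the focal pixel among its neighbours (default
#'   TRUE).
#' @return Numeric matrix of `s_i` values, NA at NONE pixels.
#' @export
local_si <- function(mask, h, include_self = TRUE) {
  stopifnot(inherits(mask, "genotype_mask"))
  h <- as.integer(h)
  if (h < 1L) stop("h must be >= 1")
  lab <- mask$labels
  focal <- which(lab != GT_NONE)
  if (!length(focal)) stop("mask contains no A or B pixels")
  nr <- nrow(lab); nc <- ncol(lab)
  SA <- .integral_image(lab == GT_A)
  SB <- .integral_image(lab == GT_B)
  rc <- arrayInd(focal, dim(lab))
  r1 <- pmax(rc[, 1] - h, 1L); r2 <- pmin(rc[, 1] + h, nr)
  c1 <- pmax(rc[, 2] - h, 1L); c2 <- pmin(rc[, 2] + h, nc)
  nA <- .box_sum(SA, r1, r2, c1, c2)
  nB <- .box_sum(SB, r1, r2, c1, c2)
  kin <- ifelse(lab[focal] == GT_A, nA, nB)
  tot <- nA + nB
  if (!include_self) {
    kin <- kin - 1
    tot <- tot - 1
  }
  s <- matrix(NA_real_, nr, nc)
  s[focal] <- ifelse(tot > 0, kin / tot, NA_real_)
  s
}

#' Global segregation index SI(h)
#'
#' Arithmetic mean of the local segregation indices over all M focal (A or B)
#' pixels. SI ranges from ~0.5 (fully mixed at scale h) to 1.0 (fully
#' segregated / single genotype).
#'
#' @inheritParams local_si
#' @return List with `si` and `m` (number of focal pixels).
#' @export
global_si <- function(mask, h, include_self = TRUE) {
  s <- local_si(mask, h, include_self)
  v <- s[!is.na(s)]
  if (!length(v)) stop("no focal pixels with defined s_i (M = 0)")
  list(si = mean(v), m = length(v))
}

#' Convert neighbourhood spans between pixels and micrometres
#'
#' A span of S um corresponds to the half-width `h = round(S / pixel_size)`
#' px; at the default 1.515 um/px the spans 7.6, 15.2, 30.3, 75.8 and
#' 151.5 um map to h = 5, 10, 20, 50 and 100 px.
#'
#' @param spans_um Spans in micrometres.
#' @param spans_px Spans in pixels.
#' @param pixel_size Micrometres per pixel.
#' @return Integer pixel half-widths, or micrometre spans.
#' @export
span_um_to_px <- function(spans_um, pixel_size = 1.515) {
  as.integer(round(spans_um / pixel_size))
}

#' @rdname span_um_to_px
#' @export
span_px_to_um <- function(spans_px, pixel_size = 1.515) {
  spans_px * pixel_size
}

#' SI(h) profile over a list of spans
#'
#' @param mask A [genotype_mask()].
#' @param spans_px Spans as pixel half-widths (strictly increasing).
#' @param spans_um Alternatively, spans in micrometres (converted via the
#'   mask's pixel size).
#' @param include_self Passed to [local_si()].
#' @return Data frame of class `si_profile`: `span_px`, `span_um`, `si`, `m`.
#' @export
si_profile <- function(mask, spans_px = NULL, spans_um = NULL,
                       include_self = TRUE) {
  stopifnot(inherits(mask, "genotype_mask"))
  if (is.null(spans_px)) {
    if (is.null(spans_um)) stop("supply spans_px or spans_um")
    spans_px <- span_um_to_px(spans_um, mask$pixel_size)
  }
  spans_px <- as.integer(spans_px)
  if (!length(spans_px)) stop("empty span list")
  if (is.unsorted(spans_px, strictly = TRUE)) {
    stop("spans must be strictly increasing")
  }
  res <- lapply(spans_px, function(h) global_si(mask, h, include_self))
  out <- data.frame(span_px = spans_px,
                    span_um = span_px_to_um(spans_px, mask$pixel_size),
                    si = vapply(res, `[[`, numeric(1), "si"),
                    m = vapply(res, `[[`, numeric(1), "m"))
  class(out) <- c("si_profile", "data.frame")
  out
}

#' Compare a measured SI profile against a printing map's reference
#'
#' Renders the idealised reference mask of `map` at the measured profile's
#' pixel size, computes its SI on the same spans, and reports the paired
#' values with the maximum absolute deviation -- the printing-fidelity
#' comparison between measured and theoretical SI(h).
#'
#' @param measured An `si_profile` (from [si_profile()]).
#' @param map A `printing_map`.
#' @param pixel_size Pixel size of the reference render; defaults to the
#'   measured profile's implied pixel size.
#' @param seed Seed for the MIXED-droplet reference render.
#' @return List with `comparison` (data frame `span_px`, `span_um`,
#'   `si_measured`, `si_reference`, `delta`) and `max_abs_delta`.
#' @export
compare_to_reference <- function(measured, map, pixel_size = NULL, seed = 1L) {
  stopifnot(inherits(measured, "si_profile"), inherits(map, "printing_map"))
  if (is.null(pixel_size)) {
    pixel_size <- measured$span_um[1] / measured$span_px[1]
  }
  ref_mask <- render_reference_image(map, pixel_size, seed = seed)
  ref <- si_profile(ref_mask, spans_px = measured$span_px)
  if (!identical(ref$span_px, measured$span_px)) stop("span mismatch")
  cmp <- data.frame(span_px = measured$span_px, span_um = measured$span_um,
                    si_measured = measured$si, si_reference = ref$si,
                    delta = measured$si - ref$si)
  list(comparison = cmp, max_abs_delta = max(abs(cmp$delta)))
}

#' Brute-force SI reference implementation
#'
#' Direct per-pixel double loop over Eqs. of the local/global SI definition.
#' Quadratic and only suitable for small masks; retained as the independent
#' oracle against which the summed-area implementation is verified.
#'
#' @inheritParams global_si
#' @return List with `si` and `m`.
#' @export
global_si_bruteforce <- function(mask, h, include_self = TRUE) {
  stopifnot(inherits(mask, "genotype_mask"))
  lab <- mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  vals <- c()
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      g <- lab[r, cc]
      if (g == GT_NONE) next
      rs <- max(1, r - h):min(nr, r + h)
      cs <- max(1, cc - h):min(nc, cc + h)
      block <- lab[rs, cs]
      kin <- sum(block == g)
      tot <- sum(block != GT_NONE)
      if (!include_self) {
        kin <- kin - 1L
        tot <- tot - 1L
      }
      if (tot > 0) vals <- c(vals, kin / tot)
    }
  }
  if (!length(vals)) stop("no focal pixels (M = 0)")
  list(si = mean(vals), m = length(vals))
}
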