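# 3D microcolony segmentation: rough intensity threshold refined by
# Hessian-eigenvalue detection of dark separating features (blobs, sheets,
# tubes) between closely packed colonies.

#' Rough intensity threshold of a voxel stack
#'
#' @param stack A [voxel_stack()].
#' @param level Intensity threshold, or `"otsu"` to compute it from the
#'   channel-sum histogram.
#' @return A `voxel_mask`: logical 3D array plus provenance.
#' @export
rough_threshold <- function(stack, level = "otsu") {
  stopifnot(inherits(stack, "voxel_stack"))
  s <- stack_channel_sum(stack)
  if (any(!is.finite(s))) stop("non-finite voxels")
  if (identical(level, "otsu")) {
    level <- otsu_threshold(matrix(s, nrow = dim(s)[1]))
  }
  stopifnot(is.finite(level))
  structure(list(mask = s > level,
                 provenance = list(op = "rough_threshold", level = level)),
            class = "voxel_mask")
}

#' Hessian separator mask of a voxel stack
#'
#' Convolves the channel-sum intensity with an (anisotropy-corrected)
#' Gaussian of physical scale `sigma_um`, builds the 3x3 Hessian of the
#' smoothed image at every voxel from Gaussian-derivative convolutions, takes
#' its eigenvalues ordered by magnitude |l1| >= |l2| >= |l3|, and returns the
#' voxels whose signed l1 exceeds `lambda_threshold`. Positive principal
#' curvature marks 3D ridge-like features that are dark relative to nearby
#' colonies; bright blob interiors (l1 strongly negative) are never flagged.
#'
#' @param stack A [voxel_stack()].
#' @param sigma_um Physical filter scale in micrometres (default 3, the
#'   expected inter-colony gap); converted per axis to voxels.
#' @param lambda_threshold Positive curvature threshold, or `"p90"` (default)
#'   for the 90th percentile of positive l1 values in the stack.
#' @return A `voxel_mask` with an extra `l1` field (the signed first
#'   eigenvalue volume).
#' @export
hessian_separator_mask <- function(stack, sigma_um = 3,
                                   lambda_threshold = "p90") {
  stopifnot(inherits(stack, "voxel_stack"), sigma_um > 0)
  s <- stack_channel_sum(stack)
  if (any(!is.finite(s))) stop("non-finite voxels")
  spacing <- c(stack$voxel_xy, stack$voxel_xy, stack$z_step)
  sigma_vox <- sigma_um / spacing
  if (any(dim(s) < 2 * ceiling(3 * sigma_vox) + 1)) {
    stop("stack smaller than the Gaussian kernel support at this sigma")
  }
  H <- hessian_derivatives_3d(s, sigma_vox, spacing)
  ev <- symeig3_by_magnitude(as.numeric(H$xx), as.numeric(H$yy),
                             as.numeric(H$zz), as.numeric(H$xy),
                             as.numeric(H$xz), as.numeric(H$yz))
  l1 <- array(ev$l1, dim(s))
  if (identical(lambda_threshold, "p90")) {
    pos <- l1[l1 > 0]
    lambda_threshold <- if (length(pos)) {
      stats::quantile(pos, 0.9, names = FALSE)
    } else Inf
  }
  stopifnot(lambda_threshold > 0)
  structure(list(mask = l1 > lambda_threshold, l1 = l1,
                 provenance = list(op = "hessian_separator_mask",
                                   sigma_um = sigma_um,
                                   lambda_threshold = lambda_threshold)),
            class = "voxel_mask")
}

#' Full 3D segmentation of a voxel stack
#'
#' Final mask = rough threshold AND NOT(separator): the Hessian separator
#' voxels are carved out of the rough bright-region mask so that closely
#' packed colonies fused by the plain threshold split into distinct
#' components. Components are labelled with 26-connectivity.
#'
#' `keep = "separators"` instead retains the literal intersection of the
#' rough mask with the separator mask (the un-negated AND combination).
#'
#' @param stack A [voxel_stack()].
#' @param level Rough threshold (see [rough_threshold()]).
#' @param sigma_um,lambda_threshold See [hessian_separator_mask()].
#' @param keep `"colonies"` (default) or `"separators"`.
#' @return List with `mask` (logical array), `labels` (integer array),
#'   `n` (component count) and `volumes` (data frame of per-component voxel
#'   and physical volumes).
#' @export
segment_3d <- function(stack, level = "otsu", sigma_um = 3,
                       lambda_threshold = "p90",
                       keep = c("colonies", "separators")) {
  keep <- match.arg(keep)
  rough <- rough_threshold(stack, level)
  if (!any(rough$mask)) {
    labs <- array(0L, dim(rough$mask))
    return(list(mask = rough$mask, labels = labs, n = 0L,
                volumes = data.frame(label = integer(0),
                                     voxels = integer(0),
                                     volume_um3 = numeric(0))))
  }
  sep <- hessian_separator_mask(stack, sigma_um, lambda_threshold)
  final <- if (keep == "colonies") rough$mask & !sep$mask else rough$mask & sep$mask
  labs <- label_components_3d(final)
  n <- max(labs)
  vox <- if (n > 0) tabulate(labs[labs > 0L], nbins = n) else integer(0)
  list(mask = final, labels = labs, n = n,
       volumes = data.frame(label = seq_len(n), voxels = vox,
                            volume_um3 = vox * stack$voxel_xy^2 * stack$z_step))
}

#' Label connected components of a 3D logical array (26-connectivity)
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same dimension; 0 = background, components
#'   numbered 1..n in first-voxel scan order.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  labels <- array(0L, d)
  # linear-index offsets of the 26 neighbours, validity checked per axis
  nb <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  todo <- which(mask)
  cur <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      idx <- arrayInd(queue, d)
      nxt <- integer(0)
      for (k in seq_len(nrow(nb))) {
        r <- idx[, 1] + nb[k, 1]; c <- idx[, 2] + nb[k, 2]
        z <- idx[, 3] + nb[k, 3]
        ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2] & z >= 1 & z <= d[3]
        if (!any(ok)) next
        lin <- (z[ok] - 1L) * d[1] * d[2] + (c[ok] - 1L) * d[1] + r[ok]
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin)) {
          labels[lin] <- cur
          nxt <- c(nxt, lin)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels
}
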