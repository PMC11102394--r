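#' Gaussian kernel specification for modeled activation
#'
#' Each reported peak is modeled as an isotropic 3D Gaussian whose width
#' reflects spatial uncertainty. By default the full width at half maximum
#' (FWHM) shrinks with the study's sample size following the published
#' two-component uncertainty model (a fixed between-template term plus a
#' between-subject term scaled by 1/n); a constant FWHM can be supplied
#' instead, which makes results independent of any particular coefficient
#' choice.
#'
#' @param fwhm Either a single FWHM in mm (constant kernel) or a function
#'   \code{n_participants -> FWHM mm}, non-increasing in n.
#' @param truncate Truncation radius as a multiple of FWHM (default 3); the
#'   kernel is normalized to unit discrete mass before truncation effects at
#'   grid edges.
#' @return A \code{kernel_spec}.
#' @export
kernel_spec <- function(fwhm = fwhm_two_component, truncate = 3) {
  f <- if (is.function(fwhm)) fwhm else function(n) fwhm
  stopifnot(truncate > 0)
  structure(list(fwhm = f, truncate = truncate), class = "kernel_spec")
}

#' Two-component spatial uncertainty model
#'
#' FWHM(n) derived from a fixed template-registration uncertainty (5.7 mm
#' Euclidean displacement) plus a between-subject uncertainty (11.6 mm)
#' attenuated by the square root of the sample size. Displacements are
#' converted to per-axis Gaussian sigmas via \code{sd = d / (2 sqrt(2/pi))}.
#'
#' @param n Number of participants.
#' @param template_mm,subject_mm The two displacement components in mm.
#' @return FWHM in mm (non-increasing in n).
#' @export
fwhm_two_component <- function(n, template_mm = 5.7, subject_mm = 11.6) {
  conv <- 2 * sqrt(2 / pi)
  sd_t <- template_mm / conv
  sd_s <- subject_mm / conv
  sqrt(sd_t^2 + sd_s^2 / n) * sqrt(8 * log(2))
}

# discrete truncated Gaussian kernel: integer offsets and unit-mass weights
discrete_kernel <- function(fwhm_mm, spacing, truncate) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  r_vox <- max(1L, ceiling(truncate * fwhm_mm / spacing))
  off <- -r_vox:r_vox
  g <- expand.grid(dx = off, dy = off, dz = off)
  d2 <- (g$dx^2 + g$dy^2 + g$dz^2) * spacing^2
  keep <- sqrt(d2) <= truncate * fwhm_mm
  g <- g[keep, ]; d2 <- d2[keep]
  w <- exp(-d2 / (2 * sigma^2))
  list(offsets = as.matrix(g), weights = w / sum(w))
}

#' Modeled activation (MA) map of one study
#'
#' Each focus contributes a discretely normalized, truncated Gaussian; the
#' study's MA value at a voxel is the maximum over its foci (non-additive),
#' so a study's evidence is not inflated by how many nearby peaks it reports.
#'
#' @param foci n x 3 matrix of world-mm peak coordinates.
#' @param n_participants Sample size (sets the kernel width).
#' @param grid A \code{voxel_grid}.
#' @param kernel A \code{kernel_spec}.
#' @return Numeric array over the grid with values in [0, 1], or \code{NULL}
#'   (with a warning) if no focus falls inside the grid.
#' @export
ma_map <- function(foci, n_participants, grid, kernel = kernel_spec()) {
  foci <- coord_matrix(foci)
  fwhm <- kernel$fwhm(n_participants)
  stopifnot(fwhm > 0)
  kern <- discrete_kernel(fwhm, grid$spacing, kernel$truncate)
  arr <- array(0, dim = grid$shape)
  shape <- grid$shape
  any_in <- FALSE
  for (i in seq_len(nrow(foci))) {
    idx <- tryCatch(world_to_voxel(foci[i, , drop = FALSE], grid),
                    error = function(e) NULL)
    if (is.null(idx)) next
    any_in <- TRUE
    pos <- sweep(kern$offsets, 2, as.numeric(idx), "+")
    ok <- pos[, 1] >= 0 & pos[, 1] < shape[1] &
          pos[, 2] >= 0 & pos[, 2] < shape[2] &
          pos[, 3] >= 0 & pos[, 3] < shape[3]
    lin <- voxel_linear_index(pos[ok, , drop = FALSE], grid)
    arr[lin] <- pmax(arr[lin], kern$weights[ok])
  }
  if (!any_in) {
    warning("study has no focus inside the grid; skipped")
    return(NULL)
  }
  arr
}

#' ALE union of modeled activation maps
#'
#' ALE(v) = 1 - prod_i (1 - MA_i(v)): the probability that at least one study
#' activated the voxel, treating studies as independent.
#'
#' @param ma_maps List of MA arrays on a shared grid.
#' @return Numeric array of ALE values in [0, 1].
#' @export
ale_map <- function(ma_maps) {
  ma_maps <- ma_maps[!vapply(ma_maps, is.null, TRUE)]
  stopifnot(length(ma_maps) >= 1)
  dims <- dim(ma_maps[[1]])
  acc <- array(1, dim = dims)
  for (m in ma_maps) {
    if (!identical(dim(m), dims)) stop("MA maps on mismatched grids")
    acc <- acc * (1 - m)
  }
  1 - acc
}

# histogram of a study's masked MA values, compressed to at most max_levels
# weighted support points (mass-preserving, mean-preserving within groups)
ma_histogram <- function(ma, mask, max_levels = 256) {
  v <- if (is.null(mask)) as.numeric(ma) else ma[mask]
  n <- length(v)
  p0 <- mean(v == 0)
  v <- v[v > 0]
  if (length(v) == 0) return(list(m = 0, q = 1))
  if (length(unique(v)) > max_levels) {
    grp <- cut(rank(v, ties.method = "first"), max_levels, labels = FALSE)
    m <- as.numeric(tapply(v, grp, mean))
    q <- as.numeric(tapply(v, grp, length)) / n
  } else {
    tab <- table(v)
    m <- as.numeric(names(tab))
    q <- as.numeric(tab) / n
  }
  if (p0 > 0) { m <- c(0, m); q <- c(p0, q) }
  list(m = m, q = q / sum(q))
}

#' Analytic null distribution of the ALE statistic
#'
#' Distribution of ALE at a voxel when every study's MA value is assigned by
#' drawing a voxel uniformly at random (independently per study): the
#' per-study histograms of masked MA values are convolved through the ALE
#' combination rule u <- 1 - (1 - u)(1 - m) on a fixed binning of [0, 1).
#'
#' @param ma_maps List of MA arrays (>= 2).
#' @param mask Optional logical array restricting the voxel population.
#' @param n_bins Number of histogram bins on [0, 1) (default 10000).
#' @param max_levels Per-study histogram compression level (default 256
#'   support points).
#' @return An \code{ale_null} object: bin probabilities, right-tail
#'   cumulative, and bin width.
#' @export
analytic_null <- function(ma_maps, mask = NULL, n_bins = 10000,
                          max_levels = 256) {
  ma_maps <- ma_maps[!vapply(ma_maps, is.null, TRUE)]
  stopifnot(length(ma_maps) >= 2, n_bins >= 2)
  # bin k carries mass at the left-edge value (k-1)/n_bins, so the starting
  # atom at ALE = 0 is represented exactly
  edges <- (seq_len(n_bins) - 1) / n_bins
  p <- numeric(n_bins)
  p[1] <- 1  # ALE = 0 before any study
  for (ma in ma_maps) {
    h <- ma_histogram(ma, mask, max_levels)
    acc <- numeric(n_bins)
    for (j in seq_along(h$m)) {
      m <- h$m[j]; q <- h$q[j]
      if (m == 0) { acc <- acc + q * p; next }
      # transformed support positions; mass is split linearly between the
      # two neighbouring edges so the distribution's mean stays exact
      pos <- (m + (1 - m) * edges) * n_bins + 1
      lo <- floor(pos)
      frac <- pos - lo
      spread <- function(target, w) {
        # target is nondecreasing (affine map): group sums via cumsum
        target <- pmin(pmax(target, 1L), n_bins)
        cw <- cumsum(w)
        last <- which(diff(target) > 0L)
        ends <- c(last, n_bins)
        acc[target[ends]] <<- acc[target[ends]] + cw[ends] - c(0, cw[last])
      }
      spread(lo, q * p * (1 - frac))
      spread(lo + 1L, q * p * frac)
    }
    p <- acc
  }
  stopifnot(abs(sum(p) - 1) < 1e-9)
  structure(list(probs = p, n_bins = n_bins,
                 tail = rev(cumsum(rev(p)))),
            class = "ale_null")
}

#' Right-tail p-value of ALE values under the analytic null
#'
#' P(ALE_null >= a), interpolated linearly within histogram bins; exactly 1
#' at a = 0.
#'
#' @param null An \code{ale_null}.
#' @param a Numeric vector of ALE values in [0, 1].
#' @return p-values in [0, 1], non-increasing in \code{a}.
#' @export
tail_p <- function(null, a) {
  nb <- null$n_bins
  k <- pmin(pmax(floor(a * nb), 0), nb - 1L)
  frac <- 1 - (a * nb - k)
  upper <- c(null$tail, 0)[k + 2L]
  pmin(1, pmax(0, upper + null$probs[k + 1L] * frac))
}

#' Convert an ALE map to an unthresholded z-map
#'
#' z(v) = qnorm(1 - p(v)) with the right-tail p from the analytic null; p is
#' clamped to [p_floor, 1 - p_floor] so z stays finite everywhere.
#'
#' @param ale ALE array.
#' @param null An \code{ale_null}.
#' @param p_floor Minimum p (default 1e-12).
#' @return Numeric array of z-values (finite).
#' @export
z_map <- function(ale, null, p_floor = 1e-12) {
  p <- tail_p(null, as.numeric(ale))
  p <- pmin(pmax(p, p_floor), 1 - p_floor)
  array(qnorm(1 - p), dim = dim(ale))
}

#' Run ALE for one topic of a database
#'
#' Builds one MA map per study of the topic, combines them into an ALE map,
#' derives the analytic null over the masked voxels and returns the
#' unthresholded z-map. No cluster-forming or thresholding is applied.
#'
#' @param db A \code{topic_database}.
#' @param topic Topic id.
#' @param grid A \code{voxel_grid}.
#' @param kernel A \code{kernel_spec}.
#' @param mask Logical array over the grid (null population and z-map
#'   domain); default: the geometric cerebellar mask on the grid.
#' @param n_bins,max_levels Passed to \code{\link{analytic_null}}.
#' @return List (class \code{ale_result}): \code{topic}, \code{ale} and
#'   \code{z} (\code{volume}s), \code{null}, \code{n_studies}.
#' @export
ale_topic <- function(db, topic, grid, kernel = kernel_spec(),
                      mask = grid_mask(grid), n_bins = 10000,
                      max_levels = 256) {
  ids <- db$studies$study_id[db$studies$topic == topic]
  if (length(ids) < 2) stop("topic ", topic, " has fewer than 2 studies")
  np <- db$studies$n_participants[match(ids, db$studies$study_id)]
  mas <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    f <- db$foci[db$foci$study_id == ids[i], c("x", "y", "z")]
    mas[[i]] <- suppressWarnings(
      ma_map(as.matrix(f), np[i], grid, kernel))
  }
  mas <- mas[!vapply(mas, is.null, TRUE)]
  if (length(mas) < 2) stop("topic ", topic, " has fewer than 2 in-grid studies")
  ale <- ale_map(mas)
  null <- analytic_null(mas, mask = mask, n_bins = n_bins,
                        max_levels = max_levels)
  z <- z_map(ale, null)
  structure(list(topic = topic, ale = volume(grid, ale, mask = mask),
                 z = volume(grid, z, mask = mask), null = null,
                 n_studies = length(mas)),
            class = "ale_result")
}
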