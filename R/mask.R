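#' Geometric cerebellar mask specification
#'
#' The cerebellum is delimited by a bounding box plus two half-space planes
#' that trim the superior and posterior margins. The planes are defined by
#' anchor points in MNI mm: the superior plane passes through (0, -50, 12) and
#' (+-60, -50, -30) in the z-|x| plane, the posterior plane through
#' (0, -50, 12) and (0, -100, -15) in the z-y plane. Their slopes and
#' intercepts are derived from those anchors (-0.70 and 0.54 with intercept 12
#' at the default geometry). A coordinate is inside the mask iff all of the
#' following hold strictly:
#' \itemize{
#'   \item \code{|x| < x_abs_max} (default 63 mm)
#'   \item \code{y_min < y < y_max} (default -103 < y < -28 mm)
#'   \item \code{z < z_max} (default 11 mm)
#'   \item \code{z < superior_slope * |x| + superior_intercept}
#'   \item \code{z < posterior_slope * (y + posterior_offset) + posterior_intercept}
#' }
#'
#' @param x_abs_max,y_min,y_max,z_max Box bounds in mm.
#' @param superior_anchors,posterior_anchors 2 x 3 matrices of the two anchor
#'   points (world mm) defining each plane.
#' @return A \code{mask_spec} object with the box bounds, the anchors, and the
#'   slopes/intercepts computed from them.
#' @export
mask_spec <- function(x_abs_max = 63, y_min = -103, y_max = -28, z_max = 11,
                      superior_anchors = rbind(c(0, -50, 12),
                                               c(60, -50, -30)),
                      posterior_anchors = rbind(c(0, -50, 12),
                                                c(0, -100, -15))) {
  stopifnot(y_min < y_max)
  sup <- plane_from_anchors(superior_anchors, axis = "abs_x")
  post <- plane_from_anchors(posterior_anchors, axis = "y", offset = 50)
  structure(list(x_abs_max = x_abs_max, y_min = y_min, y_max = y_max,
                 z_max = z_max,
                 superior_anchors = superior_anchors,
                 posterior_anchors = posterior_anchors,
                 superior = sup, posterior = post),
            class = "mask_spec")
}

#' Derive a z-bound plane from two anchor points
#'
#' Computes slope and intercept of the line z = slope * u + intercept where u
#' is \code{|x|} (superior margin) or \code{y + offset} (posterior margin).
#'
#' @param anchors 2 x 3 matrix of world-mm points.
#' @param axis "abs_x" or "y".
#' @param offset Added to y before the slope is applied (posterior plane).
#' @return List with \code{slope} and \code{intercept}.
#' @export
plane_from_anchors <- function(anchors, axis = c("abs_x", "y"), offset = 0) {
  axis <- match.arg(axis)
  u <- switch(axis, abs_x = abs(anchors[, 1]), y = anchors[, 2] + offset)
  z <- anchors[, 3]
  if (u[2] == u[1]) stop("anchor points do not define a slope")
  slope <- (z[2] - z[1]) / (u[2] - u[1])
  list(slope = slope, intercept = z[1] - slope * u[1], offset = offset)
}

#' Test world coordinates against the geometric cerebellar mask
#'
#' @param coords n x 3 matrix (or length-3 vector) of world mm.
#' @param spec A \code{mask_spec}.
#' @return Logical vector of length n. All inequalities are strict, so the
#'   plane anchor points themselves are excluded.
#' @export
in_geometric_mask <- function(coords, spec = mask_spec()) {
  coords <- coord_matrix(coords)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  abs(x) < spec$x_abs_max &
    y > spec$y_min & y < spec$y_max &
    z < spec$z_max &
    z < spec$superior$slope * abs(x) + spec$superior$intercept &
    z < spec$posterior$slope * (y + spec$posterior$offset) +
        spec$posterior$intercept
}

#' Build an atlas labeler from a NIfTI label volume
#'
#' A labeler maps world coordinates to anatomical label names; during
#' filtering a focus is kept only if at least one returned label is
#' cerebellar. This provides a generic hook for externally supplied atlas
#' volumes; the geometric mask alone is the default filtering path.
#'
#' @param label_vol A \code{volume} of integer region codes.
#' @param names Character vector mapping code \code{i} to \code{names[i]}.
#' @param cerebellar_pattern Regex identifying cerebellar labels.
#' @return A function \code{f(coords)} returning a logical vector: whether
#'   each coordinate receives at least one cerebellar label.
#' @export
volume_labeler <- function(label_vol, names,
                           cerebellar_pattern = "cerebell|vermis|dentate|lobule") {
  is_cb <- grepl(cerebellar_pattern, names, ignore.case = TRUE)
  function(coords) {
    coords <- coord_matrix(coords)
    out <- logical(nrow(coords))
    for (i in seq_len(nrow(coords))) {
      idx <- tryCatch(world_to_voxel(coords[i, , drop = FALSE],
                                     label_vol$grid),
                      error = function(e) NULL)
      if (is.null(idx)) next
      code <- label_vol$values[idx[1, 1] + 1L, idx[1, 2] + 1L, idx[1, 3] + 1L]
      out[i] <- code >= 1 && code <= length(names) && is_cb[code]
    }
    out
  }
}

#' Filter a study database to cerebellar foci and screened studies
#'
#' Applies, in order: (1) study-level screening — a study is dropped entirely
#' if any of its screening flags is in \code{excluded_flags}; (2) the
#' geometric mask — a focus survives only if strictly inside the mask;
#' (3) optional atlas labeling — if a labeler is supplied, a surviving focus
#' must additionally receive at least one cerebellar label. Studies left with
#' no foci are dropped. Each removal is attributed to the first failing
#' criterion so the audit counts reconcile exactly with the input.
#'
#' @param db A \code{topic_database}.
#' @param spec A \code{mask_spec}.
#' @param labeler Optional function from coordinates to a logical
#'   "has cerebellar label" vector (see \code{\link{volume_labeler}}).
#' @param excluded_flags Character vector of screening flags that exclude a
#'   whole study (e.g. "patients", "resting-state", "connectivity").
#' @return List with \code{db} (the filtered database) and \code{audit}
#'   (counts of studies/foci removed per criterion).
#' @export
filter_database <- function(db, spec = mask_spec(), labeler = NULL,
                            excluded_flags = character()) {
  stopifnot(inherits(db, "topic_database"))
  studies <- db$studies
  foci <- db$foci
  n_foci_in <- nrow(foci)

  flagged <- vapply(studies$screening_flags,
                    function(f) any(f %in% excluded_flags), logical(1))
  removed_study_ids <- studies$study_id[flagged]
  foci_in_flagged <- sum(foci$study_id %in% removed_study_ids)
  studies <- studies[!flagged, , drop = FALSE]
  foci <- foci[!foci$study_id %in% removed_study_ids, , drop = FALSE]

  inside <- in_geometric_mask(as.matrix(foci[, c("x", "y", "z")]), spec)
  foci_outside_mask <- sum(!inside)
  foci <- foci[inside, , drop = FALSE]

  foci_unlabeled <- 0L
  if (!is.null(labeler) && nrow(foci) > 0) {
    has_label <- labeler(as.matrix(foci[, c("x", "y", "z")]))
    foci_unlabeled <- sum(!has_label)
    foci <- foci[has_label, , drop = FALSE]
  }

  emptied <- !studies$study_id %in% unique(foci$study_id)
  studies <- studies[!emptied, , drop = FALSE]

  if (nrow(foci) == 0L) warning("no foci survive filtering")

  out <- db
  out$studies <- studies
  out$foci <- foci
  audit <- list(
    studies_in = length(flagged),
    studies_removed_screening = sum(flagged),
    studies_removed_no_foci = sum(emptied),
    studies_out = nrow(studies),
    foci_in = n_foci_in,
    foci_removed_screening = foci_in_flagged,
    foci_removed_mask = foci_outside_mask,
    foci_removed_unlabeled = foci_unlabeled,
    foci_out = nrow(foci))
  list(db = out, audit = audit)
}
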