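#' Per-cluster voxel score maps
#'
#' Collapses the topics-by-voxels matrix onto clusters: the score of cluster
#' c at voxel v aggregates the normalized z of the topics assigned to c
#' (mean by default; max optionally).
#'
#' @param tm A \code{topic_matrix}.
#' @param model A \code{cluster_model} covering all of \code{tm$topics}.
#' @param aggregator "mean" or "max".
#' @return A \code{cluster_scores} object: \code{values} (C x V), cluster
#'   ids as rownames, plus the grid/voxel bookkeeping of \code{tm}.
#' @export
cluster_scores <- function(tm, model, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  missing <- setdiff(tm$topics, names(model$assignment))
  if (length(missing))
    stop("cluster model misses topics: ", paste(missing, collapse = ", "))
  cl <- model$assignment[tm$topics]
  ids <- sort(unique(cl))
  if (!setequal(ids, seq_len(model$k)))
    stop("empty cluster in model (assignment not surjective onto 1..k)")
  agg <- switch(aggregator, mean = colMeans,
                max = function(m) apply(m, 2, max))
  vals <- t(vapply(ids, function(c_id)
    agg(tm$values[cl == c_id, , drop = FALSE]),
    numeric(ncol(tm$values))))
  rownames(vals) <- ids
  structure(list(values = vals, clusters = ids, voxels = tm$voxels,
                 grid = tm$grid, mask = tm$mask),
            class = "cluster_scores")
}

#' Winner-take-all parcellation
#'
#' Labels each masked voxel with the cluster of highest score. Voxels whose
#' scores are all zero stay unassigned (label 0); exact ties go to the lowest
#' cluster index and are counted.
#'
#' @param scores A \code{cluster_scores}.
#' @return A \code{parcellation}: label \code{volume}, \code{legend}
#'   (label -> name), \code{n_ties}.
#' @export
winner_take_all <- function(scores) {
  stopifnot(nrow(scores$values) >= 1)
  s <- scores$values
  win <- max.col(t(s), ties.method = "first")
  top <- s[cbind(win, seq_len(ncol(s)))]
  win[top == 0] <- 0L
  n_ties <- sum(colSums(s == rep(top, each = nrow(s))) > 1 & top > 0)
  vals <- array(0L, dim = scores$grid$shape)
  vals[scores$voxels] <- win
  legend <- as.character(scores$clusters)
  names(legend) <- as.character(seq_along(scores$clusters))
  structure(list(volume = volume(scores$grid, vals, mask = scores$mask),
                 legend = legend, n_ties = n_ties),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  labs <- x$volume$values[x$volume$values > 0]
  cat(sprintf("<parcellation> %d labeled voxels, %d labels (%s)\n",
              length(labs), length(unique(labs)),
              paste(unique(x$legend), collapse = ", ")))
  invisible(x)
}

#' Labels of a parcellation on its masked voxels
#' @param parc A \code{parcellation}.
#' @return Integer vector over the masked voxels.
#' @export
parcellation_labels <- function(parc) {
  m <- parc$volume$mask
  if (is.null(m)) as.integer(parc$volume$values)
  else as.integer(parc$volume$values[m])
}

#' Stochastic mode (box) filtering of a parcellation
#'
#' Smooths a label map by sweeping over the masked voxels in a seeded random
#' order and replacing each label in place (sequentially within a sweep) by
#' the most frequent label inside a centred box; unassigned voxels (label 0)
#' are excluded from the mode count. Modal ties keep the smallest label.
#'
#' @param parc A \code{parcellation}.
#' @param box Odd box edge length in voxels (default 5).
#' @param sweeps Number of random sweeps (default 10).
#' @param seed Integer seed for the visit orders.
#' @return The smoothed \code{parcellation}.
#' @export
mode_filter <- function(parc, box = 5, sweeps = 10, seed = 1L) {
  if (box %% 2 == 0) stop("box size must be odd")
  stopifnot(sweeps >= 1)
  vol <- parc$volume
  mask <- vol$mask
  if (is.null(mask)) mask <- array(TRUE, dim = vol$grid$shape)
  vox <- which(as.vector(mask))
  set.seed(seed)
  orders <- vapply(seq_len(sweeps), function(i) sample(vox),
                   integer(length(vox)))
  lab <- as.integer(vol$values)
  out <- mode_filter_cpp(lab, vol$grid$shape, as.vector(mask),
                         as.integer(box), orders - 1L)
  res <- parc
  res$volume <- volume(vol$grid, array(out, dim = vol$grid$shape),
                       mask = vol$mask)
  res
}

#' Merge parcellation clusters into networks
#'
#' Relabels a parcellation according to a cluster-to-network map (e.g. the
#' shipped 10-cluster to 7-network map). Map keys address the current
#' legend's names; every network also implicitly maps to itself, so applying
#' the same map twice is a no-op.
#'
#' @param parc A \code{parcellation}.
#' @param network_map Named character vector: legend name -> network name.
#' @return The merged \code{parcellation} with an updated legend.
#' @export
merge_networks <- function(parc, network_map) {
  ext <- c(network_map,
           structure(unique(network_map), names = unique(network_map)))
  ext <- ext[!duplicated(names(ext))]
  labs <- sort(unique(parc$volume$values[parc$volume$values > 0]))
  names_in <- parc$legend[as.character(labs)]
  if (any(!names_in %in% names(ext)))
    stop("unmapped label(s): ",
         paste(names_in[!names_in %in% names(ext)], collapse = ", "))
  nets <- unique(unname(ext[parc$legend]))
  new_of_old <- match(ext[parc$legend], nets)
  names(new_of_old) <- names(parc$legend)
  lut <- integer(max(labs) + 1L)
  lut[labs + 1L] <- new_of_old[as.character(labs)]
  vals <- parc$volume$values
  pos <- vals > 0
  vals[pos] <- lut[vals[pos] + 1L]
  legend <- nets
  names(legend) <- as.character(seq_along(nets))
  structure(list(volume = volume(parc$volume$grid, vals,
                                 mask = parc$volume$mask),
                 legend = legend, n_ties = parc$n_ties),
            class = "parcellation")
}
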