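#' Unity-based normalization of a map over a mask
#'
#' Rescales masked values linearly to [0, 1] ((x - min) / (max - min)), so
#' topics with globally weaker activation contribute on the same footing as
#' strongly activated topics. A degenerate (constant) map is returned as all
#' zeros with a warning and a \code{degenerate} attribute.
#'
#' @param values Numeric vector or array.
#' @param mask Optional logical selector of the same length/shape; values
#'   outside the mask are set to 0.
#' @return Rescaled values of the same shape.
#' @export
normalize_unity <- function(values, mask = NULL) {
  out <- values
  sel <- if (is.null(mask)) rep(TRUE, length(values)) else as.vector(mask)
  if (!any(sel)) stop("empty mask in normalize_unity")
  v <- values[sel]
  rng <- range(v)
  if (rng[2] == rng[1]) {
    warning("degenerate map (constant over mask): normalized to all zeros")
    out[] <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out[] <- 0
  out[sel] <- (v - rng[1]) / (rng[2] - rng[1])
  out
}

#' Assemble the topics-by-voxels matrix
#'
#' Stacks per-topic z-maps, unity-normalized over the masked voxels, into the
#' T x V matrix that topic clustering and voxel scoring operate on.
#'
#' @param z_volumes Named list (topic -> \code{volume}) of z-maps on a shared
#'   grid.
#' @param mask Logical array selecting the analysis voxels.
#' @return A \code{topic_matrix}: \code{values} (T x V), \code{topics},
#'   \code{voxels} (linear indices into the grid), \code{grid}, \code{mask}.
#' @export
topic_matrix <- function(z_volumes, mask) {
  stopifnot(length(z_volumes) >= 1, !is.null(names(z_volumes)))
  grid <- z_volumes[[1]]$grid
  voxels <- which(as.vector(mask))
  vals <- t(vapply(z_volumes, function(v) {
    stopifnot(identical(v$grid$shape, grid$shape))
    as.numeric(normalize_unity(v$values[voxels]))
  }, numeric(length(voxels))))
  rownames(vals) <- names(z_volumes)
  structure(list(values = vals, topics = names(z_volumes), voxels = voxels,
                 grid = grid, mask = mask),
            class = "topic_matrix")
}

#' Hierarchical clustering of topic activation profiles
#'
#' Agglomerative clustering of the topic rows under Euclidean distance.
#' Complete linkage is the default (it yields compact, relatively independent
#' clusters); Ward's method (on squared Euclidean distance, \code{ward.D2})
#' is available. Ties in merge heights are resolved by \code{stats::hclust}'s
#' deterministic (input-order) rule, so results are reproducible for a fixed
#' topic order.
#'
#' @param tm A \code{topic_matrix} (or bare numeric matrix, rows = topics).
#' @param method "complete" or "ward".
#' @return An \code{hclust} linkage tree.
#' @export
hcluster <- function(tm, method = c("complete", "ward")) {
  method <- match.arg(method)
  m <- if (inherits(tm, "topic_matrix")) tm$values else tm
  stopifnot(nrow(m) >= 2)
  if (any(!is.finite(m))) stop("non-finite values in topic matrix")
  hclust(dist(m), method = switch(method, complete = "complete",
                                  ward = "ward.D2"))
}

#' Cut a linkage tree into k clusters
#'
#' @param linkage An \code{hclust} tree.
#' @param k Number of clusters (1..T).
#' @param source Provenance label ("cerebellar", "whole_brain", ...).
#' @return A \code{cluster_model}: \code{assignment} (named topic -> cluster
#'   in 1..k), \code{k}, \code{linkage}, \code{source}.
#' @export
cut_model <- function(linkage, k, source = "cerebellar") {
  n <- length(linkage$order)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  assignment <- cutree(linkage, k = k)
  structure(list(assignment = assignment, k = k, linkage = linkage,
                 source = source),
            class = "cluster_model")
}

#' Build a cluster model from a bare topic-to-cluster assignment
#'
#' Used when an assignment is loaded back from disk (no linkage tree).
#'
#' @param assignment Named integer vector topic -> cluster in 1..k.
#' @param source Provenance label.
#' @return A \code{cluster_model}.
#' @export
cluster_model_from_assignment <- function(assignment, source = "loaded") {
  assignment <- unlist(assignment)
  storage.mode(assignment) <- "integer"
  k <- max(assignment)
  if (!setequal(unique(assignment), seq_len(k)))
    stop("assignment must be surjective onto 1..k")
  structure(list(assignment = assignment, k = k, linkage = NULL,
                 source = source),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d topics in %d clusters (%s)\n",
              length(x$assignment), x$k, x$source))
  invisible(x)
}

#' Reconcile cerebellar and whole-brain cluster solutions
#'
#' Starts from the cerebellar assignment and gives it priority: a cerebellar
#' cluster whose members fall into several whole-brain clusters is kept
#' intact if those members join in the whole-brain tree at a height of at
#' most \code{split_ratio_threshold} times that tree's maximum merge height
#' (i.e. the whole-brain solution considers them relatively close);
#' otherwise the cluster is split as the whole-brain tree dictates.
#'
#' @param cb A \code{cluster_model} from the cerebellar run.
#' @param wb_linkage \code{hclust} tree from the whole-brain run (same
#'   topics).
#' @param k_wb Cluster count at which the whole-brain tree is read (default
#'   \code{cb$k}).
#' @param split_ratio_threshold Fraction of the whole-brain tree's maximum
#'   merge height below which a split is ignored (default 0.5).
#' @return A \code{cluster_model} (source "reconciled") with a
#'   \code{decisions} data.frame recording every kept/split call.
#' @export
reconcile <- function(cb, wb_linkage, k_wb = cb$k,
                      split_ratio_threshold = 0.5) {
  topics <- names(cb$assignment)
  if (!setequal(topics, wb_linkage$labels))
    stop("cerebellar and whole-brain models cover different topic sets")
  wb_assign <- cutree(wb_linkage, k = k_wb)[topics]
  coph <- as.matrix(cophenetic(wb_linkage))[topics, topics]
  hmax <- max(wb_linkage$height)
  out <- integer(length(topics)); names(out) <- topics
  decisions <- list()
  nxt <- 0L
  for (c_id in sort(unique(cb$assignment))) {
    members <- topics[cb$assignment == c_id]
    parts <- unique(wb_assign[members])
    if (length(parts) <= 1L) {
      nxt <- nxt + 1L
      out[members] <- nxt
      next
    }
    join_h <- max(coph[members, members])
    if (join_h <= split_ratio_threshold * hmax) {
      nxt <- nxt + 1L
      out[members] <- nxt
      decisions[[length(decisions) + 1L]] <- data.frame(
        cb_cluster = c_id, action = "kept", join_height = join_h,
        threshold = split_ratio_threshold * hmax,
        members = paste(members, collapse = ","))
    } else {
      for (p in parts) {
        nxt <- nxt + 1L
        out[members[wb_assign[members] == p]] <- nxt
      }
      decisions[[length(decisions) + 1L]] <- data.frame(
        cb_cluster = c_id, action = "split", join_height = join_h,
        threshold = split_ratio_threshold * hmax,
        members = paste(members, collapse = ","))
    }
  }
  model <- structure(list(assignment = out, k = nxt, linkage = cb$linkage,
                          source = "reconciled"),
                     class = "cluster_model")
  model$decisions <- if (length(decisions)) do.call(rbind, decisions)
                     else data.frame()
  model
}
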