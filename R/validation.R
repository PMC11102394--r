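#' Rand and adjusted Rand similarity of two labelings
#'
#' The Rand index is the fraction of element pairs on which two partitions
#' agree (joined in both or separated in both); the adjusted Rand index
#' (Hubert-Arabie) corrects it for chance agreement from the contingency
#' table, so 0 is the expected value under independent random partitions.
#'
#' @param l1,l2 Label vectors of equal length (any atomic type).
#' @return List: \code{rand}, \code{adjusted_rand}, \code{contingency},
#'   \code{n}.
#' @export
rand_index <- function(l1, l2) {
  stopifnot(length(l1) == length(l2), length(l1) >= 2)
  tab <- table(l1, l2)
  n <- length(l1)
  sum_ij <- sum(tab^2)
  sum_i <- sum(rowSums(tab)^2)
  sum_j <- sum(colSums(tab)^2)
  npairs <- choose(n, 2)
  rand <- (npairs + sum_ij - (sum_i + sum_j) / 2) / npairs
  comb2 <- function(x) x * (x - 1) / 2
  s_ij <- sum(comb2(tab))
  s_i <- sum(comb2(rowSums(tab)))
  s_j <- sum(comb2(colSums(tab)))
  expected <- s_i * s_j / npairs
  maximum <- (s_i + s_j) / 2
  ari <- if (maximum == expected) 1 else (s_ij - expected) /
    (maximum - expected)
  list(rand = rand, adjusted_rand = ari, contingency = tab, n = n)
}

# apply a merge map to labels: mapped labels get their group, unmapped
# non-zero labels collapse to "other"
apply_merge <- function(labels, merge = NULL) {
  labels <- as.character(labels)
  if (is.null(merge)) return(labels)
  out <- rep("other", length(labels))
  hit <- labels %in% names(merge)
  out[hit] <- merge[labels[hit]]
  out
}

#' Compare two parcellations with merging rules
#'
#' Restricts the comparison to voxels labeled (non-zero) in both
#' parcellations, applies optional merge maps (labels not covered by a map
#' collapse into a single "other" category), and computes Rand and adjusted
#' Rand indices.
#'
#' @param p1,p2 \code{parcellation}s on the same grid.
#' @param merge1,merge2 Optional named character vectors mapping legend
#'   names to merged category names.
#' @return A similarity report: \code{rand}, \code{adjusted_rand},
#'   \code{contingency}, \code{n}, and the merge maps used.
#' @export
rand_report <- function(p1, p2, merge1 = NULL, merge2 = NULL) {
  stopifnot(identical(p1$volume$grid$shape, p2$volume$grid$shape))
  v1 <- as.integer(p1$volume$values)
  v2 <- as.integer(p2$volume$values)
  both <- v1 > 0 & v2 > 0
  if (!any(both)) stop("no voxel is labeled in both parcellations")
  n1 <- p1$legend[as.character(v1[both])]
  n2 <- p2$legend[as.character(v2[both])]
  res <- rand_index(apply_merge(n1, merge1), apply_merge(n2, merge2))
  res$merge1 <- merge1
  res$merge2 <- merge2
  res
}

#' Single-network similarity of two parcellations
#'
#' Binarizes both parcellations into "network vs other" before computing the
#' Rand indices, so each network's spatial agreement can be judged on its
#' own. If the network is absent from both, the comparison is degenerate
#' (single-class) and flagged.
#'
#' @param p1,p2 \code{parcellation}s on the same grid.
#' @param network Network (legend) name.
#' @param merge1,merge2 Optional merge maps applied before binarization.
#' @return A similarity report with an added \code{degenerate} flag.
#' @export
per_network_rand <- function(p1, p2, network, merge1 = NULL, merge2 = NULL) {
  bin <- function(merge, legend) {
    nm <- if (is.null(merge)) structure(legend, names = legend)
          else merge
    out <- ifelse(nm == network, network, "other")
    names(out) <- names(nm)
    out
  }
  res <- rand_report(p1, p2, bin(merge1, p1$legend), bin(merge2, p2$legend))
  res$degenerate <- nrow(res$contingency) < 2 && ncol(res$contingency) < 2
  res
}

# documented distance-bin rule: distances are rounded to the nearest 2 mm,
# then assigned to the nearest bin centre (6, 10, ..., 50 mm); a rounded
# distance exactly midway between two centres goes to the lower centre;
# distances beyond the +-2 mm window of every centre are unbinned (NA)
dcbc_bin <- function(d, centers) {
  r <- round(d / 2) * 2
  step <- centers[2] - centers[1]
  k <- ceiling((r - centers[1]) / step - 0.5) + 1  # midpoint -> lower centre
  k <- pmin(pmax(k, 1L), length(centers))
  k[abs(r - centers[k]) > 2] <- NA
  k
}

#' Distance-controlled boundary coefficient (DCBC)
#'
#' For voxel pairs at matched spatial distances, compares the mean Pearson
#' correlation of topic activation profiles between same-parcel pairs
#' (within) and different-parcel pairs (between): DCBC = within - between,
#' per distance bin. Positive values indicate that parcel boundaries
#' separate functionally dissimilar tissue beyond what distance alone
#' explains. Correlations are plain Pearson; negative covariances are not
#' truncated. Pair distances are rounded to the nearest 2 mm and assigned to
#' bins centred at 6, 10, ..., 50 mm (see the documented bin rule);
#' unpopulated bins are reported as NA, not zero.
#'
#' @param parc A \code{parcellation}.
#' @param profiles A \code{topic_matrix} on the same masked voxels.
#' @param centers Bin centres in mm (default \code{seq(6, 50, by = 4)}).
#' @param pair_budget Maximum number of sampled pairs; below the budget all
#'   pairs are enumerated exactly (default 2e6).
#' @param seed Seed for pair subsampling.
#' @return A \code{dcbc_result} data.frame: per bin, the centre, within and
#'   between mean correlations, pair counts, and \code{dcbc}.
#' @export
dcbc <- function(parc, profiles, centers = seq(6, 50, by = 4),
                 pair_budget = 2e6, seed = 1L) {
  lab <- parcellation_labels(parc)
  keep <- lab > 0
  lab <- lab[keep]
  if (length(unique(lab)) < 2)
    stop("DCBC needs at least two parcels (no between-parcel pairs)")
  xyz <- grid_coordinates(profiles$grid)[profiles$voxels, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  prof <- profiles$values[, keep, drop = FALSE]
  Tt <- nrow(prof)
  mu <- colMeans(prof)
  sdv <- apply(prof, 2, sd)
  ok_sd <- sdv > 0
  zs <- sweep(sweep(prof, 2, mu), 2, ifelse(ok_sd, sdv, 1), "/")
  V <- ncol(zs)
  nb <- length(centers)
  sums <- matrix(0, nb, 2); counts <- matrix(0, nb, 2)
  colnames(sums) <- colnames(counts) <- c("within", "between")

  accumulate <- function(i, j) {
    good <- ok_sd[i] & ok_sd[j]
    i <- i[good]; j <- j[good]
    if (!length(i)) return()
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    b <- dcbc_bin(d, centers)
    sel <- !is.na(b)
    if (!any(sel)) return()
    i <- i[sel]; j <- j[sel]; b <- b[sel]
    r <- colSums(zs[, i, drop = FALSE] * zs[, j, drop = FALSE]) / (Tt - 1)
    cls <- ifelse(lab[i] == lab[j], 1L, 2L)
    for (kk in unique(b)) for (cc in 1:2) {
      pick <- b == kk & cls == cc
      if (any(pick)) {
        sums[kk, cc] <<- sums[kk, cc] + sum(r[pick])
        counts[kk, cc] <<- counts[kk, cc] + sum(pick)
      }
    }
  }

  n_pairs <- V * (V - 1) / 2
  if (n_pairs <= pair_budget) {
    chunk <- max(1L, floor(5e5 / V))
    i0 <- 1L
    while (i0 < V) {
      i1 <- min(V - 1L, i0 + chunk - 1L)
      ii <- rep(i0:i1, times = V - (i0:i1))
      jj <- unlist(lapply(i0:i1, function(i) (i + 1L):V))
      accumulate(ii, jj)
      i0 <- i1 + 1L
    }
  } else {
    set.seed(seed)
    m <- as.integer(pair_budget)
    ii <- sample.int(V, m, replace = TRUE)
    jj <- sample.int(V, m, replace = TRUE)
    sel <- ii < jj
    accumulate(ii[sel], jj[sel])
  }

  within_r <- ifelse(counts[, 1] > 0, sums[, 1] / counts[, 1], NA)
  between_r <- ifelse(counts[, 2] > 0, sums[, 2] / counts[, 2], NA)
  structure(data.frame(center_mm = centers, within_r = within_r,
                       between_r = between_r,
                       dcbc = within_r - between_r,
                       n_within = counts[, 1], n_between = counts[, 2]),
            class = c("dcbc_result", "data.frame"))
}

# split the studies of one topic into two non-overlapping halves; the extra
# study of an odd count goes to half A; with paired = TRUE and a pair_id
# column, one member of each pair goes to each half (identical halves when
# pairs are duplicates)
split_topic_studies <- function(studies, paired = FALSE) {
  if (paired && !is.null(studies$pair_id)) {
    first <- !duplicated(studies$pair_id)
    return(list(a = studies$study_id[first], b = studies$study_id[!first]))
  }
  ids <- sample(studies$study_id)
  na <- ceiling(length(ids) / 2)
  list(a = ids[seq_len(na)], b = ids[-seq_len(na)])
}

#' Duplicate every study of a database
#'
#' Utility for reliability checks: each study appears twice (suffixed ids,
#' shared \code{pair_id}), so a paired split can produce two identical
#' halves.
#'
#' @param db A \code{topic_database}.
#' @return A \code{topic_database} with 2x the studies.
#' @export
duplicate_database <- function(db) {
  copy <- function(suffix) {
    st <- db$studies
    st$pair_id <- st$study_id
    st$study_id <- paste0(st$study_id, suffix)
    fc <- db$foci
    fc$study_id <- paste0(fc$study_id, suffix)
    list(st = st, fc = fc)
  }
  a <- copy("_a"); b <- copy("_b")
  out <- db
  out$studies <- rbind(a$st, b$st)
  out$foci <- rbind(a$fc, b$fc)
  out
}

#' Split-half reliability of a parcellation
#'
#' Per repetition, the studies of every topic are split into two
#' non-overlapping halves; each half gets its own ALE analysis, z-maps,
#' unity normalization and winner-take-all parcellation using the FIXED
#' topic-to-cluster model from the full run. Reliability is the Rand index
#' between the two halves' parcellations, averaged over repetitions, both on
#' the raw cluster labels and (if a network map is given) after network
#' merging. Per-voxel displacement frequency is the fraction of repetitions
#' in which the halves disagree at that voxel; whitening masks flag voxels
#' whose displacement exceeds the 30/40/50 percent thresholds.
#'
#' @param db A \code{topic_database} (every topic needs >= 2 studies).
#' @param model A \code{cluster_model} fixed from the full analysis.
#' @param grid,kernel,mask,n_bins,max_levels ALE settings (as in
#'   \code{\link{ale_topic}}).
#' @param reps Number of repetitions (default 20).
#' @param seed Integer seed.
#' @param network_map Optional named map legend name -> network.
#' @param paired Use paired splitting over a \code{pair_id} column (see
#'   \code{\link{duplicate_database}}).
#' @param thresholds Whitening thresholds on displacement frequency.
#' @return A \code{split_half_result}: per-rep \code{rand}/\code{ari} (and
#'   network-level variants), their means, the displacement-frequency
#'   \code{volume}, and the whitening masks.
#' @export
split_half <- function(db, model, grid, kernel = kernel_spec(),
                       mask = grid_mask(grid), reps = 20, seed = 1L,
                       n_bins = 2000, max_levels = 128,
                       network_map = NULL, paired = FALSE,
                       thresholds = c(0.3, 0.4, 0.5)) {
  counts <- studies_per_topic(db)
  if (any(counts < 2))
    stop("every topic needs >= 2 studies for a half split: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  topics <- db$topics
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, reps)
  rand <- ari <- rand_net <- ari_net <- numeric(reps)
  disagree <- array(0, dim = grid$shape)
  half_parc <- function(ids) {
    sub <- db
    sub$studies <- db$studies[db$studies$study_id %in% ids, , drop = FALSE]
    sub$foci <- db$foci[db$foci$study_id %in% ids, , drop = FALSE]
    zv <- lapply(topics, function(tp)
      ale_topic(sub, tp, grid, kernel, mask, n_bins = n_bins,
                max_levels = max_levels)$z)
    names(zv) <- topics
    winner_take_all(cluster_scores(topic_matrix(zv, mask), model))
  }
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    halves <- lapply(topics, function(tp)
      split_topic_studies(db$studies[db$studies$topic == tp, , drop = FALSE],
                          paired = paired))
    pa <- half_parc(unlist(lapply(halves, `[[`, "a")))
    pb <- half_parc(unlist(lapply(halves, `[[`, "b")))
    res <- rand_report(pa, pb)
    rand[r] <- res$rand; ari[r] <- res$adjusted_rand
    if (!is.null(network_map)) {
      resn <- rand_report(merge_networks(pa, network_map),
                          merge_networks(pb, network_map))
      rand_net[r] <- resn$rand; ari_net[r] <- resn$adjusted_rand
    }
    va <- as.integer(pa$volume$values); vb <- as.integer(pb$volume$values)
    disagree <- disagree + array((va != vb) & (va > 0 | vb > 0),
                                 dim = grid$shape)
  }
  freq <- disagree / reps
  whitened <- lapply(thresholds, function(th)
    volume(grid, array(as.integer(freq > th & mask), dim = grid$shape),
           mask = mask))
  names(whitened) <- paste0("gt", round(100 * thresholds))
  structure(list(rand = rand, ari = ari,
                 mean_rand = mean(rand), mean_ari = mean(ari),
                 rand_network = if (is.null(network_map)) NULL else rand_net,
                 ari_network = if (is.null(network_map)) NULL else ari_net,
                 mean_rand_network = if (is.null(network_map)) NULL
                                     else mean(rand_net),
                 displacement = volume(grid, freq, mask = mask),
                 whitened = whitened, reps = reps),
            class = "split_half_result")
}

#' Score a parcellation against planted ground truth
#'
#' Rasterizes the planted regions on the parcellation's grid and compares
#' labels on the voxels labeled in both (Rand / adjusted Rand).
#'
#' @param parc A \code{parcellation}.
#' @param truth A \code{ground_truth}.
#' @param spec Geometric mask used for rasterization.
#' @return A similarity report (see \code{\link{rand_report}}).
#' @export
recovery_score <- function(parc, truth, spec = mask_spec()) {
  tv <- rasterize_truth(truth, parc$volume$grid, spec)
  truth_parc <- structure(
    list(volume = tv,
         legend = structure(as.character(truth$regions$region),
                            names = as.character(truth$regions$region)),
         n_ties = 0L),
    class = "parcellation")
  rand_report(parc, truth_parc)
}
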