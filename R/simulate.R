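#' Simulation configuration for synthetic coordinate databases
#'
#' Defines the study conditions a synthetic database is generated under:
#' how many studies load on each topic, how many peaks a study reports, how
#' large its sample is, how tightly peaks scatter around their generating
#' region, and what fraction of peaks is unrelated background.
#'
#' @param studies_per_topic Studies per topic (default 40).
#' @param foci_per_study_mean Mean reported peaks per study (1 + Poisson,
#'   default mean 8).
#' @param n_participants_mean Mean participants per study (Poisson, floored at
#'   5; default 20, a typical task-fMRI group size).
#' @param focus_scatter_sd Isotropic Gaussian scatter of peaks around their
#'   region centre, mm (default 6).
#' @param background_rate Fraction of peaks drawn uniformly over the mask
#'   rather than from a region (default 0.1).
#' @param flag_rates Named numeric vector: per-study probability of each
#'   screening flag (default none).
#' @param seed Integer seed; the generator fans it out into per-study
#'   substreams so that adding studies never perturbs earlier ones.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(studies_per_topic = 40, foci_per_study_mean = 8,
                       n_participants_mean = 20, focus_scatter_sd = 6,
                       background_rate = 0.1, flag_rates = numeric(),
                       seed = 1L) {
  stopifnot(studies_per_topic >= 1, foci_per_study_mean > 0,
            n_participants_mean >= 1, focus_scatter_sd >= 0,
            background_rate >= 0, background_rate <= 1,
            all(flag_rates >= 0 & flag_rates <= 1))
  structure(list(studies_per_topic = as.integer(studies_per_topic),
                 foci_per_study_mean = foci_per_study_mean,
                 n_participants_mean = n_participants_mean,
                 focus_scatter_sd = focus_scatter_sd,
                 background_rate = background_rate,
                 flag_rates = flag_rates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted ground truth for a synthetic database
#'
#' Each region is a sphere (centre, radius) inside the cerebellar mask; each
#' topic belongs to one latent cluster and emits peaks from the regions it
#' weights. This is the latent structure the topic clustering is assumed to
#' recover.
#'
#' @param regions data.frame with columns \code{region}, \code{cx}, \code{cy},
#'   \code{cz} (centre, mm) and \code{radius} (mm, positive).
#' @param topic_groups Named integer vector: topic id -> cluster id.
#' @param topic_region_weights Matrix (topics x regions) of emission
#'   probabilities; each row sums to 1. Defaults to each topic emitting only
#'   from the region of its own cluster (regions indexed by cluster id).
#' @param check_mask If TRUE (cerebellar scenario), region centres must lie
#'   inside the geometric mask.
#' @return A \code{ground_truth} object.
#' @export
ground_truth <- function(regions, topic_groups, topic_region_weights = NULL,
                         check_mask = TRUE) {
  stopifnot(all(c("region", "cx", "cy", "cz", "radius") %in% names(regions)),
            all(regions$radius > 0))
  topics <- names(topic_groups)
  if (is.null(topic_region_weights)) {
    topic_region_weights <- matrix(0, length(topics), nrow(regions),
                                   dimnames = list(topics, regions$region))
    for (t in topics)
      topic_region_weights[t, topic_groups[[t]]] <- 1
  }
  stopifnot(nrow(topic_region_weights) == length(topics),
            ncol(topic_region_weights) == nrow(regions),
            all(abs(rowSums(topic_region_weights) - 1) < 1e-9))
  if (check_mask) {
    centers <- as.matrix(regions[, c("cx", "cy", "cz")])
    inside <- in_geometric_mask(centers)
    if (!all(inside))
      stop("ground-truth region centre outside the cerebellar mask: ",
           paste(regions$region[!inside], collapse = ", "))
  }
  structure(list(regions = regions, topic_groups = topic_groups,
                 topic_region_weights = topic_region_weights,
                 check_mask = check_mask),
            class = "ground_truth")
}

#' Reference synthetic scenario
#'
#' Twelve topics in four latent clusters (three topics per cluster), each
#' cluster anchored at one of four well-separated spherical regions inside the
#' cerebellar mask; 40 studies per topic, 6 mm peak scatter, 10 percent
#' uniform background. This is the scenario used throughout the package's
#' recovery tests.
#'
#' @param n_groups Number of latent clusters (at most 4 at default geometry).
#' @param topics_per_group Topics per cluster.
#' @param seed Seed stored in the paired \code{sim_config}.
#' @return List with \code{truth} (a \code{ground_truth}) and \code{cfg}
#'   (a \code{sim_config}).
#' @export
reference_scenario <- function(n_groups = 4, topics_per_group = 3, seed = 1L) {
  centers <- rbind(c(-32, -60, -28), c(32, -60, -28),
                   c(0, -85, -25), c(0, -52, -14))[seq_len(n_groups), ,
                                                   drop = FALSE]
  regions <- data.frame(region = seq_len(n_groups),
                        cx = centers[, 1], cy = centers[, 2],
                        cz = centers[, 3], radius = 15)
  topics <- sprintf("topic%02d", seq_len(n_groups * topics_per_group))
  groups <- rep(seq_len(n_groups), each = topics_per_group)
  names(groups) <- topics
  list(truth = ground_truth(regions, groups),
       cfg = sim_config(seed = seed))
}

# deterministic per-study substream seed below 2^31, keyed by topic and
# study index so adding studies (or topics) never perturbs earlier streams
substream_seed <- function(seed, topic_index, study_index) {
  (as.numeric(seed) * 7919 + topic_index * 15485863 +
     study_index * 104729) %% 2147483629
}

#' Generate a synthetic topic database
#'
#' For each topic, \code{cfg$studies_per_topic} studies are drawn; each study
#' reports \code{1 + Poisson} peaks. A peak is background (uniform over the
#' geometric mask) with probability \code{cfg$background_rate}, otherwise it
#' is the centre of a region sampled by the topic's emission weights plus
#' isotropic Gaussian scatter. Participant counts are Poisson floored at 5.
#' Screening flags are attached per-study at the configured rates. The
#' generator is deterministic given \code{cfg$seed} and uses per-study
#' substreams, so earlier studies are unchanged when studies are added.
#'
#' @param cfg A \code{sim_config}.
#' @param truth A \code{ground_truth}.
#' @param spec Mask used for background sampling (and the region-centre
#'   check), default shipped geometry.
#' @return A \code{topic_database}.
#' @export
generate_database <- function(cfg, truth, spec = mask_spec()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  topics <- names(truth$topic_groups)
  centers <- as.matrix(truth$regions[, c("cx", "cy", "cz")])
  studies <- list(); foci <- list()
  idx <- 0L
  for (ti in seq_along(topics)) {
    topic <- topics[ti]
    w <- truth$topic_region_weights[ti, ]
    for (si in seq_len(cfg$studies_per_topic)) {
      idx <- idx + 1L
      set.seed(substream_seed(cfg$seed, ti, si))
      sid <- sprintf("%s_s%03d", topic, si)
      n_foci <- 1L + stats::rpois(1, cfg$foci_per_study_mean - 1)
      n_part <- max(5L, stats::rpois(1, cfg$n_participants_mean))
      is_bg <- stats::runif(n_foci) < cfg$background_rate
      pts <- matrix(NA_real_, n_foci, 3)
      n_sig <- sum(!is_bg)
      if (n_sig > 0) {
        reg <- sample.int(nrow(centers), n_sig, replace = TRUE, prob = w)
        pts[!is_bg, ] <- centers[reg, , drop = FALSE] +
          matrix(stats::rnorm(3 * n_sig, sd = cfg$focus_scatter_sd),
                 n_sig, 3)
      }
      if (any(is_bg))
        pts[is_bg, ] <- uniform_in_mask(sum(is_bg), spec)
      flags <- names(cfg$flag_rates)[
        stats::runif(length(cfg$flag_rates)) < cfg$flag_rates]
      studies[[idx]] <- data.frame(study_id = sid, n_participants = n_part,
                                   topic = topic, stringsAsFactors = FALSE)
      studies[[idx]]$screening_flags <- list(flags)
      studies[[idx]]$terms <- list(character())
      foci[[idx]] <- data.frame(study_id = sid, x = pts[, 1], y = pts[, 2],
                                z = pts[, 3])
    }
  }
  topic_database(do.call(rbind, studies), do.call(rbind, foci),
                 topics = topics,
                 provenance = list(generator = "generate_database",
                                   seed = cfg$seed))
}

# rejection-sample points uniformly inside the geometric mask
uniform_in_mask <- function(n, spec = mask_spec()) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 4L + 8L
    cand <- cbind(stats::runif(m, -spec$x_abs_max, spec$x_abs_max),
                  stats::runif(m, spec$y_min, spec$y_max),
                  stats::runif(m, -60, spec$z_max))
    cand <- cand[in_geometric_mask(cand, spec), , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Rasterize planted regions into a label volume
#'
#' Each in-mask voxel is assigned the label of the nearest region centre
#' (a Voronoi partition restricted to the mask), giving the planted
#' parcellation that recovery is scored against.
#'
#' @param truth A \code{ground_truth}.
#' @param grid A \code{voxel_grid}.
#' @param spec Geometric mask.
#' @return A \code{volume} of integer labels (0 outside the mask).
#' @export
rasterize_truth <- function(truth, grid, spec = mask_spec()) {
  mask <- grid_mask(grid, spec)
  xyz <- grid_coordinates(grid, mask)
  centers <- as.matrix(truth$regions[, c("cx", "cy", "cz")])
  d2 <- sapply(seq_len(nrow(centers)), function(r)
    rowSums(sweep(xyz, 2, centers[r, ])^2))
  lab <- truth$regions$region[max.col(-d2, ties.method = "first")]
  vals <- array(0L, dim = grid$shape)
  vals[mask] <- lab
  volume(grid, vals, mask = mask)
}

#' Generate a synthetic term-by-study incidence structure
#'
#' For each topic, the first term receives \code{n_studies} study ids; each
#' later term receives a study set whose Jaccard overlap with the first
#' term's set matches the requested target (shared ids plus fresh ids).
#'
#' @param topics Named list: topic id -> ordered character vector of terms.
#' @param target_overlap Either a single value applied to all non-leading
#'   terms or a named list (per topic) of per-term targets for terms 2..k.
#'   Targets are Jaccard fractions in [0, 1].
#' @param n_studies Studies per term set (default 200).
#' @param seed Integer seed.
#' @return A \code{term_incidence} object (see \code{\link{term_incidence}}).
#' @export
generate_term_incidence <- function(topics, target_overlap = 0.4,
                                    n_studies = 200, seed = 1L) {
  set.seed(seed)
  sets <- list()
  fresh <- 0L
  new_ids <- function(k) {
    ids <- sprintf("study%06d", fresh + seq_len(k)); fresh <<- fresh + k; ids
  }
  for (topic in names(topics)) {
    terms <- topics[[topic]]
    s1 <- new_ids(n_studies)
    sets[[terms[1]]] <- s1
    for (a in seq_along(terms)[-1]) {
      t <- if (is.list(target_overlap)) target_overlap[[topic]][a - 1]
           else target_overlap
      if (t < 0 || t > 1)
        stop("infeasible overlap target ", t,
             ": required shared count exceeds the marginal set size")
      k <- round(2 * n_studies * t / (1 + t))
      sets[[terms[a]]] <- c(sample(s1, k), new_ids(n_studies - k))
    }
  }
  term_incidence(sets, topics)
}
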