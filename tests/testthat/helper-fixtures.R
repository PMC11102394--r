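# shared fixtures and independent oracles

# tiny database builder: one study per row of `studies`, foci supplied as a
# list of n x 3 matrices in the same order
tiny_db <- function(topics, n_participants, foci, flags = NULL) {
  ids <- sprintf("s%02d", seq_along(topics))
  st <- data.frame(study_id = ids, n_participants = n_participants,
                   topic = topics, stringsAsFactors = FALSE)
  st$screening_flags <- if (is.null(flags))
    replicate(length(ids), character(), simplify = FALSE) else flags
  fc <- do.call(rbind, lapply(seq_along(ids), function(i) {
    m <- foci[[i]]
    data.frame(study_id = ids[i], x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  topic_database(st, fc)
}

# brute-force Rand / adjusted Rand by enumerating all element pairs
rand_oracle <- function(l1, l2) {
  n <- length(l1)
  agree <- 0; together1 <- 0; together2 <- 0; both <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    t1 <- l1[i] == l1[j]; t2 <- l2[i] == l2[j]
    agree <- agree + (t1 == t2)
    together1 <- together1 + t1; together2 <- together2 + t2
    both <- both + (t1 && t2)
    total <- total + 1
  }
  expected <- together1 * together2 / total
  maximum <- (together1 + together2) / 2
  list(rand = agree / total,
       adjusted_rand = if (maximum == expected) 1 else
         (both - expected) / (maximum - expected))
}

# brute-force distance binner implementing the documented rule one pair at
# a time: round to nearest 2 mm, nearest centre, midpoint to lower centre
bin_oracle <- function(d, centers) {
  r <- round(d / 2) * 2
  best <- NA
  for (k in seq_along(centers)) {
    off <- abs(r - centers[k])
    if (off > 2) next
    if (is.na(best) || off < abs(r - centers[best])) best <- k
  }
  best
}

# parcellation from a label vector over the masked voxels of a grid
mk_parc_grid <- function(labels, grid, mask) {
  vals <- array(0L, dim = grid$shape)
  vals[as.vector(mask)] <- as.integer(labels)
  u <- sort(unique(labels[labels > 0]))
  structure(list(volume = volume(grid, vals, mask = mask),
                 legend = structure(as.character(u),
                                    names = as.character(u)),
                 n_ties = 0L),
            class = "parcellation")
}

# small 3-cluster score fixture on an 1-voxel-spacing toy grid
toy_scores <- function(values, spacing = 1) {
  nv <- ncol(values)
  grid <- voxel_grid(c(nv, 1, 1), spacing = spacing)
  mask <- array(TRUE, dim = grid$shape)
  rownames(values) <- seq_len(nrow(values))
  structure(list(values = values, clusters = seq_len(nrow(values)),
                 voxels = seq_len(nv), grid = grid, mask = mask),
            class = "cluster_scores")
}
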