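#' Term-by-study incidence structure
#'
#' Holds, for every candidate key term, the set of study ids mentioning it,
#' together with each topic's ordered candidate-term list. Term centrality
#' within a topic is always computed relative to the topic's first (most
#' representative) term.
#'
#' @param sets Named list: term -> character vector of study ids.
#' @param topics Named list: topic id -> ordered character vector of terms.
#' @return A \code{term_incidence} object.
#' @export
term_incidence <- function(sets, topics) {
  stopifnot(is.list(sets), is.list(topics), length(topics) > 0)
  if (any(!vapply(topics, length, 1L)))
    stop("every topic needs a non-empty candidate term list")
  missing <- setdiff(unlist(topics), names(sets))
  if (length(missing))
    stop("terms without study sets: ", paste(missing, collapse = ", "))
  structure(list(sets = lapply(sets, unique), topics = topics),
            class = "term_incidence")
}

term_sets <- function(incidence, topic) {
  terms <- incidence$topics[[topic]]
  if (is.null(terms)) stop("unknown topic: ", topic)
  incidence$sets[terms]
}

#' Within-topic term uniqueness
#'
#' The relative increase in the cumulative study pool when term \code{a} is
#' added: \code{|S1 u ... u Sa| / |S1 u ... u S(a-1)|}, where \code{Si} is the
#' study set of the topic's i-th term. A value of 1 means term \code{a}
#' contributes no new studies; larger values mean the term pulls in studies
#' not covered so far.
#'
#' @param incidence A \code{term_incidence}.
#' @param topic Topic id.
#' @param a Term index (>= 2).
#' @return The uniqueness ratio (>= 1).
#' @export
uniqueness <- function(incidence, topic, a) {
  sets <- term_sets(incidence, topic)
  stopifnot(a >= 2, a <= length(sets))
  prev <- unique(unlist(sets[seq_len(a - 1)]))
  if (length(prev) == 0L)
    stop("cumulative study union through term ", a - 1,
         " is empty: uniqueness undefined")
  length(unique(unlist(sets[seq_len(a)]))) / length(prev)
}

#' Within-topic term overlap
#'
#' The fraction of the cumulative study pool shared between term \code{a} and
#' the leading term: \code{|S1 n Sa| / |S1 u ... u Sa|}. High overlap means
#' term \code{a} names largely the same studies as the topic's most
#' representative term.
#'
#' @inheritParams uniqueness
#' @return The overlap ratio in [0, 1].
#' @export
overlap <- function(incidence, topic, a) {
  sets <- term_sets(incidence, topic)
  stopifnot(a >= 2, a <= length(sets))
  cum <- unique(unlist(sets[seq_len(a)]))
  if (length(cum) == 0L)
    stop("cumulative study union through term ", a, " is empty")
  length(intersect(sets[[1]], sets[[a]])) / length(cum)
}

#' Centrality table for a topic's candidate terms
#'
#' @inheritParams uniqueness
#' @return data.frame with one row per term (index, term, uniqueness,
#'   overlap, cumulative study count); the leading term has NA centrality.
#' @export
term_centrality <- function(incidence, topic) {
  sets <- term_sets(incidence, topic)
  k <- length(sets)
  data.frame(
    topic = topic, a = seq_len(k), term = names(sets),
    uniqueness = c(NA, vapply(seq_len(k)[-1], function(a)
      uniqueness(incidence, topic, a), 1)),
    overlap = c(NA, vapply(seq_len(k)[-1], function(a)
      overlap(incidence, topic, a), 1)),
    cumulative_studies = vapply(seq_len(k), function(a)
      length(unique(unlist(sets[seq_len(a)]))), 1L),
    stringsAsFactors = FALSE)
}

#' Select key terms per topic by centrality
#'
#' Keeps at most \code{max_terms} leading terms per topic (terms must be
#' unique across topics), computes per-term overlap and uniqueness, and drops
#' terms whose overlap falls below \code{omission_fraction} times the grand
#' mean overlap. The grand mean is pooled over all topics' terms 2..max_terms
#' and computed before any omission. Term order (and any centrality-driven
#' reordering) affects reporting only, never which studies a topic selects:
#' the topic's study pool is the union over its kept terms' sets, which is
#' order-invariant.
#'
#' @param incidence A \code{term_incidence}.
#' @param max_terms Maximum key terms per topic (default 5).
#' @param omission_fraction Omission threshold as a fraction of the grand
#'   mean overlap (default 0.25).
#' @param pool c("terms", "topics"): whether the grand mean pools all term
#'   rows or averages per-topic means (default pooled term rows).
#' @return List with \code{centrality} (data.frame over all topics, with a
#'   \code{kept} column), \code{threshold} (the absolute omission cut),
#'   \code{kept} (named list topic -> kept terms) and \code{studies} (named
#'   list topic -> selected study ids, union over kept terms).
#' @export
select_terms <- function(incidence, max_terms = 5, omission_fraction = 0.25,
                         pool = c("terms", "topics")) {
  pool <- match.arg(pool)
  topics <- names(incidence$topics)
  all_terms <- unlist(lapply(topics, function(t)
    head(incidence$topics[[t]], max_terms)))
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup)) {
    owners <- topics[vapply(topics, function(t)
      dup[1] %in% head(incidence$topics[[t]], max_terms), TRUE)]
    stop(sprintf("term '%s' is shared between topics %s: %s",
                 dup[1], owners[1], owners[2]))
  }
  trimmed <- incidence
  trimmed$topics <- lapply(incidence$topics, head, max_terms)
  cent <- do.call(rbind, lapply(topics, function(t)
    term_centrality(trimmed, t)))
  later <- cent[cent$a >= 2, , drop = FALSE]
  grand_mean <- if (pool == "terms") mean(later$overlap)
                else mean(tapply(later$overlap, later$topic, mean))
  threshold <- omission_fraction * grand_mean
  cent$kept <- cent$a == 1 | cent$overlap >= threshold
  kept <- lapply(topics, function(t)
    cent$term[cent$topic == t & cent$kept])
  names(kept) <- topics
  studies <- lapply(kept, function(terms)
    unique(unlist(incidence$sets[terms])))
  list(centrality = cent, threshold = threshold, grand_mean = grand_mean,
       kept = kept, studies = studies)
}

#' Load the shipped functional topic configuration
#'
#' The package ships the 22 functional topics of the NeuroSynth
#' v5-topics-50 release with their ordered key terms (up to five per topic,
#' unique across topics), as used for the cerebellar parcellation.
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return Named list: topic id -> ordered character vector of key terms.
#' @export
load_topic_config <- function(path = system.file("extdata",
                                                 "paper_topics.yaml",
                                                 package = "cbparcel")) {
  cfg <- yaml::read_yaml(path)
  topics <- lapply(cfg$topics, function(t) as.character(t$terms))
  names(topics) <- vapply(cfg$topics, function(t) as.character(t$id),
                          character(1))
  topics
}

#' Load the shipped cluster-to-network map
#'
#' Maps the 10 functional clusters onto 7 networks (the three executive
#' clusters merge, as do the two limbic clusters).
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return Named character vector: cluster label -> network name.
#' @export
load_network_config <- function(path = system.file("extdata",
                                                   "networks.yaml",
                                                   package = "cbparcel")) {
  cfg <- yaml::read_yaml(path)
  out <- vapply(cfg$networks, function(x) as.character(x$network),
                character(1))
  names(out) <- vapply(cfg$networks, function(x) as.character(x$cluster),
                       character(1))
  out
}
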