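#' Construct a topic database
#'
#' The central container for coordinate-based meta-analysis: one row per
#' study with participant count, topic membership, screening flags and key
#' terms, plus a long table of activation foci (peak coordinates, MNI mm).
#'
#' @param studies data.frame with columns \code{study_id} (character),
#'   \code{n_participants} (positive integer), \code{topic} (character), and
#'   list columns \code{screening_flags} and \code{terms} (character vectors;
#'   optional, default empty).
#' @param foci data.frame with columns \code{study_id}, \code{x}, \code{y},
#'   \code{z} (world mm).
#' @param topics Character vector of topic ids (defaults to those present).
#' @param provenance Free-form list (e.g. generator seed and settings).
#' @return An object of class \code{topic_database}.
#' @export
topic_database <- function(studies, foci, topics = NULL, provenance = list()) {
  studies <- as.data.frame(studies)
  foci <- as.data.frame(foci)
  stopifnot(all(c("study_id", "n_participants", "topic") %in% names(studies)),
            all(c("study_id", "x", "y", "z") %in% names(foci)))
  if (any(studies$n_participants < 1))
    stop("n_participants must be >= 1 for every study")
  if (anyDuplicated(studies$study_id))
    stop("duplicate study_id in studies table")
  if (!all(foci$study_id %in% studies$study_id))
    stop("foci reference unknown study_id")
  if (is.null(studies$screening_flags))
    studies$screening_flags <- replicate(nrow(studies), character(),
                                         simplify = FALSE)
  if (is.null(studies$terms))
    studies$terms <- replicate(nrow(studies), character(), simplify = FALSE)
  if (is.null(topics)) topics <- sort(unique(studies$topic))
  if (!all(studies$topic %in% topics))
    stop("study topic not listed in topics")
  structure(list(studies = studies, foci = foci, topics = topics,
                 provenance = provenance),
            class = "topic_database")
}

#' @export
print.topic_database <- function(x, ...) {
  cat(sprintf("<topic_database> %d studies, %d foci, %d topics\n",
              nrow(x$studies), nrow(x$foci), length(x$topics)))
  invisible(x)
}

#' Number of studies per topic
#' @param db A \code{topic_database}.
#' @return Named integer vector over \code{db$topics}.
#' @export
studies_per_topic <- function(db) {
  tab <- table(factor(db$studies$topic, levels = db$topics))
  out <- as.integer(tab)
  names(out) <- db$topics
  out
}

#' Read a foci table from CSV/TSV
#'
#' Expected dialect: one row per focus with mandatory columns
#' \code{study_id}, \code{x}, \code{y}, \code{z}, \code{n} (participants) and
#' \code{topic}; optional columns \code{flags} and \code{terms} hold
#' semicolon-separated values, constant within a study. Study-level fields are
#' taken from each study's first row.
#'
#' @param path CSV (comma) or TSV (tab) file; the delimiter is chosen by file
#'   extension (.tsv/.txt = tab).
#' @return A \code{topic_database}.
#' @export
read_foci_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character")
  mandatory <- c("study_id", "x", "y", "z", "n", "topic")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty foci table: ", path)
    return(topic_database(
      studies = data.frame(study_id = character(), n_participants = integer(),
                           topic = character()),
      foci = data.frame(study_id = character(), x = numeric(), y = numeric(),
                        z = numeric())))
  }
  for (col in c("x", "y", "z", "n")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s at data row %d",
                   raw[[col]][bad[1]], col, bad[1]))
    raw[[col]] <- num
  }
  first <- raw[!duplicated(raw$study_id), , drop = FALSE]
  split_field <- function(v) {
    if (is.null(v)) return(replicate(nrow(first), character(),
                                     simplify = FALSE))
    lapply(strsplit(v, ";", fixed = TRUE),
           function(s) s[nzchar(s)])
  }
  studies <- data.frame(study_id = first$study_id,
                        n_participants = as.integer(first$n),
                        topic = first$topic,
                        stringsAsFactors = FALSE)
  studies$screening_flags <- split_field(first$flags)
  studies$terms <- split_field(first$terms)
  topic_database(studies = studies,
                 foci = raw[, c("study_id", "x", "y", "z")],
                 provenance = list(source = path))
}

#' Write a topic database as a TSV foci table
#'
#' Inverse of \code{\link{read_foci_table}} for the documented dialect.
#'
#' @param db A \code{topic_database}.
#' @param path Output path (.tsv).
#' @return \code{path}, invisibly.
#' @export
write_foci_table <- function(db, path) {
  st <- db$studies
  join <- function(v) vapply(v, paste, character(1), collapse = ";")
  meta <- data.frame(study_id = st$study_id, n = st$n_participants,
                     topic = st$topic, flags = join(st$screening_flags),
                     terms = join(st$terms), stringsAsFactors = FALSE)
  out <- merge(db$foci, meta, by = "study_id", sort = FALSE)
  out <- out[, c("study_id", "x", "y", "z", "n", "topic", "flags", "terms")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
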