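# Distance -> taxonomic-level thresholds. The distance between a read and its
# closest reference fragment estimates how high in the taxonomy the read's
# source diverged from anything in the database, and therefore the most
# specific rank ("TL") the assignment may use. Thresholds are read-length
# specific because 4-mer frequencies from shorter reads are noisier.

DEFAULT_CLASSES <- list(
  sanger       = list(min_length = 600L, breaks = c(0.28, 0.32),
                      ranks = c("genus", "family", "class")),
  titanium_400 = list(min_length = 300L, breaks = c(0.35, 0.41),
                      ranks = c("genus", "family", "class")),
  standard_250 = list(min_length = 150L, breaks = c(0.43, 0.51),
                      ranks = c("genus", "family", "class")),
  gs20_100     = list(min_length = 0L, breaks = 0.6,
                      ranks = c("genus", "family"))
)

#' Threshold table mapping compositional distance to assignment rank
#'
#' The defaults encode the published ranges: Sanger-length reads get genus
#' below 0.28, family from 0.28 to 0.32, class above; 454-Titanium 0.35/0.41;
#' 454-Standard 0.43/0.51; 454-GS20 genus below 0.6, family otherwise. A
#' distance landing exactly on a boundary resolves to the less specific rank.
#' Read lengths map to classes at the midpoints between the technologies'
#' nominal lengths: >= 600 bp Sanger, 300-599 Titanium, 150-299 Standard,
#' < 150 GS20.
#'
#' @param classes named list; each element needs `min_length` (inclusive
#'   lower read-length bound selecting the class), strictly increasing
#'   `breaks`, and `ranks` (one more than `breaks`, strictly coarsening).
#' @return an object of class `"threshold_table"`.
#' @export
threshold_table <- function(classes = DEFAULT_CLASSES) {
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    if (!all(c("min_length", "breaks", "ranks") %in% names(cl)))
      stop("class '", nm, "' needs min_length, breaks, ranks")
    if (length(cl$ranks) != length(cl$breaks) + 1L)
      stop("class '", nm, "': need one more rank than breaks")
    if (is.unsorted(cl$breaks, strictly = TRUE))
      stop("class '", nm, "': breaks must strictly increase")
    if (any(diff(rank_pos(cl$ranks)) <= 0))
      stop("class '", nm, "': ranks must strictly coarsen with distance")
  }
  if (!any(vapply(classes, function(cl) cl$min_length == 0L, logical(1))))
    stop("one class must have min_length 0 so every read length is covered")
  structure(list(classes = classes), class = "threshold_table")
}

#' Read-length class of a read
#'
#' @param read_length read length in bp.
#' @param thresholds a [threshold_table()].
#' @return the class name whose length interval contains `read_length`.
#' @export
read_length_class <- function(read_length, thresholds = threshold_table()) {
  mins <- vapply(thresholds$classes, `[[`, numeric(1), "min_length")
  ok <- mins <= read_length
  if (!any(ok)) stop("no read-length class covers length ", read_length)
  names(which.max(mins[ok]))
}

#' Most specific rank allowed for a given closest-fragment distance
#'
#' Picks the read-length class, then the rank whose distance interval
#' contains `d_min`; boundary values resolve to the less specific rank.
#'
#' @param d_min Manhattan distance to the closest reference fragment.
#' @param read_length read length in bp.
#' @param thresholds a [threshold_table()].
#' @return a rank name (`"genus"`, `"family"` or `"class"` under the
#'   defaults).
#' @export
determine_level <- function(d_min, read_length,
                            thresholds = threshold_table()) {
  stopifnot(d_min >= 0)
  cl <- thresholds$classes[[read_length_class(read_length, thresholds)]]
  cl$ranks[1L + sum(d_min >= cl$breaks)]
}

#' Read a threshold table from YAML or TSV
#'
#' YAML mirrors the [threshold_table()] structure:
#' ```yaml
#' sanger: {min_length: 600, breaks: [0.28, 0.32], ranks: [genus, family, class]}
#' ```
#' The TSV dialect is long-format with columns `class`, `min_length`,
#' `rank`, `max_distance` (empty/NA `max_distance` on each class's last,
#' open-ended row).
#'
#' @param path file path; dialect chosen by extension (`.yml`/`.yaml` vs
#'   anything else).
#' @return a [threshold_table()].
#' @export
read_threshold_table <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    classes <- lapply(raw, function(cl)
      list(min_length = as.integer(cl$min_length),
           breaks = as.numeric(cl$breaks),
           ranks = as.character(cl$ranks)))
    return(threshold_table(classes))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("class", "min_length", "rank", "max_distance")
  if (!all(need %in% names(tab)))
    stop("threshold TSV must have columns: ", paste(need, collapse = ", "))
  classes <- lapply(split(tab, tab$class), function(d) {
    d <- d[order(d$max_distance, na.last = TRUE), ]
    list(min_length = as.integer(d$min_length[1L]),
         breaks = as.numeric(d$max_distance[!is.na(d$max_distance)]),
         ranks = as.character(d$rank))
  })
  threshold_table(classes)
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("Distance thresholds for the taxonomic level of assignment:\n")
  for (nm in names(x$classes)) {
    cl <- x$classes[[nm]]
    iv <- character(length(cl$ranks))
    b <- c(0, cl$breaks, Inf)
    for (i in seq_along(cl$ranks))
      iv[i] <- sprintf("%s < %s", cl$ranks[i],
                       ifelse(is.finite(b[i + 1]), format(b[i + 1]), "Inf"))
    cat(sprintf("  %-13s (reads >= %4d bp): %s\n", nm, cl$min_length,
                paste(iv, collapse = ", ")))
  }
  invisible(x)
}
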