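#' Electrode montage
#'
#' A montage bundles the analysis channel labels, the excluded reference
#' labels, flat 2-D layout coordinates and a symmetric neighbourhood
#' structure used for bad-channel interpolation.
#'
#' @param labels character vector of analysis channel names.
#' @param coords numeric matrix (n x 2) of layout coordinates, rows named by
#'   `labels`.
#' @param reference_labels character vector of reference electrode names,
#'   excluded from analysis.
#' @param neighbor_dist maximum layout distance for two channels to count as
#'   neighbours.
#' @return an object of class `eeg_montage` with elements `labels`,
#'   `reference_labels`, `coords` and `adjacency` (named list of character
#'   vectors).
#' @export
montage <- function(labels, coords, reference_labels = character(),
                    neighbor_dist = 1.65) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  if (anyDuplicated(labels)) stop("duplicate channel labels in montage")
  if (length(intersect(labels, reference_labels)) > 0L)
    stop("reference labels must not appear among analysis labels")
  coords <- as.matrix(coords)
  if (nrow(coords) != length(labels)) stop("one coordinate row per label required")
  rownames(coords) <- labels
  d <- as.matrix(stats::dist(coords))
  adjacency <- lapply(seq_along(labels), function(i) {
    nb <- labels[d[i, ] <= neighbor_dist & seq_along(labels) != i]
    nb
  })
  names(adjacency) <- labels
  structure(
    list(labels = labels, reference_labels = reference_labels,
         coords = coords, adjacency = adjacency),
    class = "eeg_montage"
  )
}

#' Default 32-electrode 10-20 montage
#'
#' Thirty analysis channels on the extended international 10-20 layout plus
#' the two mastoid references (M1/M2) used during acquisition. Coordinates
#' are a schematic flat projection (nose up); neighbourhoods are pairs closer
#' than `neighbor_dist` in that projection.
#'
#' @inheritParams montage
#' @return an `eeg_montage` object.
#' @export
default_montage <- function(neighbor_dist = 1.65) {
  pos <- c(
    "Fp1", -1.0,  3.0,  "Fpz", 0.0,  3.0,  "Fp2", 1.0,  3.0,
    "F7",  -3.2,  2.0,  "F3",  -1.6, 2.0,  "Fz",  0.0,  2.0,
    "F4",   1.6,  2.0,  "F8",   3.2, 2.0,
    "FC5", -2.4,  1.0,  "FC1", -0.8, 1.0,  "FC2", 0.8,  1.0,  "FC6", 2.4, 1.0,
    "T7",  -3.2,  0.0,  "C3",  -1.6, 0.0,  "Cz",  0.0,  0.0,
    "C4",   1.6,  0.0,  "T8",   3.2, 0.0,
    "CP5", -2.4, -1.0,  "CP1", -0.8, -1.0, "CP2", 0.8, -1.0,  "CP6", 2.4, -1.0,
    "P7",  -3.2, -2.0,  "P3",  -1.6, -2.0, "Pz",  0.0, -2.0,
    "P4",   1.6, -2.0,  "P8",   3.2, -2.0,
    "POz",  0.0, -2.7,
    "O1",  -1.0, -3.3,  "Oz",   0.0, -3.3, "O2",  1.0, -3.3
  )
  m <- matrix(pos, ncol = 3L, byrow = TRUE)
  labels <- m[, 1L]
  coords <- matrix(as.numeric(m[, 2:3]), ncol = 2L,
                   dimnames = list(labels, c("x", "y")))
  montage(labels, coords, reference_labels = c("M1", "M2"),
          neighbor_dist = neighbor_dist)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " analysis channels, references: ",
      paste(x$reference_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a montage as YAML
#'
#' @param m an `eeg_montage`.
#' @param path file path.
#' @return `read_montage` returns an `eeg_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  yaml::write_yaml(list(
    labels = m$labels,
    reference_labels = m$reference_labels,
    coords = lapply(seq_along(m$labels), function(i) as.numeric(m$coords[i, ])),
    adjacency = m$adjacency
  ), path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  y <- yaml::read_yaml(path)
  coords <- do.call(rbind, lapply(y$coords, as.numeric))
  m <- montage(unlist(y$labels), coords,
               reference_labels = as.character(unlist(y$reference_labels)))
  # keep the serialized adjacency (it may have been hand-edited)
  if (!is.null(y$adjacency)) {
    adj <- lapply(y$adjacency, function(v) as.character(unlist(v)))
    m$adjacency <- adj[m$labels]
  }
  m
}
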