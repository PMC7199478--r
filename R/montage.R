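#' Sensor montage and neighbor graph
#'
#' The 32-channel extended 10-20 layout used throughout the package
#' ("easycap32"). Electrode positions are built from the idealized spherical
#' 10-20 construction on a unit sphere: the head is a unit sphere, the
#' nasion-inion and ear-to-ear arcs span 180 degrees, electrodes sit at the
#' canonical 10%/20% arc fractions, and intermediate 10-10 sites (F3, FC5,
#' CP1, ...) are geodesic midpoints of their four flanking 10-20 sites. No
#' per-subject digitization is modeled. Coordinates use the EEG convention
#' x = right, y = anterior, z = up.
#'
#' @name montage
NULL

# inclination from vertex (deg) and azimuth from nasion direction
# (deg, positive toward the right ear), for the directly-constructed sites
.tentwenty_angles <- function() {
  ring <- 72 # the 10% ring through Fp1/Fp2 ... O1/O2
  list(
    Fp1 = c(ring, -18), Fp2 = c(ring, 18),
    F7  = c(ring, -54), F8  = c(ring, 54),
    T7  = c(ring, -90), T8  = c(ring, 90),
    P7  = c(ring, -126), P8 = c(ring, 126),
    O1  = c(ring, -162), O2 = c(ring, 162),
    Oz  = c(ring, 180),
    Fz  = c(36, 0), Cz = c(0, 0), Pz = c(36, 180),
    C3  = c(36, -90), C4 = c(36, 90),
    # inferior row, 10% below the ring
    TP9 = c(90, -108), TP10 = c(90, 108),
    PO9 = c(90, -144), PO10 = c(90, 144)
  )
}

.sph_to_cart <- function(incl_deg, az_deg) {
  incl <- incl_deg * pi / 180
  az <- az_deg * pi / 180
  c(sin(incl) * sin(az), sin(incl) * cos(az), cos(incl))
}

# geodesic midpoint on the unit sphere
.sph_mid <- function(a, b) {
  m <- a + b
  m / sqrt(sum(m^2))
}

#' Build a sensor montage
#'
#' Constructs the supported 32-channel extended 10-20 montage with unit-sphere
#' 3-D positions and a 2-D azimuthal-equidistant projection from the vertex
#' (the de-facto standard flattening for scalp maps).
#'
#' @param layout_name Layout identifier; only `"easycap32"` is supported.
#'
#' @return A tibble of class `eeg_montage` with columns `label`, `x`, `y`,
#'   `z` (unit-norm 3-D position) and `x2d`, `y2d` (flat projection;
#'   vertex at the origin, nasion toward +y2d).
#' @export
#' @examples
#' mon <- build_montage()
#' nrow(mon) # 32
build_montage <- function(layout_name = "easycap32") {
  if (!identical(layout_name, "easycap32")) {
    stop("unknown montage layout: '", layout_name,
         "' (supported: \"easycap32\")", call. = FALSE)
  }
  ang <- .tentwenty_angles()
  pos <- lapply(ang, function(a) .sph_to_cart(a[1], a[2]))

  # intermediate 10-10 sites: geodesic midpoint of the midpoints of the
  # flanking anterior/posterior row pairs
  quad <- function(a1, a2, b1, b2) {
    .sph_mid(.sph_mid(pos[[a1]], pos[[a2]]), .sph_mid(pos[[b1]], pos[[b2]]))
  }
  pos$F3 <- .sph_mid(pos$F7, pos$Fz)
  pos$F4 <- .sph_mid(pos$F8, pos$Fz)
  pos$P3 <- .sph_mid(pos$P7, pos$Pz)
  pos$P4 <- .sph_mid(pos$P8, pos$Pz)
  pos$FC5 <- quad("F3", "F7", "C3", "T7")
  pos$FC1 <- quad("F3", "Fz", "C3", "Cz")
  pos$FC2 <- quad("F4", "Fz", "C4", "Cz")
  pos$FC6 <- quad("F4", "F8", "C4", "T8")
  pos$CP5 <- quad("C3", "T7", "P3", "P7")
  pos$CP1 <- quad("C3", "Cz", "P3", "Pz")
  pos$CP2 <- quad("C4", "Cz", "P4", "Pz")
  pos$CP6 <- quad("C4", "T8", "P4", "P8")

  labels <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10"
  )
  xyz <- do.call(rbind, pos[labels])

  # azimuthal-equidistant projection from the vertex: radius = inclination
  incl <- acos(pmin(1, pmax(-1, xyz[, 3])))
  az <- atan2(xyz[, 1], xyz[, 2])
  out <- tibble::tibble(
    label = labels,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    x2d = incl * sin(az), y2d = incl * cos(az)
  )
  class(out) <- c("eeg_montage", class(out))
  out
}

#' Pairwise 3-D chord distances between montage sensors
#'
#' @param montage An `eeg_montage`.
#' @return A symmetric labeled matrix of Euclidean (chord) distances between
#'   unit-sphere sensor positions.
#' @export
montage_distances <- function(montage) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(montage$label, montage$label)
  d
}

#' Default calibrated neighbor distance threshold
#'
#' Chord-distance threshold on the unit sphere calibrated once for the
#' easycap32 montage so that the neighbor graph has a mean degree between 6
#' and 7 sensors, matching the neighborhood density conventionally used for
#' sensor-space clustering on 32-channel caps.
#'
#' @return A scalar chord distance.
#' @export
default_neighbor_threshold <- function() 0.72

#' Build the sensor neighbor graph
#'
#' Two sensors are neighbors iff their 3-D chord distance is at most
#' `distance_threshold`. When called without an explicit threshold the
#' calibrated default is used and the resulting mean degree is required to
#' lie in \[6, 7\] (the density assumed by the cluster test); an explicit
#' threshold disables that check unless `require_calibrated = TRUE`.
#'
#' @param montage An `eeg_montage`.
#' @param distance_threshold Chord-distance cutoff (> 0 for a non-empty
#'   graph); defaults to [default_neighbor_threshold()].
#' @param require_calibrated If TRUE, error unless the mean degree lies in
#'   \[6, 7\]. Defaults to TRUE when `distance_threshold` is not supplied.
#'
#' @return A tibble of class `neighbor_graph` with one row per undirected
#'   sensor pair (columns `from`, `to`, `distance`), plus attributes
#'   `labels`, `distance_threshold`, `mean_degree`, and `adjacency` (named
#'   list of neighbor label vectors, the symmetric relation).
#' @export
#' @examples
#' nb <- build_neighbors(build_montage())
#' attr(nb, "mean_degree")
build_neighbors <- function(montage, distance_threshold = NULL,
                            require_calibrated = is.null(distance_threshold)) {
  if (is.null(distance_threshold)) {
    distance_threshold <- default_neighbor_threshold()
  }
  stopifnot(distance_threshold >= 0)
  d <- montage_distances(montage)
  n <- nrow(d)
  adj_mat <- d <= distance_threshold
  diag(adj_mat) <- FALSE
  degrees <- rowSums(adj_mat)
  mean_degree <- mean(degrees)
  if (require_calibrated && (mean_degree < 6 || mean_degree > 7)) {
    stop(sprintf(
      paste0("neighbor-graph calibration failed: threshold %.4g gives mean ",
             "degree %.2f, outside [6, 7]"),
      distance_threshold, mean_degree), call. = FALSE)
  }
  idx <- which(adj_mat & upper.tri(adj_mat), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = montage$label[idx[, 1]],
    to = montage$label[idx[, 2]],
    distance = d[idx]
  )
  adjacency <- lapply(seq_len(n), function(i) montage$label[adj_mat[i, ]])
  names(adjacency) <- montage$label
  structure(
    edges,
    class = c("neighbor_graph", class(edges)),
    labels = montage$label,
    distance_threshold = distance_threshold,
    mean_degree = mean_degree,
    adjacency = adjacency
  )
}

#' Is the neighbor graph connected?
#'
#' Breadth-first reachability over the symmetric adjacency relation.
#'
#' @param graph A `neighbor_graph`.
#' @return TRUE iff every sensor is reachable from the first.
#' @export
neighbors_connected <- function(graph) {
  adjacency <- attr(graph, "adjacency")
  labels <- attr(graph, "labels")
  seen <- stats::setNames(rep(FALSE, length(labels)), labels)
  queue <- labels[1]
  seen[queue] <- TRUE
  while (length(queue) > 0) {
    nxt <- unique(unlist(adjacency[queue], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  all(seen)
}

#' Write / read a montage as a plain-text coordinate table
#'
#' One line per channel: `label x y z`, whitespace-separated. The 2-D
#' projection is recomputed on read.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `read_montage` returns an `eeg_montage`;
#'   `write_montage` returns `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  readr::write_delim(montage[, c("label", "x", "y", "z")], path,
                     delim = " ", col_names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  tab <- readr::read_table(path, col_names = c("label", "x", "y", "z"),
                           col_types = "cddd", progress = FALSE)
  incl <- acos(pmin(1, pmax(-1, tab$z)))
  az <- atan2(tab$x, tab$y)
  out <- tibble::tibble(tab, x2d = incl * sin(az), y2d = incl * cos(az))
  class(out) <- c("eeg_montage", class(out))
  out
}

#' Export a neighbor graph as an edge-list text file
#'
#' @param graph A `neighbor_graph`.
#' @param path File path; tab-separated `from to distance` lines.
#' @return `path`, invisibly.
#' @export
write_neighbors <- function(graph, path) {
  readr::write_tsv(tibble::as_tibble(graph), path, col_names = FALSE)
  invisible(path)
}
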