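#' Extract the 11 facial distances and facial area from one face
#'
#' Measures every feature in the distance registry on a mesh + landmark
#' pair: linear features as straight-line distances between landmarks,
#' geodesic features as shortest paths over the refined mesh edge graph
#' (see [mesh_geodesic_graph()]), plus the landmark-triangle facial area.
#'
#' @param mesh a [face_mesh()].
#' @param landmarks a [landmark_set()] for the same subject; every landmark
#'   must lie within `snap_tol` of the mesh surface.
#' @param registry distance registry (default [default_distance_registry()]).
#' @param triangulation facial-area triangulation
#'   (default [default_area_triangulation()]).
#' @param refine Steiner points per mesh edge for the geodesic graph.
#' @param snap_tol landmark snap tolerance, mm.
#' @param sex,group optional labels copied into the output row.
#' @return one-row data.frame: `subject_id`, `sex`, `group`, the 11 distance
#'   columns (mm) and `facial_area` (mm^2).
#' @export
extract_features <- function(mesh, landmarks,
                             registry = default_distance_registry(),
                             triangulation = default_area_triangulation(),
                             refine = 3L, snap_tol = 2,
                             sex = NA_character_, group = NA_character_) {
  lm_names <- unique(c(registry$from, registry$to))
  missing <- setdiff(lm_names, rownames(landmarks))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  p <- unclass(landmarks)

  vals <- stats::setNames(numeric(nrow(registry)), registry$feature)
  lin <- registry$type == "linear"
  if (any(lin)) {
    d <- p[registry$from[lin], , drop = FALSE] - p[registry$to[lin], , drop = FALSE]
    vals[lin] <- sqrt(rowSums(d^2))
  }
  geo <- which(!lin)
  if (length(geo)) {
    gnames <- unique(c(registry$from[geo], registry$to[geo]))
    vidx <- snap_to_surface(mesh, p[gnames, , drop = FALSE], tol = snap_tol)
    names(vidx) <- gnames
    graph <- mesh_geodesic_graph(mesh, refine = refine)
    dm <- geodesic_between_vertices(graph, vidx, vidx)
    dimnames(dm) <- list(gnames, gnames)
    vals[geo] <- dm[cbind(registry$from[geo], registry$to[geo])]
  }
  if (any(vals <= 0)) stop("non-positive facial distance measured")

  out <- data.frame(subject_id = attr(landmarks, "subject_id"),
                    sex = sex, group = group, stringsAsFactors = FALSE)
  out[registry$feature] <- as.list(vals)
  out$facial_area <- facial_area(landmarks, triangulation)
  out
}

#' Read / write feature tables
#'
#' CSV schema: `subject_id,sex,group,<11 distance columns>,facial_area`.
#' `read_features` checks that all 11 canonical distance columns are present.
#'
#' @param path CSV path.
#' @return data.frame of features.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing))
    stop("feature CSV missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname read_features
#' @param features data.frame of features.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# n x 11 numeric matrix of the canonical features, with checks
feature_matrix <- function(features) {
  missing <- setdiff(feature_names(), names(features))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(features[, feature_names(), drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing feature value(s) (NA) in feature table")
  m
}
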