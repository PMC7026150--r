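#' Canonical anthropometric landmark names
#'
#' The 13 landmarks used throughout the package, following standard
#' craniofacial (Farkas) nomenclature: trichion (tr), nasion (n), pronasale
#' (prn), subnasale (sn), labiale superius (ls), stomion (sto), left/right
#' exocanthion (ex), left/right alare (al), left/right frontotemporale (ft)
#' and right zygion (zy). Bilateral points carry `_l`/`_r` suffixes.
#'
#' @return character vector of 13 names.
#' @export
canonical_landmarks <- function() {
  c("trichion", "nasion", "pronasale", "subnasale", "labiale_superius",
    "stomion", "exocanthion_l", "exocanthion_r", "alare_l", "alare_r",
    "frontotemporale_l", "frontotemporale_r", "zygion_r")
}

#' Landmark set for one subject
#'
#' @param points named list or 13 x 3 matrix with rownames; coordinates in mm.
#' @param subject_id subject identifier.
#' @return object of class `landmark_set`: a 13 x 3 matrix with landmark
#'   rownames plus a `subject_id` attribute.
#' @export
landmark_set <- function(points, subject_id = "unknown") {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("landmark coordinates must be 3D")
  want <- canonical_landmarks()
  missing <- setdiff(want, rownames(points))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(rownames(points), want)
  if (length(extra))
    stop("unknown landmark(s): ", paste(extra, collapse = ", "))
  points <- points[want, , drop = FALSE]
  colnames(points) <- c("x", "y", "z")
  structure(points, subject_id = as.character(subject_id),
            class = c("landmark_set", "matrix", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject '%s': %d landmarks (mm)\n",
              attr(x, "subject_id"), nrow(x)))
  print(unclass(x))
  invisible(x)
}

#' Read / write landmark CSV
#'
#' CSV schema: `subject_id,landmark,x,y,z`, one row per landmark, mm.
#' A file may hold several subjects; `read_landmarks` returns a named list
#' of [landmark_set()] objects.
#'
#' @param path CSV path.
#' @return named list of `landmark_set` objects (one per subject).
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ","))
  out <- lapply(split(df, df$subject_id), function(s) {
    m <- as.matrix(s[, c("x", "y", "z")])
    rownames(m) <- s$landmark
    landmark_set(m, subject_id = s$subject_id[1])
  })
  out
}

#' @rdname read_landmarks
#' @param landmarks a `landmark_set` or list of them.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  rows <- do.call(rbind, lapply(landmarks, function(lm) {
    data.frame(subject_id = attr(lm, "subject_id"),
               landmark = rownames(lm),
               x = lm[, 1], y = lm[, 2], z = lm[, 3],
               row.names = NULL)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Registry of the 11 facial distances
#'
#' Maps each feature to its landmark pair and measurement type. Three
#' distances are straight-line (linear); eight are surface geodesics. The
#' pairing follows standard anthropometric definitions: alar-base width =
#' alare L-R; nose height = nasion-subnasale; upper lip height =
#' subnasale-stomion; outer-canthal width = exocanthion L-R; forehead
#' height = trichion-nasion; forehead width = frontotemporale L-R; right
#' upper cheek height = right exocanthion-right zygion; nasal tip
#' protrusion = subnasale-pronasale; nasal bridge length =
#' nasion-pronasale. The registry is configuration: pass a modified copy to
#' [extract_features()] to override any pairing.
#'
#' @return data.frame with columns `feature`, `from`, `to`, `type`.
#' @export
default_distance_registry <- function() {
  data.frame(
    feature = c("linear_alar_base_width", "linear_nose_height",
                "linear_upper_lip_height",
                "geodesic_outer_canthal_width", "geodesic_forehead_height",
                "geodesic_forehead_width", "geodesic_right_upper_cheek_height",
                "geodesic_nasal_tip_protrusion", "geodesic_nose_height",
                "geodesic_upper_lip_height", "geodesic_nasal_bridge_length"),
    from = c("alare_l", "nasion", "subnasale",
             "exocanthion_l", "trichion", "frontotemporale_l",
             "exocanthion_r", "subnasale", "nasion", "subnasale", "nasion"),
    to = c("alare_r", "subnasale", "stomion",
           "exocanthion_r", "nasion", "frontotemporale_r",
           "zygion_r", "pronasale", "subnasale", "stomion", "pronasale"),
    type = c("linear", "linear", "linear",
             rep("geodesic", 8)),
    stringsAsFactors = FALSE
  )
}

#' Names of the 11 facial distance features
#' @return character vector in canonical column order.
#' @export
feature_names <- function() default_distance_registry()$feature

#' Default facial-area triangulation
#'
#' A fixed, documented set of landmark triangles whose summed areas define
#' the facial area. The set combines a full-face fan anchored at pronasale,
#' an upper/mid-face fan anchored at nasion, and lower-face panels around
#' the mouth; panels deliberately overlap, which matches the magnitude of
#' facial areas reported for child faces by landmark-triangle summation
#' (a single-cover triangulation of 13 points spans only about half that
#' area). The area operation itself accepts any user triangulation.
#'
#' @return character matrix, one landmark-name triple per row.
#' @export
default_area_triangulation <- function() {
  tri <- rbind(
    # full-face fan from pronasale around the perimeter
    c("pronasale", "trichion", "frontotemporale_r"),
    c("pronasale", "frontotemporale_r", "exocanthion_r"),
    c("pronasale", "exocanthion_r", "zygion_r"),
    c("pronasale", "zygion_r", "alare_r"),
    c("pronasale", "alare_r", "stomion"),
    c("pronasale", "stomion", "alare_l"),
    c("pronasale", "alare_l", "exocanthion_l"),
    c("pronasale", "exocanthion_l", "frontotemporale_l"),
    c("pronasale", "frontotemporale_l", "trichion"),
    # upper/mid-face fan from nasion
    c("nasion", "trichion", "frontotemporale_r"),
    c("nasion", "frontotemporale_r", "exocanthion_r"),
    c("nasion", "exocanthion_r", "zygion_r"),
    c("nasion", "zygion_r", "alare_r"),
    c("nasion", "alare_r", "subnasale"),
    c("nasion", "subnasale", "alare_l"),
    c("nasion", "alare_l", "exocanthion_l"),
    c("nasion", "exocanthion_l", "frontotemporale_l"),
    c("nasion", "frontotemporale_l", "trichion"),
    # lower face / mouth panels
    c("subnasale", "alare_r", "stomion"),
    c("subnasale", "stomion", "alare_l"),
    c("labiale_superius", "alare_l", "alare_r"),
    c("labiale_superius", "stomion", "zygion_r"),
    c("stomion", "alare_r", "zygion_r"),
    c("exocanthion_r", "alare_r", "zygion_r")
  )
  colnames(tri) <- c("a", "b", "c")
  tri
}

#' Facial area from landmark triangles
#'
#' Sum over the triangulation of one-half the magnitude of the edge
#' cross-product. Invariant under rigid rotation and translation of the
#' landmark set; scales with the square of any uniform scaling.
#'
#' @param landmarks a [landmark_set()].
#' @param triangulation character matrix of landmark-name triples
#'   (default [default_area_triangulation()]).
#' @return area in mm^2.
#' @export
facial_area <- function(landmarks, triangulation = default_area_triangulation()) {
  triangulation <- as.matrix(triangulation)
  if (ncol(triangulation) != 3L) stop("triangulation rows must be name triples")
  if (any(triangulation[, 1] == triangulation[, 2] |
          triangulation[, 2] == triangulation[, 3] |
          triangulation[, 1] == triangulation[, 3]))
    stop("degenerate triangle: repeated landmark in a triple")
  bad <- setdiff(unique(as.vector(triangulation)), canonical_landmarks())
  if (length(bad))
    stop("triangulation references unknown landmark(s): ",
         paste(bad, collapse = ", "))
  p <- unclass(landmarks)
  a <- p[triangulation[, 1], , drop = FALSE]
  b <- p[triangulation[, 2], , drop = FALSE]
  cc <- p[triangulation[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}
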