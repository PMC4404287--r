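#' Definition table of the 23 facial distances
#'
#' Maps each named distance to its landmark endpoints. Alar length is the
#' only composite entry: the subalare-pronasale span is measured on both
#' sides and averaged, so its `from`/`to` list both left and right codes.
#'
#' @return Tibble with columns `distance`, `from`, `to` (landmark codes;
#'   `|`-separated for the averaged alar length).
#' @export
distance_definitions <- function() {
  tibble::tribble(
    ~distance,                  ~from,            ~to,
    "forehead_width",           "Ft_L",           "Ft_R",
    "outer_canthal_width",      "Ex_L",           "Ex_R",
    "nasal_bridge_length",      "N",              "Prn",
    "nasal_tip_protrusion",     "Sn",             "Prn",
    "philtrum_length",          "Sn",             "Ls",
    "nose_width",               "Al_L",           "Al_R",
    "eye_fissure_length_left",  "Ex_L",           "En_L",
    "eye_fissure_length_right", "Ex_R",           "En_R",
    "intercanthal_width",       "En_L",           "En_R",
    "mouth_width",              "Ch_L",           "Ch_R",
    "upper_facial_height",      "N",              "Sto",
    "nose_height",              "N",              "Sn",
    "nasal_root_height_left",   "En_L",           "N",
    "nasal_root_height_right",  "En_R",           "N",
    "upper_lip_height",         "Sn",             "Sto",
    "upper_vermillion_height",  "Ls",             "Sto",
    "lower_vermillion_height",  "Sto",            "Li",
    "forehead_height",          "Tr",             "G",
    "mandible_height",          "Sto",            "Pg",
    "alar_base_width",          "Sbal_L",         "Sbal_R",
    "alar_length",              "Sbal_L|Sbal_R",  "Prn|Prn",
    "upper_profile_height",     "Tr",             "Prn",
    "lower_profile_height",     "Prn",            "Pg"
  )
}

#' Euclidean distance between two 3D points
#'
#' @param p,q Numeric length-3 vectors (mm).
#' @return Straight-line distance in mm.
#' @export
euclidean_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3 || length(q) != 3 || !all(is.finite(c(p, q)))) {
    abort("euclidean_distance() needs two finite length-3 coordinates.")
  }
  sqrt(sum((p - q)^2))
}

#' Compute the 23 facial distances from a landmark set
#'
#' Each distance is the straight-line 3D Euclidean distance between its
#' two endpoint landmarks per [distance_definitions()]; alar length is the
#' mean of the left and right subalare-pronasale spans. Distances whose
#' endpoints are missing from the landmark set are omitted with a warning
#' rather than imputed.
#'
#' @param lm A [landmark_set()].
#' @return One-row tibble: `subject_id` plus one column per computable
#'   distance (mm).
#' @export
#' @examples
#' tpl <- face_template()
#' compute_distances(tpl)
compute_distances <- function(lm) {
  pts <- as_tibble(lm)
  if (nrow(pts) == 0) abort("Empty landmark set: no distances computable.")
  coords <- setNames(
    lapply(seq_len(nrow(pts)), function(i) c(pts$x[i], pts$y[i], pts$z[i])),
    pts$landmark
  )
  defs <- distance_definitions()
  have <- function(code) code %in% names(coords)
  vals <- pmap(defs, function(distance, from, to) {
    fr <- strsplit(from, "|", fixed = TRUE)[[1]]
    to <- strsplit(to, "|", fixed = TRUE)[[1]]
    if (!all(vapply(c(fr, to), have, logical(1)))) return(NA_real_)
    mean(map_dbl(seq_along(fr), function(k) {
      euclidean_distance(coords[[fr[k]]], coords[[to[k]]])
    }))
  })
  vals <- setNames(as.numeric(vals), defs$distance)
  missing <- names(vals)[is.na(vals)]
  if (length(missing) == length(vals)) {
    abort("No distance has both endpoints present in this landmark set.")
  }
  if (length(missing) > 0) {
    warn(paste0("Omitting distance(s) with missing endpoint landmarks: ",
                paste(missing, collapse = ", ")))
  }
  out <- as_tibble(as.list(vals[!is.na(vals)]))
  dplyr::bind_cols(tibble(subject_id = attr(lm, "subject_id") %||% "subject"), out)
}

#' Total surface area of a triangulated mesh
#'
#' Sums, over triangles, half the magnitude of the cross product of two
#' edge vectors. Zero-area (degenerate) triangles contribute nothing and
#' trigger a warning; real scan meshes often contain such slivers.
#'
#' @param mesh A [face_mesh()].
#' @return Total area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "face_mesh"))
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(areas == 0)) {
    warn(sprintf("%d zero-area triangle(s) contribute nothing to the surface area.",
                 sum(areas == 0)))
  }
  sum(areas)
}
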