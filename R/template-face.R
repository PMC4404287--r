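#' Bilaterally symmetric 21-landmark template face
#'
#' A fabricated but anatomically plausible template in a frontal frame
#' (x lateral, y vertical, z anterior; mm). No subject coordinates are
#' published, so only the distances the template induces matter: it is the
#' scaffold that [landmarks_from_distances()] deforms to hit sampled
#' target distances.
#'
#' @return A [landmark_set()] with all 21 landmarks.
#' @export
face_template <- function() {
  pts <- tibble::tribble(
    ~landmark, ~x,      ~y,     ~z,
    "Tr",      0,       80,     10,
    "G",       0,       25,     12,
    "Ft_L",    -62.06,  40,     0,
    "Ft_R",    62.06,   40,     0,
    "Ex_L",    -48.285, 10,     0,
    "Ex_R",    48.285,  10,     0,
    "En_L",    -16.5,   10,     5,
    "En_R",    16.5,    10,     5,
    "N",       0,       15,     8,
    "Prn",     0,       -24.59, 33.91,
    "Sn",      0,       -30,    15,
    "Al_L",    -16.355, -25,    8,
    "Al_R",    16.355,  -25,    8,
    "Sbal_L",  -10,     -28,    12,
    "Sbal_R",  10,      -28,    12,
    "Ls",      0,       -38,    14,
    "Sto",     0,       -45,    12,
    "Li",      0,       -52,    13,
    "Ch_L",    -25,     -45,    8,
    "Ch_R",    25,      -45,    8,
    "Pg",      0,       -75,    10
  )
  landmark_set(pts, subject_id = "template", source = "synthetic template")
}

as_coord_list <- function(lm) {
  pts <- as_tibble(lm)
  setNames(lapply(seq_len(nrow(pts)), function(i) c(pts$x[i], pts$y[i], pts$z[i])),
           pts$landmark)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

# Intersect two spheres (centres c1/c2, radii r1/r2) within the plane
# spanned by (c2 - c1) and a reference direction; returns the solution
# nearest `near`. Errors with the offending distance names if infeasible.
sphere_intersect_midline <- function(c1, r1, c2, r2, near, offenders) {
  d <- c2 - c1
  L <- sqrt(sum(d^2))
  if (L > r1 + r2 + 1e-9 || L < abs(r1 - r2) - 1e-9) {
    abort(
      paste0("Target distances are geometrically infeasible (triangle inequality): ",
             paste(offenders, collapse = ", ")),
      class = "facedim_infeasible"
    )
  }
  u <- unit_vec(d)
  # perpendicular to u inside the midline (x = const) plane
  w <- c(0, u[3], -u[2])
  if (sum(w^2) < 1e-12) w <- c(0, 1, 0) else w <- unit_vec(w)
  a <- (r1^2 + L^2 - r2^2) / (2 * L)
  b2 <- max(r1^2 - a^2, 0)
  b <- sqrt(b2)
  cand <- list(c1 + a * u + b * w, c1 + a * u - b * w)
  dists <- map_dbl(cand, function(p) sum((p - near)^2))
  cand[[which.min(dists)]]
}

#' Deform the template face to match target distances
#'
#' Solves per-landmark displacements of [face_template()] so that the
#' induced facial distances equal the targets where an exact geometric
#' construction exists, and approximate them otherwise. Exact: the six
#' dimorphic distances (forehead width, outer canthal width, nasal bridge
#' length, nasal tip protrusion, philtrum length, nose width) plus the
#' paired widths, nose height, upper facial height, forehead height,
#' mandible height and lower vermillion height. Landmarks already pinned
#' by those constructions determine the remaining distances, which
#' therefore track the template's proportions rather than the targets.
#'
#' @param targets Named numeric vector of target distances in mm (any
#'   subset of [distance_names()]; other names, e.g. `facial_area`, are
#'   ignored).
#' @param template Template [landmark_set()].
#' @param subject_id Identifier for the returned set.
#' @return A deformed [landmark_set()].
#' @export
landmarks_from_distances <- function(targets, template = face_template(),
                                     subject_id = "synthetic") {
  targets <- targets[names(targets) %in% distance_names()]
  L <- as_coord_list(template)
  tpl <- as_coord_list(face_template())
  tgt <- function(nm, default) if (nm %in% names(targets)) targets[[nm]] else default

  # nose triangle: N fixed; Sn along the template nasion->subnasale axis;
  # Prn by sphere-sphere intersection in the midline plane
  nh <- tgt("nose_height", euclidean_distance(L$N, L$Sn))
  nb <- tgt("nasal_bridge_length", euclidean_distance(L$N, L$Prn))
  tp <- tgt("nasal_tip_protrusion", euclidean_distance(L$Sn, L$Prn))
  L$Sn <- L$N + nh * unit_vec(tpl$Sn - tpl$N)
  L$Prn <- sphere_intersect_midline(
    L$N, nb, L$Sn, tp, near = tpl$Prn,
    offenders = c("nasal_bridge_length", "nasal_tip_protrusion", "nose_height")
  )

  # paired widths: set +/- x, keep template elevation/depth
  widths <- c(forehead_width = "Ft", outer_canthal_width = "Ex",
              intercanthal_width = "En", nose_width = "Al",
              mouth_width = "Ch", alar_base_width = "Sbal")
  for (nm in names(widths)) {
    if (!nm %in% names(targets)) next
    half <- targets[[nm]] / 2
    lcode <- paste0(widths[[nm]], "_L"); rcode <- paste0(widths[[nm]], "_R")
    L[[lcode]] <- c(-half, L[[lcode]][2], L[[lcode]][3])
    L[[rcode]] <- c(half, L[[rcode]][2], L[[rcode]][3])
  }

  # chained midline placements along template directions
  place <- function(code, anchor, dist_nm, tpl_from, tpl_to) {
    if (!dist_nm %in% names(targets)) return()
    L[[code]] <<- L[[anchor]] + targets[[dist_nm]] * unit_vec(tpl[[tpl_to]] - tpl[[tpl_from]])
  }
  place("Ls", "Sn", "philtrum_length", "Sn", "Ls")
  place("Sto", "N", "upper_facial_height", "N", "Sto")
  place("Li", "Sto", "lower_vermillion_height", "Sto", "Li")
  place("Tr", "G", "forehead_height", "G", "Tr")
  place("Pg", "Sto", "mandible_height", "Sto", "Pg")

  pts <- tibble(
    landmark = names(L),
    x = map_dbl(L, 1), y = map_dbl(L, 2), z = map_dbl(L, 3)
  )
  landmark_set(pts, subject_id = subject_id, source = "synthetic deformation")
}

#' Generate a synthetic landmark cohort
#'
#' Samples a distance cohort from `spec` and deforms the template face to
#' match each subject's sampled distances, so that measuring the returned
#' landmark sets with [compute_distances()] closes the loop on the exactly
#' constructible distances (within numerical tolerance).
#'
#' @param spec A [cohort_spec()].
#' @param template Template [landmark_set()].
#' @return List with `cohort` (the sampled distance tibble) and
#'   `landmarks` (named list of [landmark_set()]s, one per subject).
#' @export
generate_landmark_cohort <- function(spec, template = face_template()) {
  coh <- generate_distance_cohort(spec)
  feats <- intersect(cohort_feature_names(coh), distance_names())
  sets <- map(seq_len(nrow(coh)), function(i) {
    tg <- setNames(as.numeric(coh[i, feats]), feats)
    landmarks_from_distances(tg, template = template,
                             subject_id = coh$subject_id[i])
  })
  list(cohort = coh, landmarks = setNames(sets, coh$subject_id))
}
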