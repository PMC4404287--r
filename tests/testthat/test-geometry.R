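test_that("euclidean_distance matches closed forms and is symmetric", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)),
               euclidean_distance(c(4, 6, 3), c(1, 2, 3)))
  expect_error(euclidean_distance(c(0, 0), c(1, 1, 1)), "length-3")
})

test_that("compute_distances applies the fixed endpoint map", {
  lm <- landmark_set(data.frame(
    landmark = c("Ft_L", "Ft_R"), x = c(-62, 62), y = 40, z = 0))
  d <- suppressWarnings(compute_distances(lm))
  expect_equal(d$forehead_width, 124)

  tpl <- face_template()
  d <- compute_distances(tpl)
  expect_setequal(setdiff(names(d), "subject_id"), distance_names())
  # alar length is the mean of the two subalare-pronasale spans
  pts <- as.data.frame(tpl); rownames(pts) <- pts$landmark
  co <- function(code) as.numeric(pts[code, c("x", "y", "z")])
  expect_equal(d$alar_length,
               mean(c(euclidean_distance(co("Sbal_L"), co("Prn")),
                      euclidean_distance(co("Sbal_R"), co("Prn")))))
})

test_that("distances needing a missing landmark are omitted, others kept", {
  tpl <- face_template()
  no_prn <- landmark_set(as.data.frame(tpl)[tpl$landmark != "Prn", ],
                         subject_id = "noPrn")
  expect_warning(d <- compute_distances(no_prn), "nasal_bridge_length")
  lost <- c("nasal_bridge_length", "nasal_tip_protrusion", "alar_length",
            "upper_profile_height", "lower_profile_height")
  expect_setequal(setdiff(distance_names(), setdiff(names(d), "subject_id")), lost)
  expect_error(compute_distances(landmark_set(data.frame(
    landmark = character(0), x = numeric(0), y = numeric(0), z = numeric(0)))),
    "Empty landmark set")
})

test_that("distances and areas are rigid-motion invariant and scale correctly", {
  tpl <- face_template()
  d0 <- compute_distances(tpl)
  # a rotation about an arbitrary axis plus a translation
  th <- 0.83; ax <- c(1, 2, 3) / sqrt(14)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shift <- c(10, -20, 5)
  xyz <- as.matrix(as.data.frame(tpl)[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -shift)
  moved <- landmark_set(data.frame(landmark = tpl$landmark, x = xyz[, 1],
                                   y = xyz[, 2], z = xyz[, 3]))
  d1 <- compute_distances(moved)
  expect_equal(as.numeric(d1[-1]), as.numeric(d0[-1]), tolerance = 1e-9)

  scaled <- landmark_set(data.frame(landmark = tpl$landmark, x = 2.5 * tpl$x,
                                    y = 2.5 * tpl$y, z = 2.5 * tpl$z))
  d2 <- compute_distances(scaled)
  expect_equal(as.numeric(d2[-1]), 2.5 * as.numeric(d0[-1]), tolerance = 1e-9)

  ico <- generate_icosphere(10, 2)
  a0 <- mesh_surface_area(ico)
  expect_equal(mesh_surface_area(face_mesh(ico$vertices %*% t(R), ico$triangles)),
               a0, tolerance = 1e-9)
  expect_equal(mesh_surface_area(face_mesh(3 * ico$vertices, ico$triangles)),
               9 * a0, tolerance = 1e-9)
})

test_that("a bilaterally symmetric face has equal left/right paired distances", {
  d <- compute_distances(face_template())
  expect_equal(d$eye_fissure_length_left, d$eye_fissure_length_right)
  expect_equal(d$nasal_root_height_left, d$nasal_root_height_right)
})

test_that("mesh surface area matches closed forms", {
  tri <- face_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(mesh_surface_area(tri), 0.5)

  # unit-edge regular tetrahedron: total area 4 * (sqrt(3)/4) = sqrt(3)
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  expect_equal(mesh_surface_area(face_mesh(v, f)), sqrt(3), tolerance = 1e-12)

  area <- mesh_surface_area(generate_icosphere(50, 4))
  expect_lt(abs(area - 4 * pi * 50^2) / (4 * pi * 50^2), 0.005)
})

test_that("zero-area triangles warn and contribute nothing", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # second triangle is collinear
  expect_warning(a <- mesh_surface_area(face_mesh(v, f)), "zero-area")
  expect_equal(a, 0.5)
})
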