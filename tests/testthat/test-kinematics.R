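# Tibial frames, flexion angles, displacement fields and cohort averaging.

test_that("the tibial frame recovers the generator axes", {
  s <- fixture_subject()
  fr <- s$tibial_frame
  # generator builds the tibia in canonical AP/ML/SI axes
  expect_lt(acos(abs(sum(fr$ml_axis * c(0, 1, 0)))) * 180 / pi, 1)
  expect_lt(acos(abs(sum(fr$si_axis * c(0, 0, 1)))) * 180 / pi, 1)
  expect_lt(acos(abs(sum(fr$ap_axis * c(1, 0, 0)))) * 180 / pi, 1)
  # sign conventions: anterior, superior positive
  expect_gt(sum(fr$ap_axis * c(1, 0, 0)), 0)
  expect_gt(sum(fr$si_axis * c(0, 0, 1)), 0)
  # right-handed within 1e-10
  expect_equal(meniscusdyn:::cross3(fr$ap_axis, fr$ml_axis), fr$si_axis,
               tolerance = 1e-10)
})

test_that("the tibial frame is equivariant under rigid rotations", {
  s <- fixture_subject()
  tib <- s$poses[[1]]$tibia_fibula
  fr <- tibial_frame(tib, s$plateau_vertex_indices)
  tr <- random_rigid_transform(3)
  fr2 <- tibial_frame(apply_transform(tib, tr), s$plateau_vertex_indices)
  R <- tr$rotation
  expect_equal(fr2$ap_axis, as.vector(R %*% fr$ap_axis), tolerance = 1e-9)
  expect_equal(fr2$ml_axis, as.vector(R %*% fr$ml_axis), tolerance = 1e-9)
  expect_equal(fr2$si_axis, as.vector(R %*% fr$si_axis), tolerance = 1e-9)
})

test_that("degenerate plateaus are rejected", {
  s <- fixture_subject()
  tib <- s$poses[[1]]$tibia_fibula
  line_pts <- s$plateau_vertex_indices[1:3]
  tib$vertices[line_pts, ] <- cbind(1:3, 2 * (1:3), 3 * (1:3))
  expect_error(tibial_frame(tib, line_pts), "collinear")
  expect_error(tibial_frame(tib, integer(0)), "at least 3")
})

test_that("flexion angle tracks constructed rotations about the ML axis", {
  s <- fixture_subject()
  fr <- s$tibial_frame
  femur0 <- apply_transform(s$poses[[1]]$femur,
                            invert_transform(s$analytic_motion[[1]]))
  expect_lt(abs(flexion_angle(femur0, fr, s$shaft_vertex_indices)), 0.5)

  rot30 <- rigid_transform(rotation_about_axis(fr$ml_axis, 30), c(0, 0, 0))
  expect_equal(flexion_angle(apply_transform(femur0, rot30), fr,
                             s$shaft_vertex_indices), 30, tolerance = 0.5)

  # extra internal rotation about SI is removed by the sagittal projection
  rot_si <- rigid_transform(rotation_about_axis(fr$si_axis, 5), c(0, 0, 0))
  femur_c <- apply_transform(apply_transform(femur0, rot30), rot_si)
  expect_equal(flexion_angle(femur_c, fr, s$shaft_vertex_indices), 30,
               tolerance = 1)

  expect_error(flexion_angle(femur0, fr, integer(0)), "empty")
})

test_that("flexion angle is monotone in the generator flexion parameter", {
  s <- fixture_subject()
  femur0 <- apply_transform(s$poses[[1]]$femur,
                            invert_transform(s$analytic_motion[[1]]))
  angles <- seq(0, 120, by = 15)
  rec <- vapply(angles, function(th) {
    fem <- apply_transform(femur0, meniscusdyn:::femur_pose_transform(s$params, th))
    flexion_angle(fem, s$tibial_frame, s$shaft_vertex_indices)
  }, 0)
  expect_true(all(diff(rec) > 0))
})

test_that("displacement fields are exact per-vertex differences", {
  m <- mesh_uv_sphere(radius = 5, n_lat = 6, n_lon = 8)

  f0 <- displacement_field(m, m)
  expect_true(all(f0$magnitudes == 0))

  tr <- rigid_transform(diag(3), c(3, 4, 0))
  ft <- displacement_field(m, apply_transform(m, tr))
  expect_equal(ft$magnitudes, rep(5, n_vertices(m)), tolerance = 1e-12)

  # rotation about an axis through the centroid: chord length 2 r sin(t/2)
  th <- 30
  rot <- rigid_transform(rotation_about_axis(c(0, 0, 1), th), c(0, 0, 0))
  fr <- displacement_field(m, apply_transform(m, rot))
  r_axis <- sqrt(rowSums(m$vertices[, 1:2]^2))
  expect_equal(fr$magnitudes, 2 * r_axis * sin(th / 2 * pi / 180),
               tolerance = 1e-9)

  # magnitude[k] == ||vector[k]||
  expect_equal(fr$magnitudes, sqrt(rowSums(fr$vectors^2)), tolerance = 1e-12)

  other <- mesh_uv_sphere(radius = 5, n_lat = 7, n_lon = 8)
  expect_error(displacement_field(m, other), "correspondence")
})

test_that("displacement fields are antisymmetric", {
  s <- fixture_subject()
  f_ab <- ground_truth_displacement(s, "0", "60", "meniscus_medial")
  f_ba <- ground_truth_displacement(s, "60", "0", "meniscus_medial")
  expect_equal(f_ab$vectors, -f_ba$vectors, tolerance = 1e-12)
})

test_that("AP projection is bounded by the 3D magnitude", {
  s <- fixture_subject()
  fr <- s$tibial_frame
  m <- s$poses[[1]]$meniscus_medial

  along_ap <- m
  along_ap$vertices <- m$vertices + rep(2.5, n_vertices(m)) %o% fr$ap_axis
  f <- displacement_field(m, along_ap)
  expect_equal(ap_projection(f, fr), f$magnitudes, tolerance = 1e-9)

  along_ml <- m
  along_ml$vertices <- m$vertices + rep(2.5, n_vertices(m)) %o% fr$ml_axis
  f <- displacement_field(m, along_ml)
  expect_lt(max(ap_projection(f, fr)), 1e-9)

  f90 <- ground_truth_displacement(s, "0", "90", "meniscus_lateral")
  expect_true(all(ap_projection(f90, fr) <= f90$magnitudes + 1e-12))
})

test_that("maximal point displacement respects masks and tie-breaks", {
  m <- mesh_box(dims = c(2, 2, 2))
  tr <- rigid_transform(diag(3), c(0, 3, 4))
  f <- displacement_field(m, apply_transform(m, tr))
  mx <- max_point_displacement(f)
  expect_equal(mx$mm, 5)
  expect_identical(mx$vertex, 1L)   # all tie: lowest index wins

  shifted <- m
  shifted$vertices[5, ] <- shifted$vertices[5, ] + c(0, 0, 2)
  f1 <- displacement_field(m, shifted)
  expect_identical(max_point_displacement(f1)$vertex, 5L)

  rot <- rigid_transform(rotation_about_axis(c(0, 0, 1), 20), c(0, 0, 0))
  sph <- mesh_uv_sphere(radius = 4, n_lat = 8, n_lon = 10)
  fr_ <- displacement_field(sph, apply_transform(sph, rot))
  r_axis <- sqrt(rowSums(sph$vertices[, 1:2]^2))
  expect_equal(r_axis[max_point_displacement(fr_)$vertex], max(r_axis),
               tolerance = 1e-9)

  expect_error(max_point_displacement(f, integer(0)), "empty")
})

test_that("cohort mean meshes are frame-normalized arithmetic means", {
  s <- fixture_subject()
  m <- s$poses[[1]]$meniscus_medial
  fr <- s$tibial_frame

  one <- mean_corresponded_mesh(list(m, m, m), list(fr, fr, fr))
  expect_equal(one$vertices, frame_coordinates(m$vertices, fr),
               tolerance = 1e-12)

  t_ap <- rigid_transform(diag(3), 2 * fr$ap_axis)
  plus <- apply_transform(m, t_ap)
  minus <- apply_transform(m, invert_transform(t_ap))
  mid <- mean_corresponded_mesh(list(plus, minus), list(fr, fr))
  expect_equal(mid$vertices, frame_coordinates(m$vertices, fr),
               tolerance = 1e-9)

  # per-subject rigid motions applied jointly to mesh and frame cancel
  tib <- s$poses[[1]]$tibia_fibula
  trs <- lapply(1:3, random_rigid_transform)
  meshes <- lapply(trs, function(tr) apply_transform(m, tr))
  frames <- lapply(trs, function(tr)
    tibial_frame(apply_transform(tib, tr), s$plateau_vertex_indices))
  avg <- mean_corresponded_mesh(meshes, frames)
  expect_equal(avg$vertices, frame_coordinates(m$vertices, fr),
               tolerance = 1e-8)
})

test_that("meniscus region masks partition the tube by arclength thirds", {
  s <- fixture_subject()
  m <- s$poses[[1]]$meniscus_medial
  masks <- meniscus_region_masks(m)
  expect_setequal(unlist(masks), seq_len(n_vertices(m)))
  expect_length(intersect(masks$anterior_horn, masks$posterior_horn), 0)
  expect_length(intersect(masks$anterior_horn, masks$body), 0)
})

test_that("displacement fields export to CSV with magnitudes", {
  m <- mesh_box()
  f <- displacement_field(m, apply_transform(
    m, rigid_transform(diag(3), c(1, 2, 2))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_displacement_field(f, path)
  df <- read.csv(path)
  expect_named(df, c("vertex_index", "dx", "dy", "dz", "magnitude_mm"))
  expect_equal(df$magnitude_mm, rep(3, 8))
})
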