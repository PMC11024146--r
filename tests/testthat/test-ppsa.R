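# Principal Polynomial Shape Analysis: flattening, fitting, sampling.

test_that("shape vectors round-trip through assembly and disassembly", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  vec <- assemble_shape_vector(s$poses[[1]], layout)
  expect_length(vec, layout$total_length)
  total_nv <- sum(vapply(ppsa_component_names(), function(nm)
    n_vertices(s$poses[[1]][[nm]]), 0L))
  expect_identical(layout$total_length, 3L * total_nv)

  back <- disassemble_shape_vector(vec, layout)
  for (nm in ppsa_component_names())
    expect_identical(back[[nm]]$vertices, s$poses[[1]][[nm]]$vertices)

  # poses differing only in one component differ only on that span
  v2 <- assemble_shape_vector(s$poses[[2]], layout)
  pose_mix <- s$poses[[1]]
  pose_mix$meniscus_medial <- s$poses[[2]]$meniscus_medial
  vmix <- assemble_shape_vector(pose_mix, layout)
  diff_idx <- which(vmix != vec)
  off_femur <- 3L * n_vertices(s$poses[[1]]$femur)
  off_tib <- off_femur + 3L * n_vertices(s$poses[[1]]$tibia_fibula)
  span_med <- off_tib + seq_len(3L * n_vertices(s$poses[[1]]$meniscus_medial))
  expect_true(all(diff_idx %in% span_med))

  expect_error(assemble_shape_vector(s$poses[[2]], layout), NA)
  expect_error(disassemble_shape_vector(vec[-1], layout), "length")
})

test_that("component extraction preserves correspondence", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  pose <- disassemble_shape_vector(
    assemble_shape_vector(s$poses[[3]], layout), layout)
  m1 <- extract_component(pose, "meniscus_lateral")
  expect_identical(m1$vertices, s$poses[[3]]$meniscus_lateral$vertices)
  m0 <- extract_component(s$poses[[1]], "meniscus_lateral")
  expect_s3_class(displacement_field(m0, m1), "displacement_field")
  expect_error(extract_component(pose, "patella"), "unknown component")
})

test_that("linear motion reduces PPSA to the linear principal model", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  base <- assemble_shape_vector(s$poses[[1]], layout)
  dir <- sin(seq_along(base))
  dir <- dir / sqrt(sum(dir^2))
  ts <- c(0, 10, 25, 40)
  vecs <- lapply(ts, function(t) base + t * dir)
  model <- fit_ppsa(vecs, flexion_angles = ts, degree = 3, layout = layout)
  # corrections vanish: reconstruction is the line through the data
  recon45 <- meniscusdyn:::ppsa_shape_at(model, model$training_scores[2])
  expect_lt(max(abs(recon45 - vecs[[2]])), 1e-8)
  corr_mag <- vapply(seq_len(ncol(model$correction_directions)), function(j)
    max(abs(model$correction_directions[, j] *
              max(abs(model$polynomial_coefficients[, j])))), 0)
  expect_lt(max(corr_mag, 0), 1e-8)
})

test_that("degree n-1 PPSA interpolates every training pose", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  angles <- vapply(s$poses, function(p)
    flexion_angle(p$femur, s$tibial_frame, s$shaft_vertex_indices), 0)
  vecs <- lapply(s$poses, assemble_shape_vector, layout = layout)
  model <- fit_ppsa(vecs, angles, degree = 3, layout = layout)

  for (k in 1:4) {
    pose_k <- sample_pose(model, angles[k])
    for (nm in ppsa_component_names()) {
      err <- max(abs(pose_k[[nm]]$vertices - s$poses[[k]][[nm]]$vertices))
      expect_lt(err, 1e-6)
    }
  }
})

test_that("sampling at intermediate angles round-trips the flexion angle", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  angles <- vapply(s$poses, function(p)
    flexion_angle(p$femur, s$tibial_frame, s$shaft_vertex_indices), 0)
  model <- fit_ppsa(lapply(s$poses, assemble_shape_vector, layout = layout),
                    angles, degree = 3, layout = layout)

  pose45 <- sample_pose(model, 45)
  rec <- flexion_angle(pose45$femur, s$tibial_frame, s$shaft_vertex_indices)
  expect_equal(rec, 45, tolerance = 1)

  # monotone: increasing requested angles give increasing recomputed angles
  req <- seq(ceiling(angles[1]) + 1, floor(angles[4]) - 1, length.out = 6)
  recs <- vapply(req, function(a) {
    p <- sample_pose(model, a)
    flexion_angle(p$femur, s$tibial_frame, s$shaft_vertex_indices)
  }, 0)
  expect_true(all(diff(recs) > 0))

  expect_error(sample_pose(model, 120), "outside the calibrated interval")
  expect_warning(p120 <- sample_pose(model, angles[4] + 3,
                                     extrapolate = TRUE), "extrapolating")
})

test_that("PPSA preconditions are enforced", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  vecs <- lapply(s$poses, assemble_shape_vector, layout = layout)
  expect_error(fit_ppsa(vecs[1:3], c(0, 30, 60), degree = 3),
               "degree must be between")
  expect_error(fit_ppsa(vecs[1:2], c(0, 30)), "at least 3")
  expect_error(fit_ppsa(vecs, c(0, 30, 30, 90)), "duplicate")
})

test_that("PPSA is equivariant under a common rigid transform", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  angles <- vapply(s$poses, function(p)
    flexion_angle(p$femur, s$tibial_frame, s$shaft_vertex_indices), 0)
  model <- fit_ppsa(lapply(s$poses, assemble_shape_vector, layout = layout),
                    angles, degree = 3, layout = layout)

  tr <- random_rigid_transform(5)
  poses_t <- lapply(s$poses, function(p) {
    for (nm in ppsa_component_names()) p[[nm]] <- apply_transform(p[[nm]], tr)
    p
  })
  model_t <- fit_ppsa(lapply(poses_t, assemble_shape_vector,
                             layout = layout), angles, degree = 3,
                      layout = layout)
  a <- 47.3
  p1 <- sample_pose(model, a)
  p2 <- sample_pose(model_t, a)
  for (nm in ppsa_component_names())
    expect_equal(p2[[nm]]$vertices,
                 apply_transform(p1[[nm]], tr)$vertices, tolerance = 1e-8)
})

test_that("PPSA models serialize to JSON and back", {
  s <- fixture_subject()
  layout <- shape_layout(s$poses[[1]])
  angles <- vapply(s$poses, function(p)
    flexion_angle(p$femur, s$tibial_frame, s$shaft_vertex_indices), 0)
  model <- fit_ppsa(lapply(s$poses, assemble_shape_vector, layout = layout),
                    angles, degree = 3, layout = layout)
  path <- withr::local_tempfile(fileext = ".json")
  write_ppsa_model(model, path)
  back <- read_ppsa_model(path)
  a <- 52.5
  p1 <- sample_pose(model, a)
  p2 <- sample_pose(back, a)
  for (nm in ppsa_component_names())
    expect_equal(p2[[nm]]$vertices, p1[[nm]]$vertices, tolerance = 1e-9)
})
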