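test_that("sampled lesions are unilateral, connected and exactly sized", {
  sch <- small_scheme()
  dims <- dim(sch$labels)
  hemi <- voxel_hemisphere(sch)
  # a single-voxel lesion lands on the requested side
  m1 <- sample_lesion(sch, "left", 1L, seed = 5)
  expect_equal(sum(m1$volume), 1L)
  expect_equal(unique(hemi[m1$volume == 1L]), "left")
  # many seeded draws: exact volume, one hemisphere, face-connected
  set.seed(42)
  sides <- sample(c("left", "right"), 1000, replace = TRUE)
  sizes <- sample(1:40, 1000, replace = TRUE)
  for (k in seq_len(1000)) {
    m <- sample_lesion(sch, sides[k], sizes[k], seed = k)
    vox <- which(m$volume == 1L)
    expect_equal(length(vox), sizes[k])
    expect_true(all(hemi[vox] == sides[k]))
    if (length(vox) > 1L) {
      seen <- vox[1]; frontier <- vox[1]
      while (length(frontier)) {
        nb <- setdiff(intersect(gldmap:::.face_neighbours(frontier, dims),
                                vox), seen)
        seen <- c(seen, nb); frontier <- nb
      }
      expect_length(seen, length(vox))
    }
  }
})

test_that("lesion sampling is deterministic and guards its volume bounds", {
  sch <- small_scheme()
  a <- sample_lesion(sch, "right", 25L, seed = 9)
  b <- sample_lesion(sch, "right", 25L, seed = 9)
  expect_identical(a$volume, b$volume)
  expect_error(sample_lesion(sch, "left", 0L), "sizing error")
  expect_error(sample_lesion(sch, "left", 10000L), "sizing error")
})

test_that("masks round-trip losslessly through NIfTI and misalignment is rejected", {
  sch <- small_scheme()
  m <- sample_lesion(sch, "left", 17L, seed = 2)
  path <- tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  back <- read_mask(path, sch)
  expect_identical(back$volume, m$volume)
  expect_equal(sum(back$volume), 17L)
  expect_equal(back$side, "left")
  other <- make_parcel_scheme(c(10, 10, 10), 4L, seed = 1)
  expect_error(read_mask(path, other), "alignment error")
  expect_error(read_mask(tempfile(), sch), "no such file")
  unlink(path)
})

test_that("damage fractions are exact overlap ratios", {
  sch <- small_scheme()
  empty <- structure(list(volume = array(0L, dim(sch$labels)),
                          patient_id = "x", side = NA), class = "lesion_mask")
  expect_equal(damage_fractions(empty, sch), rep(0, 8))
  # lesion exactly equal to parcel 3
  vol <- array(0L, dim(sch$labels)); vol[sch$labels == 3L] <- 1L
  full <- structure(list(volume = vol, patient_id = "x", side = NA),
                    class = "lesion_mask")
  fr <- damage_fractions(full, sch)
  expect_equal(fr[3], 1.0)
  expect_equal(fr[-3], rep(0, 7))
  # fraction x parcel size recovers the lesion voxel count exactly
  for (sd in 1:20) {
    m <- sample_lesion(sch, "right", sample(1:50, 1), seed = sd)
    fr <- damage_fractions(m, sch)
    expect_equal(sum(fr * sch$parcels$n_vox), sum(m$volume))
  }
})

test_that("forced damage-fraction arithmetic: 2 of 8 voxels gives 0.25", {
  # hand-built scheme: 4 quadrant parcels of exactly 8 voxels each
  labels <- array(0L, c(4, 4, 2))
  for (x in 1:4) for (y in 1:4)
    labels[x, y, ] <- 1L + (x > 2) * 2L + (y > 2) * 1L
  sch <- structure(list(
    labels = labels,
    parcels = data.frame(parcel_id = 1:4,
                         hemisphere = c("left", "left", "right", "right"),
                         lobe = c("frontal", "posterior",
                                  "frontal", "posterior"),
                         n_vox = rep(8L, 4)),
    voxel_size_mm = c(2, 2, 2), seed = NA), class = "parcel_scheme")
  vol <- array(0L, dim(sch$labels))
  vol[which(sch$labels == 2L)[1:2]] <- 1L      # 2 of parcel 2's 8 voxels
  m <- structure(list(volume = vol, patient_id = "x", side = NA),
                 class = "lesion_mask")
  expect_equal(damage_fractions(m, sch), c(0, 0.25, 0, 0))
})

test_that("lobe classification follows the >= 70% lesion-volume rule", {
  # hand-built scheme with 4 quadrant parcels of exactly 16 voxels, so
  # voxel counts recovered from fractions are float-exact
  labels <- array(0L, c(4, 4, 4))
  for (x in 1:4) for (y in 1:4)
    labels[x, y, ] <- 1L + (x > 2) * 2L + (y > 2) * 1L
  sch <- structure(list(
    labels = labels,
    parcels = data.frame(parcel_id = 1:4,
                         hemisphere = c("left", "left", "right", "right"),
                         lobe = c("frontal", "posterior",
                                  "frontal", "posterior"),
                         n_vox = rep(16L, 4)),
    voxel_size_mm = c(2, 2, 2), seed = NA), class = "parcel_scheme")
  # 100% right frontal
  fr <- c(0, 0, 1, 0)
  cl <- classify_patient(fr, sch)
  expect_equal(cl$lobe_group, "frontal")
  expect_equal(cl$side, "right")
  # exactly 70% of lesioned voxels frontal (7 of 10): rule is >=
  fr <- c(0, 0, 7 / 16, 3 / 16)
  expect_equal(classify_patient(fr, sch)$lobe_group, "frontal")
  # 60/40 split: excluded
  fr <- c(0, 0, 6 / 16, 4 / 16)
  expect_equal(classify_patient(fr, sch)$lobe_group, "excluded")
  # 70% posterior: posterior, and majority side left
  fr <- c(3 / 16, 7 / 16, 0, 0)
  cl <- classify_patient(fr, sch)
  expect_equal(cl$lobe_group, "posterior")
  expect_equal(cl$side, "left")
  expect_error(classify_patient(numeric(4), sch), "empty-lesion")
})

test_that("classification is invariant to parcel relabelling", {
  sch <- default_scheme()
  set.seed(11)
  fr <- numeric(64)
  fr[sample(64, 6)] <- runif(6, 0.2, 1)
  base <- classify_patient(fr, sch)
  perm <- sample(64)
  sch2 <- sch
  sch2$parcels <- sch$parcels[perm, ]
  expect_equal(classify_patient(fr[perm], sch2)$lobe_group, base$lobe_group)
  expect_equal(classify_patient(fr[perm], sch2)$side, base$side)
})

test_that("binarization applies the >= tau rule", {
  m <- matrix(c(0.5, 0.49, 0.1, 0), 2, 2)
  expect_equal(binarize_damage(m, 0.5), matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_equal(binarize_damage(m, 1e-12), (m > 0) + 0L)  # any damage
  expect_true(all(binarize_damage(matrix(0.05, 3, 3), 0.1) == 0L))
  expect_error(binarize_damage(m, 0), "tau")
  expect_error(binarize_damage(m, 1.5), "tau")
})
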