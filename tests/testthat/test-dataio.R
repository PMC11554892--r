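# Readers/writers: patient records, VTK meshes, EAMS clouds, vein trees,
# scenario reports.

test_that("patient records load with printed values preserved and invariants checked", {
  path <- system.file("extdata", "patient_records.csv", package = "crtsim")
  recs <- read_patient_records(path)
  expect_equal(nrow(recs), 6)
  p2 <- recs[recs$patient_id == "P2", ]
  expect_equal(p2$edv - p2$esv, 76)
  expect_equal(p2$sv, 76)
  expect_equal(p2$ef, 15.2)
  # rounding-level discrepancies are reported, not repaired
  val <- attr(recs, "validation")
  expect_true(is.data.frame(val))
  p4 <- val[val$patient_id == "P4", ]
  expect_true(any(p4$issue == "sv-consistency"))   # printed SV 73 vs EDV-ESV 74
  expect_equal(recs[recs$patient_id == "P4", "sv"], 73)  # preserved as printed
})

test_that("record reader flags structural violations and malformed input", {
  d <- read.csv(system.file("extdata", "patient_records.csv", package = "crtsim"))
  tmp <- withr::local_tempfile(fileext = ".csv")

  # header-only file -> empty set
  write.csv(d[0, ], tmp, row.names = FALSE)
  expect_equal(nrow(read_patient_records(tmp)), 0)

  # EDV < ESV -> warning plus validation entry
  bad <- d[1, ]; bad$edv <- 100; bad$esv <- 200; bad$sv <- -100; bad$ef <- -100
  write.csv(bad, tmp, row.names = FALSE)
  expect_warning(r <- read_patient_records(tmp), "ordering")
  expect_true("volumes" %in% attr(r, "validation")$issue)

  # missing mandatory column
  write.csv(d[, setdiff(names(d), "esv")], tmp, row.names = FALSE)
  expect_error(read_patient_records(tmp), "esv")

  # non-numeric cell names the row
  bad <- d; bad$edv[2] <- "abc"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_patient_records(tmp), "row 2")
})

test_that("VTK mesh round trip preserves geometry and fields", {
  mesh <- test_mesh()
  fib <- generate_fibers(mesh)
  psi <- seq_len(nrow(mesh$nodes)) * 1e-4
  tmp <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, tmp, point_data = list(psi = psi),
                 cell_data = list(f = fib$f, z = rep(1, nrow(mesh$elems))))
  back <- read_mesh_vtk(tmp)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(back$elems, mesh$elems)
  expect_equal(back$point_data$psi, psi, tolerance = 1e-12)
  expect_equal(back$cell_data$f, fib$f, tolerance = 1e-12)
})

test_that("VTK reader rejects non-hexahedral content", {
  tmp <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "x", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               "POINTS 4 double", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "CELLS 1 5", "4 0 1 2 3", "CELL_TYPES 1", "10"), tmp)
  expect_error(read_mesh_vtk(tmp), "non-hexahedral")
})

test_that("EAMS CSV round trip partitions regions correctly", {
  pts <- matrix(rnorm(18), 6, 3)
  cl <- eams_cloud(pts, abs(rnorm(6)) / 10,
                   c("septum", "septum", "cs", "cs", "cs", "lateral"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_eams(cl, tmp)
  back <- read_eams(tmp)
  expect_equal(unname(table(back$region)[c("cs", "lateral", "septum")]),
               c(3L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(back$points, cl$points, tolerance = 1e-12)
  expect_equal(back$at, cl$at, tolerance = 1e-12)
  expect_error(eams_cloud(pts, rep(0.1, 6), rep("apex", 6)), "region")
})

test_that("vein tree JSON round trip preserves branches and arc lengths", {
  veins <- generate_vein_tree(test_mesh(), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_veins(veins, tmp)
  back <- read_veins(tmp)
  expect_equal(length(back$branches), length(veins$branches))
  for (k in seq_along(veins$branches)) {
    a1 <- sum(sqrt(rowSums(diff(veins$branches[[k]])^2)))
    a2 <- sum(sqrt(rowSums(diff(back$branches[[k]])^2)))
    expect_lt(abs(a1 - a2) / a1, 1e-9)
  }
})

test_that("scenario report round trips through JSON", {
  rep0 <- structure(
    data.frame(scenario = c("pre-operative", "LEAS"),
               dpdt_max = c(2000, 2100), sv = c(70, 80), ef = c(25, 28),
               sw = c(5000, 6000), d_dpdt_pct = c(0, 5), d_sv_pct = c(0, 14.3),
               d_ef_points = c(0, 3), d_sw_pct = c(0, 20), status = "ok"),
    class = c("scenario_report", "data.frame"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep0, tmp, meta = list(seed = 1))
  back <- read_report(tmp)
  expect_equal(back$report$sv, rep0$sv)
  expect_equal(back$meta$seed, 1)
  expect_true(file.exists(sub("\\.json$", ".csv", tmp)))
})

test_that("bundle generation is deterministic in the seed", {
  b1 <- suppressWarnings(synth_patient_bundle(seed = 11, mesh_h = 6,
                                              counts = c(septum = 4, cs = 10, lateral = 5)))
  b2 <- suppressWarnings(synth_patient_bundle(seed = 11, mesh_h = 6,
                                              counts = c(septum = 4, cs = 10, lateral = 5)))
  b3 <- suppressWarnings(synth_patient_bundle(seed = 12, mesh_h = 6,
                                              counts = c(septum = 4, cs = 10, lateral = 5)))
  expect_identical(b1$eams_sinus$at, b2$eams_sinus$at)
  expect_identical(b1$veins$branches, b2$veins$branches)
  expect_false(identical(b1$eams_sinus$at, b3$eams_sinus$at))
})
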