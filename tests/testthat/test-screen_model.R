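test_that("measurement tables round-trip through CSV bit-exactly", {
  m <- tiny_measurements()
  m$luminescence <- c(1e5, 1e5 / 3, 12345.678901234567)  # awkward doubles
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(nrow(back), 3L)
  expect_identical(back$luminescence, m$luminescence)
  expect_identical(back$concentration_um, m$concentration_um)
  expect_identical(back$well, m$well)
})

test_that("invalid measurement tables are rejected with the offending row", {
  m <- tiny_measurements()

  bad <- m; bad$luminescence[2] <- -5
  expect_error(validate_measurements(bad), "luminescence.*row 2")

  bad <- m; bad$well[3] <- "A01"
  expect_error(validate_measurements(bad), "duplicate \\(plate_id, well\\).*row 3")

  bad <- m; bad$concentration_um[1] <- 1  # DMSO at non-zero concentration
  expect_error(validate_measurements(bad), "vehicle well.*row 1")

  bad <- m; bad$condition[2] <- "FED"
  expect_error(validate_measurements(bad), "condition.*row 2")

  expect_error(validate_measurements(m[-7]), "missing column")
  expect_error(read_measurements("no/such/file.csv"), "not found")
})

test_that("annotation reader parses targets and rejects invalid tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,name,targets,role",
               "C001,romidepsin,HDAC,LIBRARY",
               "C002,dual,HDAC;HSP90,LIBRARY",
               "DMSO,vehicle,,VEHICLE"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 3L)
  expect_equal(split_targets(ann$targets)[[1]], "HDAC")
  expect_equal(split_targets(ann$targets)[[2]], c("HDAC", "HSP90"))
  expect_length(split_targets(ann$targets)[[3]], 0L)

  dup <- rbind(ann, ann[1, ])
  expect_error(validate_annotations(dup), "duplicate compound_id.*C001")

  no_target <- ann; no_target$targets[1] <- ""
  expect_error(validate_annotations(no_target), "without annotated target.*C001")
})

test_that("a full synthetic screen parses with the counts its config implies", {
  config <- screen_config(seed = 1L)
  dir <- withr::local_tempdir()
  simulate_screen(config, out_dir = dir)
  m <- read_measurements(file.path(dir, "measurements.csv"))
  ann <- read_annotations(file.path(dir, "annotations.csv"))

  n_levels <- length(config$grid)
  expect_equal(sum(!m$compound_id %in% sentinel_ids()),
               config$n_compounds * n_levels * config$n_replicates)
  # control/vehicle counts follow from the plate layout
  reserved <- config$vehicle_wells_per_plate +
    length(control_grids()$EIPA) + length(control_grids()$TORIN1)
  compounds_per_plate <- (96L - reserved) %/% n_levels
  n_plates <- ceiling(config$n_compounds / compounds_per_plate) *
    config$n_replicates
  expect_equal(length(unique(m$plate_id)), n_plates)
  expect_equal(sum(m$compound_id == "DMSO"),
               n_plates * config$vehicle_wells_per_plate)
  expect_equal(sum(m$compound_id == "EIPA"),
               n_plates * length(control_grids()$EIPA))
  expect_equal(nrow(ann), config$n_compounds + 3L)
})

test_that("report bundles round-trip, including full-precision summaries", {
  aucs <- c(23.7 - 7.3, 23.7, 23.7 + 7.3)
  auc_table <- data.frame(compound_id = c("C1", "C2", "C3"), auc = aucs,
                          n_replicates = 4L,
                          replicate_aucs = "1;2;3;4",
                          stringsAsFactors = FALSE)
  s <- summarize_screen(auc_table)
  hits <- call_hits(auc_table, s)
  empty_groups <- group_hits(hits[hits$direction == "NONE", ],
                             data.frame(compound_id = c("C1", "C2", "C3"),
                                        name = "x", targets = "T",
                                        role = "LIBRARY"))
  dir <- withr::local_tempdir()
  write_report(list(summary = s, auc_table = auc_table, hits = hits,
                    target_groups = empty_groups), dir)
  back <- read_report(dir)
  expect_equal(back$summary$mean_auc, 23.7)
  expect_identical(back$auc_table$auc, auc_table$auc)
  expect_identical(back$hits$direction, hits$direction)
  expect_equal(nrow(back$target_groups), 0L)  # zero-row hit table is valid
  expect_error(write_report(list(summary = s), dir), "missing element")
})
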