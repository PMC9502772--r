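# Shared fixtures and the independent AUC oracle.

# Dense numeric integration of the piecewise-linear viability interpolant
# (anchored at 0 uM / viability 1). Evaluation points include the grid kinks,
# so the fine-grid trapezoid integrates the interpolant essentially exactly;
# this path shares no code with auc_single().
auc_oracle <- function(viability, grid) {
  x <- c(0, as.numeric(grid))
  y <- c(1, viability)
  xs <- sort(unique(c(x, seq(0, max(x), length.out = 5001L))))
  ys <- stats::approx(x, y, xout = xs)$y
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
}

# Minimal 3-row measurement table (one plate, one DMSO + two compound wells).
tiny_measurements <- function() {
  data.frame(
    plate_id = "P01", well = c("A01", "A02", "A03"),
    compound_id = c("DMSO", "C001", "C001"),
    concentration_um = c(0, 0.2, 1),
    condition = "GLN_STARVED_BSA", replicate = 1L,
    luminescence = c(1e5, 5e4, 2.5e4), stringsAsFactors = FALSE)
}

tiny_annotations <- function() {
  data.frame(
    compound_id = c("C001", "DMSO"),
    name = c("compound-1", "vehicle"),
    targets = c("HDAC", ""),
    role = c("LIBRARY", "VEHICLE"), stringsAsFactors = FALSE)
}

# One-plate measurement table with a full library grid for `compounds`
# (viability matrix rows = replicates), DMSO wells, and control series with
# given per-level viabilities. Luminescence = dmso_mean * viability.
plate_measurements <- function(compound_viability = list(),
                               eipa = c(1, 0.9, 0.4, 0.05),
                               torin1 = c(1, 1.5, 1.6, 0.3),
                               dmso_mean = 1e5, n_dmso = 4L,
                               plate_id = "P01", replicate = 1L,
                               condition = "GLN_STARVED_BSA") {
  grid <- as.numeric(default_grid())
  ctrl <- control_grids()
  compound_id <- c(rep("DMSO", n_dmso),
                   rep("EIPA", length(ctrl$EIPA)),
                   rep("TORIN1", length(ctrl$TORIN1)))
  conc <- c(rep(0, n_dmso), as.numeric(ctrl$EIPA), as.numeric(ctrl$TORIN1))
  viab <- c(rep(1, n_dmso), eipa, torin1)
  for (id in names(compound_viability)) {
    v <- compound_viability[[id]]
    compound_id <- c(compound_id, rep(id, length(grid)))
    conc <- c(conc, grid)
    viab <- c(viab, v)
  }
  n <- length(compound_id)
  data.frame(
    plate_id = plate_id,
    well = as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12),
                             paste0)))[seq_len(n)],
    compound_id = compound_id, concentration_um = conc,
    condition = condition, replicate = replicate,
    luminescence = dmso_mean * viab, stringsAsFactors = FALSE)
}

# Annotation + hit fixtures for the published positive-regulator compounds.
published_hit_fixture <- function() {
  ann <- data.frame(
    compound_id = c("romidepsin", "PCI-24781", "LAQ824", "MGCD0103",
                    "trichostatin A", "17-AAG", "AT13387", "(-)-Deguelin",
                    "CDDO-Me", "GMX-1778", "APO866", "OSI-906",
                    "BMS-536924", "inert-1"),
    name = c("romidepsin", "PCI-24781", "LAQ824", "MGCD0103",
             "trichostatin A", "17-AAG", "AT13387", "(-)-Deguelin",
             "CDDO-Me", "GMX-1778", "APO866", "OSI-906",
             "BMS-536924", "inert-1"),
    targets = c(rep("HDAC", 5), rep("HSP90", 4), rep("NAMPT", 2),
                rep("IGF-1R", 2), "OTHER"),
    role = "LIBRARY", stringsAsFactors = FALSE)
  hits <- data.frame(
    compound_id = ann$compound_id,
    auc = c(rep(10, 13), 25),
    direction = c(rep("DECREASE", 13), "NONE"),
    regulator_class = c(rep("POSITIVE_REGULATOR_TARGET", 13), "NONE"),
    stringsAsFactors = FALSE)
  list(annotations = ann, hits = hits)
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- sort(list.files(dir, recursive = TRUE))
  sums
}
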