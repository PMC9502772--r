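# Synthetic screen generator: Hill-shaped planted effects, 96-well plate
# maps with per-plate DMSO/EIPA/Torin1 wells, multiplicative lognormal noise,
# and a ground-truth table for every planted parameter.

#' Specify the planted dose-response of a synthetic compound
#'
#' Phenomenological Hill-curve families standing in for unknown true
#' dose-responses: `INERT` (viability 1 everywhere), `INHIBITOR`
#' (sigmoid decline to `bottom`), `ENHANCER` (sigmoid rise to `emax`), and
#' `BIPHASIC` (enhancement followed by kill above `kill_ec50`, the
#' Torin1-like enhance-then-kill shape).
#'
#' @param kind One of `"INERT"`, `"INHIBITOR"`, `"ENHANCER"`, `"BIPHASIC"`.
#' @param ec50 Midpoint of the first phase, uM > 0.
#' @param hill Hill slope > 0.
#' @param bottom Inhibitor floor, >= 0.
#' @param emax Enhancer ceiling, >= 1.
#' @param kill_ec50 Midpoint of the biphasic kill phase, uM > `ec50`.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(kind = c("INERT", "INHIBITOR", "ENHANCER", "BIPHASIC"),
                        ec50 = 1, hill = 1, bottom = 0, emax = 2,
                        kill_ec50 = ec50 * 10) {
  kind <- match.arg(kind)
  if (kind != "INERT") {
    stopifnot(ec50 > 0, hill > 0, bottom >= 0, emax >= 1)
    if (kind == "BIPHASIC" && kill_ec50 <= ec50) {
      stop("BIPHASIC effect requires kill_ec50 > ec50", call. = FALSE)
    }
  }
  structure(list(kind = kind, ec50 = ec50, hill = hill, bottom = bottom,
                 emax = emax, kill_ec50 = kill_ec50),
            class = "effect_spec")
}

#' Noise-free viability of a planted effect
#'
#' INERT returns 1; INHIBITOR returns
#' `bottom + (1 - bottom) / (1 + (c/ec50)^hill)`; ENHANCER returns
#' `1 + (emax - 1) * c^hill / (c^hill + ec50^hill)`; BIPHASIC multiplies the
#' enhancer term by an inhibitor term with midpoint `kill_ec50`. All kinds
#' return exactly 1 at c = 0, matching the vehicle anchor.
#'
#' @param effect An `effect_spec`.
#' @param conc Numeric vector of concentrations, uM >= 0.
#' @return Numeric vector of non-negative viabilities.
#' @export
true_viability <- function(effect, conc) {
  stopifnot(inherits(effect, "effect_spec"))
  conc <- as.numeric(conc)
  if (any(conc < 0 | !is.finite(conc))) {
    stop("true_viability: concentration must be finite and >= 0",
         call. = FALSE)
  }
  hillf <- function(c, ec50, h) {
    # occupancy c^h / (c^h + ec50^h), exactly 0 at c = 0
    ifelse(c == 0, 0, 1 / (1 + (ec50 / c)^h))
  }
  switch(effect$kind,
    INERT = rep(1, length(conc)),
    INHIBITOR = effect$bottom +
      (1 - effect$bottom) * (1 - hillf(conc, effect$ec50, effect$hill)),
    ENHANCER = 1 + (effect$emax - 1) * hillf(conc, effect$ec50, effect$hill),
    BIPHASIC = (1 + (effect$emax - 1) * hillf(conc, effect$ec50, effect$hill)) *
      (1 - hillf(conc, effect$kill_ec50, effect$hill))
  )
}

#' Stock-into-well dilution
#'
#' Final concentration when `stock_vol` uL of stock at `stock_um` uM is added
#' to `well_vol` uL of medium: `stock_um * stock_vol / (stock_vol +
#' well_vol)`. The screen's 10 uL into 40 uL additions dilute every stock
#' 5-fold (e.g. 125 uM stock to 25 uM final; 500 uM EIPA stock to 100 uM).
#'
#' @param stock_um Stock concentration, uM.
#' @param stock_vol Added volume, uL > 0.
#' @param well_vol Medium volume already in the well, uL > 0.
#' @return Final concentration, uM.
#' @export
dilution <- function(stock_um, stock_vol, well_vol) {
  if (any(stock_vol <= 0) || any(well_vol <= 0)) {
    stop("dilution: volumes must be > 0", call. = FALSE)
  }
  stock_um * stock_vol / (stock_vol + well_vol)
}

#' Configuration of a synthetic screen
#'
#' Defaults mirror the screen design: a 225-compound library at
#' (0.2, 1, 5, 25) uM in 4 replicates under glutamine starvation + 5\% BSA,
#' with DMSO vehicle wells and EIPA/Torin1 dose series on every 96-well
#' plate, and a 9.6-fold BSA rescue over plain starvation. Measurement noise
#' is multiplicative lognormal with mean 1 and coefficient of variation
#' `noise_cv` (default 0.1, an artifact choice: true screen noise is
#' unreported).
#'
#' @param n_compounds Library size.
#' @param grid Library concentration grid.
#' @param n_replicates Replicates per compound.
#' @param noise_cv CV of the multiplicative lognormal noise, >= 0.
#' @param noise_model `"lognormal"` (default) or `"gaussian"` (additive on
#'   the multiplicative factor, truncated at 0).
#' @param vehicle_wells_per_plate DMSO wells per plate.
#' @param baseline_luminescence Luminescence of an untreated glutamine-starved
#'   well, arbitrary units.
#' @param rescue_fold Fold viability gain of the BSA condition over plain
#'   starvation.
#' @param complete_factor Luminescence factor of complete medium over plain
#'   starvation (>= rescue_fold by default).
#' @param condition Condition the screen plates run in.
#' @param seed Master seed; per-plate substreams are derived from it so that
#'   adding a plate never perturbs earlier plates.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(n_compounds = 225L, grid = default_grid(),
                          n_replicates = 4L, noise_cv = 0.1,
                          noise_model = c("lognormal", "gaussian"),
                          vehicle_wells_per_plate = 4L,
                          baseline_luminescence = 1e5,
                          rescue_fold = 9.6, complete_factor = 12,
                          condition = "GLN_STARVED_BSA", seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid <- as_concentration_grid(grid)
  stopifnot(n_compounds >= 1, n_replicates >= 1, noise_cv >= 0,
            vehicle_wells_per_plate >= 1, baseline_luminescence > 0,
            rescue_fold > 0, complete_factor > 0)
  if (!condition %in% screen_conditions()) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds), grid = grid,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, noise_model = noise_model,
                 vehicle_wells_per_plate = as.integer(vehicle_wells_per_plate),
                 baseline_luminescence = baseline_luminescence,
                 rescue_fold = rescue_fold, complete_factor = complete_factor,
                 condition = condition, seed = as.integer(seed)),
            class = "screen_config")
}

#' Planted effect layout for a synthetic library
#'
#' Assigns effects by position: the first `n_inhibitors` compounds are strong
#' inhibitors, the next `n_enhancers` enhancers, the next `n_biphasic`
#' biphasic, and the remainder inert. Defaults plant 20 strong inhibitors
#' (EC50 0.5 uM, bottom 0) and 5 strong enhancers (Emax 2, EC50 0.5 uM) in a
#' 225-compound library.
#'
#' @param n_compounds Library size.
#' @param n_inhibitors,n_enhancers,n_biphasic Planted counts.
#' @param inhibitor,enhancer,biphasic `effect_spec`s used for each class.
#' @return Named list of `effect_spec`, names `C001`, `C002`, ...
#' @export
planted_effects <- function(n_compounds = 225L, n_inhibitors = 20L,
                            n_enhancers = 5L, n_biphasic = 0L,
                            inhibitor = effect_spec("INHIBITOR", ec50 = 0.5,
                                                    hill = 1, bottom = 0),
                            enhancer = effect_spec("ENHANCER", ec50 = 0.5,
                                                   hill = 1, emax = 2),
                            biphasic = effect_spec("BIPHASIC", ec50 = 0.1,
                                                   hill = 1.5, emax = 1.8,
                                                   kill_ec50 = 10)) {
  n_planted <- n_inhibitors + n_enhancers + n_biphasic
  if (n_planted > n_compounds) {
    stop("more planted effects than compounds", call. = FALSE)
  }
  kinds <- c(rep(list(inhibitor), n_inhibitors),
             rep(list(enhancer), n_enhancers),
             rep(list(biphasic), n_biphasic),
             rep(list(effect_spec("INERT")), n_compounds - n_planted))
  names(kinds) <- sprintf("C%03d", seq_len(n_compounds))
  kinds
}

# Default shapes of the on-plate controls. EIPA inhibits in its 20-100 uM
# window; Torin1 enhances around 0.2-1 uM and kills at its 5 uM top dose.
control_effects <- function() {
  list(EIPA = effect_spec("INHIBITOR", ec50 = 40, hill = 2, bottom = 0.05),
       TORIN1 = effect_spec("BIPHASIC", ec50 = 0.05, hill = 1.5,
                            emax = 1.6, kill_ec50 = 3))
}

derive_seed <- function(master, index) {
  # deterministic substream seed, kept within 32-bit integer range
  as.integer((as.double(master) * 7919 + as.double(index) * 104729) %%
               2147483647) + 1L
}

noise_factors <- function(n, cv, model) {
  if (cv == 0 || n == 0L) return(rep(1, n))
  if (model == "lognormal") {
    sdlog <- sqrt(log1p(cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(stats::rnorm(n, mean = 1, sd = cv), 0)
  }
}

well_names <- function(n) {
  all_wells <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  if (n > length(all_wells)) {
    stop("plate layout exceeds 96 wells", call. = FALSE)
  }
  all_wells[seq_len(n)]
}

#' Generate a complete synthetic screen
#'
#' Lays the library out on 96-well plates (per plate: the configured DMSO
#' vehicle wells, the 4-point EIPA and Torin1 control series, then as many
#' whole library compounds x grid levels as fit), one plate set per
#' replicate. Well luminescence is
#' `baseline x condition factor x true viability x noise`, with noise drawn
#' from a per-plate substream of the master seed, so identical seed and
#' configuration give bit-identical output.
#'
#' @param config A [screen_config()].
#' @param effects Named list of [effect_spec()] covering every compound id
#'   `C001 ... C<n>`; default [planted_effects()] sized to the config.
#' @return List with `measurements`, `annotations` and `truth` data.frames.
#'   The truth table records every planted parameter
#'   (`compound_id,kind,ec50,hill,bottom,emax,kill_ec50`).
#' @export
generate_screen <- function(config = screen_config(),
                            effects = planted_effects(config$n_compounds)) {
  stopifnot(inherits(config, "screen_config"))
  ids <- sprintf("C%03d", seq_len(config$n_compounds))
  missing_fx <- setdiff(ids, names(effects))
  if (length(missing_fx)) {
    stop("effects missing for compound(s): ",
         paste(utils::head(missing_fx, 3L), collapse = ", "), call. = FALSE)
  }
  grid <- as.numeric(config$grid)
  ctrl <- control_grids()
  ctrl_fx <- control_effects()
  n_levels <- length(grid)
  n_reserved <- config$vehicle_wells_per_plate +
    length(ctrl$EIPA) + length(ctrl$TORIN1)
  compounds_per_plate <- (96L - n_reserved) %/% n_levels
  if (compounds_per_plate < 1L) {
    stop("plate layout leaves no room for library wells", call. = FALSE)
  }
  n_plates <- ceiling(config$n_compounds / compounds_per_plate)
  cond_factor <- switch(config$condition,
                        GLN_STARVED = 1,
                        GLN_STARVED_BSA = config$rescue_fold,
                        COMPLETE = config$complete_factor)

  plate_tables <- vector("list", n_plates * config$n_replicates)
  k <- 0L
  for (rep_i in seq_len(config$n_replicates)) {
    for (plate_i in seq_len(n_plates)) {
      k <- k + 1L
      plate_id <- sprintf("P%02d_R%d", plate_i, rep_i)
      first <- (plate_i - 1L) * compounds_per_plate + 1L
      last <- min(plate_i * compounds_per_plate, config$n_compounds)
      lib_ids <- ids[first:last]
      compound_id <- c(
        rep(sentinel_ids()[["vehicle"]], config$vehicle_wells_per_plate),
        rep("EIPA", length(ctrl$EIPA)),
        rep("TORIN1", length(ctrl$TORIN1)),
        rep(lib_ids, each = n_levels))
      conc <- c(rep(0, config$vehicle_wells_per_plate),
                as.numeric(ctrl$EIPA), as.numeric(ctrl$TORIN1),
                rep(grid, times = length(lib_ids)))
      tv <- numeric(length(compound_id))
      tv[compound_id == sentinel_ids()[["vehicle"]]] <- 1
      eipa_sel <- compound_id == "EIPA"
      tv[eipa_sel] <- true_viability(ctrl_fx$EIPA, conc[eipa_sel])
      torin_sel <- compound_id == "TORIN1"
      tv[torin_sel] <- true_viability(ctrl_fx$TORIN1, conc[torin_sel])
      for (id in lib_ids) {
        sel <- compound_id == id
        tv[sel] <- true_viability(effects[[id]], conc[sel])
      }
      # substream keyed by (replicate, plate position): adding plates or
      # replicates never perturbs the noise of existing ones
      set.seed(derive_seed(config$seed, rep_i * 4096L + plate_i))
      noise <- noise_factors(length(compound_id), config$noise_cv,
                             config$noise_model)
      plate_tables[[k]] <- data.frame(
        plate_id = plate_id, well = well_names(length(compound_id)),
        compound_id = compound_id, concentration_um = conc,
        condition = config$condition, replicate = rep_i,
        luminescence = config$baseline_luminescence * cond_factor * tv * noise,
        stringsAsFactors = FALSE)
    }
  }
  measurements <- do.call(rbind, plate_tables)
  rownames(measurements) <- NULL

  kinds <- vapply(effects[ids], `[[`, character(1), "kind")
  # synthetic target labels: consecutive triples share a target so that
  # planted hits aggregate into multi-hit groups, as real libraries do
  target <- sprintf("TGT%03d", (seq_len(config$n_compounds) - 1L) %/% 3L + 1L)
  annotations <- rbind(
    data.frame(compound_id = ids, name = paste0("compound-", ids),
               targets = target, role = "LIBRARY", stringsAsFactors = FALSE),
    data.frame(compound_id = c("DMSO", "EIPA", "TORIN1"),
               name = c("vehicle", "EIPA", "Torin1"),
               targets = c("", "NHE1", "MTOR"),
               role = c("VEHICLE", "CONTROL_INHIBITOR", "CONTROL_ENHANCER"),
               stringsAsFactors = FALSE))
  param_or_na <- function(field) {
    vapply(ids, function(id) {
      fx <- effects[[id]]
      if (fx$kind == "INERT") NA_real_
      else if (field == "kill_ec50" && fx$kind != "BIPHASIC") NA_real_
      else as.numeric(fx[[field]])
    }, numeric(1), USE.NAMES = FALSE)
  }
  truth <- data.frame(compound_id = ids, kind = unname(kinds),
                      ec50 = param_or_na("ec50"), hill = param_or_na("hill"),
                      bottom = param_or_na("bottom"),
                      emax = param_or_na("emax"),
                      kill_ec50 = param_or_na("kill_ec50"),
                      stringsAsFactors = FALSE)
  list(measurements = validate_measurements(measurements),
       annotations = validate_annotations(annotations),
       truth = truth)
}

#' Generate a BSA-rescue viability experiment
#'
#' Emulates the cell-line comparison of growth under glutamine starvation
#' with and without 5\% BSA: per replicate, luminescence is the starved
#' baseline times `rescue_fold` in the BSA arm, times multiplicative noise.
#' Used to exercise [fold_change()] against a known planted fold.
#'
#' @param rescue_fold Planted fold (default 9.6, the strongest of the three
#'   cell lines the assay was built on).
#' @param cv Noise coefficient of variation.
#' @param n_replicates Replicates per condition (default 3).
#' @param baseline_luminescence Starved-arm mean luminescence.
#' @param group Label for the group/cell-line column.
#' @param seed Seed.
#' @return Data.frame with `group`, `condition`, `replicate`, `viability`
#'   (luminescence scaled to the starved-arm expectation).
#' @export
generate_rescue_experiment <- function(rescue_fold = 9.6, cv = 0.1,
                                       n_replicates = 3L,
                                       baseline_luminescence = 1e5,
                                       group = "MPD-line", seed = 1L) {
  stopifnot(rescue_fold > 0, cv >= 0, n_replicates >= 2)
  set.seed(derive_seed(seed, 0L))
  cond <- rep(c("GLN_STARVED", "GLN_STARVED_BSA"), each = n_replicates)
  factor <- ifelse(cond == "GLN_STARVED_BSA", rescue_fold, 1)
  lum <- baseline_luminescence * factor *
    noise_factors(length(cond), cv, "lognormal")
  data.frame(group = group, condition = cond,
             replicate = rep(seq_len(n_replicates), times = 2L),
             viability = lum / baseline_luminescence,
             stringsAsFactors = FALSE)
}
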