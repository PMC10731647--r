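# File interfaces: the versioned chemical-model JSON document and the CSV
# formats shared by the instrument-facing modules.

CHEMICAL_MODEL_VERSION <- 1L

#' Write a chemical-model document to JSON
#'
#' The document bundles the pKa ladder, the candidate complex species and the
#' default equilibrium conditions: everything the speciation, ITC and TRLFS
#' stages must agree on.
#'
#' @param scheme a [protolysis_scheme()].
#' @param species list of [complex_species()].
#' @param conditions an [equilibrium_conditions()] or NULL.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chemical_model <- function(scheme, species, conditions = NULL, path) {
  doc <- list(
    version = CHEMICAL_MODEL_VERSION,
    pKa = scheme$pKa,
    species = lapply(species, function(s)
      list(m = s$m, l = s$l, log_beta = s$log_beta, label = s$label)),
    conditions = if (!is.null(conditions))
      conditions[c("metal_total", "ligand_total", "pH", "temperature",
                   "ionic_strength")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a chemical-model JSON document
#'
#' @param path file path.
#' @return list with `scheme`, `species`, `conditions` (NULL if absent).
#' @export
read_chemical_model <- function(path) {
  if (!file.exists(path)) stop("chemical model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  v <- doc$version
  if (is.null(v) || as.integer(v) > CHEMICAL_MODEL_VERSION)
    stop("unsupported chemical-model document version: ",
         if (is.null(v)) "<missing>" else v)
  scheme <- protolysis_scheme(vapply(doc$pKa, as.numeric, numeric(1)))
  species <- lapply(doc$species, function(s)
    complex_species(s$m, s$l, s$log_beta,
                    if (!is.null(s$label)) s$label))
  conditions <- NULL
  if (!is.null(doc$conditions))
    conditions <- equilibrium_conditions(
      doc$conditions$metal_total, doc$conditions$ligand_total,
      doc$conditions$pH,
      temperature = doc$conditions$temperature %||% 25,
      ionic_strength = doc$conditions$ionic_strength %||% 0.1)
  list(scheme = scheme, species = species, conditions = conditions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read NMR titration series from CSV
#'
#' Expected columns: `signal_id`, `pD`, `shift_ppm`.
#'
#' @param path CSV file path.
#' @return named list of [nmr_titration_series()], one per signal.
#' @export
read_nmr_csv <- function(path) {
  if (!file.exists(path)) stop("NMR CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("signal_id", "pD", "shift_ppm")
  if (!all(need %in% names(df)))
    stop("NMR CSV must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$pD) | !is.finite(df$shift_ppm))
  if (length(bad))
    stop("non-numeric NMR data at row(s) ", paste(bad, collapse = ", "))
  out <- lapply(split(df, df$signal_id), function(d)
    nmr_titration_series(d$signal_id[1], d$pD, d$shift_ppm))
  out[unique(df$signal_id)]
}

#' Write NMR titration series to CSV
#' @param series list of [nmr_titration_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nmr_csv <- function(series, path) {
  if (inherits(series, "nmr_titration_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(signal_id = s$signal_id, pD = s$pD, shift_ppm = s$shift)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ITC thermogram from CSV
#'
#' Expected columns: `injection_index`, `volume_uL`, and `heat_uJ` or
#' `heat_ucal` (converted with 1 cal = 4.184 J).
#'
#' @param path CSV file path.
#' @param pH solution pH to attach.
#' @param is_blank background flag.
#' @return list: `thermogram` ([thermogram()]) and `volumes` (litres).
#' @export
read_itc_csv <- function(path, pH = NA_real_, is_blank = FALSE) {
  if (!file.exists(path)) stop("ITC CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"injection_index" %in% names(df) || !"volume_uL" %in% names(df))
    stop("ITC CSV must have columns injection_index, volume_uL and ",
         "heat_uJ (or heat_ucal)")
  df <- df[order(df$injection_index), ]
  heats <- if ("heat_uJ" %in% names(df)) df$heat_uJ else
    if ("heat_ucal" %in% names(df)) ucal_to_uJ(df$heat_ucal) else
      stop("ITC CSV needs a heat_uJ or heat_ucal column")
  bad <- which(!is.finite(heats) | !is.finite(df$volume_uL))
  if (length(bad))
    stop("non-numeric ITC data at row(s) ", paste(bad, collapse = ", "))
  list(thermogram = thermogram(heats, pH, label = basename(path),
                               is_blank = is_blank),
       volumes = df$volume_uL * 1e-6)
}

#' Write an ITC thermogram to CSV
#' @param tg a [thermogram()].
#' @param volumes per-injection volumes, litres.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(tg, volumes, path) {
  utils::write.csv(data.frame(injection_index = seq_along(tg$heats),
                              volume_uL = volumes * 1e6,
                              heat_uJ = tg$heats),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a TRLFS cube to a directory of per-sample CSV matrices
#'
#' One CSV per titration step (rows = wavelength nm, columns = delay us)
#' plus a `manifest.json` recording totals, pH, and the absolute delay
#' schedule, making the directory self-describing.
#'
#' @param cube a [trlfs_cube()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trlfs_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- dim(cube$intensities)[1]
  files <- sprintf("sample_%02d.csv", seq_len(S))
  for (s in seq_len(S)) {
    m <- cube$intensities[s, , ]
    df <- data.frame(wavelength_nm = cube$wavelength, m)
    names(df)[-1] <- sprintf("delay_%g", cube$schedule$delays)
    utils::write.csv(df, file.path(dir, files[s]), row.names = FALSE)
  }
  manifest <- list(version = 1, files = files,
                   metal_total = cube$metal_total,
                   ligand_total = cube$ligand_total, pH = cube$pH,
                   excitation = cube$excitation,
                   schedule = list(a = cube$schedule$a,
                                   n_gates = cube$schedule$n_gates,
                                   initial_delay = cube$schedule$initial_delay,
                                   gate_width = cube$schedule$gate_width,
                                   delays_us = cube$schedule$delays))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a TRLFS cube from a directory written by [write_trlfs_cube()]
#' @param dir directory containing per-sample CSVs and `manifest.json`.
#' @return a [trlfs_cube()].
#' @export
read_trlfs_cube <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("manifest.json not found in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  sched <- build_delay_schedule(mf$schedule$a, mf$schedule$n_gates,
                                mf$schedule$initial_delay,
                                mf$schedule$gate_width)
  if (max(abs(sched$delays - mf$schedule$delays_us)) > 1e-9)
    stop("manifest delay schedule is inconsistent with its parameters")
  mats <- lapply(mf$files, function(f) {
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  })
  wavelength <- utils::read.csv(file.path(dir, mf$files[1]),
                                check.names = FALSE)[[1]]
  X <- array(0, dim = c(length(mats), length(wavelength), sched$n_gates))
  for (s in seq_along(mats)) X[s, , ] <- mats[[s]]
  trlfs_cube(X, wavelength, sched, mf$metal_total, mf$ligand_total, mf$pH,
             excitation = mf$excitation %||% 394)
}

#' Export a speciation titration series to CSV
#'
#' One row per titration step; columns: totals, pH, free concentrations and
#' each complex species (molar units).
#'
#' @param results list of `speciation_result`.
#' @param path output path.
#' @return the data frame written, invisibly.
#' @export
write_speciation_csv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(metal_total = r$conditions$metal_total,
                      ligand_total = r$conditions$ligand_total,
                      pH = r$conditions$pH,
                      free_metal = r$free_metal,
                      free_ligand = r$free_ligand)
    for (nm in names(r$complexes)) row[[nm]] <- r$complexes[[nm]]
    row
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
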