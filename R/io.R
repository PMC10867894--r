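#' Default run configuration
#'
#' Flat, sectioned key-value configuration describing one run. Every default
#' is the model's published operating point: ion diameter 0.355 nm, monomer
#' diameter 1.2 sigma, K = 827 kBT/nm^2, R0 = 0.426 nm, permittivity 62
#' (PEC) / 78 (supernatant), pKa 4.2 / 5.6, dt = 0.01 tau, 500 reaction
#' attempts every 1e4 dynamics steps. All lengths in the file are SI
#' (nanometres) or reduced where marked; concentrations are mol/L.
#'
#' @param phase `"pec"` or `"supernatant"`.
#' @param seed RNG seed for the run.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(phase = c("pec", "supernatant"), seed = 1L) {
  phase <- match.arg(phase)
  structure(list(
    phase = phase,
    seed = as.integer(seed),
    units = list(length_nm = 0.355, temperature = 298.15),
    species = list(sigma_mon = 1.2, lam_mon = 0),
    interactions = list(eps_r_pec = 62, eps_r_sup = 78,
                        k_bond_kT_nm2 = 827, r0_nm = 0.426,
                        cutoff_factor = 2.5, ewald_accuracy = 1e-3),
    reservoir = list(pH = 7, c_salt = 0.15, c_acid = 0, c_divalent = 0,
                     pKa1 = 4.2, pKa2 = 5.6, pKw = 14),
    box = list(n_chains_per_species = 32L, chain_length = 32L,
               target_phi = 0.15, L_sup = 10),
    protocol = list(relax_steps = 1e5, md_steps_per_cycle = 1e4,
                    mc_attempts_per_cycle = 500, n_cycles = 1000,
                    sample_every = 100, gamma = 1, dt = 0.01,
                    phi_scan = numeric(0))
  ), class = "run_config")
}

#' Read / write a run configuration
#'
#' Configurations serialize losslessly to a flat sectioned key-value text
#' file (YAML).
#'
#' @param config a `run_config` list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML has no scalar/vector distinction: restore numeric vector fields
  if (!is.null(cfg$protocol))
    cfg$protocol$phi_scan <- as.numeric(unlist(cfg$protocol$phi_scan))
  structure(cfg, class = "run_config")
}

#' Write a trajectory in XYZ format
#'
#' One frame per sample, species labels in column 1, coordinates in reduced
#' units.
#'
#' @param trajectory a `pec_trajectory`.
#' @param path output file.
#' @export
write_xyz <- function(trajectory, path) {
  labels <- trajectory$species_table$name[trajectory$species_idx]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(trajectory$frames)) {
    p <- trajectory$frames[[f]]
    writeLines(c(as.character(nrow(p)),
                 sprintf("frame %d t= %g L= %g", f, trajectory$times[f],
                         trajectory$L)), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", labels, p[, 1], p[, 2], p[, 3]),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_xyz()]
#' @param path file path.
#' @return list with `frames`, `labels`, `times`, `L`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  L <- NA_real_
  labels <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    times <- c(times, as.numeric(hdr[which(hdr == "t=") + 1]))
    L <- as.numeric(hdr[which(hdr == "L=") + 1])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(block, "\\s+"))
    labels <- parts[, 1]
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), n, 3)
    i <- i + 2 + n
  }
  list(frames = frames, labels = labels, times = times, L = L)
}

#' Write a data frame as tab-separated values
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Checkpoint and restore a full simulation state
#'
#' Stores the state together with R's RNG state so a run can be resumed
#' bit-reproducibly.
#'
#' @param state a [system_state()].
#' @param path checkpoint file (binary, run-time artifact).
#' @export
checkpoint_state <- function(state, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(state = state, rng = rng), path)
  invisible(path)
}

#' @rdname checkpoint_state
#' @export
restore_checkpoint <- function(path) {
  chk <- readRDS(path)
  if (!is.null(chk$rng))
    assign(".Random.seed", chk$rng, envir = globalenv())
  chk$state
}

#' Write a reproducibility manifest
#'
#' Records the configuration hash, seed and software versions next to every
#' set of run outputs so any output is reproducible from config + seed
#' alone.
#'
#' @param config_path path of the configuration the run used.
#' @param seed seed used.
#' @param path output JSON path.
#' @param extra named list of additional fields.
#' @export
write_manifest <- function(config_path, seed, path, extra = list()) {
  man <- c(list(
    config = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package = "pecsim",
    package_version = as.character(utils::packageVersion("pecsim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
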