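# Text formats tying the pipeline together: a versioned trajectory format,
# XYZ export, binodal/profile TSVs, flat key-value run configs and run
# manifests.

TRAJ_FORMAT_VERSION <- 1L

#' Write a trajectory to the versioned text format
#'
#' Header lines (`key value`) carry the box side, temperature, seed and the
#' per-chain sequences; each frame block starts with `frame <step> <energy>`
#' followed by one `x y z` line per bead in bead order.
#'
#' @param traj a `lattice_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  cfg <- traj$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# condensr trajectory v%d", TRAJ_FORMAT_VERSION),
    sprintf("box_side %d", cfg$box_side),
    sprintf("temperature %.10g", traj$temperature),
    sprintf("seed %d", traj$seed),
    sprintf("local_only %d", as.integer(traj$moves$local_only)),
    sprintf("n_chains %d", length(cfg$sequences))
  ), con)
  for (s in cfg$sequences) {
    writeLines(sprintf("chain %s %s", s$id, s$raw_residues), con)
  }
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("frame %d %.10g", traj$steps[i], traj$energies[i]), con)
    write.table(traj$frames[[i]], con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path trajectory file.
#' @return A `lattice_trajectory` (acceptance tallies are not round-tripped;
#'   `energy_drift` is recomputed as 0).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# condensr trajectory v", lines[1])) {
    stop("not a condensr trajectory file: ", path)
  }
  val <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    strsplit(ln, " +")[[1]][2]
  }
  box <- as.integer(val("box_side"))
  temperature <- as.numeric(val("temperature"))
  seed <- as.integer(val("seed"))
  local_only <- as.integer(val("local_only")) == 1L
  chain_lines <- grep("^chain ", lines, value = TRUE)
  seqs <- lapply(chain_lines, function(ln) {
    parts <- strsplit(ln, " +")[[1]]
    encode_sequence(parts[3], id = parts[2])
  })
  lens <- vapply(seqs, length, integer(1))
  frame_at <- grep("^frame ", lines)
  if (!length(frame_at)) stop("trajectory contains no frames")
  frames <- list(); steps <- integer(0); energies <- numeric(0)
  for (i in seq_along(frame_at)) {
    hdr <- strsplit(lines[frame_at[i]], " +")[[1]]
    steps[i] <- as.integer(hdr[2])
    energies[i] <- as.numeric(hdr[3])
    block <- lines[(frame_at[i] + 1):(frame_at[i] + sum(lens))]
    frames[[i]] <- matrix(as.integer(unlist(strsplit(block, " +"))),
                          ncol = 3, byrow = TRUE)
  }
  cfg <- lattice_config(frames[[length(frames)]],
                        rep(seq_along(seqs), lens), seqs, box)
  structure(
    list(config = cfg, frames = frames, steps = steps, energies = energies,
         temperature = temperature, seed = seed,
         moves = move_set(local_only = local_only),
         acceptance = NULL, energy_drift = 0),
    class = "lattice_trajectory")
}

#' Export a configuration or trajectory to XYZ for visualisation
#'
#' @param x a `lattice_config` or `lattice_trajectory`.
#' @param path output file.
#' @export
write_xyz <- function(x, path) {
  frames <- if (inherits(x, "lattice_trajectory")) x$frames else list(x$coords)
  cfg <- if (inherits(x, "lattice_trajectory")) x$config else x
  elem <- ifelse(cfg$sticker, "S", "C")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c(sprintf("%d", nrow(fr)), "condensr frame"), con)
    writeLines(sprintf("%s %d %d %d", elem, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Write a binodal (or any profile table) to TSV
#'
#' @param x data.frame (e.g. a `binodal` or `radial_profile`).
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an experimental binodal arm from TSV
#'
#' Expects columns `T` and `c` (temperature, concentration); extra columns
#' (e.g. a units field) are preserved as attributes.
#'
#' @param path TSV file.
#' @return data.frame with columns `T` and `c`.
#' @export
read_binodal_arm <- function(path) {
  df <- read.delim(path)
  if (!all(c("T", "c") %in% names(df))) {
    stop("binodal arm file needs columns 'T' and 'c'")
  }
  out <- df[, c("T", "c")]
  extra <- setdiff(names(df), c("T", "c"))
  for (e in extra) attr(out, e) <- df[[e]][1]
  out
}

#' Read a flat key-value run configuration
#'
#' Lines are `key = value` (or `key value`); `#` starts a comment;
#' `include <path>` splices another file (relative to the including file).
#' Values are coerced to numeric where possible; comma-separated values
#' become vectors.
#'
#' @param path config file.
#' @param defaults named list of defaults the file overrides.
#' @return Named list.
#' @export
read_run_config <- function(path, defaults = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    if (grepl("^include\\s", ln)) {
      inc <- file.path(dirname(path), trimws(sub("^include\\s+", "", ln)))
      out <- modifyList(out, read_run_config(inc))
      next
    }
    parts <- strsplit(ln, "\\s*=\\s*|\\s+")[[1]]
    if (length(parts) < 2) stop("cannot parse config line: ", ln)
    key <- parts[1]
    raw <- paste(parts[-1], collapse = " ")
    vals <- trimws(strsplit(raw, ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else
      if (length(vals) > 1) vals else raw
  }
  out
}

#' Physical defaults of the pipeline configuration
#'
#' Contact range sqrt(3) l.u., radial shell width 1/4 l.u., top-centrality
#' fraction 5%, simulation temperature grid 40-60, NCPR coefficient 0, and
#' optional unit-conversion constants (defaulting to 1, i.e. simulation
#' units; set them to published scaling factors to report Kelvin/molar).
#'
#' @return Named list of defaults, each overridable via [read_run_config()].
#' @export
default_run_config <- function() {
  list(contact_range = sqrt(3), shell_width = 0.25, top_fraction = 0.05,
       temperatures = seq(40, 60, by = 5), ncpr_coefficient = 0,
       reference_ncpr = 0, temperature_scale = 1, concentration_scale = 1,
       sweeps = 2000, snapshot_interval = 50, box_side = 40)
}

#' Write a run manifest
#'
#' Records the package version, seed, configuration (with an md5 hash) and
#' any result paths, as JSON; re-running a manifest's configuration and seed
#' reproduces deterministic outputs bit-identically.
#'
#' @param config named list (run configuration).
#' @param seed integer seed used for the run.
#' @param path output JSON path.
#' @param outputs optional named list/vector of output file paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seed, path, outputs = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  manifest <- list(
    package = "condensr",
    version = as.character(packageVersion("condensr")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Aggregate replicate values as mean and standard error
#'
#' Shared replicate-aggregation helper: given a data.frame of per-replicate
#' values and grouping columns, returns group means and standard errors
#' about the mean.
#'
#' @param df data.frame.
#' @param value name of the value column.
#' @param by character vector of grouping columns.
#' @return data.frame with `mean`, `se` and `n` per group.
#' @export
aggregate_replicates <- function(df, value, by) {
  sp <- split(df[[value]], df[by], drop = TRUE)
  keys <- do.call(rbind, strsplit(names(sp), "\\."))
  out <- data.frame(keys)
  names(out) <- by
  out$mean <- vapply(sp, mean, numeric(1))
  out$se <- vapply(sp, function(x) {
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  out$n <- vapply(sp, length, integer(1))
  rownames(out) <- NULL
  out
}
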