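#' Write snapshots to a multi-frame XYZ file
#'
#' One model per frame. The comment line carries `cycle=<c> replica=<r>
#' frame=<f>`; the element column encodes the copy label: `S` for the site
#' marker, `L<k>` for ligand copy k. Coordinates are written with 17
#' significant digits so a written archive reconstructs the exact double-
#' precision state (required for bit-for-bit resume).
#'
#' @param snapshots list of snapshots.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(snapshots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sn in snapshots) {
    st <- sn$state
    n <- nrow(st$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("cycle=%d replica=%d frame=%d",
                       sn$cycle, sn$replica, sn$frame), con)
    elem <- ifelse(st$copy_id == 0L, "S", paste0("L", st$copy_id))
    writeLines(sprintf("%s %.17g %.17g %.17g", elem,
                       st$positions[, 1], st$positions[, 2], st$positions[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file written by [write_xyz()]
#'
#' Velocities are not part of the XYZ format: restored states carry zero
#' velocities (the cascade engine regenerates velocities at every restart
#' anyway) and unit masses.
#'
#' @param path XYZ file.
#' @return list of snapshots.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("XYZ parse error at line %d: expected an atom count", i))
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ parse error at line %d: truncated frame", i))
    meta <- lines[i + 1L]
    kv <- regmatches(meta, gregexpr("(\\w+)=(-?\\d+)", meta))[[1]]
    md <- stats::setNames(
      as.integer(sub(".*=", "", kv)), sub("=.*", "", kv))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
      stop(sprintf("XYZ parse error at line %d: need 'element x y z'",
                   i + 1L + bad[1]))
    elem <- vapply(parts, `[[`, character(1), 1L)
    pos <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, 2:4)))),
                  n, 3, byrow = TRUE)
    if (anyNA(pos))
      stop(sprintf("XYZ parse error near line %d: non-numeric coordinate", i + 2L))
    copy_id <- rep(NA_integer_, n)
    copy_id[elem == "S"] <- 0L
    is_lig <- grepl("^L\\d+$", elem)
    copy_id[is_lig] <- as.integer(sub("^L", "", elem[is_lig]))
    if (anyNA(copy_id))
      stop(sprintf("XYZ parse error near line %d: unknown element label", i + 2L))
    st <- system_state(pos, matrix(0, n, 3), rep(1, n), copy_id)
    out[[length(out) + 1L]] <- snapshot(
      st, cycle = md[["cycle"]], replica = md[["replica"]],
      frame = md[["frame"]])
    i <- i + 2L + n
  }
  out
}

#' Write a finished run to a results directory
#'
#' Produces `cycles.csv` (cycle, replica, frame, rc to 9 significant digits,
#' selected flag), one XYZ archive per cycle, `paths.json` (back-traced
#' binding pathways, when a cutoff is set), and `manifest.json` (config echo,
#' seed, termination reason, package version, per-cycle archive checksums).
#'
#' @param result a [run_pacs()] result with its snapshot archive.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- result$table
  csv <- data.frame(cycle = tab$cycle, replica = tab$replica,
                    frame = tab$frame, rc = format_sig9(tab$rc),
                    selected = as.integer(tab$selected))
  utils::write.csv(csv, file.path(dir, "cycles.csv"), row.names = FALSE,
                   quote = FALSE)
  checksums <- character(0)
  if (!is.null(result$archive)) {
    for (cyc in seq_along(result$archive)) {
      f <- file.path(dir, sprintf("traj_cycle%04d.xyz", cyc))
      write_xyz(result$archive[[cyc]], f)
      checksums[sprintf("traj_cycle%04d.xyz", cyc)] <-
        unname(tools::md5sum(f))
    }
  }
  paths <- if (!is.na(result$config$cutoff) &&
               result$termination_reason == "cutoff")
    trace_binding_paths(result) else list()
  jsonlite::write_json(paths, file.path(dir, "paths.json"), digits = NA)
  manifest <- list(
    package = "pacsmd",
    version = as.character(utils::packageVersion("pacsmd")),
    seed = result$config$seed,
    config = serialize_config(result$config),
    termination_reason = result$termination_reason,
    cycles_completed = length(result$cycles),
    checksums = as.list(checksums),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write an MSM summary to a results directory
#'
#' Writes `msm.json` (lag, transition matrix, stationary distribution,
#' implied timescales) and `free_energy.csv` (rc_center, F).
#'
#' @param model a `transition_model` from [msm_profile()] or
#'   [profile_along_rc()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_msm <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(lag = model$lag, T = model$T, pi = model$pi,
         timescales = model$timescales, active_set = model$active_set,
         kBT = model$kBT),
    file.path(dir, "msm.json"), auto_unbox = TRUE, digits = NA)
  prof <- model$profile
  prof$rc_center <- format_sig9(prof$rc_center)
  prof$F <- format_sig9(prof$F)
  prof$pi <- format_sig9(prof$pi)
  utils::write.csv(prof, file.path(dir, "free_energy.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an atom-selection table
#'
#' Two whitespace-separated columns, `role index`, where role is `site` or
#' `L<k>` for ligand copy k; lines starting with `#` are comments.
#'
#' @param path text file.
#' @return an [atom_selection()].
#' @export
read_selection_table <- function(path) {
  tab <- utils::read.table(path, col.names = c("role", "index"),
                           colClasses = c("character", "integer"),
                           comment.char = "#")
  site <- tab$index[tab$role == "site"]
  lig_roles <- sort(unique(tab$role[grepl("^L\\d+$", tab$role)]))
  ligand <- lapply(lig_roles, function(r) tab$index[tab$role == r])
  atom_selection(ligand = ligand, site = site)
}

#' Build an atom selection from a PDB file
#'
#' Convenience for driving an external engine: selects the carbon atoms of a
#' ligand residue name and of one or more binding-site residues, the usual
#' definition of the ligand and site centres of mass.
#'
#' @param pdb_path PDB file.
#' @param ligand_resname residue name of the ligand (each residue instance
#'   becomes one copy).
#' @param site_resid residue number(s) defining the binding site.
#' @param elety_pattern atom-name filter (default: carbon atoms).
#' @return an [atom_selection()].
#' @export
selection_from_pdb <- function(pdb_path, ligand_resname, site_resid,
                               elety_pattern = "^C") {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  carbon <- grepl(elety_pattern, at$elety)
  site <- which(at$resno %in% site_resid & carbon & at$resid != ligand_resname)
  lig_rows <- which(at$resid == ligand_resname & carbon)
  ligand <- split(lig_rows, paste(at$chain[lig_rows], at$resno[lig_rows]))
  names(ligand) <- NULL
  atom_selection(ligand = ligand, site = site)
}
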