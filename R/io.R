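#' Write velocity fields to a TSV file with a JSON sidecar
#'
#' Serializes one or more velocity fields as a headered TSV with columns
#' `frame`, `region_id`, `x`, `y`, `vx`, `vy` (full double precision) and a
#' JSON metadata sidecar at `<path>.json` holding the declared units, the
#' frame times and the footprint polygon when present. The round trip
#' through [read_field()] is lossless.
#'
#' @param fields A [velocity_field()] or list of them.
#' @param path Output TSV path.
#' @param units Length unit of the coordinates (e.g. `"r0"` or `"um"`).
#' @return `path`, invisibly.
#' @export
write_field <- function(fields, path, units = "r0") {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    data.frame(frame = i, region_id = seq_len(nrow(f$positions)),
               x = f$positions[, 1], y = f$positions[, 2],
               vx = f$velocities[, 1], vy = f$velocities[, 2])
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- Filter(Negate(is.null), lapply(fields, `[[`, "footprint"))
  meta <- list(units = units,
               times = vapply(fields, `[[`, numeric(1), "time"),
               n_frames = length(fields))
  if (length(fp) > 0) meta$footprint <- unname(apply(fp[[1]], 1, c, simplify = FALSE))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read velocity fields from a TSV file
#'
#' Reads a field table written by [write_field()] (or exported by external
#' optical-flow software in the same schema). The JSON sidecar
#' `<path>.json` must be present and declare the units. Records are
#' regrouped by `frame` and sorted by `region_id`, so row order in the file
#' does not matter. Malformed rows and missing columns are reported by name
#' and line.
#'
#' @param path TSV path.
#' @return A list of [velocity_field()] objects, with attribute `"units"`.
#' @export
read_field <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("format error: metadata sidecar not found: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$units)) stop("format error: sidecar declares no units")
  tab <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("frame", "region_id", "x", "y", "vx", "vy")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  }
  for (cn in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[cn]]))))
    if (length(bad) > 0) {
      stop("format error: non-numeric or non-finite '", cn, "' at line(s) ",
           paste(utils::head(bad + 1, 5), collapse = ", "))
    }
  }
  if (anyDuplicated(tab[c("frame", "region_id")])) {
    stop("format error: duplicate (frame, region_id) records")
  }
  footprint <- if (!is.null(meta$footprint)) {
    fp <- meta$footprint
    if (is.list(fp)) do.call(rbind, lapply(fp, as.numeric)) else
      matrix(as.numeric(fp), ncol = 2)
  }
  frames <- sort(unique(tab$frame))
  fields <- lapply(seq_along(frames), function(i) {
    sub <- tab[tab$frame == frames[i], ]
    sub <- sub[order(sub$region_id), ]
    t_i <- if (!is.null(meta$times) && i <= length(meta$times)) {
      as.numeric(meta$times[i])
    } else {
      NA_real_
    }
    velocity_field(cbind(sub$x, sub$y), cbind(sub$vx, sub$vy),
                   time = t_i, footprint = footprint)
  })
  attr(fields, "units") <- meta$units
  fields
}

#' Write a trajectory to TSV plus JSON metadata
#'
#' Columns `frame`, `time`, `particle_id`, `x`, `y`, `phi`, `vx`, `vy`
#' (velocities by forward frame difference; the last frame carries `NA`).
#' The sidecar `<path>.json` records the model parameters, seed and the
#' topology edge list.
#'
#' @param traj A [simulate_sheet()] trajectory.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nf <- length(traj$frames)
  dt <- traj$sample_interval
  rows <- lapply(seq_len(nf), function(t) {
    p <- traj$frames[[t]]$positions
    v <- if (t < nf) (traj$frames[[t + 1]]$positions - p) / dt else
      matrix(NA_real_, nrow(p), 2)
    data.frame(frame = t, time = traj$times[t],
               particle_id = seq_len(nrow(p)), x = p[, 1], y = p[, 2],
               phi = traj$frames[[t]]$headings, vx = v[, 1], vy = v[, 2])
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(params = unclass(traj$params), seed = traj$seed,
               sample_interval = traj$sample_interval,
               edges = unname(apply(traj$topology$edges, 1, c,
                                    simplify = FALSE)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
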