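ROLE_CODE <- c(MEMBRANE = "M", NUCLEUS = "N", ACTIN = "A", ACTIN_HEAD = "H")

prov_lines <- function(cfg, prefix = "#") {
  sprintf("%s cellspring %s; config %s; seed %d", prefix,
          as.character(packageVersion("cellspring")), config_hash(cfg),
          cfg$seed)
}

fmt <- function(x) sprintf("%.12g", x)

#' Write a trajectory to disk
#'
#' Extended-XYZ (`format = "xyz"`, the default): one block per frame, a
#' count line, then a comment line carrying the frame time and energy
#' breakdown as `key=value` pairs; the element column encodes the bead
#' role (M = membrane, N = nucleus, A = actin, H = actin head) and the z
#' column is 0, so standard molecular viewers open the file. Positions are
#' printed with 12 significant digits.
#'
#' CSV (`format = "csv"`): provenance comments, then
#' `frame,bead,role,filament_id,x,y` rows.
#'
#' @param trajectory A `cell_trajectory`.
#' @param path Output file.
#' @param format `"xyz"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("xyz", "csv")) {
  format <- match.arg(format)
  cfg <- trajectory$config
  en <- trajectory$energies
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (q in seq_along(trajectory$frames)) {
      fr <- trajectory$frames[[q]]
      n <- nrow(fr$positions)
      writeLines(as.character(n), con)
      comment <- paste0(
        'Properties=species:S:1:pos:R:3 time=', fmt(fr$time),
        ' stretch=', fmt(en$stretch[q]), ' bend=', fmt(en$bend[q]),
        ' attraction=', fmt(en$attraction[q]),
        ' repulsion=', fmt(en$repulsion[q]), ' area=', fmt(en$area[q]),
        ' total=', fmt(en$total[q]),
        ' provenance="cellspring ', packageVersion("cellspring"),
        '; config ', config_hash(cfg), '; seed ', cfg$seed, '"')
      writeLines(comment, con)
      writeLines(paste(ROLE_CODE[fr$role], fmt(fr$positions[, 1]),
                       fmt(fr$positions[, 2]), "0"), con)
    }
  } else {
    writeLines(prov_lines(cfg), con)
    writeLines("frame,bead,role,filament_id,x,y", con)
    for (q in seq_along(trajectory$frames)) {
      fr <- trajectory$frames[[q]]
      writeLines(paste(q, seq_len(nrow(fr$positions)), fr$role,
                       fr$filament_id, fmt(fr$positions[, 1]),
                       fmt(fr$positions[, 2]), sep = ","), con)
    }
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Roundtrips roles exactly and positions to the printed precision. The
#' generating configuration and energies are not reconstructed; frame
#' times are taken from the XYZ comment line (frame index for CSV input).
#'
#' @param path File to read.
#' @param format `"xyz"` or `"csv"`; guessed from the extension by default.
#' @return A `cell_trajectory` (frames, times; config `NULL`).
#' @export
read_trajectory <- function(path,
                            format = if (grepl("\\.csv$", path)) "csv" else "xyz") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- match.arg(format, c("xyz", "csv"))
  code2role <- setNames(names(ROLE_CODE), ROLE_CODE)
  frames <- list()
  times <- numeric()
  if (format == "xyz") {
    lines <- readLines(path)
    ln <- 1L
    while (ln <= length(lines)) {
      if (!grepl("^\\s*\\d+\\s*$", lines[ln]))
        stop("malformed trajectory: expected bead count at line ", ln,
             call. = FALSE)
      n <- as.integer(lines[ln])
      if (ln + 1L + n > length(lines))
        stop("malformed trajectory: truncated frame starting at line ", ln,
             call. = FALSE)
      comment <- lines[ln + 1L]
      tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]][2]
      tm <- if (is.na(tm)) length(frames) else as.numeric(tm)
      rec <- strsplit(trimws(lines[(ln + 2L):(ln + 1L + n)]), "\\s+")
      bad <- which(lengths(rec) < 3L)
      if (length(bad))
        stop("malformed trajectory record at line ", ln + 1L + bad[1],
             call. = FALSE)
      species <- vapply(rec, `[[`, "", 1L)
      role <- code2role[species]
      if (anyNA(role))
        stop("unknown species code at line ", ln + 1L + which(is.na(role))[1],
             call. = FALSE)
      pos <- cbind(as.numeric(vapply(rec, `[[`, "", 2L)),
                   as.numeric(vapply(rec, `[[`, "", 3L)))
      if (anyNA(pos))
        stop("non-numeric coordinate in frame starting at line ", ln,
             call. = FALSE)
      frames[[length(frames) + 1L]] <- structure(
        list(positions = pos, velocities = matrix(0, n, 2),
             role = unname(role),
             filament_id = rep(-1L, n), time = tm),
        class = "cell_state")
      times <- c(times, tm)
      ln <- ln + 2L + n
    }
  } else {
    tab <- read.csv(path, comment.char = "#")
    need <- c("frame", "bead", "role", "filament_id", "x", "y")
    if (!all(need %in% names(tab)))
      stop("malformed trajectory CSV: need columns ",
           paste(need, collapse = ", "), call. = FALSE)
    for (q in sort(unique(tab$frame))) {
      part <- tab[tab$frame == q, ]
      part <- part[order(part$bead), ]
      frames[[length(frames) + 1L]] <- structure(
        list(positions = cbind(part$x, part$y),
             velocities = matrix(0, nrow(part), 2),
             role = as.character(part$role),
             filament_id = as.integer(part$filament_id), time = q),
        class = "cell_state")
      times <- c(times, q)
    }
  }
  structure(list(frames = frames, times = times, energies = NULL,
                 events = NULL, config = NULL),
            class = "cell_trajectory")
}

#' Write per-frame morphometrics as CSV
#'
#' Fixed header `frame_time, projection_length, n_protrusions, cell_area,
#' circularity, persistence_fraction`; one row per frame, plus a final
#' trajectory-level summary row holding only `persistence_fraction`.
#' Provenance (package version, config hash, seed) is written as comment
#' lines.
#'
#' @param metrics Output of [measure_trajectory()].
#' @param path Output file.
#' @param cfg Optional [sim_config()] for the provenance header.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(prov_lines(cfg), con)
  m <- metrics
  m$persistence_fraction <- NA_real_
  summary_row <- data.frame(frame_time = NA_real_, projection_length = NA_real_,
                            n_protrusions = NA_integer_, cell_area = NA_real_,
                            circularity = NA_real_,
                            persistence_fraction =
                              attr(metrics, "persistence_fraction"))
  write.csv(rbind(m, summary_row), con, row.names = FALSE)
  invisible(path)
}

#' Render a cell contour as SVG
#'
#' Draws the membrane ring as a closed polyline, the nuclear ring, the
#' actin filaments as polylines with their head beads marked, on
#' equal-aspect axes with deterministic styling (the same frame always
#' yields a byte-identical file).
#'
#' @param state A `cell_state`.
#' @param path Output `.svg` file.
#' @param topology Optional `cell_topology`; when given, filament beads
#'   inserted by growth are drawn in their chain order.
#' @return `path`, invisibly.
#' @export
render_contour <- function(state, path, topology = NULL) {
  p <- state$positions
  pad <- 2
  xr <- range(p[, 1]) + c(-pad, pad)
  yr <- range(p[, 2]) + c(-pad, pad)
  w <- 480
  h <- round(w * diff(yr) / diff(xr))
  sx <- function(x) (x - xr[1]) / diff(xr) * w
  sy <- function(y) (yr[2] - y) / diff(yr) * h  # flip: SVG y grows downward
  pts <- function(idx) paste(sprintf("%.3f,%.3f", sx(p[idx, 1]),
                                     sy(p[idx, 2])), collapse = " ")
  fil_order <- function(f) {
    idx <- which(state$filament_id == f)
    if (is.null(topology)) return(idx)
    # walk the bond chain from the anchored base to the head
    bd <- topology$bonds
    onf <- bd[state$filament_id[bd$i] == f & state$filament_id[bd$j] == f, ]
    nbr <- split(c(onf$j, onf$i), c(onf$i, onf$j))
    base <- idx[state$role[idx] != "ACTIN_HEAD" &
                  vapply(as.character(idx),
                         function(q) length(nbr[[q]]) == 1L, TRUE)]
    cur <- if (length(base)) base[1] else idx[1]
    chain <- cur
    repeat {
      nxt <- setdiff(nbr[[as.character(cur)]], chain)
      if (length(nxt) == 0L) break
      cur <- nxt[1]
      chain <- c(chain, cur)
    }
    chain
  }

  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    sprintf('<!-- cellspring %s; t=%s -->',
            as.character(packageVersion("cellspring")), fmt(state$time)),
    '<rect width="100%" height="100%" fill="white"/>')
  mem <- which(state$role == "MEMBRANE")
  nuc <- which(state$role == "NUCLEUS")
  out <- c(out, sprintf(
    '<polygon points="%s" fill="none" stroke="#1f77b4" stroke-width="2"/>',
    pts(mem)))
  out <- c(out, sprintf(
    '<polygon points="%s" fill="#d0d0f0" stroke="#4040a0" stroke-width="1.5"/>',
    pts(nuc)))
  for (f in sort(unique(state$filament_id[state$filament_id > 0L]))) {
    chain <- fil_order(f)
    out <- c(out, sprintf(
      '<polyline points="%s" fill="none" stroke="#d62728" stroke-width="1"/>',
      pts(chain)))
    hd <- which(state$role == "ACTIN_HEAD" & state$filament_id == f)
    out <- c(out, sprintf(
      '<circle cx="%.3f" cy="%.3f" r="3" fill="#d62728"/>',
      sx(p[hd, 1]), sy(p[hd, 2])))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
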