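# Domain types and I/O for path-ensemble tables and atomic configurations.

ppa_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ppa_error")))
}

#' Interface set along the order parameter
#'
#' A strictly increasing sequence of interface positions
#' \eqn{\lambda_0 < \lambda_1 < \dots < \lambda_n} (in the units of the order
#' parameter; Angstrom for an interionic distance). The first and last values
#' are the reactant and product state boundaries \eqn{\lambda_A} and
#' \eqn{\lambda_B}.
#'
#' @param lambdas numeric vector of length >= 2, strictly increasing.
#' @return An object of class `ppa_interfaces` with elements `lambdas`,
#'   `lam_A` and `lam_B`.
#' @examples
#' ppa_interfaces(c(3.2, 3.4, 3.6, 3.8, 4.1, 7.0))
#' @export
ppa_interfaces <- function(lambdas) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2L)
    ppa_error("an interface set needs at least two interfaces", "ppa_value_error")
  if (any(diff(lambdas) <= 0))
    ppa_error("interfaces must be strictly increasing", "ppa_value_error")
  structure(list(lambdas = lambdas,
                 lam_A = lambdas[1L],
                 lam_B = lambdas[length(lambdas)]),
            class = "ppa_interfaces")
}

#' A single sampled path
#'
#' One accepted path from a path-sampling run: a frame table (time in fs,
#' order parameter `lambda`, plus any number of collective-variable columns)
#' together with its ensemble metadata. Times must be strictly increasing;
#' `weight` is the statistical weight of the path (1 before reweighting).
#'
#' @param path_id identifier, coerced to character.
#' @param frames data.frame with columns `time`, `lambda` and optionally
#'   further numeric CV columns.
#' @param ensemble ensemble label, e.g. `"0-"`, `"0+"`, `"1+"`.
#' @param mc_cycle nonnegative integer Monte Carlo cycle number.
#' @param weight positive statistical weight.
#' @param start_side,end_side `"A"` or `"B"`.
#' @return An object of class `ppa_path`.
#' @export
ppa_path <- function(path_id, frames, ensemble = "0+", mc_cycle = 0,
                     weight = 1, start_side = "A", end_side = "A") {
  if (!is.data.frame(frames) || nrow(frames) == 0L)
    ppa_error("frames must be a nonempty data.frame", "ppa_value_error")
  if (!all(c("time", "lambda") %in% names(frames)))
    ppa_error("frames needs 'time' and 'lambda' columns", "ppa_format_error")
  if (nrow(frames) > 1L && any(diff(frames$time) <= 0)) {
    bad <- which(diff(frames$time) <= 0)[1L] + 1L
    ppa_error(sprintf("path '%s': time not strictly increasing at frame %d",
                      path_id, bad), "ppa_format_error")
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    ppa_error(sprintf("path '%s': weight must be a positive scalar", path_id),
              "ppa_value_error")
  if (!start_side %in% c("A", "B") || !end_side %in% c("A", "B"))
    ppa_error("start_side/end_side must be 'A' or 'B'", "ppa_value_error")
  if (mc_cycle < 0)
    ppa_error("mc_cycle must be nonnegative", "ppa_value_error")
  structure(list(path_id = as.character(path_id),
                 ensemble = as.character(ensemble),
                 mc_cycle = as.integer(mc_cycle),
                 weight = as.numeric(weight),
                 start_side = start_side,
                 end_side = end_side,
                 frames = frames),
            class = "ppa_path")
}

#' @export
print.ppa_path <- function(x, ...) {
  cat(sprintf("<ppa_path '%s'> ensemble [%s], %d frames, weight %.4g, %s->%s\n",
              x$path_id, x$ensemble, nrow(x$frames), x$weight,
              x$start_side, x$end_side))
  invisible(x)
}

cv_names_of <- function(path) {
  setdiff(names(path$frames), c("time", "lambda"))
}

#' Validate ensemble boundary conditions of a path set
#'
#' Checks, for every path not in the `[0-]` ensemble, that the stored frames
#' satisfy the ensemble definition: the path starts inside state A
#' (\eqn{\lambda < \lambda_A}), ends inside A or B, and reaches its own
#' ensemble interface. `[0-]` paths must stay inside A. Violations raise an
#' error rather than being silently fixed.
#'
#' @param paths list of [ppa_path] objects.
#' @param interfaces a [ppa_interfaces] object.
#' @return Invisibly `TRUE` when all paths validate.
#' @export
validate_paths <- function(paths, interfaces) {
  stopifnot(inherits(interfaces, "ppa_interfaces"))
  lamA <- interfaces$lam_A
  lamB <- interfaces$lam_B
  for (p in paths) {
    lam <- p$frames$lambda
    if (p$ensemble == "0-") {
      if (max(lam) >= lamA)
        ppa_error(sprintf("path '%s' in [0-] leaves state A", p$path_id),
                  "ppa_value_error")
      next
    }
    i <- ensemble_index(p$ensemble)
    if (lam[1L] >= lamA)
      ppa_error(sprintf("path '%s' does not start inside state A", p$path_id),
                "ppa_value_error")
    last <- lam[length(lam)]
    if (last >= lamA && last < lamB)
      ppa_error(sprintf("path '%s' does not end inside state A or B", p$path_id),
                "ppa_value_error")
    if (max(lam) < interfaces$lambdas[i + 1L])
      ppa_error(sprintf("path '%s' does not cross its ensemble interface [%s]",
                        p$path_id, p$ensemble), "ppa_value_error")
  }
  invisible(TRUE)
}

ensemble_index <- function(label) {
  # "[i+]" labels -> integer i; "0-" is not a plus ensemble
  if (!grepl("^[0-9]+\\+$", label))
    ppa_error(sprintf("not a [i+] ensemble label: '%s'", label),
              "ppa_value_error")
  as.integer(sub("\\+$", "", label))
}

#' Read a path ensemble from a frame table and a metadata table
#'
#' The frame table is a CSV with mandatory header
#' `path_id,frame,time_fs,lambda,<cv1>,...` (0-based frame index); the
#' metadata table has columns
#' `path_id,ensemble,mc_cycle,weight,start_side,end_side`. Every `path_id`
#' appearing in the frame table must appear exactly once in the metadata.
#'
#' @param path_file CSV file of per-frame records.
#' @param meta_file CSV file of per-path metadata.
#' @return A list of [ppa_path] objects, ordered by (ensemble, mc_cycle).
#' @seealso [write_path_table()]
#' @export
read_path_table <- function(path_file, meta_file) {
  frames <- utils::read.csv(path_file, check.names = FALSE)
  meta <- utils::read.csv(meta_file, check.names = FALSE)
  need_f <- c("path_id", "frame", "time_fs", "lambda")
  need_m <- c("path_id", "ensemble", "mc_cycle", "weight",
              "start_side", "end_side")
  if (!all(need_f %in% names(frames)))
    ppa_error(sprintf("frame table lacks columns: %s",
                      paste(setdiff(need_f, names(frames)), collapse = ", ")),
              "ppa_format_error")
  if (!all(need_m %in% names(meta)))
    ppa_error(sprintf("metadata table lacks columns: %s",
                      paste(setdiff(need_m, names(meta)), collapse = ", ")),
              "ppa_format_error")
  meta$path_id <- as.character(meta$path_id)
  frames$path_id <- as.character(frames$path_id)
  dup <- meta$path_id[duplicated(meta$path_id)]
  if (length(dup))
    ppa_error(sprintf("duplicate path_id in metadata: '%s'", dup[1L]),
              "ppa_format_error")
  unknown <- setdiff(unique(frames$path_id), meta$path_id)
  if (length(unknown))
    ppa_error(sprintf("frame table references unknown path_id '%s'",
                      unknown[1L]), "ppa_format_error")
  cvs <- setdiff(names(frames), need_f)
  split_frames <- split(frames, frames$path_id)
  meta <- meta[order(meta$ensemble, meta$mc_cycle), , drop = FALSE]
  paths <- vector("list", nrow(meta))
  for (k in seq_len(nrow(meta))) {
    id <- meta$path_id[k]
    fr <- split_frames[[id]]
    if (is.null(fr))
      ppa_error(sprintf("no frames for path_id '%s'", id), "ppa_format_error")
    fr <- fr[order(fr$frame), , drop = FALSE]
    fdf <- data.frame(time = fr$time_fs, lambda = fr$lambda)
    for (cv in cvs) fdf[[cv]] <- fr[[cv]]
    paths[[k]] <- ppa_path(id, fdf,
                           ensemble = meta$ensemble[k],
                           mc_cycle = meta$mc_cycle[k],
                           weight = meta$weight[k],
                           start_side = meta$start_side[k],
                           end_side = meta$end_side[k])
  }
  paths
}

fmt10 <- function(x) {
  # 10 significant digits so write -> read round-trips at analysis tolerance
  formatC(x, digits = 10, format = "g")
}

#' Write a path ensemble to a frame table and a metadata table
#'
#' Inverse of [read_path_table()]. Numeric fields are written with 10
#' significant digits so that a read/write cycle is stable at analysis
#' tolerance.
#'
#' @param paths list of [ppa_path] objects.
#' @param path_file,meta_file destination CSV paths.
#' @return Invisibly `NULL`.
#' @export
write_path_table <- function(paths, path_file, meta_file) {
  if (!length(paths)) ppa_error("no paths to write", "ppa_value_error")
  cvs <- cv_names_of(paths[[1L]])
  con <- tryCatch(file(path_file, "w"),
                  error = function(e) ppa_error(
                    sprintf("cannot open '%s' for writing", path_file),
                    "ppa_io_error"))
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("path_id", "frame", "time_fs", "lambda", cvs),
                   collapse = ","), con)
  for (p in paths) {
    fr <- p$frames
    cols <- cbind(p$path_id, seq_len(nrow(fr)) - 1L, fmt10(fr$time),
                  fmt10(fr$lambda))
    for (cv in cvs) cols <- cbind(cols, fmt10(fr[[cv]]))
    writeLines(apply(cols, 1L, paste, collapse = ","), con)
  }
  meta <- data.frame(
    path_id = vapply(paths, `[[`, "", "path_id"),
    ensemble = vapply(paths, `[[`, "", "ensemble"),
    mc_cycle = vapply(paths, `[[`, 0L, "mc_cycle"),
    weight = fmt10(vapply(paths, `[[`, 0, "weight")),
    start_side = vapply(paths, `[[`, "", "start_side"),
    end_side = vapply(paths, `[[`, "", "end_side"))
  utils::write.csv(meta, meta_file, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Keep every stride-th path of the Monte Carlo chain
#'
#' Within each ensemble, paths are ranked by Monte Carlo cycle and the paths
#' whose 0-based rank is divisible by `stride` are kept, i.e. the first path
#' always survives and `ceiling(n / stride)` paths remain.
#'
#' @param paths list of [ppa_path] objects.
#' @param stride positive integer subsampling stride.
#' @return The retained paths, in (ensemble, mc_cycle) order.
#' @export
subsample_chain <- function(paths, stride) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1)
    ppa_error("stride must be a positive integer", "ppa_value_error")
  stride <- as.integer(stride)
  ens <- vapply(paths, `[[`, "", "ensemble")
  cyc <- vapply(paths, `[[`, 0L, "mc_cycle")
  keep <- logical(length(paths))
  for (e in unique(ens)) {
    idx <- which(ens == e)
    idx <- idx[order(cyc[idx])]
    keep[idx[seq(1L, length(idx), by = stride)]] <- TRUE
  }
  paths[keep]
}

#' Atomic configuration
#'
#' @param species character vector of element symbols.
#' @param coords numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param box optional numeric vector of three positive orthorhombic box edge
#'   lengths (Angstrom); `NULL` means no periodicity.
#' @return An object of class `ppa_config`.
#' @export
configuration <- function(species, coords, box = NULL) {
  coords <- as.matrix(coords)
  if (length(species) != nrow(coords))
    ppa_error("species and coords must have the same length", "ppa_value_error")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0))
      ppa_error("box must be three positive edge lengths", "ppa_value_error")
  }
  dimnames(coords) <- NULL
  structure(list(species = as.character(species), coords = coords, box = box),
            class = "ppa_config")
}

parse_xyz_comment <- function(line) {
  m <- regmatches(line, regexec('Lattice="([^"]+)"', line))[[1L]]
  if (length(m) == 2L) {
    v <- as.numeric(strsplit(trimws(m[2L]), "\\s+")[[1L]])
    if (length(v) != 9L)
      ppa_error("Lattice entry must contain 9 numbers", "ppa_format_error")
    off <- v[-c(1L, 5L, 9L)]
    if (any(abs(off) > 1e-10))
      ppa_error("only orthorhombic (diagonal) lattices are supported",
                "ppa_format_error")
    return(v[c(1L, 5L, 9L)])
  }
  m <- regmatches(line, regexec("box=([0-9eE+.,-]+)", line))[[1L]]
  if (length(m) == 2L) {
    v <- as.numeric(strsplit(m[2L], ",")[[1L]])
    if (length(v) != 3L)
      ppa_error("box entry must contain 3 edge lengths", "ppa_format_error")
    return(v)
  }
  NULL
}

#' Read configurations from an (extended) XYZ file
#'
#' Plain or extended XYZ; an orthorhombic box is picked up from the comment
#' line, either as `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"` or as `box=Lx,Ly,Lz`.
#' Coordinates are taken to be in Angstrom.
#'
#' @param file path to the XYZ file.
#' @return A list of [configuration()] objects, one per frame.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  cfgs <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      ppa_error(sprintf("bad atom count line at frame %d", frame),
                "ppa_format_error")
    if (pos + 1L + nat > length(lines))
      ppa_error(sprintf("atom-count mismatch at frame %d: %d atoms declared",
                        frame, nat), "ppa_format_error")
    box <- parse_xyz_comment(lines[pos + 1L])
    at <- lines[pos + 1L + seq_len(nat)]
    tok <- strsplit(trimws(at), "\\s+")
    if (any(vapply(tok, length, 0L) < 4L))
      ppa_error(sprintf("malformed atom line at frame %d", frame),
                "ppa_format_error")
    species <- vapply(tok, `[[`, "", 1L)
    coords <- t(vapply(tok, function(t)
      as.numeric(t[2:4]), numeric(3L)))
    if (anyNA(coords))
      ppa_error(sprintf("non-numeric coordinate at frame %d", frame),
                "ppa_format_error")
    cfgs[[frame + 1L]] <- configuration(species, coords, box)
    pos <- pos + 2L + nat
    frame <- frame + 1L
  }
  cfgs
}

#' Write configurations to an extended XYZ file
#'
#' @param cfgs a [configuration()] or list of them.
#' @param file destination path.
#' @return Invisibly `NULL`.
#' @export
write_xyz <- function(cfgs, file) {
  if (inherits(cfgs, "ppa_config")) cfgs <- list(cfgs)
  out <- character(0L)
  for (cfg in cfgs) {
    n <- length(cfg$species)
    comment <- if (is.null(cfg$box)) "" else
      sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
              fmt10(cfg$box[1L]), fmt10(cfg$box[2L]), fmt10(cfg$box[3L]))
    rows <- sprintf("%s %s %s %s", cfg$species,
                    fmt10(cfg$coords[, 1L]), fmt10(cfg$coords[, 2L]),
                    fmt10(cfg$coords[, 3L]))
    out <- c(out, as.character(n), comment, rows)
  }
  writeLines(out, file)
  invisible(NULL)
}

#' Query point for predictive power analysis
#'
#' A (crossing interface, reaction interface) pair
#' \eqn{\lambda_A \le \lambda^c \le \lambda^r}.
#'
#' @param lam_c crossing interface position.
#' @param lam_r reaction interface position.
#' @param lam_A reactant state boundary.
#' @return An object of class `ppa_query`.
#' @export
ppa_query <- function(lam_c, lam_r, lam_A = lam_c) {
  if (!(lam_A <= lam_c && lam_c <= lam_r))
    ppa_error("need lam_A <= lam_c <= lam_r", "ppa_value_error")
  structure(list(lam_c = lam_c, lam_r = lam_r, lam_A = lam_A),
            class = "ppa_query")
}
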