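#' Read a trajectory file
#'
#' Dispatches on format (guessed from the extension when `format = NULL`).
#' XYZ and GRO are parsed directly (GRO coordinates are converted from nm to
#' Angstrom); PDB and DCD go through the bio3d package.  A particle
#' selection keeps a fixed subset across all frames.
#'
#' @param path File path.
#' @param format One of `"xyz"`, `"gro"`, `"pdb"`, `"dcd"`, or `NULL`.
#' @param selection Particle subset: integer indices or a compact string
#'   like `"1-10,15"`; `NULL` keeps all.
#' @param topology For DCD, an optional PDB path providing particle names.
#' @return An `ldacv_traj`.
#' @export
read_trajectory <- function(path, format = NULL, selection = NULL,
                            topology = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  traj <- switch(format,
    xyz = read_xyz(path),
    gro = read_gro(path),
    pdb = read_pdb_traj(path),
    dcd = read_dcd_traj(path, topology),
    stop("unknown trajectory format: ", format, call. = FALSE))
  if (!is.null(selection)) {
    idx <- parse_selection(selection, dim(traj)[1])
    traj <- as_traj(unclass(traj)[idx, , , drop = FALSE],
                    ids = attr(traj, "ids")[idx])
  }
  message(sprintf("read %d frames of %d particles from %s",
                  dim(traj)[3], dim(traj)[1], path))
  traj
}

parse_selection <- function(selection, N) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
  } else if (is.character(selection)) {
    parts <- strsplit(selection, ",")[[1]]
    idx <- unlist(lapply(parts, function(p) {
      r <- as.integer(strsplit(p, "-")[[1]])
      if (length(r) == 2) seq(r[1], r[2]) else r
    }))
  } else {
    stop("unknown selection", call. = FALSE)
  }
  if (any(is.na(idx)) || any(idx < 1) || any(idx > N))
    stop("unknown selection: indices outside 1..", N, call. = FALSE)
  idx
}

#' @rdname read_trajectory
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ids <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ header at line ", i, call. = FALSE)
    if (i + 1 + n > length(lines))
      stop("truncated XYZ frame at line ", i, call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    ids <- vapply(tok, `[`, character(1), 1)
    xyz <- t(vapply(tok, function(tk) as.numeric(tk[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames in XYZ file", call. = FALSE)
  N <- vapply(frames, nrow, integer(1))
  if (length(unique(N)) != 1)
    stop("inconsistent atom count across XYZ frames", call. = FALSE)
  as_traj(frames, ids = ids)
}

#' Write a trajectory in XYZ format
#' @param traj Trajectory to write.
#' @param path Output path.
#' @param ids Optional element/particle names (default from the trajectory,
#'   else `"C"`).
#' @param digits Coordinate precision.
#' @export
write_xyz <- function(traj, path, ids = NULL, digits = 8) {
  traj <- as_traj(traj)
  N <- dim(traj)[1]
  if (is.null(ids)) ids <- attr(traj, "ids")
  if (is.null(ids)) ids <- rep("C", N)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_len(dim(traj)[3])) {
    writeLines(c(as.character(N), sprintf("frame %d", f)), con)
    X <- traj[, , f]
    writeLines(sprintf(fmt, ids, X[, 1], X[, 2], X[, 3]), con)
  }
  invisible(path)
}

#' @rdname read_trajectory
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ids <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (i + 1 > length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n)) stop("malformed GRO header at line ", i + 1, call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    ids <- trimws(substr(block, 11, 15))
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44))) * 10  # nm -> Angstrom
    frames[[length(frames) + 1]] <- xyz
    i <- i + 3 + n  # title, count, atoms, box line
  }
  if (length(frames) == 0) stop("no frames in GRO file", call. = FALSE)
  as_traj(frames, ids = ids)
}

#' @rdname read_trajectory
#' @export
read_pdb_traj <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz  # frames x (3N), ordered x1 y1 z1 x2 ...
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  N <- ncol(xyz) / 3
  a <- array(0, dim = c(N, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz)))
    a[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  as_traj(a, ids = pdb$atom$elety[seq_len(N)])
}

#' @rdname read_trajectory
#' @export
read_dcd_traj <- function(path, topology = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading DCD requires the bio3d package", call. = FALSE)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  N <- ncol(xyz) / 3
  a <- array(0, dim = c(N, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz)))
    a[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  ids <- NULL
  if (!is.null(topology)) {
    top <- read_pdb_traj(topology)
    ids <- attr(top, "ids")
  }
  as_traj(a, ids = ids)
}

#' Read / write plain-text label files (one integer per line)
#' @param path File path.
#' @return Integer vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  as.integer(readLines(path))
}

#' @rdname read_labels
#' @param labels Integer labels to write.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' Write a COLVAR-style time series
#'
#' Whitespace-separated columns with a `#! FIELDS ...` header line, the
#' dialect common to biasing engines and their plotting habits.
#'
#' @param data Data frame of per-frame values (e.g. a `langevin_run$colvar`).
#' @param path Output path.
#' @export
write_colvar <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(data), collapse = " ")), con)
  m <- vapply(as.data.frame(data), function(col) sprintf("%.10g", col),
              character(nrow(data)))
  writeLines(apply(matrix(m, nrow = nrow(data)), 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_colvar
#' @return `read_colvar()`: a tibble with the named columns.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", header))
    stop("not a COLVAR file (missing '#! FIELDS' header)", call. = FALSE)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", header), "[[:space:]]+")[[1]]
  d <- read.table(path, comment.char = "#")
  names(d) <- fields
  tibble::as_tibble(d)
}

#' Save / load a trained position-LDA model
#'
#' The model (coefficients, global reference mean and covariance, sign
#' convention, training metadata) is stored as structured JSON, a plain-text
#' format that round-trips at full double precision.
#'
#' @param model A [train_poslda()] model.
#' @param path File path.
#' @export
write_lda_model <- function(model, path) {
  model <- check_model(model)
  obj <- list(format = "ldacv-model", version = 1L,
              v = model$v, mean = model$ref$mean, cov = model$ref$cov,
              tau = model$ref$tau, sign = model$sign,
              states = as.list(model$states), meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "ldacv-model"))
    stop("not an ldacv model file", call. = FALSE)
  ref <- shape_ref(obj$mean, obj$cov, tau = obj$tau)
  structure(list(v = as.numeric(obj$v), ref = ref, sign = obj$sign,
                 states = unlist(obj$states),
                 meta = lapply(obj$meta, function(x) x)),
            class = "poslda_model")
}

#' Export LDA coefficients as plain text
#'
#' One `vx vy vz` triple per particle, for use by external engines.
#'
#' @inheritParams write_lda_model
#' @export
write_cv_coeffs <- function(model, path) {
  model <- check_model(model)
  V <- matrix(model$v, ncol = 3)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), path)
  invisible(path)
}

#' Save / load a state set
#' @param states A [state_set()].
#' @param path File path.
#' @export
write_state_set <- function(states, path) {
  stopifnot(inherits(states, "state_set"))
  obj <- list(format = "ldacv-states", version = 1L,
              weights = states$weights,
              refs = lapply(states$refs, function(r)
                list(mean = r$mean, cov = r$cov, tau = r$tau)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_state_set
#' @export
read_state_set <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "ldacv-states"))
    stop("not an ldacv state-set file", call. = FALSE)
  refs <- lapply(obj$refs, function(r) shape_ref(r$mean, r$cov, tau = r$tau))
  state_set(refs, weights = as.numeric(obj$weights))
}

#' Read a run configuration file
#'
#' A single YAML file holding input paths, state choices, LDA tolerances,
#' bias parameters, simulator parameters, seeds and an output directory.
#' Parameter domains are validated (`gamma > 1`, `sigma > 0`, `kappa > 0`)
#' and referenced input paths must exist.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("trajectory", "labels", "model", "topology")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured path does not exist: ", cfg[[key]], call. = FALSE)
  }
  b <- cfg$bias
  if (!is.null(b)) {
    if (!is.null(b$gamma) && b$gamma <= 1) stop("bias gamma must be > 1", call. = FALSE)
    if (!is.null(b$sigma) && b$sigma <= 0) stop("bias sigma must be > 0", call. = FALSE)
    if (!is.null(b$deltaE) && b$deltaE <= 0) stop("bias deltaE must be > 0", call. = FALSE)
  }
  if (!is.null(cfg$walls) && !is.null(cfg$walls$kappa) && cfg$walls$kappa <= 0)
    stop("wall kappa must be > 0", call. = FALSE)
  structure(cfg, class = "run_config")
}
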