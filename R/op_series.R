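# Per-frame order parameters: minimum-image distances between two atoms
# and proper dihedrals over four atoms.  These are the local constriction
# indicators used to diagnose gating (e.g. the selectivity-filter distance
# D1 = His173:NE2 -- Ser183:O and the cytoplasmic-end distance
# D2 = His67:CB -- Ile165:CD, plus the His173 ring dihedral CA-CG-CD2-NE2
# and the His67 sidechain dihedral CG-CB-CA-C).

#' Construct an order-parameter series
#' @noRd
new_op_series <- function(name, values, times, units, kind, atoms,
                          chain = NA_character_) {
  stopifnot(length(values) == length(times))
  structure(list(name = name, values = as.numeric(values),
                 times = as.numeric(times), units = units, kind = kind,
                 atoms = as.integer(atoms), chain = chain),
            class = "op_series")
}

#' @export
print.op_series <- function(x, ...) {
  cat("<op_series> ", x$name, " (", x$kind, ", ", x$units, "), ",
      length(x$values), " frames\n", sep = "")
  invisible(x)
}

#' Compute an order-parameter time series over a trajectory
#'
#' @param traj a `trajectory`.
#' @param selections list of 2 (distance) or 4 (dihedral)
#'   `atom_selection`s, each resolving to exactly one atom.
#' @param kind `"distance"` (minimum-image, Angstrom) or `"dihedral"`
#'   (degrees).
#' @param name series name (e.g. `"D1"`, `"chi_His67"`).
#' @param chain optional chain id tag carried into tidy exports (a tetramer
#'   is analyzed as four independent per-monomer series).
#' @return an `op_series`.
#' @export
op_series <- function(traj, selections, kind = c("distance", "dihedral"),
                      name = NULL, chain = NA_character_) {
  kind <- match.arg(kind)
  need <- if (kind == "distance") 2L else 4L
  if (length(selections) != need)
    stop(kind, " order parameter needs ", need, " selections", call. = FALSE)
  idx <- vapply(seq_along(selections), function(i)
    resolve_one(selections[[i]],
                what = paste0("order parameter '", name %||% kind,
                              "' selection ", i)),
    integer(1))
  nf <- n_frames(traj)
  vals <- numeric(nf)
  if (kind == "distance") {
    p <- t(traj$coords[idx[1], , ])   # nf x 3 after transpose
    q <- t(traj$coords[idx[2], , ])
    if (nf == 1L) { p <- matrix(p, ncol = 3); q <- matrix(q, ncol = 3) }
    # per-frame box (constant boxes are the common case)
    d <- p - q
    for (k in 1:3) {
      bk <- traj$box[k, ]
      d[, k] <- d[, k] - bk * round(d[, k] / bk)
    }
    vals <- sqrt(rowSums(d * d))
    units <- "A"
  } else {
    for (f in seq_len(nf)) {
      xyz <- traj$coords[, , f]
      vals[f] <- dihedral_angle(xyz[idx[1], ], xyz[idx[2], ],
                                xyz[idx[3], ], xyz[idx[4], ])
    }
    units <- "deg"
  }
  new_op_series(name %||% kind, vals, traj$times, units, kind, idx, chain)
}

#' Write order-parameter series to tidy CSV
#'
#' Long format: frame, time_ns, chain, op_name, value.
#'
#' @param ops an `op_series` or list of them.
#' @param path output path.
#' @export
write_op_csv <- function(ops, path) {
  if (inherits(ops, "op_series")) ops <- list(ops)
  df <- do.call(rbind, lapply(ops, function(o)
    data.frame(frame = seq_along(o$values), time_ns = o$times,
               chain = o$chain, op_name = o$name, value = o$values,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read order-parameter series back from tidy CSV
#'
#' @param path CSV path written by [write_op_csv()].
#' @return named list of `op_series` (units/kind metadata is not stored in
#'   the CSV and is marked unknown).
#' @export
read_op_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$op_name), function(d)
    new_op_series(d$op_name[1], d$value, d$time_ns, units = "unknown",
                  kind = "unknown", atoms = integer(0),
                  chain = d$chain[1]))
}
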